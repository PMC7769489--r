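#' Make a cube from corner coordinates
#'
#' Convenience constructor for the axis-aligned boxes used by the relation
#' functions: a named numeric vector `min_x,min_y,min_z,max_x,max_y,max_z`
#' (metres; y is up).
#' @param min,max Length-3 numeric vectors `(x, y, z)`.
#' @return Named numeric vector of length 6.
#' @export
cube <- function(min, max) {
  v <- c(min, max)
  names(v) <- COORD_COLS
  if (any(min > max)) stop("validation error: min_corner exceeds max_corner")
  v
}

as_box_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, 1L, 6L) else x
}

# per-axis projection overlap (negative value = gap) for box matrices n x 6
box_overlaps <- function(A, B) {
  cbind(pmin(A[, 4], B[, 4]) - pmax(A[, 1], B[, 1]),
        pmin(A[, 5], B[, 5]) - pmax(A[, 2], B[, 2]),
        pmin(A[, 6], B[, 6]) - pmax(A[, 3], B[, 3]))
}

box_centres <- function(A) (A[, 1:3, drop = FALSE] + A[, 4:6, drop = FALSE]) / 2

touching_vec <- function(A, B, eps) {
  ov <- box_overlaps(A, B)
  n_pos <- rowSums(ov > 0)
  pmin(ov[, 1], ov[, 2], ov[, 3]) >= -eps & n_pos >= 2L
}

#' Touching / non-touching relation between two cubes
#'
#' Two cubes touch when a pair of opposing faces lies within `eps_touch`
#' along one axis while their projections overlap (strictly) on the two other
#' axes, in any of the six face configurations, or when the boxes
#' interpenetrate. Exact face coincidence has measure zero in floating point,
#' hence the proximity band.
#'
#' @param a,b Cubes (see [cube()]).
#' @param params A [relation_params()] object.
#' @return `"T"` or `"N"`.
#' @export
touching <- function(a, b, params = relation_params()) {
  if (touching_vec(as_box_matrix(a), as_box_matrix(b), params$eps_touch))
    "T" else "N"
}

# Candidate logical matrix over base labels for box matrices; columns in
# shadow tie-break priority order. The directional tests follow the printed
# one-sided comparisons (Left: max vs max, Right: max vs min, and their y/z
# analogues); overlapping arrangements yield several candidates and the
# shadow rule picks one.
BASE_LABELS <- c("Ab", "Be", "L", "R", "F", "Ba", "In", "Sa")

candidates_vec <- function(A, B) {
  ov <- box_overlaps(A, B)
  exc_x <- ov[, 2] >= 0 & ov[, 3] >= 0   # y and z extents not disjoint
  exc_y <- ov[, 1] >= 0 & ov[, 3] >= 0
  exc_z <- ov[, 1] >= 0 & ov[, 2] >= 0
  # P inside Q (open-top containment); P must reach at least 1 mm below Q's
  # rim, so a cube merely resting on another (face contact at Q's top, where
  # the boundary comparison is float noise) never counts as contained
  inside <- function(P, Q)
    Q[, 1] <= P[, 1] & P[, 4] <= Q[, 4] &
    Q[, 3] <= P[, 3] & P[, 6] <= Q[, 6] &
    Q[, 2] + 1e-3 < P[, 5] & P[, 5] <= Q[, 5]
  cbind(Ab = A[, 5] > B[, 2] & exc_y,
        Be = A[, 5] < B[, 5] & exc_y,
        L  = A[, 4] < B[, 4] & exc_x,
        R  = A[, 4] > B[, 1] & exc_x,
        F  = A[, 6] > B[, 3] & exc_z,
        Ba = A[, 6] < B[, 6] & exc_z,
        In = inside(A, B),
        Sa = inside(B, A))
}

#' Candidate static base relations between two cubes
#'
#' Evaluates the one-sided directional tests (left/right, above/below,
#' front/back) with their overlap exception conditions, plus the containment
#' tests for inside/surround. Several labels may hold simultaneously; the
#' shadow rule ([static_relation()]) disambiguates.
#'
#' @param a,b Cubes.
#' @return Character vector, subset of
#'   `c("Ab","Be","L","R","F","Ba","In","Sa")`.
#' @export
candidate_static_relations <- function(a, b) {
  m <- candidates_vec(as_box_matrix(a), as_box_matrix(b))
  BASE_LABELS[as.logical(m[1L, ])]
}

shadow_vec <- function(A, B, label) {
  ov <- box_overlaps(A, B)
  pos <- function(x) pmax(x, 0)
  switch(label,
         Ab = , Be = pos(ov[, 1]) * pos(ov[, 3]),   # project along y: x-z area
         L = , R =   pos(ov[, 2]) * pos(ov[, 3]),   # along x: y-z area
         F = , Ba =  pos(ov[, 1]) * pos(ov[, 2]),   # along z: x-y area
         In = , Sa = pos(ov[, 1]) * pos(ov[, 3]),   # footprint overlap
         stop("domain error: no shadow for label '", label, "'"))
}

#' Shadow area of a static relation
#'
#' Area (m^2) of the rectangle intersection obtained by projecting the facing
#' surface of `a` onto the opposing surface of `b` along the axis of `label`.
#' Used to select a single static relation when several directional tests
#' hold.
#'
#' @param a,b Cubes.
#' @param label A base label from [candidate_static_relations()].
#' @return Non-negative area in m^2.
#' @export
shadow_area <- function(a, b, label) {
  A <- as_box_matrix(a); B <- as_box_matrix(b)
  if (!label %in% candidate_static_relations(a, b))
    stop("domain error: label '", label, "' not applicable to this pair")
  shadow_vec(A, B, label)[1L]
}

ssr_vec <- function(A, B, tnr_is_t, far, params) {
  n <- nrow(A)
  cand <- candidates_vec(A, B)
  dir_labels <- c("Ab", "Be", "L", "R", "F", "Ba")
  sh <- sapply(dir_labels, function(l) shadow_vec(A, B, l))
  if (n == 1L) sh <- matrix(sh, 1L, 6L, dimnames = list(NULL, dir_labels))
  sh[!cand[, dir_labels, drop = FALSE]] <- -Inf
  best <- max.col(sh, ties.method = "first")  # column order = tie priority
  ssr <- dir_labels[best]
  ssr[!is.finite(sh[cbind(seq_len(n), best)])] <- "O"  # no candidate at all
  ssr[ssr %in% c("L", "R", "F", "Ba")] <- "Ar"
  # containment beats the directional/shadow rule: it is the more specific fit
  ssr[cand[, "Sa"]] <- "Sa"
  ssr[cand[, "In"]] <- "In"
  up <- tnr_is_t
  ssr[up & ssr == "Ab"] <- "To"
  ssr[up & ssr == "Be"] <- "Bo"
  ssr[up & ssr == "Ar"] <- "ArT"
  ssr[far] <- "O"
  ssr
}

#' Static spatial relation between two cubes
#'
#' Among the candidate base relations the one with the biggest shadow wins;
#' ties break by the fixed priority Ab > Be > L > R > F > Ba. The
#' view-dependent side labels L/R/F/Ba collapse to "Ar" (around). When the
#' pair is touching, Ab/Be/Ar upgrade to To/Bo/ArT. Containment (In/Sa) takes
#' precedence over the directional labels. Pairs whose centre distance
#' exceeds `far_threshold`, or with no applicable relation, get "O".
#'
#' @param a,b Cubes.
#' @param tnr `"T"` or `"N"`, the touching relation for the same frame.
#' @param params A [relation_params()] object.
#' @return One SSR label.
#' @export
static_relation <- function(a, b, tnr = touching(a, b, params),
                            params = relation_params()) {
  A <- as_box_matrix(a); B <- as_box_matrix(b)
  d <- sqrt(sum((box_centres(A) - box_centres(B))^2))
  ssr_vec(A, B, tnr == "T", d > params$far_threshold, params)[1L]
}

dsr_scalar <- function(d_now, d_end, tnr_now_t, disp_a, disp_b, params) {
  if (d_now > params$far_threshold) return("Q")
  if (tnr_now_t) {
    ma <- disp_a > params$eps_move
    mb <- disp_b > params$eps_move
    if (ma && mb) return("MT")
    if (!ma && !mb) return("HT")
    return("FMT")
  }
  dd <- d_end - d_now
  if (-dd > params$xi_motion) return("GC")
  if (dd > params$xi_motion) return("MA")
  if (abs(dd) < params$xi_stable) return("S")
  "Q"
}

#' Dynamic spatial relation of a cube pair over a time window
#'
#' Evaluated at the first frame of a window of `theta + 1` frames, looking
#' forward: (1) a pair whose centre distance currently exceeds
#' `far_threshold` gets "Q"; (2) a touching pair gets MT / HT / FMT according
#' to whether both, neither, or exactly one centre moves more than `eps_move`
#' across the window; (3) otherwise a distance change beyond `xi_motion`
#' gives GC (closing) or MA (parting); (4) a distance change below
#' `xi_stable` gives "S"; (5) anything else is "Q".
#'
#' @param a_window,b_window Numeric matrices `(theta+1) x 6` of the two
#'   cubes' corner coordinates over the window.
#' @param params A [relation_params()] object.
#' @return One DSR label.
#' @export
dynamic_relation <- function(a_window, b_window, params = relation_params()) {
  A <- as_box_matrix(a_window); B <- as_box_matrix(b_window)
  if (nrow(A) < params$theta + 1L || nrow(B) < params$theta + 1L)
    stop("undefined-history error: window shorter than theta + 1 frames")
  ca <- box_centres(A); cb <- box_centres(B)
  n <- params$theta + 1L
  d_now <- sqrt(sum((ca[1L, ] - cb[1L, ])^2))
  d_end <- sqrt(sum((ca[n, ] - cb[n, ])^2))
  tnr_t <- touching_vec(A[1L, , drop = FALSE], B[1L, , drop = FALSE],
                        params$eps_touch)
  dsr_scalar(d_now, d_end, tnr_t,
             sqrt(sum((ca[n, ] - ca[1L, ])^2)),
             sqrt(sum((cb[n, ] - cb[1L, ])^2)), params)
}

# Vectorised relation stream for one object pair over all frames of a
# trajectory. Geometry only: U/A/X overrides happen in the eSEC builder.
pair_stream <- function(traj, a, b, params) {
  A <- traj$coords[, a, , drop = TRUE]
  B <- traj$coords[, b, , drop = TRUE]
  if (is.null(dim(A))) { A <- matrix(A, 1L, 6L); B <- matrix(B, 1L, 6L) }
  nf <- nrow(A)
  ca <- box_centres(A); cb <- box_centres(B)
  d <- sqrt(rowSums((ca - cb)^2))
  tnr_t <- touching_vec(A, B, params$eps_touch)
  far <- d > params$far_threshold
  ssr <- ssr_vec(A, B, tnr_t, far, params)
  fe <- pmin(seq_len(nf) + params$theta, nf)  # forward window, truncated at end
  disp_a <- sqrt(rowSums((ca[fe, , drop = FALSE] - ca)^2))
  disp_b <- sqrt(rowSums((cb[fe, , drop = FALSE] - cb)^2))
  dd <- d[fe] - d
  dsr <- rep("Q", nf)
  dsr[abs(dd) < params$xi_stable] <- "S"
  dsr[-dd > params$xi_motion] <- "GC"
  dsr[dd > params$xi_motion] <- "MA"
  ma <- disp_a > params$eps_move
  mb <- disp_b > params$eps_move
  dsr[tnr_t] <- ifelse(ma & mb, "MT", ifelse(!ma & !mb, "HT", "FMT"))[tnr_t]
  dsr[far] <- "Q"
  list(tnr = ifelse(tnr_t, "T", "N"), ssr = ssr, dsr = dsr, dist = d)
}

#' Per-frame relations of one object pair
#'
#' Debugging view of the geometric relation stream between two objects of a
#' trajectory, one row per frame (no role bookkeeping: absent/destroyed
#' objects are reported as A/X, but unborn-role masking does not apply here).
#'
#' @param traj An `esec_trajectory`.
#' @param a,b Object ids.
#' @param params A [relation_params()] object.
#' @return `data.frame` with columns `frame`, `tnr`, `ssr`, `dsr`, `dist`.
#' @export
pair_relations <- function(traj, a, b, params = relation_params()) {
  s <- pair_stream(traj, a, b, params)
  tnr <- s$tnr; ssr <- s$ssr; dsr <- s$dsr
  ab <- traj$absent[, a] | traj$absent[, b]
  de <- traj$destroyed[, a] | traj$destroyed[, b]
  tnr[ab] <- ssr[ab] <- dsr[ab] <- "A"
  tnr[de] <- ssr[de] <- dsr[de] <- "X"
  data.frame(frame = seq_along(tnr) - 1L, tnr = tnr, ssr = ssr, dsr = dsr,
             dist = s$dist, stringsAsFactors = FALSE)
}
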