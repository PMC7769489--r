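# Independent, deliberately naive re-implementations used as oracles.
# Scalar arithmetic and explicit branching throughout: these share no code
# path with the vectorised implementations they check.

# static relation by direct transliteration of the directional tests, the
# containment tests, and the max-shadow selection
naive_static <- function(a, b, tnr, far_threshold = 1.0) {
  ca <- (a[1:3] + a[4:6]) / 2
  cb <- (b[1:3] + b[4:6]) / 2
  if (sqrt(sum((ca - cb)^2)) > far_threshold) return("O")
  xmin <- function(v) v[1]; ymin <- function(v) v[2]; zmin <- function(v) v[3]
  xmax <- function(v) v[4]; ymax <- function(v) v[5]; zmax <- function(v) v[6]
  exc <- function(p, q, mn1, mx1, mn2, mx2) {
    !(mn1(p) > mx1(q)) && !(mn1(q) > mx1(p)) &&
      !(mn2(p) > mx2(q)) && !(mn2(q) > mx2(p))
  }
  cands <- character(0)
  if (xmax(a) < xmax(b) && exc(a, b, ymin, ymax, zmin, zmax))
    cands <- c(cands, "L")
  if (xmax(a) > xmin(b) && exc(a, b, ymin, ymax, zmin, zmax))
    cands <- c(cands, "R")
  if (ymax(a) < ymax(b) && exc(a, b, xmin, xmax, zmin, zmax))
    cands <- c(cands, "Be")
  if (ymax(a) > ymin(b) && exc(a, b, xmin, xmax, zmin, zmax))
    cands <- c(cands, "Ab")
  if (zmax(a) < zmax(b) && exc(a, b, xmin, xmax, ymin, ymax))
    cands <- c(cands, "Ba")
  if (zmax(a) > zmin(b) && exc(a, b, xmin, xmax, ymin, ymax))
    cands <- c(cands, "F")
  inside <- function(p, q)
    xmin(q) <= xmin(p) && xmax(p) <= xmax(q) &&
    zmin(q) <= zmin(p) && zmax(p) <= zmax(q) &&
    ymin(q) + 1e-3 < ymax(p) && ymax(p) <= ymax(q)
  if (inside(a, b)) return("In")
  if (inside(b, a)) return("Sa")
  if (!length(cands)) return("O")
  seg <- function(lo1, hi1, lo2, hi2) max(0, min(hi1, hi2) - max(lo1, lo2))
  shadow <- function(lab) {
    if (lab %in% c("Ab", "Be"))
      seg(xmin(a), xmax(a), xmin(b), xmax(b)) *
        seg(zmin(a), zmax(a), zmin(b), zmax(b))
    else if (lab %in% c("L", "R"))
      seg(ymin(a), ymax(a), ymin(b), ymax(b)) *
        seg(zmin(a), zmax(a), zmin(b), zmax(b))
    else
      seg(xmin(a), xmax(a), xmin(b), xmax(b)) *
        seg(ymin(a), ymax(a), ymin(b), ymax(b))
  }
  prio <- c("Ab", "Be", "L", "R", "F", "Ba")
  cands <- prio[prio %in% cands]
  sh <- vapply(cands, shadow, numeric(1))
  lab <- cands[which.max(sh)]
  if (lab %in% c("L", "R", "F", "Ba")) lab <- "Ar"
  if (identical(tnr, "T")) {
    if (lab == "Ab") lab <- "To"
    else if (lab == "Be") lab <- "Bo"
    else if (lab == "Ar") lab <- "ArT"
  }
  lab
}

# brute-force progressive decision: explicit scan over columns, checking the
# unique-argmax / margin / persists-to-end conditions literally
naive_classify <- function(test, training, margin = 0) {
  sim <- prefix_class_similarity(test, training)
  jmax <- nrow(sim)
  for (j in seq_len(jmax)) {
    w <- which.max(sim[j, ])
    lead_ok <- all(sim[j, -w] < sim[j, w]) &&
      (sim[j, w] - max(sim[j, -w])) / 100 >= margin
    persists <- TRUE
    for (j2 in seq(j, jmax))
      if (any(sim[j2, -which.max(sim[j, ])] >= sim[j2, which.max(sim[j, ])]))
        persists <- FALSE
    if (lead_ok && persists)
      return(list(label = colnames(sim)[w], column = j))
  }
  list(label = colnames(sim)[which.max(sim[jmax, ])], column = jmax)
}

# random valid eSEC matrix (adjacent columns distinct)
random_esec <- function(k, label = NULL) {
  repeat {
    tnr <- matrix(sample(c("T", "N", "U"), 10 * k, TRUE), 10, k)
    ssr <- matrix(sample(c("Ab", "Be", "Ar", "To", "O", "U"), 10 * k, TRUE),
                  10, k)
    dsr <- matrix(sample(c("MT", "HT", "GC", "MA", "S", "Q", "U"), 10 * k,
                         TRUE), 10, k)
    m <- rbind(tnr, ssr, dsr)
    distinct <- k == 1 ||
      all(vapply(seq_len(k - 1), function(j) any(m[, j] != m[, j + 1]),
                 logical(1)))
    if (distinct) return(esec(m, action_label = label))
  }
}

# constant-column eSEC built from a 30-symbol vector
column_esec <- function(col, k = 1, label = NULL) {
  m <- matrix(rep(col, k), 30, k)
  if (k > 1) for (j in seq(2, k, by = 2)) m[1, j] <- ifelse(m[1, j] == "T", "N", "T")
  esec(m, action_label = label)
}

# a plain 30-symbol column that satisfies the alphabet constraints
base_column <- function() {
  c(rep(c("T", "N"), 5),
    rep(c("To", "Ab"), 5),
    rep(c("HT", "S"), 5))
}

# random axis-aligned cube with rational corners in a small workspace
random_cube <- function() {
  lo <- round(stats::runif(3, -0.4, 0.3), 2)
  cube(lo, lo + round(stats::runif(3, 0.05, 0.4), 2))
}

# tiny hand-built trajectory: hand descends onto cube "a" and lifts it;
# "b" rests on the ground; optional distractor cubes are static
toy_trajectory <- function(n_distractors = 0, fps = 20) {
  nf <- 120
  ids <- c("ground", "hand", "a", "b",
           if (n_distractors > 0) paste0("d", seq_len(n_distractors)))
  coords <- array(NA_real_, c(nf, length(ids), 6),
                  dimnames = list(NULL, ids, NULL))
  box <- function(centre, s) c(centre - s / 2, centre + s / 2)
  for (f in seq_len(nf)) {
    t <- (f - 1) / fps
    coords[f, "ground", ] <- c(-1.5, -0.05, -1.5, 1.5, 0, 1.5)
    coords[f, "a", ] <- box(c(0.4, 0.05, 0), 0.1)
    coords[f, "b", ] <- box(c(-0.3, 0.06, 0.25), 0.12)
    # hand: far -> above a -> touch (1.5 s) -> lift with a -> stays
    hy <- if (t < 1) 1.2 - 0 else max(0.16, 1.2 - 0.5 * (t - 1))
    hx <- if (t < 1) 2 - 1.6 * t else 0.4
    coords[f, "hand", ] <- box(c(hx, hy, 0), 0.12)
    if (t >= 3.5) {  # lift a with the hand
      dy <- min(0.3, 0.4 * (t - 3.5))
      coords[f, "a", ] <- box(c(0.4, 0.05 + dy, 0), 0.1)
      coords[f, "hand", ] <- box(c(0.4, 0.16 + dy, 0), 0.12)
    }
    if (n_distractors > 0)
      for (d in seq_len(n_distractors))
        coords[f, paste0("d", d), ] <- box(c(-1.2, 0.05, -1.2 + 0.3 * d), 0.1)
  }
  trajectory(coords, fps = fps, hand_id = "hand", ground_id = "ground",
             action_label = "toy")
}
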