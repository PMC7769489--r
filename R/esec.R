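ROW_BLOCKS <- c("TNR", "SSR", "DSR")

esec_rownames <- function() {
  as.vector(vapply(ROW_BLOCKS, function(b) paste0(PAIR_ORDER, ":", b),
                   character(10)))
}

#' Assign fundamental-object roles
#'
#' Hand and ground are given; the numbered roles 1..3 go to the non-hand,
#' non-ground objects in the order in which they first gain or lose a
#' touching relation with any other object in the scene (ties broken by
#' lexicographic object id). Objects whose touching relations never change
#' are distractors and receive no role.
#'
#' @param traj An `esec_trajectory`.
#' @param params A [relation_params()] object.
#' @return An object of class `role_map`: list with `hand_id`, `ground_id`,
#'   `obj_ids` (character, length 0-3) and `birth_frame` (1-based frame of
#'   the first touching change per numbered role).
#' @export
assign_roles <- function(traj, params = relation_params()) {
  ids <- traj$object_ids
  cand <- setdiff(ids, c(traj$hand_id, traj$ground_id))
  nf <- n_frames(traj)
  first_change <- stats::setNames(rep(Inf, length(cand)), cand)
  if (nf >= 2L) {
    for (obj in cand) {
      others <- setdiff(ids, obj)
      for (other in others) {
        A <- traj$coords[, obj, , drop = TRUE]
        B <- traj$coords[, other, , drop = TRUE]
        tt <- touching_vec(A, B, params$eps_touch)
        chg <- which(tt[-1L] != tt[-nf])
        if (length(chg))
          first_change[obj] <- min(first_change[obj], chg[1L] + 1L)
      }
    }
  }
  born <- first_change[is.finite(first_change)]
  if (length(born) == 0L) stop("no action detected: no touching change occurs")
  ord <- order(born, names(born))
  obj_ids <- names(born)[ord][seq_len(min(3L, length(born)))]
  structure(list(hand_id = traj$hand_id, ground_id = traj$ground_id,
                 obj_ids = obj_ids,
                 birth_frame = as.integer(born[ord][seq_along(obj_ids)])),
            class = "role_map")
}

#' @export
print.role_map <- function(x, ...) {
  cat("Fundamental-object roles:\n  hand:", x$hand_id,
      "\n  ground:", x$ground_id, "\n")
  for (k in seq_along(x$obj_ids))
    cat(sprintf("  object %d: %s (first touching change at frame %d)\n",
                k, x$obj_ids[k], x$birth_frame[k]))
  invisible(x)
}

#' Construct an eSEC matrix object
#'
#' @param mat Character matrix with 30 rows (10 pairs x TNR/SSR/DSR blocks)
#'   and one column per relational event.
#' @param action_label Optional action class label.
#' @return An object of class `esec_matrix`.
#' @export
esec <- function(mat, action_label = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 30L)
    stop("format error: an eSEC matrix must have exactly 30 rows, got ",
         nrow(mat))
  if (ncol(mat) < 1L) stop("domain error: eSEC matrix has no columns")
  rownames(mat) <- esec_rownames()
  ok <- rbind(matrix(mat[1:10, ] %in% TNR_SYMBOLS, 10L),
              matrix(mat[11:20, ] %in% SSR_SYMBOLS, 10L),
              matrix(mat[21:30, ] %in% DSR_SYMBOLS, 10L))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("validation error: symbol '", mat[bad[1L], bad[2L]],
         "' invalid in row ", rownames(mat)[bad[1L]])
  }
  if (ncol(mat) > 1L) {
    same <- vapply(seq_len(ncol(mat) - 1L),
                   function(j) all(mat[, j] == mat[, j + 1L]), logical(1))
    if (any(same))
      stop("validation error: adjacent eSEC columns ", which(same)[1L],
           " and ", which(same)[1L] + 1L, " are identical")
  }
  structure(list(mat = mat, action_label = action_label),
            class = "esec_matrix")
}

#' @export
print.esec_matrix <- function(x, ...) {
  cat(sprintf("eSEC matrix: %d columns%s\n", ncol(x$mat),
              if (!is.null(x$action_label))
                paste0(" (action: ", x$action_label, ")") else ""))
  print(x$mat, quote = FALSE)
  invisible(x)
}

#' Number of event columns of an eSEC matrix
#' @param e An `esec_matrix`.
#' @export
n_columns <- function(e) ncol(e$mat)

#' Build the eSEC matrix of a trajectory
#'
#' Computes per-frame touching/static/dynamic relations for the ten
#' fundamental-object pairs, masks pairs whose numbered roles are not yet
#' born as "U" and pairs with absent/destroyed members as "A"/"X", then
#' compresses the frame stream into event columns: a new column is emitted
#' whenever the 30-symbol vector changes and the changed state persists for
#' at least `params$debounce` frames (shorter excursions are threshold
#' flicker and are dropped). The chain ends one debounce interval after the
#' hand's pairs have all returned to non-touching at far distance, or at the
#' trajectory end.
#'
#' @param traj An `esec_trajectory`.
#' @param params A [relation_params()] object.
#' @return An `esec_matrix` carrying the trajectory's `action_label`.
#' @export
build_esec <- function(traj, params = relation_params()) {
  roles <- assign_roles(traj, params)
  nf <- n_frames(traj)
  role_id <- c(H = roles$hand_id, G = roles$ground_id,
               stats::setNames(roles$obj_ids,
                               as.character(seq_along(roles$obj_ids))))
  birth <- c(H = 1L, G = 1L,
             stats::setNames(roles$birth_frame,
                             as.character(seq_along(roles$obj_ids))))
  frame_idx <- seq_len(nf)
  sym <- matrix("U", 30L, nf, dimnames = list(esec_rownames(), NULL))
  hand_pair <- grepl("H", PAIR_ORDER)
  hand_far <- matrix(TRUE, sum(hand_pair), nf)
  hand_touch <- matrix(FALSE, sum(hand_pair), nf)
  hp <- 0L
  for (k in seq_along(PAIR_ORDER)) {
    rs <- strsplit(PAIR_ORDER[k], ",")[[1]]
    if (hand_pair[k]) hp <- hp + 1L
    if (!all(rs %in% names(role_id))) next  # role never assigned: stays U
    a <- role_id[[rs[1]]]; b <- role_id[[rs[2]]]
    s <- pair_stream(traj, a, b, params)
    tnr <- s$tnr; ssr <- s$ssr; dsr <- s$dsr
    ab <- traj$absent[, a] | traj$absent[, b]
    de <- traj$destroyed[, a] | traj$destroyed[, b]
    tnr[ab] <- ssr[ab] <- dsr[ab] <- "A"
    tnr[de] <- ssr[de] <- dsr[de] <- "X"
    unborn <- frame_idx < max(birth[[rs[1]]], birth[[rs[2]]])
    tnr[unborn] <- ssr[unborn] <- dsr[unborn] <- "U"
    sym[k, ] <- tnr
    sym[k + 10L, ] <- ssr
    sym[k + 20L, ] <- dsr
    if (hand_pair[k]) {
      hand_far[hp, ] <- s$dist > params$far_threshold
      hand_touch[hp, ] <- tnr == "T"
    }
  }
  # terminate once the hand has withdrawn: all hand pairs far again after the
  # last hand contact
  last_touch <- if (any(hand_touch)) max(which(colSums(hand_touch) > 0)) else 1L
  far_all <- colSums(!hand_far) == 0L
  done <- which(far_all & frame_idx > last_touch)
  if (length(done))
    sym <- sym[, seq_len(min(nf, done[1L] + params$debounce)), drop = FALSE]
  # heal micro-flicker per row (runs of <= 2 frames absorb into the
  # preceding state) so that e.g. the one-frame HT blips at the stroke
  # reversals of a sawing motion do not fragment the sustained FMT state
  for (i in seq_len(nrow(sym))) {
    r <- rle(sym[i, ])
    short <- which(r$lengths <= 2L)
    for (j in short) if (j > 1L) r$values[j] <- r$values[j - 1L]
    sym[i, ] <- inverse.rle(r)
  }
  keys <- apply(sym, 2, paste, collapse = "\r")
  r <- rle(keys)
  keep <- r$lengths >= params$debounce
  keep[c(1L, length(keep))] <- TRUE  # start state and terminal state stay
  starts <- cumsum(c(1L, r$lengths))[-(length(r$lengths) + 1L)]
  starts <- starts[keep]
  kept <- keys[starts]
  dedup <- c(TRUE, kept[-1L] != kept[-length(kept)])
  cols <- starts[dedup]
  esec(sym[, cols, drop = FALSE], action_label = traj$action_label)
}

#' Write an eSEC matrix to TSV
#'
#' 30 data rows; first field is the row label `pair:block` (for instance
#' `H,1:TNR`), remaining fields one symbol per event column. `#` header
#' lines carry the action label.
#' @param e An `esec_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_esec <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(e$action_label))
    writeLines(paste0("# action_label: ", e$action_label), con)
  writeLines(paste(rownames(e$mat),
                   apply(e$mat, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read an eSEC matrix from TSV
#' @param path TSV path written by [write_esec()].
#' @return An `esec_matrix`.
#' @export
read_esec <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  label <- NULL
  lab_line <- grep("^# action_label:", hdr, value = TRUE)
  if (length(lab_line))
    label <- trimws(sub("^# action_label:", "", lab_line[1L]))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != 30L)
    stop("format error: expected 30 eSEC rows, got ", length(body))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields)) - 1L
  if (length(ncols) != 1L || ncols < 1L)
    stop("format error: ragged or empty eSEC rows")
  mat <- t(vapply(fields, function(f) f[-1L], character(ncols[1L])))
  if (ncols == 1L) mat <- matrix(vapply(fields, `[`, character(1), 2L), 30L, 1L)
  esec(mat, action_label = label)
}
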