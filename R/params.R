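#' Relation-extraction parameters
#'
#' Thresholds controlling how touching (TNR), static (SSR) and dynamic (DSR)
#' spatial relations are computed from cube geometry, and how per-frame
#' relation streams are compressed into event columns.
#'
#' The dynamic relations are judged over a sliding window of `theta` frames
#' (0.5 s at the default 20 fps), the time scale on which a hand typically
#' changes object relations during a manipulation.
#'
#' @param eps_touch Face-contact tolerance in metres. Two cubes touch when a
#'   pair of opposing faces is within this distance along one axis while their
#'   projections overlap on the two other axes, or when the boxes
#'   interpenetrate.
#' @param xi_stable Distance-change threshold (m) below which a non-touching
#'   pair counts as "Stable" over the window.
#' @param xi_motion Distance-change threshold (m) above which a non-touching
#'   pair counts as "Getting Closer" / "Moving Apart" over the window.
#' @param theta Dynamic-relation window length in frames.
#' @param eps_move Centre-displacement tolerance (m): an object counts as
#'   moving within the window when its centre travels farther than this.
#' @param far_threshold Centre-distance cutoff (m) beyond which a pair has no
#'   static relation ("O") and no dynamic relation ("Q").
#' @param debounce Minimum number of consecutive frames a changed 30-symbol
#'   relation vector must persist before it is emitted as a new eSEC column;
#'   shorter excursions are treated as threshold flicker and dropped.
#' @return An object of class `relation_params` (a validated list).
#' @export
relation_params <- function(eps_touch = 1e-3,
                            xi_stable = 0.01,
                            xi_motion = 0.1,
                            theta = 10L,
                            eps_move = 5e-3,
                            far_threshold = 1.0,
                            debounce = 12L) {
  p <- list(eps_touch = eps_touch, xi_stable = xi_stable,
            xi_motion = xi_motion, theta = as.integer(theta),
            eps_move = eps_move, far_threshold = far_threshold,
            debounce = as.integer(debounce))
  for (nm in c("eps_touch", "xi_stable", "xi_motion", "eps_move",
               "far_threshold")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("relation_params: '", nm, "' must be a positive number")
  }
  if (p$theta < 1L) stop("relation_params: 'theta' must be >= 1")
  if (p$debounce < 1L) stop("relation_params: 'debounce' must be >= 1")
  class(p) <- "relation_params"
  p
}

#' @export
print.relation_params <- function(x, ...) {
  cat("Relation extraction parameters:\n")
  cat(sprintf("  eps_touch     %g m (face-contact tolerance)\n", x$eps_touch))
  cat(sprintf("  xi_stable     %g m (Stable threshold)\n", x$xi_stable))
  cat(sprintf("  xi_motion     %g m (GC/MA threshold)\n", x$xi_motion))
  cat(sprintf("  theta         %d frames (dynamic window)\n", x$theta))
  cat(sprintf("  eps_move      %g m (centre-motion tolerance)\n", x$eps_move))
  cat(sprintf("  far_threshold %g m (O/Q cutoff)\n", x$far_threshold))
  cat(sprintf("  debounce      %d frames (event persistence)\n", x$debounce))
  invisible(x)
}

# Relation alphabets, exported as constants for validation and tests.

#' Relation alphabets
#'
#' Symbol sets for the three relation types. `U` marks a pair involving a
#' fundamental-object role that has not yet been assigned ("born"), `A` an
#' absent (occluded) object, `X` a destroyed object, `O`/`Q` a pair too far
#' apart to hold a static/dynamic relation.
#' @name alphabets
#' @export
TNR_SYMBOLS <- c("T", "N", "U", "A", "X")

#' @rdname alphabets
#' @export
SSR_SYMBOLS <- c("Ab", "Be", "Ar", "To", "Bo", "ArT", "In", "Sa", "O",
                 "U", "A", "X")

#' @rdname alphabets
#' @export
DSR_SYMBOLS <- c("MT", "HT", "FMT", "GC", "MA", "S", "Q", "U", "A", "X")

#' Fundamental-object pair order of the eSEC rows
#'
#' The ten unordered pairs of the five fundamental-object roles (H = hand,
#' G = ground, 1..3 = manipulated objects in order of first touching /
#' untouching change), in the fixed row order used by all eSEC matrices built
#' by this package. Rows 1-10 of an eSEC are the TNR of these pairs, rows
#' 11-20 the SSR, rows 21-30 the DSR.
#' @export
PAIR_ORDER <- c("H,1", "H,2", "H,3", "H,G", "1,2",
                "1,3", "1,G", "2,3", "2,G", "3,G")

#' The ten manipulation action classes
#' @export
ACTIONS <- c("chop", "cut", "hide", "uncover", "put_on_top",
             "take_down", "lay", "push", "shake", "stir")
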