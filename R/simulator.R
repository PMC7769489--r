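#' Simulation configuration
#'
#' Scene and duration parameters for the scripted scenario generator. The
#' per-action duration distributions (mean, SD and admissible range in
#' seconds) are the study's stimulus statistics; scenario durations are drawn
#' from a normal distribution truncated to the range. Motion speeds inside a
#' script are fixed; drawn duration variability is absorbed by the hold
#' phases, so the relational event sequence of an action class does not
#' depend on the drawn duration.
#'
#' @param fps Frames per second of the generated trajectories.
#' @param workspace_radius Radius (m) of the ring on which manipulated
#'   objects sit; transports move along this ring.
#' @param hand_size Edge length (m) of the hand cube.
#' @param cube_size Range (m) for generic manipulated-cube edge lengths.
#' @param n_distractors Range (count) of never-touched distractor cubes.
#' @param durations Data frame with columns `action`, `mean`, `sd`, `min`,
#'   `max` (seconds).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(fps = 20,
                              workspace_radius = 0.45,
                              hand_size = 0.12,
                              cube_size = c(0.10, 0.16),
                              n_distractors = c(1L, 3L),
                              durations = default_durations()) {
  stopifnot(fps > 0, workspace_radius > 0,
            all(durations$min <= durations$mean),
            all(durations$mean <= durations$max))
  structure(list(fps = fps, workspace_radius = workspace_radius,
                 hand_size = hand_size, cube_size = cube_size,
                 n_distractors = as.integer(n_distractors),
                 durations = durations),
            class = "simulation_config")
}

#' Default per-action scenario duration distributions (seconds)
#' @export
default_durations <- function() {
  data.frame(
    action = ACTIONS,
    mean = c(17.86, 19.50, 13.43, 12.66, 10.90, 10.60, 11.23, 12.56, 12.10, 20.23),
    sd   = c(3.56, 3.13, 2.40, 3.20, 2.006, 3.04, 1.79, 1.73, 2.05, 4.67),
    min  = c(13, 13, 9, 9, 8, 6, 8, 9, 9, 14),
    max  = c(27, 25, 20, 21, 16, 18, 15, 17, 17, 31),
    stringsAsFactors = FALSE)
}

#' Draw a scenario duration for an action
#'
#' Truncated-normal draw over the action's admissible range. The published
#' duration statistics are empirical moments of the recorded (range-limited)
#' stimuli, so the pre-truncation location is calibrated such that the mean
#' of the truncated distribution equals the published mean.
#' @param action One of [ACTIONS].
#' @param config A [simulation_config()].
#' @return Duration in seconds.
#' @export
sample_duration <- function(action, config = simulation_config()) {
  d <- config$durations[config$durations$action == action, ]
  if (nrow(d) != 1L) stop("domain error: unknown action '", action, "'")
  trunc_mean <- function(mu) {
    a <- (d$min - mu) / d$sd; b <- (d$max - mu) / d$sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + d$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - d$mean,
                       c(d$mean - 2 * d$sd, d$mean + 2 * d$sd))$root
  repeat {
    x <- stats::rnorm(1L, mu, d$sd)
    if (x >= d$min && x <= d$max) return(x)
  }
}

## ---- keyframe rig -----------------------------------------------------

rig_new <- function(hold_extra = 0) {
  e <- new.env(parent = emptyenv())
  e$t <- 0
  e$cur <- list()        # id -> current box (length-6)
  e$keys <- list()       # id -> list(times, boxes)
  e$flags <- list(absent = list(), destroyed = list())
  e$hold_extra <- hold_extra
  e$n_holds <- 0L
  e
}

rig_add <- function(rig, id, box) {
  rig$cur[[id]] <- box
  rig$keys[[id]] <- list(t = rig$t, b = list(box))
  invisible(rig)
}

rig_key <- function(rig, id) {
  k <- rig$keys[[id]]
  k$t <- c(k$t, rig$t)
  k$b <- c(k$b, list(rig$cur[[id]]))
  rig$keys[[id]] <- k
}

# translate ids rigidly by delta over dur seconds
rig_move <- function(rig, ids, delta, dur) {
  for (id in ids) rig_key(rig, id)
  rig$t <- rig$t + dur
  for (id in ids) {
    rig$cur[[id]] <- rig$cur[[id]] + rep(delta, 2L)
    rig_key(rig, id)
  }
  invisible(rig)
}

rig_hold <- function(rig, dt) {
  rig$t <- rig$t + dt + rig$hold_extra
  rig$n_holds <- rig$n_holds + 1L
  invisible(rig)
}

rig_wait <- function(rig, dt) {
  rig$t <- rig$t + dt
  invisible(rig)
}

# rotate ids about the vertical axis through the origin by dphi (radians),
# optionally climbing dy, over dur seconds; sampled densely so linear
# interpolation between keyframes tracks the circle
rig_arc <- function(rig, ids, dphi, dur, dy = 0) {
  steps <- max(2L, ceiling(abs(dphi) / (2 * pi / 120)), ceiling(dur * 25))
  for (s in seq_len(steps)) {
    a <- dphi / steps
    rot <- function(b) {
      ctr <- (b[1:3] + b[4:6]) / 2
      half <- (b[4:6] - b[1:3]) / 2
      x <- ctr[1] * cos(a) - ctr[3] * sin(a)
      z <- ctr[1] * sin(a) + ctr[3] * cos(a)
      ctr2 <- c(x, ctr[2] + dy / steps, z)
      c(ctr2 - half, ctr2 + half)
    }
    for (id in ids) rig_key(rig, id)
    rig$t <- rig$t + dur / steps
    for (id in ids) {
      rig$cur[[id]] <- rot(rig$cur[[id]])
      rig_key(rig, id)
    }
  }
  invisible(rig)
}

# tangential triangle-wave oscillation along the ring (for saw/stir/shake)
rig_oscillate <- function(rig, ids, dphi_amp, half_period, n_half) {
  dir <- 1
  for (i in seq_len(n_half)) {
    rig_arc(rig, ids, dir * dphi_amp, half_period)
    dir <- -dir
  }
  invisible(rig)
}

# linearly morph one object's box (used by lay); mover ids ride on top
rig_morph <- function(rig, id, new_box, dur, riders = character(0)) {
  old_top <- rig$cur[[id]][5]
  for (x in c(id, riders)) rig_key(rig, x)
  rig$t <- rig$t + dur
  rig$cur[[id]] <- new_box
  drop_y <- new_box[5] - old_top
  for (x in riders)
    rig$cur[[x]] <- rig$cur[[x]] + c(0, drop_y, 0, 0, drop_y, 0)
  for (x in c(id, riders)) rig_key(rig, x)
  invisible(rig)
}

rig_flag <- function(rig, id, which) {
  rig$flags[[which]][[id]] <- rig$t
  invisible(rig)
}

rig_sample <- function(rig, fps, ids, hand_id, ground_id,
                       action_label = NULL, seed = NULL, tail = 0.6) {
  total <- rig$t + tail
  nf <- max(2L, ceiling(total * fps))
  times <- (seq_len(nf) - 1L) / fps
  coords <- array(NA_real_, c(nf, length(ids), 6L),
                  dimnames = list(NULL, ids, COORD_COLS))
  for (id in ids) {
    k <- rig$keys[[id]]
    bm <- do.call(rbind, k$b)
    dup <- c(FALSE, diff(k$t) < 1e-12)   # consecutive keys at one instant
    tt <- k$t[!dup]; bm <- bm[!dup, , drop = FALSE]
    for (cc in 1:6) {
      coords[, id, cc] <- if (length(tt) == 1L) bm[1L, cc]
      else stats::approx(tt, bm[, cc], xout = times, rule = 2)$y
    }
  }
  flag_mat <- function(which) {
    m <- matrix(FALSE, nf, length(ids), dimnames = list(NULL, ids))
    for (id in names(rig$flags[[which]]))
      m[times >= rig$flags[[which]][[id]], id] <- TRUE
    m
  }
  trajectory(coords, fps = fps, hand_id = hand_id, ground_id = ground_id,
             absent = flag_mat("absent"), destroyed = flag_mat("destroyed"),
             action_label = action_label, seed = seed)
}

## ---- scene geometry ---------------------------------------------------

deg <- function(x) x * pi / 180

ring_pos <- function(r, phi, y) c(r * cos(phi), y, r * sin(phi))

box_at <- function(centre, size) {
  if (length(size) == 1L) size <- rep(size, 3L)
  c(centre - size / 2, centre + size / 2)
}

on_ground <- function(r, phi, size) {
  if (length(size) == 1L) size <- rep(size, 3L)
  box_at(ring_pos(r, phi, size[2] / 2), size)
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

sample_geometry <- function(action, config) {
  r <- config$workspace_radius
  g <- list(r = r, fps = config$fps, hand = config$hand_size)
  g$phi1 <- deg(-50 + runif1(-3, 3))
  g$phi2 <- g$phi1 + deg(55 + runif1(-4, 4))      # second object / target
  g$phi3 <- g$phi1 - deg(60 + runif1(-4, 4))      # hide's cover start
  g$phi_put <- g$phi1 - deg(70 + runif1(-3, 3))   # take/uncover put-down
  g$phi_start <- g$phi1 + deg(30 + runif1(-5, 5))   # enter beside object 1
  sz <- config$cube_size
  g$s1 <- runif1(sz[1], sz[2])
  g$s2 <- runif1(sz[1], sz[2])
  if (action %in% c("chop", "cut")) {
    g$s1 <- runif1(0.09, 0.10)          # tool
    g$s2 <- runif1(0.15, 0.17)          # target
  } else if (action == "hide") {
    g$s2 <- runif1(0.18, 0.20)          # target
    g$s1 <- g$s2 + 0.10                 # cover encloses target footprint
  } else if (action == "uncover") {
    g$s2 <- runif1(0.10, 0.11)
    g$s1 <- g$s2 + 0.10                 # cover footprint
    g$cover_h <- 0.14                   # flat cover: tall enough to enclose
  } else if (action == "stir") {
    g$s1 <- runif1(0.09, 0.10)          # short stirring tool
    g$s2 <- runif1(0.25, 0.27)          # container
  } else if (action == "take_down") {
    g$s1 <- runif1(0.10, 0.12)
    g$s2 <- runif1(0.13, 0.15)
  }
  nd <- sample(seq(config$n_distractors[1], config$n_distractors[2]), 1L)
  if (nd > 0L) {
    # distractors sit across the workspace, away from the hand's flight path
    ang <- g$phi1 + deg(180 + seq(-50, 50, length.out = max(nd, 2L))[seq_len(nd)] +
                          stats::runif(nd, -8, 8))
    g$distractors <- lapply(seq_len(nd), function(i)
      on_ground(runif1(0.85, 1.2), ang[i], runif1(0.08, 0.15)))
  } else g$distractors <- list()
  g
}

## ---- action scripts ---------------------------------------------------

# Motion speeds (m/s) are fixed: drawn duration variability goes into hold
# phases only, so the relational event sequence of a class is invariant.
# Phase lengths are sized so intended relational states persist well beyond
# the event debounce while threshold transients stay well below it.
V_FLY <- 1.2      # approach outside the workspace
V_GATE <- 0.5     # approach inside the workspace
V_DESC <- 0.8     # grasp descent
V_LIFT <- 0.38
V_ARC <- 0.32     # ring transport
V_PLACE <- 0.35   # put-down descent
V_COVER <- 0.18   # hide's covering sink
V_STRIKE <- 0.4   # chop strokes
V_WITHDRAW <- 2.2
V_FAST_DESC <- 0.7
CLEAR <- 0.45     # carry clearance above the landing surface

hand_start_box <- function(g) {
  box_at(c(2.2 * cos(g$phi_start), 0.9, 2.2 * sin(g$phi_start)), g$hand)
}

# move the hand from its current position to target centre in a straight
# line at speed v
fly_to <- function(rig, ids, target_centre, v) {
  cur <- (rig$cur[["hand"]][1:3] + rig$cur[["hand"]][4:6]) / 2
  delta <- target_centre - cur
  len <- sqrt(sum(delta^2))
  if (len < 1e-9) return(invisible(rig))
  rig_move(rig, ids, delta, len / v)
}

# shared opening: static scene, fast flight to a gate outside the far
# boundary, slow approach to a hover above the grasp point, grasp descent
enter_and_grasp <- function(rig, g, phi, grasp_top_y, hover = 0.30) {
  rig_wait(rig, 0.6)
  gate_h <- grasp_top_y + hover + g$hand / 2 + 0.25
  fly_to(rig, "hand", c(1.35 * cos(g$phi_start), gate_h,
                        1.35 * sin(g$phi_start)), V_FLY)
  fly_to(rig, "hand", ring_pos(g$r, phi, grasp_top_y + hover + g$hand / 2),
         V_GATE)
  fly_to(rig, "hand", ring_pos(g$r, phi, grasp_top_y + g$hand / 2), V_DESC)
  rig_hold(rig, 1.5)
}

# shared closing: raise the hand off the object (visible release phase) or
# withdraw in one fast motion, then leave the workspace
release_withdraw <- function(rig, g, fast = TRUE) {
  if (!fast) rig_move(rig, "hand", c(0, 0.45, 0), 0.45 / V_PLACE)
  fly_to(rig, "hand",
         c(2.2 * cos(g$phi_start), 0.9, 2.2 * sin(g$phi_start)), V_WITHDRAW)
  rig_wait(rig, 0.6)
}

carry_height <- function(g, land_top) land_top + g$s1 / 2 + CLEAR

put_down <- function(rig, hands, down, v = V_PLACE) {
  fast <- min(0.30, down / 2)
  rig_move(rig, hands, c(0, -(down - fast), 0), (down - fast) / v)
  rig_move(rig, hands, c(0, -fast, 0), fast / 1.2)
}

script_put_on_top <- function(rig, g) {
  rig_add(rig, "obj1", on_ground(g$r, g$phi1, g$s1))
  rig_add(rig, "obj2", on_ground(g$r, g$phi2, g$s2))
  enter_and_grasp(rig, g, g$phi1, g$s1)
  hands <- c("hand", "obj1")
  up <- carry_height(g, g$s2) - g$s1 / 2
  rig_move(rig, hands, c(0, up, 0), up / V_LIFT)
  rig_arc(rig, hands, g$phi2 - g$phi1, abs(g$phi2 - g$phi1) * g$r / V_ARC)
  down <- CLEAR
  rig_move(rig, hands, c(0, -down, 0), down / V_PLACE)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = FALSE)
  rig
}

# two-segment carry for take/uncover: a brisk first swing separates the
# carried object's footprint from the revealed object, then a slower swing
# completes the transport
carry_away <- function(rig, g, hands, from, to) {
  dphi <- to - from
  rig_arc(rig, hands, 0.4 * dphi, abs(0.4 * dphi) * g$r / 0.48)
  rig_arc(rig, hands, 0.6 * dphi, abs(0.6 * dphi) * g$r / 0.24)
}

script_take_down <- function(rig, g) {
  rig_add(rig, "obj2", on_ground(g$r, g$phi1, g$s2))
  rig_add(rig, "obj1", box_at(ring_pos(g$r, g$phi1, g$s2 + g$s1 / 2), g$s1))
  enter_and_grasp(rig, g, g$phi1, g$s2 + g$s1)
  hands <- c("hand", "obj1")
  up <- 0.50
  rig_move(rig, hands, c(0, up, 0), up / 0.45)
  carry_away(rig, g, hands, g$phi1, g$phi_put)
  down <- up + g$s2
  rig_move(rig, hands, c(0, -down, 0), down / V_FAST_DESC)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = TRUE)
  rig
}

script_uncover <- function(rig, g) {
  rig_add(rig, "obj2", on_ground(g$r, g$phi1, g$s2))
  rig_add(rig, "obj1", on_ground(g$r, g$phi1,
                                 c(g$s1, g$cover_h, g$s1)))  # enclosing cover
  enter_and_grasp(rig, g, g$phi1, g$cover_h)
  hands <- c("hand", "obj1")
  up <- 0.60
  rig_move(rig, hands, c(0, up, 0), up / 0.45)
  carry_away(rig, g, hands, g$phi1, g$phi_put)
  rig_move(rig, hands, c(0, -up, 0), up / V_FAST_DESC)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = TRUE)
  rig
}

script_hide <- function(rig, g) {
  rig_add(rig, "obj1", on_ground(g$r, g$phi3, g$s1))  # cover starts aside
  rig_add(rig, "obj2", on_ground(g$r, g$phi2, g$s2))
  g$phi_start <- g$phi3 + (g$phi_start - g$phi1)      # enter beside the cover
  enter_and_grasp(rig, g, g$phi3, g$s1)
  hands <- c("hand", "obj1")
  up <- 0.25                             # low carry: bottom just clears target
  rig_move(rig, hands, c(0, up, 0), up / 0.5)
  rig_arc(rig, hands, g$phi2 - g$phi3, abs(g$phi2 - g$phi3) * g$r / V_ARC)
  rig_move(rig, hands, c(0, -(up - g$s2), 0), (up - g$s2) / V_PLACE)
  # covering: sink slowly around the target until the cover reaches ground
  rig_move(rig, hands, c(0, -g$s2, 0), g$s2 / V_COVER)
  rig_flag(rig, "obj2", "absent")
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = FALSE)
  rig
}

saw_or_strike_base <- function(rig, g, combined_carry) {
  rig_add(rig, "obj1", on_ground(g$r, g$phi1, g$s1))
  rig_add(rig, "obj2", on_ground(g$r, g$phi2, g$s2))
  enter_and_grasp(rig, g, g$phi1, g$s1)
  hands <- c("hand", "obj1")
  up <- carry_height(g, g$s2) - g$s1 / 2
  dphi <- g$phi2 - g$phi1
  if (combined_carry) {
    # one diagonal climb-and-swing: the tool closes in on the target region
    rig_arc(rig, hands, dphi, up / 0.45, dy = up)
  } else {
    rig_move(rig, hands, c(0, up, 0), up / V_LIFT)
    rig_arc(rig, hands, dphi, abs(dphi) * g$r / V_ARC)
  }
  rig_move(rig, hands, c(0, -CLEAR, 0), CLEAR / V_PLACE)
  rig_hold(rig, 1.5)
  hands
}

# lift the tool off the target, swing it back to its origin, put it down
tool_return <- function(rig, g, hands) {
  lift <- 0.50
  rig_move(rig, hands, c(0, lift, 0), lift / V_LIFT)
  rig_arc(rig, hands, g$phi1 - g$phi2, abs(g$phi1 - g$phi2) * g$r / V_ARC)
  down <- g$s2 + g$s1 / 2 + lift - g$s1 / 2
  put_down(rig, hands, down)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = TRUE)
}

script_cut <- function(rig, g) {
  hands <- saw_or_strike_base(rig, g, combined_carry = TRUE)
  amp <- deg(7)                         # sawing stroke along the ring
  rig_oscillate(rig, hands, amp, 0.22, 6L)
  rig_flag(rig, "obj2", "destroyed")    # target divides mid-saw
  rig_oscillate(rig, hands, amp, 0.22, 6L)
  tool_return(rig, g, hands)
  rig
}

script_chop <- function(rig, g) {
  hands <- saw_or_strike_base(rig, g, combined_carry = FALSE)
  strike <- 0.30
  for (i in 1:2) {
    rig_move(rig, hands, c(0, strike, 0), strike / V_STRIKE)
    rig_move(rig, hands, c(0, -strike, 0), strike / V_STRIKE)
    if (i == 2L) rig_flag(rig, "obj2", "destroyed")
    rig_hold(rig, 1.5)
  }
  tool_return(rig, g, hands)
  rig
}

script_stir <- function(rig, g) {
  rig_add(rig, "obj1", on_ground(g$r, g$phi1, g$s1))
  rig_add(rig, "obj2", on_ground(g$r, g$phi2, g$s2))  # container cube
  enter_and_grasp(rig, g, g$phi1, g$s1)
  hands <- c("hand", "obj1")
  up <- g$s2 + 0.35                      # tool bottom to rim + clearance
  rig_move(rig, hands, c(0, up, 0), up / V_LIFT)
  rig_arc(rig, hands, g$phi2 - g$phi1, abs(g$phi2 - g$phi1) * g$r / V_ARC)
  depth <- 0.06                          # tool top sinks below the rim
  down <- 0.35 + depth + g$s1            # from clearance into the container
  rig_move(rig, hands, c(0, -down, 0), down / V_PLACE)
  rig_hold(rig, 1.2)
  rig_oscillate(rig, hands, deg(6), 0.22, 6L)
  rig_hold(rig, 1.2)
  rig_move(rig, hands, c(0, down, 0), down / 1.4)  # brisk pull-out
  back <- -deg(30) * sign(g$phi2 - g$phi1)
  rig_arc(rig, hands, back, abs(back) * g$r / 0.2)
  put_down(rig, hands, up)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = TRUE)
  rig
}

script_shake <- function(rig, g) {
  rig_add(rig, "obj1", on_ground(g$r, g$phi1, g$s1))
  enter_and_grasp(rig, g, g$phi1, g$s1)
  hands <- c("hand", "obj1")
  up <- 0.60
  rig_move(rig, hands, c(0, up, 0), up / V_LIFT)
  rig_oscillate(rig, hands, deg(15), 0.28, 6L)
  put_down(rig, hands, up)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = FALSE)
  rig
}

script_push <- function(rig, g) {
  rig_add(rig, "obj1", on_ground(g$r, g$phi1, g$s1))
  rig_wait(rig, 0.6)
  # side contact: the hand sits just behind obj1 along the ring
  psi <- (g$s1 + g$hand) / 2 / g$r
  side <- g$phi1 - sign(g$phi2 - g$phi1) * psi
  gate_h <- g$s1 / 2 + 0.45
  fly_to(rig, "hand", c(1.35 * cos(g$phi_start), gate_h,
                        1.35 * sin(g$phi_start)), V_FLY)
  fly_to(rig, "hand", ring_pos(g$r, side, gate_h), V_GATE)
  fly_to(rig, "hand", ring_pos(g$r, side, g$hand / 2 + 0.01), V_DESC)
  rig_hold(rig, 1.5)
  push_span <- deg(50) * sign(g$phi2 - g$phi1)
  rig_arc(rig, c("hand", "obj1"), push_span, abs(push_span) * g$r / 0.45)
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = TRUE)
  rig
}

script_lay <- function(rig, g) {
  h <- 0.30                              # upright height of the slab
  w <- 0.12
  rig_add(rig, "obj1", box_at(ring_pos(g$r, g$phi1, h / 2), c(w, h, w)))
  enter_and_grasp(rig, g, g$phi1, h)
  ctr <- ring_pos(g$r, g$phi1, w / 2)
  rig_morph(rig, "obj1", box_at(ctr, c(h, w, w)), 1.4, riders = "hand")
  rig_hold(rig, 1.5)
  release_withdraw(rig, g, fast = FALSE)
  rig
}

SCRIPTS <- list(chop = script_chop, cut = script_cut, hide = script_hide,
                uncover = script_uncover, put_on_top = script_put_on_top,
                take_down = script_take_down, lay = script_lay,
                push = script_push, shake = script_shake, stir = script_stir)

## ---- generators -------------------------------------------------------

make_rig <- function(action, g, hold_extra) {
  rig <- rig_new(hold_extra)
  rig_add(rig, "ground", c(-1.5, -0.05, -1.5, 1.5, 0, 1.5))
  rig_add(rig, "hand", hand_start_box(g))
  for (i in seq_along(g$distractors))
    rig_add(rig, paste0("dist", i), g$distractors[[i]])
  SCRIPTS[[action]](rig, g)
  rig
}

#' Generate one scripted action scenario
#'
#' Builds a cube-scene trajectory following the action's script
#' (approach, grasp, lift/transport/oscillate, release, withdraw, with
#' action-specific phases such as sawing, striking, covering or stirring)
#' with randomised object sizes, placements, distractor cubes and total
#' duration. The scene always starts with the hand far outside the
#' workspace. Deterministic given `seed`.
#'
#' @param action One of [ACTIONS].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return An `esec_trajectory` labelled with the action.
#' @export
generate_scenario <- function(action, config = simulation_config(),
                              seed = 1L) {
  if (!action %in% ACTIONS)
    stop("domain error: unknown action '", action, "'")
  with_seed(seed, {
    for (attempt in 1:20) {
      g <- sample_geometry(action, config)
      target <- sample_duration(action, config)
      probe <- make_rig(action, g, 0)
      nominal <- probe$t + 0.6
      extra <- if (probe$n_holds > 0L)
        max(0, target - nominal) / probe$n_holds else 0
      rig <- make_rig(action, g, extra)
      out <- rig_sample(rig, config$fps, names(rig$cur),
                        hand_id = "hand", ground_id = "ground",
                        action_label = action, seed = seed)
      if (scene_feasible(out)) return(out)
    }
    stop("infeasible workspace: could not place cubes disjointly for '",
         action, "'")
  })
}

# static sanity: distractors must not touch anything and the first frame's
# cubes must only touch where the script stacks or encloses them
scene_feasible <- function(traj) {
  ids <- traj$object_ids
  dist_ids <- grep("^dist", ids, value = TRUE)
  eps <- 1e-3
  for (d in dist_ids)
    for (o in setdiff(ids, c(d, traj$ground_id)))
      if (any(touching_vec(traj$coords[, d, , drop = TRUE],
                           traj$coords[, o, , drop = TRUE], eps)))
        return(FALSE)
  TRUE
}

#' Generate a labelled scenario dataset
#'
#' `n_per_action` scenarios of each of the ten actions, with per-scenario
#' sub-seeds derived from `seed`.
#'
#' @param n_per_action Scenarios per action class.
#' @param config A [simulation_config()].
#' @param seed Root seed.
#' @return List of `esec_trajectory` objects with a `manifest` attribute
#'   (`data.frame` with `action` and `seed` per scenario).
#' @export
generate_dataset <- function(n_per_action, config = simulation_config(),
                             seed = 1L) {
  stopifnot(n_per_action >= 1L)
  sub <- with_seed(seed,
                   sample.int(.Machine$integer.max,
                              n_per_action * length(ACTIONS)))
  manifest <- data.frame(
    action = rep(ACTIONS, each = n_per_action),
    seed = sub, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(manifest)), function(i)
    generate_scenario(manifest$action[i], config, manifest$seed[i]))
  attr(out, "manifest") <- manifest
  out
}

#' Simulate observer button presses from an information model
#'
#' For each trial of each action, walks through the action's steps and draws
#' a Bernoulli response with
#' `logit(p) = intercept + b_abs * info + b_cum * cum_info + b_int * info * cum_info`
#' under the named generating model; the first success is the trial's
#' response column.
#'
#' @param true_model One of [INFO_MODELS].
#' @param coefficients Named numeric vector with any of `intercept`,
#'   `absolute`, `cumulative`, `interaction` (missing terms are 0).
#' @param info An `info_table`.
#' @param trials_per_action Number of trials per action.
#' @param seed Integer seed.
#' @return `data.frame` with `action`, `trial`, `response_column` (`NA` when
#'   no response fell within the action).
#' @export
generate_responses <- function(true_model, coefficients, info,
                               trials_per_action, seed = 1L) {
  co <- c(intercept = 0, absolute = 0, cumulative = 0, interaction = 0)
  co[names(coefficients)] <- coefficients
  if (any(!is.finite(co))) stop("domain error: coefficients must be finite")
  acts <- unique(info$action)
  with_seed(seed, {
    out <- do.call(rbind, lapply(acts, function(act) {
      steps <- action_steps(info, act, true_model)
      eta <- co["intercept"] + co["absolute"] * steps$info +
        co["cumulative"] * steps$cum_info +
        co["interaction"] * steps$info * steps$cum_info
      p <- stats::plogis(eta)
      rc <- vapply(seq_len(trials_per_action), function(tr) {
        hit <- which(stats::runif(length(p)) < p)
        if (length(hit)) steps$column[hit[1L]] else NA_integer_
      }, integer(1))
      data.frame(action = act, trial = seq_len(trials_per_action),
                 response_column = rc, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
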