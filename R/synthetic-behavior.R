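# Persistent-random-walk simulation of larvae in the four-quadrant arena,
# with Bernoulli boundary decisions and ground-truth event bookkeeping.

#' Parameters for the choice-assay trajectory generator
#'
#' Defaults state the assay: ten larvae placed at the center of a 10-cm
#' plate, tracked at 1 frame/s for 5 minutes, with a wild-type-like
#' turn-back probability of 0.955 at the lit-to-dark boundary and a
#' dark-to-lit entry probability of 0.75.
#'
#' @param n_larvae number of larvae (default 10).
#' @param arena an [arena_config()].
#' @param step_length_mean mean step length, cm per frame.
#' @param heading_persistence directional persistence in `[0, 1]`; the
#'   per-frame heading change is Gaussian with s.d.
#'   `(1 - heading_persistence) * pi` radians.
#' @param p_turn_back_lit_to_dark probability that an approach to the
#'   boundary from a lit quadrant ends in a turn back into the light.
#' @param p_enter_dark_to_lit probability that an approach from a dark
#'   quadrant ends in a cross into the light.
#' @param duration assay length, seconds (default 300).
#' @param frame_rate frames per second (default 1).
#' @param band_width boundary decision band half-width, cm (default 0.5);
#'   one Bernoulli decision is drawn per band visit, not per frame,
#'   matching how discrete approach outcomes are scored.
#' @param seed integer seed.
#' @return an object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(n_larvae = 10,
                                arena = arena_config(),
                                step_length_mean = 0.1,
                                heading_persistence = 0.9,
                                p_turn_back_lit_to_dark = 0.955,
                                p_enter_dark_to_lit = 0.75,
                                duration = 300,
                                frame_rate = 1,
                                band_width = 0.5,
                                seed = NULL) {
  check_count(n_larvae, "n_larvae", min = 1L)
  stopifnot(inherits(arena, "arena_config"))
  check_number(step_length_mean, "step_length_mean", min = 0)
  check_number(heading_persistence, "heading_persistence", min = 0, max = 1)
  check_number(p_turn_back_lit_to_dark, "p_turn_back_lit_to_dark",
               min = 0, max = 1)
  check_number(p_enter_dark_to_lit, "p_enter_dark_to_lit", min = 0, max = 1)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  check_number(band_width, "band_width", min = 0, strict_min = TRUE)
  if (band_width >= arena$radius) {
    stop("'band_width' must be smaller than the arena radius", call. = FALSE)
  }
  if (!is.null(seed)) check_count(seed, "seed")
  structure(list(n_larvae = n_larvae, arena = arena,
                 step_length_mean = step_length_mean,
                 heading_persistence = heading_persistence,
                 p_turn_back_lit_to_dark = p_turn_back_lit_to_dark,
                 p_enter_dark_to_lit = p_enter_dark_to_lit,
                 duration = duration, frame_rate = frame_rate,
                 band_width = band_width, seed = seed),
            class = "behavior_sim_params")
}

#' Simulate larval trajectories in the choice arena
#'
#' Each larva performs a persistent random walk from the arena center.
#' When it enters the boundary band from side S, one Bernoulli outcome is
#' drawn (turn back vs cross, with the side-appropriate probability) and
#' enforced on the path: a turn-back reflects any step that would cross
#' the boundary line, a cross biases the normal velocity component until
#' the line is crossed. The dish wall reflects specularly. Ground truth
#' records every approach with its drawn outcome.
#'
#' @param params a [behavior_sim_params()] object.
#' @return list with `trajectories` (a [trajectory_set()]) and
#'   `ground_truth` (data frame `larva_id`, `time`, `origin_side`,
#'   `outcome`).
#' @export
simulate_trajectories <- function(params) {
  stopifnot(inherits(params, "behavior_sim_params"))
  p <- params
  n_frames <- round(p$duration * p$frame_rate)
  arena <- p$arena
  a <- arena$quadrant_axes_angle * pi / 180
  lit_of <- function(v) { # lit flag in arena frame
    s <- sign(v[1]) * sign(v[2])
    if (arena$lit_parity == "pos") s > 0 else s < 0
  }
  gt <- list()
  rows <- vector("list", p$n_larvae)
  with_seed(p$seed, {
    for (id in seq_len(p$n_larvae)) {
      v <- c(0, 0) # arena-frame coordinates relative to center
      heading <- stats::runif(1, 0, 2 * pi)
      xs <- numeric(n_frames); ys <- numeric(n_frames)
      xs[1] <- v[1]; ys[1] <- v[2]
      open <- FALSE; suppressed <- TRUE # starts at center, inside the band
      origin <- NA; outcome <- NA_character_
      axis <- NA_integer_; s0 <- NA_real_
      # hold the lit flag at `target` while a visit is open: a pending
      # turn-back must never flip it, and a completed cross must never
      # revert (corners near the center involve both boundary lines);
      # reads the current visit's axis from this environment
      enforce_lit <- function(cand, v, target) {
        if (lit_of(cand) != target) {
          for (k in 1:2) {
            if (sign(cand[k]) != sign(v[k]) && sign(v[k]) != 0 &&
                cand[k] != 0) {
              cand[k] <- -cand[k]
            }
          }
          if (lit_of(cand) != target && cand[axis] != 0) {
            cand[axis] <- -cand[axis]
          }
        }
        cand
      }
      for (f in 2:n_frames) {
        heading <- heading +
          stats::rnorm(1, 0, (1 - p$heading_persistence) * pi)
        step <- if (p$step_length_mean > 0) {
          stats::rgamma(1, shape = 4, scale = p$step_length_mean / 4)
        } else 0
        cand <- v + step * c(cos(heading), sin(heading))
        # dish wall: specular (radial) reflection
        rr <- sqrt(sum(cand^2))
        if (rr > arena$radius) {
          cand <- cand * (2 * arena$radius - rr) / rr
        }
        if (open) {
          # enforce the drawn outcome on the realized path
          if (outcome == "turn_back") {
            cand <- enforce_lit(cand, v, origin)
          } else if (lit_of(v) != origin) {
            cand <- enforce_lit(cand, v, !origin) # cross completed: commit
          } else if (sign(cand[axis]) == s0) {
            cand[axis] <- cand[axis] - s0 * max(step, p$step_length_mean) * 0.75
            if (sign(cand[axis]) == s0 && abs(cand[axis]) >= p$band_width) {
              cand[axis] <- s0 * 0.9 * p$band_width # stay in band until crossed
            }
          }
        }
        dist <- min(abs(cand))
        in_band <- dist < p$band_width
        prev_in_band <- min(abs(v)) < p$band_width
        if (suppressed) {
          if (!in_band) suppressed <- FALSE
        } else if (!open && in_band && !prev_in_band) {
          open <- TRUE
          origin <- lit_of(v)
          axis <- which.min(abs(cand))
          s0 <- sign(v[axis])
          if (s0 == 0) s0 <- sign(cand[axis])
          pr <- if (origin) p$p_turn_back_lit_to_dark else
            1 - p$p_enter_dark_to_lit
          outcome <- if (stats::runif(1) < pr) "turn_back" else "cross"
          gt[[length(gt) + 1L]] <- data.frame(
            larva_id = id, time = (f - 1) / p$frame_rate,
            origin_side = if (origin) "lit" else "dark", outcome = outcome)
          if (outcome == "turn_back") cand <- enforce_lit(cand, v, origin)
        } else if (open && !in_band) {
          open <- FALSE
        }
        if (step > 0) heading <- atan2(cand[2] - v[2], cand[1] - v[1])
        v <- cand
        xs[f] <- v[1]; ys[f] <- v[2]
      }
      # arena frame -> world frame (inverse of rotate_to_arena)
      wx <- cos(a) * xs - sin(a) * ys + arena$center[1]
      wy <- sin(a) * xs + cos(a) * ys + arena$center[2]
      rows[[id]] <- data.frame(larva_id = id, frame = seq_len(n_frames),
                               x = wx, y = wy)
    }
  })
  positions <- do.call(rbind, rows)
  ground_truth <- if (length(gt) > 0L) {
    g <- do.call(rbind, gt); rownames(g) <- NULL; g
  } else {
    data.frame(larva_id = integer(0), time = numeric(0),
               origin_side = character(0), outcome = character(0))
  }
  list(trajectories = trajectory_set(positions, frame_rate = p$frame_rate),
       ground_truth = ground_truth)
}
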