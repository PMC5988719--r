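# Choice-assay analysis: quadrant assignment, performance index, boundary
# event detection and entry/turn-back probabilities.

#' Arena configuration for the four-quadrant choice assay
#'
#' A circular plate split into four quadrants by two perpendicular lines
#' through the center; one diagonal pair of quadrants is illuminated.
#'
#' @param radius plate radius in cm (default 5, a 10-cm dish).
#' @param center arena center `c(x, y)` in cm.
#' @param quadrant_axes_angle rotation of the quadrant axes, degrees.
#' @param lit_parity `"pos"` if the quadrants where the rotated
#'   coordinates have equal signs (quadrants I and III) are illuminated,
#'   `"neg"` for the other diagonal pair.
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(radius = 5, center = c(0, 0),
                         quadrant_axes_angle = 0,
                         lit_parity = c("pos", "neg")) {
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  check_number(quadrant_axes_angle, "quadrant_axes_angle")
  lit_parity <- match.arg(lit_parity)
  structure(list(radius = radius, center = center,
                 quadrant_axes_angle = quadrant_axes_angle,
                 lit_parity = lit_parity),
            class = "arena_config")
}

#' Trajectory set container
#'
#' @param positions data frame with columns `larva_id`, `frame`, `x`, `y`
#'   (cm); frames must be strictly increasing within each larva.
#' @param frame_rate frames per second (default 1).
#' @return an object of class `trajectory_set`.
#' @export
trajectory_set <- function(positions, frame_rate = 1) {
  req <- c("larva_id", "frame", "x", "y")
  if (!is.data.frame(positions) || !all(req %in% names(positions))) {
    stop("'positions' needs columns larva_id, frame, x, y", call. = FALSE)
  }
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  for (id in unique(positions$larva_id)) {
    fr <- positions$frame[positions$larva_id == id]
    if (any(diff(fr) <= 0)) {
      stop(sprintf("frames not strictly increasing for larva '%s'", id),
           call. = FALSE)
    }
  }
  structure(list(positions = positions, frame_rate = frame_rate),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: %d larvae, %d positions @ %g fps>\n",
              length(unique(x$positions$larva_id)), nrow(x$positions),
              x$frame_rate))
  invisible(x)
}

# Rotate positions into the arena's quadrant frame: columns xr, yr.
rotate_to_arena <- function(x, y, arena) {
  a <- arena$quadrant_axes_angle * pi / 180
  dx <- x - arena$center[1]; dy <- y - arena$center[2]
  list(xr = cos(a) * dx + sin(a) * dy, yr = -sin(a) * dx + cos(a) * dy)
}

#' Assign positions to quadrants
#'
#' Quadrants are numbered 1-4 counterclockwise in the rotated frame;
#' positions exactly on a boundary line (within `tol`) belong to neither
#' quadrant (`NA`). The `lit` flag follows the arena's `lit_parity`.
#'
#' @param x,y position coordinates (cm), vectorized.
#' @param arena an [arena_config()].
#' @param tol on-line tolerance in cm.
#' @return data frame with columns `quadrant` (integer or `NA`) and `lit`
#'   (logical or `NA`).
#' @export
assign_quadrant <- function(x, y, arena, tol = 1e-9) {
  stopifnot(inherits(arena, "arena_config"))
  r <- rotate_to_arena(x, y, arena)
  on_line <- abs(r$xr) <= tol | abs(r$yr) <= tol
  quad <- ifelse(r$xr > 0 & r$yr > 0, 1L,
          ifelse(r$xr < 0 & r$yr > 0, 2L,
          ifelse(r$xr < 0 & r$yr < 0, 3L, 4L)))
  quad[on_line] <- NA_integer_
  same_sign <- sign(r$xr) * sign(r$yr) > 0
  lit <- if (arena$lit_parity == "pos") same_sign else !same_sign
  lit[on_line] <- NA
  data.frame(quadrant = quad, lit = lit)
}

#' Performance index of a trajectory set
#'
#' PI = (positions in lit quadrants - positions in dark quadrants) /
#' total counted positions, pooled over all larvae and frames. Positions
#' on a boundary line are excluded from all counts (they are neither lit
#' nor dark), which keeps PI free of tie-breaking artifacts. The literal
#' per-larva denominator (counts divided by the number of larvae) is
#' available as `denominator = "larvae"`; it is not bounded by [-1, 1].
#'
#' @param trajectories a [trajectory_set()].
#' @param arena an [arena_config()].
#' @param denominator `"positions"` (default) or `"larvae"`.
#' @return an object of class `performance_index_result` with `pi`,
#'   `n_light`, `n_dark`, `n_total`, `n_larvae`.
#' @export
performance_index <- function(trajectories, arena,
                              denominator = c("positions", "larvae")) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(arena, "arena_config"))
  denominator <- match.arg(denominator)
  pos <- trajectories$positions
  if (nrow(pos) == 0L) stop("empty trajectory set", call. = FALSE)
  q <- assign_quadrant(pos$x, pos$y, arena)
  n_light <- sum(q$lit, na.rm = TRUE)
  n_dark <- sum(!q$lit, na.rm = TRUE)
  n_larvae <- length(unique(pos$larva_id))
  n_total <- n_light + n_dark
  denom <- if (denominator == "positions") n_total else n_larvae
  if (denom == 0) stop("no countable positions", call. = FALSE)
  structure(list(pi = (n_light - n_dark) / denom,
                 n_light = n_light, n_dark = n_dark, n_total = n_total,
                 n_larvae = n_larvae, denominator = denominator),
            class = "performance_index_result")
}

#' @export
print.performance_index_result <- function(x, ...) {
  cat(sprintf("<PI = %+.3f (lit %d, dark %d, total %d; %d larvae)>\n",
              x$pi, x$n_light, x$n_dark, x$n_total, x$n_larvae))
  invisible(x)
}

#' Detect boundary approach events and their outcomes
#'
#' A band visit opens when a larva moves to within `band_width` cm of the
#' nearest quadrant-boundary line from side S (the lit flag of its last
#' out-of-band position). The visit closes as `cross` if the larva's
#' lit flag flips while in the band (or, failing that, within `max_dwell`
#' seconds the visit closes as `turn_back`); it closes as `turn_back` if
#' the larva exits the band on side S. One outcome is scored per band
#' visit, however much the larva oscillates inside it. A direct side flip
#' with no in-band frame (large steps) is scored as a cross.
#'
#' @param trajectories a [trajectory_set()].
#' @param arena an [arena_config()].
#' @param band_width boundary band half-width in cm (default 0.5); must be
#'   smaller than the arena radius.
#' @param max_dwell maximum in-band dwell in seconds before a visit is
#'   closed (default 10).
#' @return data frame with columns `larva_id`, `time` (s, band entry),
#'   `origin_side` (`"lit"`/`"dark"`), `outcome` (`"cross"`/`"turn_back"`).
#' @export
detect_boundary_events <- function(trajectories, arena, band_width = 0.5,
                                   max_dwell = 10) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(arena, "arena_config"))
  check_number(band_width, "band_width", min = 0, strict_min = TRUE)
  if (band_width >= arena$radius) {
    stop("'band_width' must be smaller than the arena radius", call. = FALSE)
  }
  check_number(max_dwell, "max_dwell", min = 0, strict_min = TRUE)
  out <- list()
  pos <- trajectories$positions
  rate <- trajectories$frame_rate
  for (id in unique(pos$larva_id)) {
    p <- pos[pos$larva_id == id, , drop = FALSE]
    r <- rotate_to_arena(p$x, p$y, arena)
    dist <- pmin(abs(r$xr), abs(r$yr))
    in_band <- dist < band_width
    q <- assign_quadrant(p$x, p$y, arena)
    t <- (p$frame - p$frame[1]) / rate
    n <- nrow(p)
    open <- FALSE; suppressed <- in_band[1]
    origin <- NA; t_open <- NA_real_; closed <- FALSE
    emit <- function(outcome) {
      out[[length(out) + 1L]] <<- data.frame(
        larva_id = id, time = t_open,
        origin_side = if (isTRUE(origin)) "lit" else "dark",
        outcome = outcome)
    }
    for (i in seq_len(n)[-1]) {
      if (suppressed) {
        if (!in_band[i]) suppressed <- FALSE
        next
      }
      if (!open && in_band[i] && !in_band[i - 1]) {
        open <- TRUE; closed <- FALSE
        origin <- q$lit[i - 1]
        t_open <- t[i]
        if (is.na(origin)) { # entered from an on-line position; skip visit
          open <- FALSE; suppressed <- TRUE
          next
        }
      } else if (!open && !in_band[i] && !in_band[i - 1] &&
                 !is.na(q$lit[i]) && !is.na(q$lit[i - 1]) &&
                 q$lit[i] != q$lit[i - 1]) {
        # jumped clean across the band in one step
        origin <- q$lit[i - 1]; t_open <- t[i]
        emit("cross")
        next
      }
      if (open) {
        if (!closed && !is.na(q$lit[i]) && q$lit[i] != origin) {
          emit("cross"); closed <- TRUE
        }
        if (!closed && (t[i] - t_open) > max_dwell) {
          emit("turn_back"); closed <- TRUE
        }
        if (!in_band[i]) {
          if (!closed) {
            emit(if (identical(q$lit[i], origin)) "turn_back" else "cross")
          }
          open <- FALSE
        }
      }
    }
    if (open && !closed) emit("turn_back") # trajectory ended inside the band
  }
  if (length(out) == 0L) {
    return(data.frame(larva_id = character(0), time = numeric(0),
                      origin_side = character(0), outcome = character(0)))
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' Entry and turn-back probabilities from boundary events
#'
#' The entry probability is the fraction of dark-side approaches that end
#' in a cross into the lit quadrants; the turn-back probability is the
#' fraction of lit-side approaches that end with the larva turning back
#' into the lit quadrants. Raw counts are returned for exact testing.
#'
#' @param events event data frame from [detect_boundary_events()].
#' @return list with `p_enter_lit`, `n_dark_approaches`, `p_turn_back`,
#'   `n_lit_approaches`, and `counts`, a 2x2 integer matrix (rows: origin
#'   lit/dark; columns: turn_back/cross) ready for [fisher_exact_test()].
#' @export
boundary_probabilities <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("origin_side", "outcome") %in% names(events)))
  lit <- events$origin_side == "lit"
  dark <- events$origin_side == "dark"
  n_lit <- sum(lit); n_dark <- sum(dark)
  p_turn_back <- if (n_lit > 0) sum(lit & events$outcome == "turn_back") / n_lit
                 else NA_real_
  p_enter_lit <- if (n_dark > 0) sum(dark & events$outcome == "cross") / n_dark
                 else NA_real_
  counts <- matrix(c(sum(lit & events$outcome == "turn_back"),
                     sum(dark & events$outcome == "turn_back"),
                     sum(lit & events$outcome == "cross"),
                     sum(dark & events$outcome == "cross")),
                   nrow = 2, dimnames = list(origin = c("lit", "dark"),
                                             outcome = c("turn_back", "cross")))
  list(p_enter_lit = p_enter_lit, n_dark_approaches = n_dark,
       p_turn_back = p_turn_back, n_lit_approaches = n_lit,
       counts = counts)
}

#' Write a trajectory set as tabular text
#'
#' Columns: `larva_id`, `frame`, `x_cm`, `y_cm`, tab-separated.
#'
#' @param trajectories a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  p <- trajectories$positions
  df <- data.frame(larva_id = p$larva_id, frame = p$frame,
                   x_cm = p$x, y_cm = p$y)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory set from tabular text
#'
#' @param path file with columns `larva_id`, `frame`, `x_cm`, `y_cm`.
#' @param frame_rate frames per second (default 1).
#' @return a [trajectory_set()].
#' @export
load_trajectory_table <- function(path, frame_rate = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  req <- c("larva_id", "frame", "x_cm", "y_cm")
  if (!all(req %in% names(df))) {
    stop("trajectory table needs columns larva_id, frame, x_cm, y_cm",
         call. = FALSE)
  }
  trajectory_set(data.frame(larva_id = df$larva_id, frame = df$frame,
                            x = df$x_cm, y = df$y_cm),
                 frame_rate = frame_rate)
}
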