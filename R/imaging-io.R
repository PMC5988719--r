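# Image stacks, ROIs, preprocessing (mean filter, rolling-ball background)
# and ROI trace extraction; tabular trace I/O.

#' Fluorescence trace container
#'
#' @param values numeric vector of raw intensities, one per frame.
#' @param sample_rate frames per second, `> 0`.
#' @param label trace label.
#' @return an object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, sample_rate, label = "trace") {
  if (!is.numeric(values) || length(values) < 1L || !all(is.finite(values))) {
    stop("'values' must be a non-empty finite numeric vector", call. = FALSE)
  }
  check_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 label = as.character(label)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace '%s': %d frames @ %g fps (%.1f s)>\n",
              x$label, length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate))
  invisible(x)
}

#' Image stack container
#'
#' @param frames numeric array with dimensions `T x H x W` (frames, rows,
#'   columns); all intensities must be finite.
#' @param frame_interval seconds between frames.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("'frames' must be a T x H x W array", call. = FALSE)
  }
  if (!all(is.finite(frames))) {
    stop("'frames' must contain only finite intensities", call. = FALSE)
  }
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack: %d frames of %d x %d px, dt = %g s>\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' Region of interest
#'
#' Pixel membership is a two-column matrix of (row, col) indices, 1-based.
#'
#' @param pixels integer matrix with columns row, col.
#' @param label ROI label.
#' @return an object of class `roi`.
#' @export
roi <- function(pixels, label = "roi") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) != 2L) {
    stop("'pixels' must be a non-empty matrix with columns (row, col)",
         call. = FALSE)
  }
  if (any(pixels < 1) || any(pixels != round(pixels))) {
    stop("'pixels' must be positive integer (row, col) indices", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("row", "col")
  structure(list(pixels = pixels, label = as.character(label)), class = "roi")
}

#' Build an ROI from a mask matrix (nonzero = member)
#'
#' @param mask numeric or logical matrix, same shape as a stack frame.
#' @param label ROI label.
#' @return an [roi()].
#' @export
roi_from_mask <- function(mask, label = "roi") {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask selects no pixels", call. = FALSE)
  roi(idx, label = label)
}

# Offsets (dy, dx) of a neighborhood of the given radius. shape "disk"
# uses Euclidean distance (dx^2 + dy^2 <= r^2), "square" Chebyshev.
kernel_offsets <- function(radius, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  if (shape == "disk") g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Shift a matrix by (dy, dx), padding exposed entries with `fill`.
shift_matrix <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 - dy):min(h, h - dy)
  cs <- max(1, 1 - dx):min(w, w - dx)
  if (length(rs) > 0 && length(cs) > 0) out[rs, cs] <- m[rs + dy, cs + dx]
  out
}

#' Mean filter an image stack
#'
#' Replaces every pixel, per frame, by the arithmetic mean of the pixels
#' within `radius` of it. The neighborhood is a Euclidean disk by default
#' (the semantics of "radius" in common image tools); a square (Chebyshev)
#' neighborhood is available via `shape`. At frame edges the mean is taken
#' over the in-bounds part of the neighborhood. `radius = 0` is the
#' identity.
#'
#' @param stack an [image_stack()].
#' @param radius neighborhood radius in pixels, non-negative integer.
#' @param shape `"disk"` (default) or `"square"`.
#' @return a filtered [image_stack()].
#' @export
mean_filter <- function(stack, radius, shape = c("disk", "square")) {
  stopifnot(inherits(stack, "image_stack"))
  shape <- match.arg(shape)
  check_count(radius, "radius", min = 0L)
  if (radius == 0L) return(stack)
  offs <- kernel_offsets(radius, shape)
  d <- dim(stack$frames)
  out <- stack$frames
  for (f in seq_len(d[1])) {
    img <- matrix(stack$frames[f, , ], d[2], d[3])
    acc <- matrix(0, d[2], d[3])
    cnt <- matrix(0, d[2], d[3])
    for (k in seq_len(nrow(offs))) {
      s <- shift_matrix(img, offs[k, 1], offs[k, 2], NA_real_)
      inb <- !is.na(s)
      acc[inb] <- acc[inb] + s[inb]
      cnt <- cnt + inb
    }
    out[f, , ] <- acc / cnt
  }
  image_stack(out, stack$frame_interval)
}

# Heights of the ball structuring element at each in-disk offset.
ball_heights <- function(radius, offsets, height = radius,
                         method = c("ball", "paraboloid")) {
  method <- match.arg(method)
  d2 <- offsets[, 1]^2 + offsets[, 2]^2
  if (method == "ball") {
    (height / radius) * sqrt(pmax(radius^2 - d2, 0))
  } else {
    height * (1 - d2 / radius^2)
  }
}

# Grayscale erosion (min-plus) or dilation (max-plus) of one frame by a
# non-flat structuring element given as offsets + heights. Out-of-bounds
# neighbors are ignored (restricted to the valid region).
morph_frame <- function(img, offsets, heights, op = c("erode", "dilate")) {
  op <- match.arg(op)
  fill <- if (op == "erode") Inf else -Inf
  out <- matrix(fill, nrow(img), ncol(img))
  for (k in seq_len(nrow(offsets))) {
    s <- shift_matrix(img, offsets[k, 1], offsets[k, 2], fill)
    out <- if (op == "erode") pmin(out, s - heights[k]) else pmax(out, s + heights[k])
  }
  out
}

#' Rolling-ball background estimation
#'
#' Estimates the smooth image background as the surface traced by a ball
#' of the given radius rolled under the intensity landscape: a grayscale
#' opening (erosion followed by dilation) with a spherical-cap structuring
#' element. The background never exceeds the original image, so the
#' corrected image `original - background` is non-negative; features much
#' narrower than the ball survive subtraction while smooth background is
#' removed. A paraboloid approximation of the ball is available.
#'
#' @param stack an [image_stack()].
#' @param radius ball radius in pixels, `> 0`; must not exceed both frame
#'   dimensions.
#' @param height ball height in intensity units (defaults to `radius`; the
#'   intensity-to-pixel scaling of the ball is not standardized, so it is
#'   exposed).
#' @param method `"ball"` (spherical cap, default) or `"paraboloid"`.
#' @return an [image_stack()] holding the background.
#' @seealso [subtract_background()]
#' @export
rolling_ball_background <- function(stack, radius, height = radius,
                                    method = c("ball", "paraboloid")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(height, "height", min = 0, strict_min = TRUE)
  d <- dim(stack$frames)
  if (radius > d[2] && radius > d[3]) {
    stop("'radius' exceeds both image dimensions", call. = FALSE)
  }
  offs <- kernel_offsets(floor(radius), "disk")
  hts <- ball_heights(radius, offs, height = height, method = method)
  out <- stack$frames
  for (f in seq_len(d[1])) {
    img <- matrix(stack$frames[f, , ], d[2], d[3])
    er <- morph_frame(img, offs, hts, "erode")
    out[f, , ] <- morph_frame(er, offs, hts, "dilate")
  }
  image_stack(out, stack$frame_interval)
}

#' Subtract an estimated background from a stack
#'
#' @param stack an [image_stack()].
#' @param background the background [image_stack()], same dimensions.
#' @return the corrected [image_stack()].
#' @export
subtract_background <- function(stack, background) {
  stopifnot(inherits(stack, "image_stack"), inherits(background, "image_stack"))
  if (!identical(dim(stack$frames), dim(background$frames))) {
    stop("stack and background dimensions differ", call. = FALSE)
  }
  image_stack(stack$frames - background$frames, stack$frame_interval)
}

#' Extract the mean-intensity trace of an ROI
#'
#' Optionally applies the stated preprocessing in order — mean filter
#' (radius `mean_radius`), then rolling-ball background subtraction
#' (radius `ball_radius`) — and returns the per-frame arithmetic mean of
#' the ROI pixels.
#'
#' @param stack an [image_stack()].
#' @param roi an [roi()]; must lie inside the frame.
#' @param mean_radius mean-filter radius in pixels; 0 (default) disables.
#' @param ball_radius rolling-ball radius in pixels; 0 (default) disables.
#' @return a [fluorescence_trace()] at the stack's frame rate.
#' @export
extract_roi_trace <- function(stack, roi, mean_radius = 0, ball_radius = 0) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi"))
  d <- dim(stack$frames)
  px <- roi$pixels
  if (any(px[, 1] > d[2]) || any(px[, 2] > d[3])) {
    stop(sprintf("ROI '%s' extends outside the stack frame", roi$label),
         call. = FALSE)
  }
  if (mean_radius > 0) stack <- mean_filter(stack, mean_radius)
  if (ball_radius > 0) {
    bg <- rolling_ball_background(stack, ball_radius)
    stack <- subtract_background(stack, bg)
  }
  vals <- vapply(seq_len(d[1]), function(f) {
    mean(stack$frames[cbind(f, px[, 1], px[, 2])])
  }, numeric(1))
  fluorescence_trace(vals, sample_rate = 1 / stack$frame_interval,
                     label = roi$label)
}

#' Write fluorescence traces as a tabular text file
#'
#' One `time_s` column plus one column per trace, tab-separated.
#'
#' @param traces list of [fluorescence_trace()] objects sharing length and
#'   sample rate.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  lens <- vapply(traces, function(x) length(x$values), integer(1))
  rates <- vapply(traces, function(x) x$sample_rate, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
    stop("all traces must share length and sample_rate", call. = FALSE)
  }
  time_s <- (seq_len(lens[1]) - 1) / rates[1]
  df <- data.frame(time_s = time_s)
  labels <- make.unique(vapply(traces, function(x) x$label, character(1)))
  for (i in seq_along(traces)) df[[labels[i]]] <- traces[[i]]$values
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fluorescence traces from a tabular text file
#'
#' Expects a `time_s` (or first) column of uniformly spaced times and one
#' or more trace columns. The sample rate is inferred from the time
#' spacing; non-uniform spacing (beyond 1e-6 s) and missing values are
#' rejected with a location report.
#'
#' @param path input file path (tab- or comma-separated; inferred).
#' @return a list of [fluorescence_trace()] objects, in column order.
#' @export
load_trace_table <- function(path) {
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("trace table needs a time column and at least one trace column",
         call. = FALSE)
  }
  tcol <- if ("time_s" %in% names(df)) "time_s" else names(df)[1]
  times <- df[[tcol]]
  if (nrow(df) < 2L) stop("trace table needs at least two rows", call. = FALSE)
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-6)) {
    bad <- which(abs(dt - dt[1]) > 1e-6)[1] + 1L
    stop(sprintf("non-uniform time spacing at row %d of '%s'", bad, path),
         call. = FALSE)
  }
  na_idx <- which(is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) {
    stop(sprintf("missing value at row %d, column '%s'",
                 na_idx[1, 1], names(df)[na_idx[1, 2]]), call. = FALSE)
  }
  rate <- 1 / dt[1]
  cols <- setdiff(names(df), tcol)
  lapply(cols, function(cn) {
    fluorescence_trace(df[[cn]], sample_rate = rate, label = cn)
  })
}
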