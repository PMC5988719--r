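# dF/F0 normalization, sigma-threshold event detection, event frequency,
# power spectra, stimulus-response metrics and trace averaging.

#' Stimulus protocol
#'
#' Describes light-stimulation windows: `pulse` mode for brief repeated
#' pulses, `continuous` for a single long window (e.g. the 18-s paradigm).
#'
#' @param mode `"pulse"` or `"continuous"`.
#' @param onsets numeric vector of window onsets, seconds.
#' @param durations numeric vector of window durations, seconds (recycled
#'   if length 1). Windows must not overlap.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(mode = c("pulse", "continuous"),
                              onsets, durations) {
  mode <- match.arg(mode)
  if (!is.numeric(onsets) || length(onsets) < 1L || any(!is.finite(onsets)) ||
      any(onsets < 0)) {
    stop("'onsets' must be non-negative finite numbers", call. = FALSE)
  }
  durations <- rep_len(as.numeric(durations), length(onsets))
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("'durations' must be positive finite numbers", call. = FALSE)
  }
  o <- order(onsets)
  onsets <- onsets[o]; durations <- durations[o]
  if (length(onsets) > 1L &&
      any(onsets[-1] < (onsets + durations)[-length(onsets)])) {
    stop("stimulus windows overlap", call. = FALSE)
  }
  if (mode == "continuous" && length(onsets) != 1L) {
    stop("'continuous' mode takes exactly one window", call. = FALSE)
  }
  structure(list(mode = mode, onsets = onsets, durations = durations),
            class = "stimulus_protocol")
}

#' Compute dF/F0 from a raw fluorescence trace
#'
#' Two baselining conventions are implemented:
#' \describe{
#'   \item{`prior_percentile`}{F0 is the mean of the lowest quartile of
#'     samples (the lowest `ceiling(0.25 * N)` values) — the convention for
#'     spontaneous-activity recordings. This reading of "mean of the 25th
#'     percentile" is documented prominently because other readings exist.}
#'   \item{`stim_onset_frames`}{F0 is the mean of `n_f0_frames` (default 9)
#'     frames starting at the first stimulus onset — the convention for
#'     stimulation recordings. Note this makes dF/F0 near onset ~0 by
#'     construction.}
#'   \item{`pre_onset`}{alternative stimulation baseline: mean over the
#'     `pre_window` seconds before the first onset.}
#' }
#' dF/F0 is `(F - F0) / F0` elementwise.
#'
#' @param trace a [fluorescence_trace()].
#' @param mode baselining mode, see above.
#' @param protocol a [stimulus_protocol()]; required for the stimulation
#'   modes.
#' @param n_f0_frames frames averaged from onset in `stim_onset_frames`.
#' @param pre_window seconds before onset averaged in `pre_onset`.
#' @return an object of class `dff_trace` with fields `values`, `f0`,
#'   `mode`, `sample_rate`.
#' @export
compute_dff <- function(trace,
                        mode = c("prior_percentile", "stim_onset_frames",
                                 "pre_onset"),
                        protocol = NULL, n_f0_frames = 9, pre_window = 2) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  mode <- match.arg(mode)
  f <- trace$values
  n <- length(f)
  if (mode == "prior_percentile") {
    if (n < 4L) stop("trace too short: need >= 4 samples", call. = FALSE)
    k <- ceiling(0.25 * n)
    f0 <- mean(sort(f)[seq_len(k)])
  } else {
    if (is.null(protocol)) {
      stop("'protocol' is required for stimulation baselining", call. = FALSE)
    }
    onset_idx <- floor(protocol$onsets[1] * trace$sample_rate) + 1L
    if (mode == "stim_onset_frames") {
      check_count(n_f0_frames, "n_f0_frames", min = 1L)
      if (onset_idx + n_f0_frames - 1L > n) {
        stop(sprintf("need %d frames from stimulation onset", n_f0_frames),
             call. = FALSE)
      }
      f0 <- mean(f[onset_idx:(onset_idx + n_f0_frames - 1L)])
    } else {
      lo <- max(1L, onset_idx - round(pre_window * trace$sample_rate))
      if (lo >= onset_idx) {
        stop("no pre-onset samples available for baselining", call. = FALSE)
      }
      f0 <- mean(f[lo:(onset_idx - 1L)])
    }
  }
  if (!is.finite(f0) || f0 <= 0) {
    stop(sprintf("computed F0 = %g is not positive; corrupted input?", f0),
         call. = FALSE)
  }
  structure(list(values = (f - f0) / f0, f0 = f0, mode = mode,
                 sample_rate = trace$sample_rate, label = trace$label),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace '%s': %d frames @ %g fps, F0 = %.4g (%s)>\n",
              x$label, length(x$values), x$sample_rate, x$f0, x$mode))
  invisible(x)
}

#' Detect sigma-threshold events in a dF/F0 trace
#'
#' sigma is the standard deviation of the full dF/F0 series and the
#' baseline its median; an event is each maximal run of consecutive
#' samples exceeding `baseline + multiplier * sigma`, reported once at its
#' maximum. A robust sigma (1.4826 * MAD) is available. A constant trace
#' has sigma 0 and yields zero events. Optional `min_duration` (seconds)
#' drops shorter runs; `refractory` (seconds) merges events closer than
#' the given gap.
#'
#' @param dff a `dff_trace`.
#' @param multiplier threshold multiplier (default 2).
#' @param sigma_method `"sd"` (default) or `"mad"`.
#' @param min_duration,refractory optional event filters, seconds.
#' @return an object of class `event_set` with `event_times` (seconds, at
#'   the run maxima), `event_amplitudes` (dF/F0 at the maxima), `sigma`,
#'   `baseline`, `threshold_multiplier`, `duration`.
#' @export
detect_events <- function(dff, multiplier = 2, sigma_method = c("sd", "mad"),
                          min_duration = 0, refractory = 0) {
  stopifnot(inherits(dff, "dff_trace"))
  sigma_method <- match.arg(sigma_method)
  check_number(multiplier, "multiplier", min = 0)
  v <- dff$values
  if (length(v) < 4L) stop("dF/F0 series too short", call. = FALSE)
  if (any(!is.finite(v))) stop("dF/F0 series contains non-finite values",
                               call. = FALSE)
  sigma <- if (sigma_method == "sd") stats::sd(v) else stats::mad(v)
  baseline <- stats::median(v)
  times <- numeric(0); amps <- numeric(0)
  if (sigma > 0) {
    above <- v > baseline + multiplier * sigma
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      run <- starts[i]:ends[i]
      if (length(run) / dff$sample_rate < min_duration) next
      peak <- run[which.max(v[run])]
      times <- c(times, (peak - 1) / dff$sample_rate)
      amps <- c(amps, v[peak])
    }
    if (refractory > 0 && length(times) > 1L) {
      keep <- c(TRUE, diff(times) >= refractory)
      times <- times[keep]; amps <- amps[keep]
    }
  }
  structure(list(event_times = times, event_amplitudes = amps,
                 sigma = sigma, baseline = baseline,
                 threshold_multiplier = multiplier,
                 duration = length(v) / dff$sample_rate),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf(
    "<event_set: %d events in %.1f s (%.3g /s); threshold %g sigma = %.4g>\n",
    length(x$event_times), x$duration,
    length(x$event_times) / x$duration, x$threshold_multiplier, x$sigma))
  invisible(x)
}

#' Event frequency in events per second
#'
#' @param events an `event_set`.
#' @param duration analysis duration in seconds; defaults to the duration
#'   recorded in the event set.
#' @return events per second.
#' @export
event_frequency <- function(events, duration = events$duration) {
  stopifnot(inherits(events, "event_set"))
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  length(events$event_times) / duration
}

#' One-sided periodogram of a dF/F0 trace
#'
#' Rectangular-window periodogram of the mean-subtracted series,
#' normalized as power spectral density so that
#' `sum(power) * df = var(x)` (population variance; Parseval's identity),
#' with `df = sample_rate / N`. Frequencies run from 0 to the Nyquist
#' frequency.
#'
#' @param dff a `dff_trace`.
#' @return an object of class `power_spectrum` with `frequencies` (Hz) and
#'   `power` ((dF/F0)^2 per Hz).
#' @export
power_spectrum <- function(dff) {
  stopifnot(inherits(dff, "dff_trace"))
  x <- dff$values - mean(dff$values)
  n <- length(x)
  xf <- stats::fft(x)
  df <- dff$sample_rate / n
  p2 <- Mod(xf)^2 / (n^2 * df)          # two-sided density
  half <- seq_len(floor(n / 2) + 1L)    # DC .. Nyquist
  p1 <- p2[half]
  dbl <- half > 1L & (half < n / 2 + 1L | n %% 2L == 1L)
  p1[dbl] <- 2 * p1[dbl]
  structure(list(frequencies = (half - 1L) * df, power = p1,
                 sample_rate = dff$sample_rate, n = n),
            class = "power_spectrum")
}

#' Average power spectra across traces
#'
#' Pointwise mean and standard error (sd / sqrt(n)) across spectra that
#' share sample rate and length.
#'
#' @param spectra list of `power_spectrum` objects.
#' @return a list with `frequencies`, `mean_power`, `sem_power`, `n`.
#' @export
average_spectra <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  lapply(spectra, function(s) stopifnot(inherits(s, "power_spectrum")))
  rates <- vapply(spectra, function(s) s$sample_rate, numeric(1))
  ns <- vapply(spectra, function(s) s$n, numeric(1))
  if (length(unique(rates)) != 1L || length(unique(ns)) != 1L) {
    stop("spectra must share sample rate and trace length", call. = FALSE)
  }
  pw <- do.call(rbind, lapply(spectra, function(s) s$power))
  n <- nrow(pw)
  sem <- if (n >= 2L) apply(pw, 2, stats::sd) / sqrt(n) else
    rep(NA_real_, ncol(pw))
  list(frequencies = spectra[[1]]$frequencies,
       mean_power = colMeans(pw), sem_power = sem, n = n)
}

#' Stimulus-response metrics: maximum dF/F0, undershoot, return time
#'
#' `dff_max` is the maximum dF/F0 inside the stimulation windows. The
#' pre-stimulus baseline is the mean dF/F0 over the `pre_window` seconds
#' before the first onset. `undershoot` is the minimum dF/F0 within
#' `post_window` seconds after the final offset, minus that baseline
#' (negative values mean the response dipped below the pre-stimulus
#' level). `return_time` is the time after final offset at which dF/F0
#' first drops to or below the baseline, or `NA` if it stays above
#' throughout `post_window`.
#'
#' @param dff a `dff_trace`.
#' @param protocol a [stimulus_protocol()] whose windows lie inside the
#'   trace.
#' @param post_window seconds analyzed after the final offset; truncated
#'   with a warning if it extends beyond the trace.
#' @param pre_window seconds before the first onset used for the baseline.
#' @return an object of class `response_metrics` with `dff_max`,
#'   `undershoot`, `return_time`, `baseline`.
#' @export
response_metrics <- function(dff, protocol, post_window = 10, pre_window = 2) {
  stopifnot(inherits(dff, "dff_trace"), inherits(protocol, "stimulus_protocol"))
  check_number(post_window, "post_window", min = 0, strict_min = TRUE)
  v <- dff$values
  rate <- dff$sample_rate
  n <- length(v)
  t <- (seq_len(n) - 1) / rate
  last_off <- max(protocol$onsets + protocol$durations)
  if (last_off > t[n] + 1 / rate + 1e-9) {
    stop("stimulus windows extend beyond the trace", call. = FALSE)
  }
  in_stim <- rep(FALSE, n)
  for (w in seq_along(protocol$onsets)) {
    in_stim <- in_stim | (t >= protocol$onsets[w] &
                            t < protocol$onsets[w] + protocol$durations[w])
  }
  if (!any(in_stim)) stop("no samples inside stimulation windows", call. = FALSE)
  first_on <- protocol$onsets[1]
  pre <- t >= first_on - pre_window & t < first_on
  baseline <- if (any(pre)) mean(v[pre]) else 0
  if (last_off + post_window > t[n] + 1e-9) {
    warning("post_window extends beyond the trace; truncated")
  }
  post <- t >= last_off & t <= last_off + post_window
  undershoot <- if (any(post)) min(v[post]) - baseline else NA_real_
  ret_idx <- which(post & v <= baseline + 1e-12)
  return_time <- if (length(ret_idx) > 0L) t[ret_idx[1]] - last_off else
    NA_real_
  structure(list(dff_max = max(v[in_stim]), undershoot = undershoot,
                 return_time = return_time, baseline = baseline),
            class = "response_metrics")
}

#' Mean prior-event amplitude as a percentage of the evoked maximum
#'
#' @param events an `event_set` with at least one event.
#' @param evoked_max evoked response maximum (dF/F0), `> 0`.
#' @return percentage (100 x mean baseline-subtracted event amplitude /
#'   `evoked_max`); `NA` with a warning when the event set is empty.
#' @export
prior_to_evoked_ratio <- function(events, evoked_max) {
  stopifnot(inherits(events, "event_set"))
  check_number(evoked_max, "evoked_max", min = 0, strict_min = TRUE)
  if (length(events$event_amplitudes) == 0L) {
    warning("no events: prior/evoked ratio undefined")
    return(NA_real_)
  }
  100 * mean(events$event_amplitudes - events$baseline) / evoked_max
}

#' Average dF/F0 traces with an SEM band
#'
#' @param dffs list of `dff_trace` objects sharing length and rate.
#' @return list with `mean` (dF/F0), `sem` (`NA` when n = 1), `n`,
#'   `sample_rate`.
#' @export
average_traces <- function(dffs) {
  stopifnot(is.list(dffs), length(dffs) >= 1L)
  lapply(dffs, function(d) stopifnot(inherits(d, "dff_trace")))
  lens <- vapply(dffs, function(d) length(d$values), integer(1))
  rates <- vapply(dffs, function(d) d$sample_rate, numeric(1))
  if (length(unique(lens)) != 1L) stop("trace lengths differ", call. = FALSE)
  if (length(unique(rates)) != 1L) stop("sample rates differ", call. = FALSE)
  m <- do.call(rbind, lapply(dffs, function(d) d$values))
  n <- nrow(m)
  sem <- if (n >= 2L) apply(m, 2, stats::sd) / sqrt(n) else
    rep(NA_real_, ncol(m))
  list(mean = colMeans(m), sem = sem, n = n, sample_rate = rates[1])
}
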