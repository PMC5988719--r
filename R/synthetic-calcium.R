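# Forward simulation of ORN calcium fluorescence: Poisson events convolved
# with a calcium-indicator kernel, plus baseline, drift and camera noise.

#' Parameters for the spontaneous ("prior") activity trace generator
#'
#' Bundles and validates the parameters of the forward model used by
#' [simulate_calcium_trace()]. Defaults describe a wild-type-like ORN
#' recorded with a fast genetically encoded calcium indicator at 20
#' frames/s: events at 0.9 per second whose mean amplitude (0.413
#' dF/F0) is 61.1% of the default evoked response maximum (0.676).
#' The kernel decay (0.12 s) and amplitude CV (0.1) were fixed by a
#' one-off calibration study (see the methods vignette): they are the
#' fast edge of realistic single-event indicator kinetics, and they are
#' required for the 2-sigma excursion counter to recover event rates up
#' to ~1/s — slower kernels or wider amplitude spread make distinct
#' events merge or fall below the global threshold.
#'
#' @param event_rate Poisson rate of calcium events, events per second.
#' @param event_amplitude_mean mean event amplitude, dF/F0 units.
#' @param event_amplitude_cv coefficient of variation of the log-normal
#'   amplitude distribution (dimensionless).
#' @param kernel_rise_tau,kernel_decay_tau rise and decay time constants of
#'   the difference-of-exponentials event kernel, seconds. The kernel is
#'   normalized to unit peak so amplitudes are in dF/F0 units. Defaults
#'   (0.05 s rise, 0.12 s decay) are fast-indicator-like.
#' @param baseline_level resting fluorescence, camera intensity units.
#' @param noise_sigma additive Gaussian noise s.d., intensity units.
#' @param drift_slope linear baseline drift, intensity units per second.
#' @param duration recording length, seconds.
#' @param sample_rate acquisition rate, frames per second.
#' @param rate_modulation_freq optional frequency (Hz) of a sinusoidal
#'   modulation of the event rate, used to give the prior activity a
#'   rhythmic component visible as a power-spectrum peak; `NULL` (default)
#'   disables it.
#' @param rate_modulation_depth relative modulation depth in `[0, 1]`.
#' @param seed integer seed; the generator is a pure function of the
#'   parameters including the seed.
#' @return an object of class `calcium_sim_params`.
#' @seealso [simulate_calcium_trace()]
#' @export
calcium_sim_params <- function(event_rate = 0.9,
                               event_amplitude_mean = 0.413,
                               event_amplitude_cv = 0.1,
                               kernel_rise_tau = 0.05,
                               kernel_decay_tau = 0.12,
                               baseline_level = 100,
                               noise_sigma = 1,
                               drift_slope = 0,
                               duration = 60,
                               sample_rate = 20,
                               rate_modulation_freq = NULL,
                               rate_modulation_depth = 0,
                               seed = NULL) {
  check_number(event_rate, "event_rate", min = 0)
  check_number(event_amplitude_mean, "event_amplitude_mean", min = 0)
  check_number(event_amplitude_cv, "event_amplitude_cv", min = 0)
  check_number(kernel_rise_tau, "kernel_rise_tau", min = 0, strict_min = TRUE)
  check_number(kernel_decay_tau, "kernel_decay_tau",
               min = kernel_rise_tau, strict_min = TRUE)
  check_number(baseline_level, "baseline_level", min = 0, strict_min = TRUE)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(drift_slope, "drift_slope")
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  if (!is.null(rate_modulation_freq)) {
    check_number(rate_modulation_freq, "rate_modulation_freq",
                 min = 0, strict_min = TRUE)
  }
  check_number(rate_modulation_depth, "rate_modulation_depth", min = 0, max = 1)
  if (!is.null(seed)) check_count(seed, "seed")
  structure(
    list(event_rate = event_rate,
         event_amplitude_mean = event_amplitude_mean,
         event_amplitude_cv = event_amplitude_cv,
         kernel_rise_tau = kernel_rise_tau,
         kernel_decay_tau = kernel_decay_tau,
         baseline_level = baseline_level,
         noise_sigma = noise_sigma,
         drift_slope = drift_slope,
         duration = duration,
         sample_rate = sample_rate,
         rate_modulation_freq = rate_modulation_freq,
         rate_modulation_depth = rate_modulation_depth,
         seed = seed),
    class = "calcium_sim_params")
}

# Difference-of-exponentials kernel normalized to unit peak. t may be a
# vector of times (seconds) relative to event onset; negative times give 0.
event_kernel <- function(t, rise_tau, decay_tau) {
  k <- ifelse(t >= 0, exp(-t / decay_tau) - exp(-t / rise_tau), 0)
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  k / peak
}

# Draw log-normal amplitudes with a given arithmetic mean and CV.
draw_amplitudes <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Simulate a spontaneous-activity fluorescence trace with ground truth
#'
#' Generates a raw fluorescence trace as
#' `F(t) = B * (1 + sum_i a_i k(t - t_i)) + drift * t + noise`, where event
#' times `t_i` follow a (optionally sinusoidally modulated) Poisson process,
#' amplitudes `a_i` are log-normal in dF/F0 units, and `k` is a unit-peak
#' difference-of-exponentials kernel. The returned ground truth lists the
#' true event times and amplitudes for parameter-recovery tests.
#'
#' @param params a [calcium_sim_params()] object.
#' @return a list with elements `trace` (a [fluorescence_trace()]) and
#'   `ground_truth` (list with `event_times`, `event_amplitudes`).
#' @examples
#' sim <- simulate_calcium_trace(calcium_sim_params(seed = 1))
#' length(sim$ground_truth$event_times)
#' @export
simulate_calcium_trace <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  p <- params
  n <- round(p$duration * p$sample_rate)
  t <- (seq_len(n) - 1) / p$sample_rate
  with_seed(p$seed, {
    if (is.null(p$rate_modulation_freq) || p$rate_modulation_depth == 0) {
      n_ev <- stats::rpois(1, p$event_rate * p$duration)
      times <- sort(stats::runif(n_ev, 0, p$duration))
    } else {
      # inhomogeneous Poisson by thinning against the peak rate
      peak <- p$event_rate * (1 + p$rate_modulation_depth)
      n_cand <- stats::rpois(1, peak * p$duration)
      cand <- sort(stats::runif(n_cand, 0, p$duration))
      rate <- p$event_rate *
        (1 + p$rate_modulation_depth * sin(2 * pi * p$rate_modulation_freq * cand))
      keep <- stats::runif(n_cand) < rate / peak
      times <- cand[keep]
    }
    amps <- draw_amplitudes(length(times), p$event_amplitude_mean,
                            p$event_amplitude_cv)
    s <- numeric(n)
    for (i in seq_along(times)) {
      s <- s + amps[i] * event_kernel(t - times[i],
                                      p$kernel_rise_tau, p$kernel_decay_tau)
    }
    noise <- if (p$noise_sigma > 0) stats::rnorm(n, 0, p$noise_sigma) else 0
    values <- p$baseline_level * (1 + s) + p$drift_slope * t + noise
    list(
      trace = fluorescence_trace(values, sample_rate = p$sample_rate,
                                 label = "simulated"),
      ground_truth = list(event_times = times, event_amplitudes = amps)
    )
  })
}

#' Parameters for the stimulus-response trace generator
#'
#' Phenomenological model of the two response shapes seen under
#' optogenetic stimulation of larval ORNs: a wild-type-like sustained,
#' fluctuating response that ends in a below-baseline undershoot at
#' light offset, and an Orco-mutant-like strong-onset response that
#' adapts exponentially during the stimulus and returns to baseline only
#' slowly after offset (never undershooting).
#'
#' @param protocol a [stimulus_protocol()] describing light windows.
#' @param onset_gain peak response gain at stimulus onset, dF/F0 units.
#' @param adaptation_tau adaptation time constant, seconds, or `NULL` for
#'   a sustained (non-adapting, wild-type-like) response.
#' @param fluctuation_sigma s.d. of the AR(1) response fluctuation during
#'   stimulation, dF/F0 units (wild-type-like responses fluctuate).
#' @param undershoot_depth depth of the post-offset undershoot below
#'   baseline, dF/F0 units, `>= 0`; 0 for the Orco-like mode.
#' @param recovery_tau post-offset recovery time constant, seconds.
#' @param baseline_level,noise_sigma as in [calcium_sim_params()].
#' @param duration,sample_rate recording length (s) and rate (frames/s);
#'   the default 5 frames/s matches stimulation-experiment acquisition.
#' @param seed integer seed.
#' @return an object of class `stim_sim_params`.
#' @export
stim_sim_params <- function(protocol,
                            onset_gain = 0.676,
                            adaptation_tau = NULL,
                            fluctuation_sigma = 0,
                            undershoot_depth = 0,
                            recovery_tau = 2,
                            baseline_level = 100,
                            noise_sigma = 0,
                            duration = 60,
                            sample_rate = 5,
                            seed = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  check_number(onset_gain, "onset_gain", min = 0)
  if (!is.null(adaptation_tau)) {
    check_number(adaptation_tau, "adaptation_tau", min = 0, strict_min = TRUE)
  }
  check_number(fluctuation_sigma, "fluctuation_sigma", min = 0)
  check_number(undershoot_depth, "undershoot_depth", min = 0)
  check_number(recovery_tau, "recovery_tau", min = 0, strict_min = TRUE)
  check_number(baseline_level, "baseline_level", min = 0, strict_min = TRUE)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  if (!is.null(seed)) check_count(seed, "seed")
  offs <- protocol$onsets + protocol$durations
  if (any(offs > duration + 1e-9)) {
    stop("stimulus windows must lie within the trace duration", call. = FALSE)
  }
  structure(
    list(protocol = protocol, onset_gain = onset_gain,
         adaptation_tau = adaptation_tau,
         fluctuation_sigma = fluctuation_sigma,
         undershoot_depth = undershoot_depth,
         recovery_tau = recovery_tau, baseline_level = baseline_level,
         noise_sigma = noise_sigma, duration = duration,
         sample_rate = sample_rate, seed = seed),
    class = "stim_sim_params")
}

#' Simulate a stimulus-response fluorescence trace
#'
#' During each stimulus window the response is `onset_gain` (sustained,
#' wild-type-like, when `adaptation_tau` is `NULL`) or
#' `onset_gain * exp(-(t - onset)/adaptation_tau)` (adapting,
#' Orco-mutant-like). After offset, sustained-mode traces drop to
#' `-undershoot_depth` below baseline and recover exponentially with
#' `recovery_tau`; adapting-mode traces continue from their offset value
#' toward baseline with `recovery_tau`, staying at or above baseline.
#' Raw fluorescence is `baseline_level * (1 + response) + noise`.
#'
#' @param params a [stim_sim_params()] object.
#' @return a [fluorescence_trace()].
#' @export
simulate_stim_response_trace <- function(params) {
  stopifnot(inherits(params, "stim_sim_params"))
  p <- params
  n <- round(p$duration * p$sample_rate)
  t <- (seq_len(n) - 1) / p$sample_rate
  with_seed(p$seed, {
    r <- numeric(n)
    fluct <- if (p$fluctuation_sigma > 0) {
      # AR(1) with lag-1 coefficient 0.9, stationary sd fluctuation_sigma
      e <- stats::rnorm(n, 0, p$fluctuation_sigma * sqrt(1 - 0.9^2))
      as.numeric(stats::filter(e, 0.9, method = "recursive"))
    } else numeric(n)
    for (w in seq_along(p$protocol$onsets)) {
      on <- p$protocol$onsets[w]
      off <- on + p$protocol$durations[w]
      during <- t >= on & t < off
      after <- t >= off
      if (is.null(p$adaptation_tau)) {
        r[during] <- p$onset_gain + fluct[during]
        r[after] <- -p$undershoot_depth * exp(-(t[after] - off) / p$recovery_tau)
      } else {
        r[during] <- p$onset_gain * exp(-(t[during] - on) / p$adaptation_tau)
        r_off <- p$onset_gain * exp(-(off - on) / p$adaptation_tau)
        r[after] <- r_off * exp(-(t[after] - off) / p$recovery_tau)
      }
    }
    noise <- if (p$noise_sigma > 0) stats::rnorm(n, 0, p$noise_sigma) else 0
    values <- p$baseline_level * (1 + r) + noise
    fluorescence_trace(values, sample_rate = p$sample_rate,
                       label = "simulated_response")
  })
}

#' Simulate an image stack from per-ROI traces
#'
#' Paints each ROI's pixels with its trace value frame by frame on a flat
#' background, then adds Gaussian noise. Used as a fixture generator for
#' testing ROI extraction and preprocessing.
#'
#' @param rois list of [roi()] objects; footprints must be disjoint and
#'   inside the frame.
#' @param traces list of [fluorescence_trace()] objects, one per ROI, all
#'   the same length.
#' @param dims frame dimensions `c(height, width)` in pixels.
#' @param background_level background intensity.
#' @param noise_sigma per-pixel Gaussian noise s.d.
#' @param seed integer seed.
#' @return an [image_stack()] with one frame per trace sample.
#' @export
simulate_image_stack <- function(rois, traces, dims = c(32, 32),
                                 background_level = 10, noise_sigma = 0,
                                 seed = NULL) {
  stopifnot(is.list(rois), is.list(traces), length(rois) == length(traces))
  if (length(rois) == 0L) stop("at least one ROI is required", call. = FALSE)
  lapply(rois, function(r) stopifnot(inherits(r, "roi")))
  lens <- vapply(traces, function(tr) length(tr$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all traces must have the same length", call. = FALSE)
  }
  check_number(background_level, "background_level")
  check_number(noise_sigma, "noise_sigma", min = 0)
  h <- dims[1]; w <- dims[2]
  occupied <- matrix(FALSE, h, w)
  for (r in rois) {
    px <- r$pixels
    if (any(px[, 1] < 1 | px[, 1] > h | px[, 2] < 1 | px[, 2] > w)) {
      stop(sprintf("ROI '%s' extends outside the %dx%d frame", r$label, h, w),
           call. = FALSE)
    }
    idx <- cbind(px[, 1], px[, 2])
    if (any(occupied[idx])) {
      stop(sprintf("ROI '%s' overlaps another ROI", r$label), call. = FALSE)
    }
    occupied[idx] <- TRUE
  }
  n_frames <- lens[1]
  rate <- traces[[1]]$sample_rate
  with_seed(seed, {
    frames <- array(background_level, dim = c(n_frames, h, w))
    for (k in seq_along(rois)) {
      px <- rois[[k]]$pixels
      vals <- traces[[k]]$values
      for (f in seq_len(n_frames)) {
        frames[cbind(f, px[, 1], px[, 2])] <- vals[f]
      }
    }
    if (noise_sigma > 0) {
      frames <- frames + stats::rnorm(length(frames), 0, noise_sigma)
    }
    image_stack(frames, frame_interval = 1 / rate)
  })
}
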