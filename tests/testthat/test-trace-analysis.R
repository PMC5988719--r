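# dF/F0, event detection, frequency, spectra, response metrics, averaging.

test_that("compute_dff follows the lowest-quartile and onset conventions", {
  const <- fluorescence_trace(rep(5, 20), 10)
  d <- compute_dff(const, "prior_percentile")
  expect_equal(d$values, rep(0, 20))
  expect_equal(d$f0, 5)

  tr <- fluorescence_trace(1:8, 10)
  d <- compute_dff(tr, "prior_percentile")
  expect_equal(d$f0, 1.5)                # mean of the lowest 2 of 8 samples
  expect_equal(d$values[3], (3 - 1.5) / 1.5) # dF/F0 = 1.0 at F = 3

  prot <- stimulus_protocol("continuous", 0, 1)
  stim <- fluorescence_trace(c(rep(10, 9), 15, 12), 10)
  d <- compute_dff(stim, "stim_onset_frames", protocol = prot)
  expect_equal(d$f0, 10)                 # nine frames from onset
  expect_equal(d$values[10], 0.5)

  expect_error(compute_dff(fluorescence_trace(1:3, 10), "prior_percentile"),
               "4 samples")
  expect_error(compute_dff(stim, "stim_onset_frames"), "protocol")
  neg <- fluorescence_trace(c(-5, -4, -3, -2, 1, 2, 3, 4), 10)
  expect_error(compute_dff(neg, "prior_percentile"), "F0")
})

test_that("dF/F0 is invariant to positive rescaling of the raw trace", {
  set.seed(5)
  raw <- 100 + cumsum(rnorm(200))
  a <- compute_dff(fluorescence_trace(raw, 20), "prior_percentile")
  b <- compute_dff(fluorescence_trace(3.7 * raw, 20), "prior_percentile")
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("detect_events applies the 2-sigma run rule", {
  # constant trace: sigma = 0, zero events (not a division error)
  d <- structure(list(values = rep(0.5, 40), f0 = 1, mode = "prior_percentile",
                      sample_rate = 10, label = "c"), class = "dff_trace")
  expect_length(detect_events(d)$event_times, 0)

  # zeros with a single 10: median 0, sd ~2.18, threshold 4.36 < 10
  v <- c(rep(0, 20), 10)
  d <- structure(list(values = v, f0 = 1, mode = "prior_percentile",
                      sample_rate = 10, label = "s"), class = "dff_trace")
  ev <- detect_events(d)
  expect_length(ev$event_times, 1)
  expect_equal(ev$event_times, 2.0)       # sample 21 at 10 /s
  expect_equal(ev$event_amplitudes, 10)
  expect_gt(10, ev$baseline + 2 * ev$sigma)

  # event count is invariant to an additive constant
  set.seed(8)
  v2 <- rnorm(300, 0, 0.05); v2[c(50, 150, 250)] <- 1
  d2 <- structure(list(values = v2, f0 = 1, mode = "prior_percentile",
                       sample_rate = 20, label = "x"), class = "dff_trace")
  d3 <- d2; d3$values <- d2$values + 5
  expect_equal(detect_events(d2)$event_times, detect_events(d3)$event_times)

  d_bad <- d2; d_bad$values[5] <- NA
  expect_error(detect_events(d_bad), "non-finite")
})

test_that("detected counts track ground truth on simulated traces", {
  sim <- simulate_calcium_trace(calcium_sim_params(event_rate = 0.5, seed = 33))
  ev <- detect_events(compute_dff(sim$trace, "prior_percentile"))
  n_true <- length(sim$ground_truth$event_times)
  expect_lt(abs(length(ev$event_times) - n_true) / n_true, 0.2)
})

test_that("event_frequency divides count by duration", {
  expect_equal(event_frequency(make_event_set(seq(0.5, 8.5, by = 1),
                                              duration = 10)), 0.9)
  expect_equal(event_frequency(make_event_set(numeric(0), numeric(0),
                                              duration = 10)), 0)
  expect_error(event_frequency(make_event_set(1), duration = 0), "duration")
})

test_that("periodogram localizes tones, kills constants, obeys Parseval", {
  rate <- 20; t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  s <- structure(list(values = sin(2 * pi * 0.5 * t), f0 = 1,
                      mode = "prior_percentile", sample_rate = rate,
                      label = "tone"), class = "dff_trace")
  ps <- power_spectrum(s)
  expect_equal(ps$frequencies[which.max(ps$power)], 0.5)

  const <- structure(list(values = rep(2, 100), f0 = 1,
                          mode = "prior_percentile", sample_rate = rate,
                          label = "c"), class = "dff_trace")
  expect_equal(max(power_spectrum(const)$power), 0)

  set.seed(3)
  for (i in 1:5) {
    x <- structure(list(values = rnorm(240), f0 = 1,
                        mode = "prior_percentile", sample_rate = rate,
                        label = "w"), class = "dff_trace")
    ps <- power_spectrum(x)
    df <- ps$frequencies[2] - ps$frequencies[1]
    v <- mean((x$values - mean(x$values))^2)
    expect_lt(abs(sum(ps$power) * df - v) / v, 1e-6)
  }
})

test_that("spectrum averaging computes mean and SEM and checks rates", {
  mk <- function(vals, rate = 20) structure(
    list(values = vals, f0 = 1, mode = "prior_percentile",
         sample_rate = rate, label = "t"), class = "dff_trace")
  s1 <- power_spectrum(mk(sin(1:100)))
  s2 <- power_spectrum(mk(cos(1:100)))
  avg <- average_spectra(list(s1, s2))
  expect_equal(avg$mean_power, (s1$power + s2$power) / 2)
  expect_equal(avg$sem_power,
               apply(rbind(s1$power, s2$power), 2, sd) / sqrt(2))
  s3 <- power_spectrum(mk(sin(1:100), rate = 10))
  expect_error(average_spectra(list(s1, s3)), "sample rate")
})

test_that("rate-modulated traces show a spectral peak; unmodulated do not", {
  f0 <- 1.0 # Hz
  get_avg <- function(modulated) {
    specs <- lapply(1:20, function(s) {
      p <- calcium_sim_params(
        event_rate = 0.9,
        rate_modulation_freq = if (modulated) f0 else NULL,
        rate_modulation_depth = if (modulated) 1 else 0,
        seed = 4000 + s)
      power_spectrum(compute_dff(simulate_calcium_trace(p)$trace,
                                 "prior_percentile"))
    })
    average_spectra(specs)
  }
  avg_m <- get_avg(TRUE); avg_u <- get_avg(FALSE)
  band <- which(abs(avg_m$frequencies - f0) <= 0.1)
  flank <- which(abs(avg_m$frequencies - f0) > 0.25 &
                   abs(avg_m$frequencies - f0) <= 0.6)
  ratio_m <- mean(avg_m$mean_power[band]) / mean(avg_m$mean_power[flank])
  ratio_u <- mean(avg_u$mean_power[band]) / mean(avg_u$mean_power[flank])
  expect_gt(ratio_m, 1.5)   # clear local peak at the modulation frequency
  expect_lt(ratio_u, 1.5)   # absent without modulation
})

test_that("response metrics handle the degenerate and truncated cases", {
  prot <- stimulus_protocol("continuous", 10, 18)
  flat <- simulate_stim_response_trace(stim_sim_params(
    prot, onset_gain = 0, duration = 60))
  m <- response_metrics(compute_dff(flat, "pre_onset", protocol = prot), prot)
  expect_equal(m$dff_max, 0)
  expect_equal(m$return_time, 0)
  # post window longer than the trace warns and truncates
  expect_warning(
    response_metrics(compute_dff(flat, "pre_onset", protocol = prot), prot,
                     post_window = 500), "truncated")
})

test_that("prior/evoked ratio is the documented percentage", {
  expect_equal(prior_to_evoked_ratio(make_event_set(1, 0.3), 0.6), 50)
  expect_equal(prior_to_evoked_ratio(make_event_set(c(1, 2), c(0.2, 0.4)),
                                     0.6), 50)
  expect_warning(r <- prior_to_evoked_ratio(
    make_event_set(numeric(0), numeric(0)), 0.6), "undefined")
  expect_true(is.na(r))
})

test_that("trace averaging returns mean and SEM with contracts", {
  mk <- function(vals) structure(
    list(values = vals, f0 = 1, mode = "prior_percentile",
         sample_rate = 10, label = "t"), class = "dff_trace")
  a <- mk(rep(1, 10)); b <- mk(rep(-1, 10))
  avg <- average_traces(list(a, b))
  expect_equal(avg$mean, rep(0, 10))
  expect_equal(avg$sem, rep(1, 10)) # sd = sqrt(2), /sqrt(2) = 1
  same <- average_traces(list(a, a))
  expect_equal(same$mean, a$values)
  expect_equal(same$sem, rep(0, 10))
  single <- average_traces(list(a))
  expect_true(all(is.na(single$sem)))
  expect_error(average_traces(list(a, mk(rep(1, 5)))), "length")
})
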