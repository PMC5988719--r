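# Generators: determinism, degenerate cases, Poisson statistics, geometry.

test_that("calcium generator handles the no-event, no-noise case", {
  p <- calcium_sim_params(event_rate = 0, noise_sigma = 0, drift_slope = 0,
                          seed = 1)
  sim <- simulate_calcium_trace(p)
  expect_equal(sim$trace$values, rep(p$baseline_level, 1200))
  expect_length(sim$ground_truth$event_times, 0)
  expect_equal(length(sim$trace$values), round(p$duration * p$sample_rate))
})

test_that("generators are bit-identical under the same seed", {
  p <- calcium_sim_params(seed = 11)
  expect_identical(simulate_calcium_trace(p), simulate_calcium_trace(p))

  prot <- stimulus_protocol("continuous", 5, 18)
  sp <- stim_sim_params(prot, noise_sigma = 0.5, duration = 40, seed = 3)
  expect_identical(simulate_stim_response_trace(sp),
                   simulate_stim_response_trace(sp))

  bp <- behavior_sim_params(n_larvae = 3, duration = 60, seed = 7)
  expect_identical(simulate_trajectories(bp), simulate_trajectories(bp))

  r <- roi(cbind(3:4, 3:4))
  tr <- fluorescence_trace(c(10, 20, 30), 5)
  expect_identical(
    simulate_image_stack(list(r), list(tr), c(8, 8), noise_sigma = 1, seed = 5),
    simulate_image_stack(list(r), list(tr), c(8, 8), noise_sigma = 1, seed = 5))
})

test_that("invalid parameters are rejected with the parameter name", {
  expect_error(calcium_sim_params(event_rate = -1), "event_rate")
  expect_error(calcium_sim_params(kernel_rise_tau = 0), "kernel_rise_tau")
  expect_error(calcium_sim_params(kernel_decay_tau = 0.01), "kernel_decay_tau")
  expect_error(calcium_sim_params(noise_sigma = NaN), "noise_sigma")
  expect_error(calcium_sim_params(duration = 0), "duration")
  expect_error(behavior_sim_params(p_turn_back_lit_to_dark = 1.2),
               "p_turn_back_lit_to_dark")
  expect_error(behavior_sim_params(n_larvae = 0), "n_larvae")
})

test_that("event counts follow the Poisson law", {
  # 200 seeded traces at 0.5 /s over 60 s: mean count within 3 SE of 30
  counts <- vapply(1:200, function(s) {
    length(simulate_calcium_trace(
      calcium_sim_params(event_rate = 0.5, seed = s))$ground_truth$event_times)
  }, numeric(1))
  se <- sqrt(30 / 200)
  expect_lt(abs(mean(counts) - 30), 3 * se)
  # WT-like rate 0.9 /s: expected count ~54 over 60 s
  counts <- vapply(1:200, function(s) {
    length(simulate_calcium_trace(
      calcium_sim_params(event_rate = 0.9, seed = 500 + s))$ground_truth$event_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 54), 3 * sqrt(54 / 200))
})

test_that("ground-truth event times are sorted and within the recording", {
  for (s in 1:10) {
    gt <- simulate_calcium_trace(calcium_sim_params(seed = s))$ground_truth
    expect_true(all(diff(gt$event_times) >= 0))
    expect_true(all(gt$event_times >= 0 & gt$event_times <= 60))
  }
})

test_that("stimulus-response closed forms hold in the noiseless limit", {
  prot <- stimulus_protocol("continuous", 10, 18)
  # adapting (Orco-like) mode: value at offset is exp(-18/6) of the gain
  orco <- simulate_stim_response_trace(stim_sim_params(
    prot, onset_gain = 1, adaptation_tau = 6, recovery_tau = 8,
    duration = 60, sample_rate = 5))
  rel <- (orco$values - 100) / 100
  expect_equal(rel[28 * 5 + 1], exp(-18 / 6), tolerance = 1e-10)
  expect_true(all(rel >= -1e-12)) # never undershoots the baseline
  # expected response decays monotonically during stimulation
  during <- rel[(10 * 5 + 1):(28 * 5)]
  expect_true(all(diff(during) <= 1e-12))

  # sustained (WT-like) mode: post-offset minimum is baseline - depth
  wt <- simulate_stim_response_trace(stim_sim_params(
    prot, onset_gain = 1, undershoot_depth = 0.1, recovery_tau = 2,
    duration = 60, sample_rate = 5))
  relw <- (wt$values - 100) / 100
  post <- relw[(28 * 5 + 1):length(relw)]
  expect_equal(min(post), -0.1, tolerance = 1e-10)

  # zero gain: baseline only
  z <- simulate_stim_response_trace(stim_sim_params(
    prot, onset_gain = 0, duration = 60))
  expect_equal(z$values, rep(100, 300))
})

test_that("overlapping stimulus windows are rejected", {
  expect_error(stimulus_protocol("pulse", c(0, 5), c(10, 1)), "overlap")
  prot <- stimulus_protocol("continuous", 10, 18)
  expect_error(stim_sim_params(prot, duration = 20), "within the trace")
})

test_that("image-stack generator paints ROIs on the background", {
  r <- roi(rbind(c(2, 2), c(2, 3)))
  tr <- fluorescence_trace(rep(100, 4), 5)
  st <- simulate_image_stack(list(r), list(tr), c(5, 5),
                             background_level = 10, noise_sigma = 0)
  expect_equal(st$frames[1, 2, 2], 100)
  expect_equal(st$frames[3, 2, 3], 100)
  expect_equal(st$frames[2, 4, 4], 10)
  # round trip through the extractor, filters off
  got <- extract_roi_trace(st, r)
  expect_equal(got$values, tr$values)
  # overlapping ROIs rejected
  r2 <- roi(rbind(c(2, 3), c(3, 3)))
  expect_error(simulate_image_stack(list(r, r2), list(tr, tr), c(5, 5)),
               "overlap")
  # out-of-bounds ROI rejected
  r3 <- roi(rbind(c(6, 2)))
  expect_error(simulate_image_stack(list(r3), list(tr), c(5, 5)), "outside")
})

test_that("trajectories respect arena geometry and degenerate limits", {
  sim <- simulate_trajectories(behavior_sim_params(n_larvae = 5,
                                                   duration = 120, seed = 2))
  pos <- sim$trajectories$positions
  expect_true(all(sqrt(pos$x^2 + pos$y^2) <= 5 + 1e-9))
  expect_equal(nrow(pos), 5 * 120)

  frozen <- simulate_trajectories(behavior_sim_params(
    n_larvae = 2, step_length_mean = 0, duration = 30, seed = 3))
  expect_true(all(frozen$trajectories$positions$x == 0))
  expect_true(all(frozen$trajectories$positions$y == 0))
})

test_that("a certain turn-back keeps larvae on the lit side once there", {
  ar <- arena_config()
  sim <- simulate_trajectories(behavior_sim_params(
    n_larvae = 6, p_turn_back_lit_to_dark = 1, p_enter_dark_to_lit = 1,
    duration = 300, seed = 9))
  pos <- sim$trajectories$positions
  for (id in unique(pos$larva_id)) {
    p <- pos[pos$larva_id == id, ]
    lit <- assign_quadrant(p$x, p$y, ar)$lit
    # "initialized in a lit quadrant" means clear of the boundary band:
    # before its first full band exit a larva makes no scored approaches
    out_band <- pmin(abs(p$x), abs(p$y)) >= 0.5
    first_lit <- which(out_band & !is.na(lit) & lit)[1]
    if (is.na(first_lit)) next
    later <- lit[first_lit:length(lit)]
    expect_false(any(!later[!is.na(later)]))
  }
})

test_that("ground truth records every approach with a Bernoulli outcome", {
  sim <- simulate_trajectories(behavior_sim_params(seed = 21))
  gt <- sim$ground_truth
  expect_true(all(gt$outcome %in% c("cross", "turn_back")))
  expect_true(all(gt$origin_side %in% c("lit", "dark")))
  expect_true(nrow(gt) > 0)
  for (id in unique(gt$larva_id)) {
    expect_true(all(diff(gt$time[gt$larva_id == id]) > 0))
  }
})
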