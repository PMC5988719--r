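# Quadrant geometry, performance index, boundary events and probabilities.

test_that("quadrant assignment follows the sign pattern and tie rule", {
  ar <- arena_config() # axes at 0 deg, quadrants I & III lit
  q <- assign_quadrant(c(1, -1, 0, -1, 1), c(1, 1, 1, -1, -1), ar)
  expect_equal(q$quadrant, c(1L, 2L, NA, 3L, 4L))
  expect_equal(q$lit, c(TRUE, FALSE, NA, TRUE, FALSE))
  # swapped parity flips every lit flag
  ar2 <- arena_config(lit_parity = "neg")
  q2 <- assign_quadrant(c(1, -1), c(1, 1), ar2)
  expect_equal(q2$lit, c(FALSE, TRUE))
})

test_that("performance index implements the counted-position formula", {
  mk <- function(x, y, ids = 1) trajectory_set(
    data.frame(larva_id = rep(ids, each = length(x) / length(ids)),
               frame = rep(seq_len(length(x) / length(ids)), length(ids)),
               x = x, y = y))
  ar <- arena_config()
  all_lit <- mk(c(1, 2, 1.5), c(1, 2, 0.5))
  expect_equal(performance_index(all_lit, ar)$pi, 1)
  split <- mk(c(1, -1), c(1, 1))
  expect_equal(performance_index(split, ar)$pi, 0)
  # 2000 lit / 1000 dark positions -> PI = 1/3
  n_lit <- 2000; n_dark <- 1000
  xs <- c(rep(1, n_lit), rep(-1, n_dark)); ys <- rep(1, n_lit + n_dark)
  big <- trajectory_set(data.frame(larva_id = rep(1:10, each = 300),
                                   frame = rep(1:300, 10), x = xs, y = ys))
  res <- performance_index(big, ar)
  expect_equal(res$pi, 1 / 3)
  expect_equal(res$n_light, 2000)
  expect_equal(res$n_total, 3000)
  expect_equal(res$n_larvae, 10)
  expect_error(performance_index(mk(numeric(0), numeric(0)), ar), "empty")
})

test_that("PI is antisymmetric under lit-parity swap", {
  sim <- simulate_trajectories(behavior_sim_params(seed = 12))
  a <- performance_index(sim$trajectories, arena_config())$pi
  b <- performance_index(sim$trajectories,
                         arena_config(lit_parity = "neg"))$pi
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("PI and event counts are invariant under joint rotation", {
  sim <- simulate_trajectories(behavior_sim_params(n_larvae = 5,
                                                   duration = 150, seed = 14))
  pos <- sim$trajectories$positions
  theta <- 33 * pi / 180
  rot <- trajectory_set(data.frame(
    larva_id = pos$larva_id, frame = pos$frame,
    x = cos(theta) * pos$x - sin(theta) * pos$y,
    y = sin(theta) * pos$x + cos(theta) * pos$y),
    frame_rate = sim$trajectories$frame_rate)
  ar0 <- arena_config()
  ar1 <- arena_config(quadrant_axes_angle = 33)
  expect_equal(performance_index(rot, ar1)$pi,
               performance_index(sim$trajectories, ar0)$pi,
               tolerance = 1e-9)
  ev0 <- detect_boundary_events(sim$trajectories, ar0)
  ev1 <- detect_boundary_events(rot, ar1)
  expect_equal(nrow(ev0), nrow(ev1))
  expect_equal(ev0$outcome, ev1$outcome)
  expect_equal(ev0$origin_side, ev1$origin_side)
})

test_that("constructed paths give the stated boundary outcomes", {
  ar <- arena_config()
  # straight walk from dark (x < 0) across x = 0 into lit quadrant I
  xs <- seq(-2, 2, by = 0.25)
  tr <- trajectory_set(data.frame(larva_id = 1, frame = seq_along(xs),
                                  x = xs, y = 2))
  ev <- detect_boundary_events(tr, ar, band_width = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$origin_side, "dark")
  expect_equal(ev$outcome, "cross")

  # enter the band from the lit side and retreat: one turn-back
  xs <- c(2, 1.5, 1, 0.6, 0.3, 0.2, 0.4, 0.8, 1.4, 2)
  tr <- trajectory_set(data.frame(larva_id = 1, frame = seq_along(xs),
                                  x = xs, y = 2))
  ev <- detect_boundary_events(tr, ar, band_width = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$origin_side, "lit")
  expect_equal(ev$outcome, "turn_back")

  # oscillation within one band visit still scores once
  xs <- c(2, 1, 0.4, 0.2, 0.45, 0.2, 0.4, 1, 2)
  tr <- trajectory_set(data.frame(larva_id = 1, frame = seq_along(xs),
                                  x = xs, y = 2))
  expect_equal(nrow(detect_boundary_events(tr, ar, band_width = 0.5)), 1)

  expect_error(detect_boundary_events(tr, ar, band_width = 5), "band_width")
})

test_that("boundary probabilities are outcome fractions with counts", {
  ev <- data.frame(
    larva_id = 1:14,
    time = 1:14,
    origin_side = c(rep("lit", 4), rep("dark", 10)),
    outcome = c("turn_back", "turn_back", "turn_back", "cross",
                rep("cross", 10)))
  bp <- boundary_probabilities(ev)
  expect_equal(bp$p_turn_back, 0.75)
  expect_equal(bp$n_lit_approaches, 4)
  expect_equal(bp$p_enter_lit, 1)
  expect_equal(bp$n_dark_approaches, 10)
  expect_equal(sum(bp$counts), 14)
  expect_equal(bp$counts["lit", "turn_back"], 3)
  # zero approaches on one side: probability undefined
  only_lit <- ev[ev$origin_side == "lit", ]
  expect_true(is.na(boundary_probabilities(only_lit)$p_enter_lit))
})

test_that("detected events agree with generator ground truth", {
  total_agree <- 0; total_n <- 0
  for (s in 1:5) {
    sim <- simulate_trajectories(behavior_sim_params(seed = 100 + s))
    ev <- detect_boundary_events(sim$trajectories, arena_config(),
                                 band_width = 0.5)
    a <- event_agreement(sim$ground_truth, ev)
    total_agree <- total_agree + a * max(nrow(ev), nrow(sim$ground_truth))
    total_n <- total_n + max(nrow(ev), nrow(sim$ground_truth))
  }
  expect_gte(total_agree / total_n, 0.95)
})

test_that("turn-back probability is recovered from pooled approaches", {
  for (p_true in c(0.955, 0.51)) {
    events <- list(); s <- 0
    n_lit <- 0
    while (n_lit < 600) {
      s <- s + 1
      sim <- simulate_trajectories(behavior_sim_params(
        p_turn_back_lit_to_dark = p_true, seed = 7000 + s))
      ev <- detect_boundary_events(sim$trajectories, arena_config())
      events[[s]] <- ev
      n_lit <- n_lit + sum(ev$origin_side == "lit")
    }
    bp <- boundary_probabilities(do.call(rbind, events))
    expect_lt(abs(bp$p_turn_back - p_true), 0.05)
  }
})

test_that("trajectory tables round-trip", {
  sim <- simulate_trajectories(behavior_sim_params(n_larvae = 2,
                                                   duration = 20, seed = 1))
  path <- tempfile(fileext = ".tsv")
  write_trajectory_table(sim$trajectories, path)
  back <- load_trajectory_table(path)
  expect_equal(back$positions$x, sim$trajectories$positions$x,
               tolerance = 1e-6)
  expect_equal(back$positions$larva_id, sim$trajectories$positions$larva_id)
})
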