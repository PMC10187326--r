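pp_default <- function() peak_params(0.3, 0.3, 0.5)

test_that("flat and empty signals yield no peaks", {
  expect_length(find_peaks(rep(1, 100), pp_default(), sample_rate = 100), 0L)
  expect_length(find_peaks(numeric(0), pp_default(), sample_rate = 100), 0L)
})

test_that("a 2 Hz sinusoid yields one peak per cycle", {
  t <- seq(0, 9.99, by = 0.01)
  s <- 0.5 * sin(2 * pi * 2 * t)
  pk <- find_peaks(s, peak_params(0.3, 0.3, 0.5), sample_rate = 100)
  expect_length(pk, 20L)
  # peaks sit at the sinusoid maxima, 0.5 s apart (to sample resolution:
  # the true maxima fall exactly between samples)
  expect_true(all(diff(pk) %in% 49:51))
  expect_equal(sum(diff(pk)), 50 * 19, tolerance = 1e-12)
})

test_that("the closer, lower of two competing peaks is pruned", {
  v <- c(0, 0.25, 0.5, 0.75, 1.0, 0.75, 0.5, 0.45, 0.5, 0.6, 0.7, 0.8,
         0.6, 0.4, 0.2, 0.1, 0.05, 0, 0, 0)
  # peaks at 5 (height 1.0) and 12 (height 0.8), 7 samples apart
  pk <- find_peaks(v, peak_params(0.1, 10 / 10, 2), sample_rate = 10)
  expect_identical(pk, 5L)
  pk2 <- find_peaks(v, peak_params(0.1, 0.5, 2), sample_rate = 10)
  expect_identical(pk2, c(5L, 12L))
})

test_that("detection matches the naive oracle on random signals", {
  set.seed(11)
  for (i in 1:80) {
    n <- sample(30:400, 1)
    v <- random_signal(n)
    prom <- runif(1, 0.05, 0.8)
    dist <- runif(1, 0.05, 1.5)
    wmax <- runif(1, 0.05, 1.2)
    got <- find_peaks(v, peak_params(prom, dist, wmax), sample_rate = 20)
    want <- naive_find_peaks(v, 20, prom, dist, wmax)
    expect_identical(got, want)
  }
})

test_that("raising prominence or distance never adds peaks", {
  set.seed(12)
  for (i in 1:20) {
    v <- random_signal(300)
    n0 <- length(find_peaks(v, peak_params(0.2, 0.3, 1), sample_rate = 20))
    expect_lte(length(find_peaks(v, peak_params(0.4, 0.3, 1), sample_rate = 20)), n0)
    expect_lte(length(find_peaks(v, peak_params(0.2, 0.6, 1), sample_rate = 20)), n0)
  }
})

test_that("retained peaks respect the distance constraint", {
  set.seed(13)
  v <- random_signal(500)
  pk <- find_peaks(v, peak_params(0.1, 0.45, 2), sample_rate = 20)
  if (length(pk) > 1) expect_true(all(diff(pk) >= 0.45 * 20 - 1e-9))
})

test_that("hybrid counting recovers clean synthetic gait through an oracle gate", {
  sim <- simulate_recording(
    gait_scenario(600, 100,
                  bouts = list(c(10, 100, 200), c(180, 90, 150), c(360, 110, 150)),
                  seed = 21))
  cond <- condition_signal(sim$recording)
  ev <- wristep:::count_steps_gated(cond, sim$epochs, sim$epochs$true_label,
                                    pp_default())
  expect_lt(abs(ev$total - 500) / 500, 0.05)
  # conservation: per-epoch counts sum to the total
  expect_equal(sum(ev$epoch_counts), ev$total)
  # gating: nonwalk epochs contribute exactly zero
  expect_true(all(ev$epoch_counts[sim$epochs$true_label == "nonwalk"] == 0))
})

test_that("an all-nonwalk gate yields zero steps regardless of signal", {
  sim <- simulate_recording(
    gait_scenario(60, 100, bouts = list(c(5, 100, 80)), seed = 22))
  cond <- condition_signal(sim$recording)
  ev <- wristep:::count_steps_gated(cond, sim$epochs,
                                    rep("nonwalk", nrow(sim$epochs)),
                                    pp_default())
  expect_equal(ev$total, 0L)
})

test_that("spurious peaks on noise are bounded by duration / distance", {
  sim <- simulate_recording(
    gait_scenario(60, 100, arm_noise_sd = 0.3, seed = 23))
  cond <- condition_signal(sim$recording)
  ev <- wristep:::count_steps_gated(cond, sim$epochs,
                                    rep("walk", nrow(sim$epochs)),
                                    peak_params(0.1, 0.4, 1))
  expect_lte(ev$total, 60 / 0.4)
})

test_that("a short recording warns and returns zero steps", {
  tr <- orientation_windows(4, 12, 71)
  m <- train_classifier(tr, orientation_windows(2, 6, 72),
                        classifier_config(max_train_epochs = 20), 100)
  rec <- raw_recording(matrix(rnorm(300, sd = 0.01) + rep(c(0, 0, 1), each = 100),
                              ncol = 3), 100)
  expect_warning(ev <- hybrid_count(rec, m, NULL, pp_default()), "shorter")
  expect_equal(ev$total, 0L)
})

test_that("the default tuning grid spans the published ranges", {
  g <- default_peak_grid()
  expect_equal(range(g$prominence), c(0.1, 1))
  expect_equal(range(g$distance), c(0.2, 2))
  expect_equal(range(g$width_max), c(0.01, 1))
})

test_that("a single-cell grid is returned as-is", {
  sim <- simulate_recording(
    gait_scenario(60, 100, bouts = list(c(5, 100, 60)), seed = 24))
  g <- data.frame(prominence = 0.25, distance = 0.4, width_max = 0.5)
  tp <- tune_params(list(list(recording = sim$recording, epochs = sim$epochs)), g)
  expect_equal(tp$prominence, 0.25)
  expect_equal(tp$distance, 0.4)
  expect_equal(tp$width_max, 0.5)
  expect_error(tune_params(list(), g), "empty")
})

test_that("tuning lands below the constructed pulse amplitude and cadence gap", {
  val <- lapply(1:3, function(i) {
    sim <- simulate_recording(
      gait_scenario(300, 100, bouts = list(c(10, 100, 150), c(120, 100, 120)),
                    step_pulse_amplitude = 0.4, seed = 30 + i))
    list(recording = sim$recording, epochs = sim$epochs)
  })
  g <- default_peak_grid(prominence_step = 0.1, distance_step = 0.2,
                         width_step = 0.3)
  tp <- tune_params(val, g)
  expect_lte(tp$prominence, 0.4)   # else true 0.4 g pulses would be missed
  expect_lte(tp$distance, 0.6)     # else 0.6 s step spacing would merge
  # argmin: no grid cell achieves a lower MAE than the returned cell
  search <- attr(tp, "search")
  best_mae <- search$mae[search$prominence == tp$prominence &
                         search$distance == tp$distance &
                         search$width_max == tp$width_max]
  expect_equal(min(search$mae), best_mae)
})

test_that("tuning is invariant to participant order", {
  val <- lapply(1:3, function(i) {
    sim <- simulate_recording(
      gait_scenario(120, 100, bouts = list(c(10, 95 + i * 5, 80)),
                    seed = 40 + i))
    list(recording = sim$recording, epochs = sim$epochs)
  })
  g <- default_peak_grid(prominence_step = 0.3, distance_step = 0.6,
                         width_step = 0.5)
  a <- tune_params(val, g)
  b <- tune_params(rev(val), g)
  expect_equal(unclass(a)[c("prominence", "distance", "width_max")],
               unclass(b)[c("prominence", "distance", "width_max")])
})
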