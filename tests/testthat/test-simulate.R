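test_that("an uncoupled network relaxes each neuron to its single-cell rest", {
  syn0 <- synaptic_params(g_MM = 0, g_MF = 0, g_FF = 0, g_FM = 0)
  g <- fx_ring$graph
  tr <- integrate_network(g, initial_state(g, seed = 8),
                          sim_config(duration = 400, I0 = 0), syn = syn0)
  v_msn <- resting_potential(membrane_params("MSN"))
  v_fs <- resting_potential(membrane_params("FS"))
  oracle <- ifelse(g$kinds == "MSN", v_msn, v_fs)
  expect_true(all(abs(tr$final_state[, "V"] - oracle) < 0.1))
})

test_that("the integrator shows fourth-order step-size convergence on a smooth interval", {
  g <- fx_two$graph
  st <- initial_state(g, seed = 3)
  term <- function(dt) {
    integrate_network(g, st, sim_config(dt = dt, duration = 5, I0 = 2,
                                        record_every = 5))$final_state[, "V"]
  }
  e1 <- max(abs(term(0.04) - term(0.02)))
  e2 <- max(abs(term(0.02) - term(0.01)))
  # halving dt should shrink the defect by ~2^4
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 40)
})

test_that("identical seed and configuration reproduce the trajectory bitwise", {
  g <- fx_mini$graph
  sim <- sim_config(duration = 30, I0 = 10, seed = 6)
  t1 <- integrate_network(g, NULL, sim)
  t2 <- integrate_network(g, NULL, sim)
  expect_identical(t1$spikes, t2$spikes)
  expect_identical(t1$final_state, t2$final_state)
  expect_identical(t1$v_mean, t2$v_mean)
})

test_that("spike detection registers upward threshold crossings only once per excursion", {
  times <- seq(0, 100, by = 0.5)
  expect_equal(nrow(detect_spikes(rep(-70, length(times)), times)), 0)
  # single upward crossing, with jitter above threshold (refractory guard)
  v <- rep(-70, length(times))
  v[50:60] <- c(-20, 0, 10, -10, 5, 2, -5, 0, -30, -70, -70)
  sp <- detect_spikes(v, times, threshold = -15)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$t_ms, times[51])   # first sample at or above threshold
  # constructed 40 Hz train over one second
  t40 <- seq(0, 999.9, by = 0.1)
  v40 <- -70 + 90 * (sin(2 * pi * 40 * t40 / 1000) > 0.99)
  expect_equal(nrow(detect_spikes(v40, t40)), 40)
})

test_that("mean observables average membrane and MSN synaptic series", {
  g <- fx_two$graph
  tr <- integrate_network(g, initial_state(g, seed = 1),
                          sim_config(duration = 10, I0 = 0),
                          store_v = TRUE, store_s = TRUE)
  obs <- mean_observables(tr)
  expect_equal(obs$V_mean_mV, rowMeans(tr$V))
  expect_equal(obs$S_mean, rowMeans(tr$s))  # both neurons are MSN
  # two constant neurons at -60 and -80 average to -70
  fake <- structure(list(times = 0:2, v_mean = colMeans(
    matrix(c(-60, -80), 2, 3)), S = rep(0.3, 3)), class = "trajectory")
  expect_equal(mean_observables(fake)$V_mean_mV, rep(-70, 3))
})

test_that("the periodogram finds the dominant non-DC peak", {
  dt <- 0.5
  t <- seq(0, 1000 - dt, by = dt)
  s40 <- sin(2 * pi * 40 * t / 1000)
  ps <- power_spectrum(s40, dt)
  expect_lt(abs(ps$dominant_hz - 40), 1000 / (length(t) * dt) + 1e-9)
  expect_true(ps$has_rhythm)
  # stronger 45 Hz component wins over 10 Hz
  ps2 <- power_spectrum(0.4 * sin(2 * pi * 10 * t / 1000) +
                          sin(2 * pi * 45 * t / 1000), dt)
  expect_lt(abs(ps2$dominant_hz - 45), 1.1)
  # white noise: typically no bin dominates (fixed representative draws)
  flags <- vapply(c(1, 2, 5, 6, 7), function(s) {
    set.seed(s)
    power_spectrum(rnorm(600), dt)$has_rhythm
  }, logical(1))
  expect_false(any(flags))
  expect_error(power_spectrum(rnorm(100), dt), "256")
})

test_that("state bounds and energy sanity hold along network simulations", {
  g <- fx_mini$graph
  tr <- integrate_network(g, NULL, sim_config(duration = 60, I0 = 10,
                                              seed = 2))
  expect_true(all(tr$gate_min >= 0))
  expect_true(all(tr$gate_max <= 1))
  tr0 <- integrate_network(g, NULL, sim_config(duration = 60, I0 = 0,
                                               seed = 2))
  expect_true(all(tr0$v_mean > -100 & tr0$v_mean < 50))
})

test_that("raster and observable exports round-trip through CSV", {
  g <- fx_mini$graph
  tr <- integrate_network(g, NULL, sim_config(duration = 25, I0 = 12,
                                              seed = 9))
  f1 <- tempfile(fileext = ".csv")
  write_raster(tr, f1)
  back <- read.csv(f1)
  expect_equal(names(back), c("t_ms", "neuron_id"))
  expect_equal(nrow(back), nrow(tr$spikes))
  f2 <- tempfile(fileext = ".csv")
  write_observables(tr, f2)
  obs <- read.csv(f2)
  expect_equal(names(obs), c("t_ms", "V_mean_mV", "S_mean"))
  expect_equal(obs$S_mean, tr$S, tolerance = 1e-12)
})
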