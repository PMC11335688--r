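test_that("restriction averages synaptic activity over MSNs only", {
  g <- fx_ring$graph                 # 15 MSN + 1 FS
  st <- initial_state(g, seed = 1)
  st[, "s"] <- ifelse(g$kinds == "MSN", 0.7, 0.1)
  expect_equal(restrict_state(st, g), 0.7)
  st[, "s"] <- 0
  expect_equal(restrict_state(st, g), 0)
  msn <- which(g$kinds == "MSN")
  st[msn, "s"] <- rep(c(0.2, 0.6), length.out = length(msn))
  expect_equal(restrict_state(st, g),
               mean(rep(c(0.2, 0.6), length.out = length(msn))))
  expect_equal(restrict_state(st, g, over = "all"), mean(st[, "s"]))
  g_fs <- single_neuron_graph("FS")
  expect_error(restrict_state(initial_state(g_fs, 1), g_fs), "no MSNs")
})

test_that("the reference microstate is reproducible and honours settle_time = 0", {
  g <- fx_mini$graph
  cfg <- eqfree_config(seed = 5, settle_time = 0)
  expect_identical(make_reference_state(g, 10, cfg),
                   initial_state(g, seed = substream_seed(5L, 101L)))
  cfg2 <- eqfree_config(seed = 5, settle_time = 10)
  r1 <- make_reference_state(g, 10, cfg2)
  r2 <- make_reference_state(g, 10, cfg2)
  expect_identical(r1, r2)
  expect_true(all(r1[, -1] >= 0 & r1[, -1] <= 1))
  expect_true(all(is.finite(r1[, "V"])))
})

test_that("lifting writes the macrostate onto MSN synapses and nothing else", {
  g <- fx_mini$graph
  ref <- make_reference_state(g, 10, eqfree_config(seed = 5, settle_time = 10))
  msn <- g$kinds == "MSN"
  l0 <- lift_state(0.37, ref, g, lift_noise = 0, seed = 1)
  expect_true(all(l0[msn, "s"] == 0.37))
  expect_identical(l0[, 1:6], ref[, 1:6])
  expect_identical(l0[!msn, "s"], ref[!msn, "s"])
  l1 <- lift_state(0.5, ref, g, lift_noise = 0.05, seed = 2)
  expect_true(all(l1[, "s"] >= 0 & l1[, "s"] <= 1))
  expect_identical(l1, lift_state(0.5, ref, g, lift_noise = 0.05, seed = 2))
})

test_that("restriction inverts lifting in expectation, with the predicted clipping bias", {
  g <- fx_mini$graph
  ref <- make_reference_state(g, 10, eqfree_config(seed = 5, settle_time = 10))
  vals <- vapply(1:300, function(k) {
    restrict_state(lift_state(0.5, ref, g, 0.05, seed = 5000 + k), g)
  }, numeric(1))
  # CLT: sample mean of n_MSN noisy synapses, sigma = 0.05
  expect_lt(abs(mean(vals) - 0.5), 3 * 0.05 / sqrt(g$n_msn * 300) * 5)
  expect_lt(abs(sd(vals) - 0.05 / sqrt(g$n_msn)), 0.05 / sqrt(g$n_msn))
  # at the boundary, clipping biases upward by sigma * phi(0) = 0.01994
  v0 <- vapply(1:300, function(k) {
    restrict_state(lift_state(0, ref, g, 0.05, seed = 6000 + k), g)
  }, numeric(1))
  expect_lt(abs(mean(v0) - 0.05 * dnorm(0)), 0.003)
})

test_that("ensemble standard errors scale as one over the square root of the ensemble", {
  stp <- drift_stepper(function(x) -0.2 * (x - 0.4), T = 1,
                       lift_noise = 0.05, n_particles = 50)
  se5 <- vapply(1:40, function(r) {
    coarse_step(0.5, stp, n_ens = 5, seed = 100 + r)$se
  }, numeric(1))
  se20 <- vapply(1:40, function(r) {
    coarse_step(0.5, stp, n_ens = 20, seed = 500 + r)$se
  }, numeric(1))
  expect_equal(mean(se5) / mean(se20), 2, tolerance = 0.35)
  # repeated call with the same seed is identical
  expect_identical(coarse_step(0.5, stp, 5, seed = 3),
                   coarse_step(0.5, stp, 5, seed = 3))
})

test_that("a repeated mesh point yields an identical drift estimate", {
  stp <- drift_stepper(function(x) 0.1 - x^2, T = 0.5, lift_noise = 0.02,
                       n_particles = 50)
  cfg <- eqfree_config(T = 0.5, ensemble = 5,
                       S_mesh = c(0.2, 0.2, 0.4), seed = 9)
  cv <- estimate_f(stp, cfg)
  expect_identical(cv$f[1], cv$f[2])
  expect_false(identical(cv$f[1], cv$f[3]))
})

test_that("fixed points are read off analytic drift curves with stability", {
  mesh <- seq(0, 1, by = 0.05)
  curve1 <- data.frame(S = mesh, f = -(mesh - 0.3), stderr = 0)
  fp1 <- find_fixed_points(curve1)
  expect_equal(nrow(fp1), 1)
  expect_lt(abs(fp1$S_star - 0.3), 1e-3)
  expect_true(fp1$stable)

  curve2 <- data.frame(S = mesh, f = (mesh - 0.2) * (0.8 - mesh), stderr = 0)
  fp2 <- find_fixed_points(curve2)
  expect_equal(nrow(fp2), 2)
  expect_lt(max(abs(fp2$S_star - c(0.2, 0.8))), 1e-3)
  expect_equal(fp2$stable, c(FALSE, TRUE))
  expect_equal(fp2$slope, c(0.6, -0.6), tolerance = 0.05)

  curve3 <- data.frame(S = mesh, f = rep(-0.1, length(mesh)), stderr = 0)
  expect_equal(nrow(find_fixed_points(curve3)), 0)
  expect_error(find_fixed_points(data.frame(S = c(0, 1), f = c(1, -1),
                                            stderr = 0)), "3 mesh points")
})

test_that("statistically indistinguishable zeros are flagged marginal", {
  mesh <- seq(0, 1, by = 0.1)
  set.seed(4)
  f <- c(rep(0.05, 3), rnorm(5, 0, 0.002), rep(-0.05, 3))
  curve <- data.frame(S = mesh, f = f, stderr = rep(0.01, 11))
  fp <- find_fixed_points(curve)
  expect_gt(nrow(fp), 0)
  expect_true(any(fp$marginal))
})

test_that("the drift plug-in oracle is recovered pointwise within its error bars", {
  mu <- 0.05
  stp <- drift_stepper(function(x) mu - (x - 0.5)^2, T = 0.05,
                       lift_noise = 0.02, n_particles = 400, param = mu)
  cfg <- eqfree_config(T = 0.05, ensemble = 20,
                       S_mesh = seq(0, 1, 0.05), seed = 13)
  cv <- estimate_f(stp, cfg)
  z <- abs(cv$f - (mu - (cv$S - 0.5)^2)) / cv$stderr
  expect_gte(mean(z <= 2), 0.85)
  expect_true(all(z <= 4.5))
  fp <- find_fixed_points(cv)
  expect_equal(nrow(fp), 2)
  expect_lt(max(abs(sort(fp$S_star) - (0.5 + c(-1, 1) * sqrt(mu)))), 0.01)
})

test_that("the saddle-node of the synthetic drift is located by the parameter scan", {
  mk <- function(m) drift_stepper(function(x) m - (x - 0.5)^2, T = 0.1,
                                  lift_noise = 0.02, n_particles = 400,
                                  param = m)
  cfg <- eqfree_config(T = 0.1, ensemble = 20, S_mesh = seq(0, 1, 0.05),
                       seed = 17)
  bd <- bifurcation_scan(seq(-0.1, 0.1, by = 0.05), mk, cfg,
                         crit_tol = 0.01)
  expect_false(is.na(bd$I_crit))
  expect_lte(abs(bd$bracket[2] - bd$bracket[1]), 0.01 + 1e-12)
  expect_lt(abs(bd$I_crit), 0.03)
  # branches on the two-fixed-point side carry one stable and one unstable
  at05 <- bd$branches[abs(bd$branches$param - 0.05) < 1e-9, ]
  expect_equal(nrow(at05), 2)
  expect_setequal(at05$stable, c(TRUE, FALSE))
})

test_that("the horizon diagnostic accepts a converged coarse description", {
  # linear drift, horizon short enough that the chord bias is sub-noise
  fac <- function(T) drift_stepper(function(x) -0.2 * (x - 0.4), T = T,
                                   lift_noise = 0.05, n_particles = 50)
  cfg <- eqfree_config(T = 0.1, ensemble = 10, S_mesh = seq(0, 1, 0.1),
                       seed = 19)
  hd <- horizon_diagnostic(fac, cfg)
  expect_equal(names(hd), c("S", "f_T", "se_T", "f_2T", "se_2T", "agree"))
  expect_gte(attr(hd, "frac_agree"), 0.8)
})

test_that("drift curves and diagrams export with metadata", {
  stp <- drift_stepper(function(x) -x + 0.3, T = 0.5, lift_noise = 0.02,
                       n_particles = 50, param = 1.5)
  cfg <- eqfree_config(T = 0.5, ensemble = 4, S_mesh = seq(0, 1, 0.25),
                       seed = 2)
  cv <- estimate_f(stp, cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_fcurve(cv, f1, f2)
  back <- read.csv(f1)
  expect_equal(names(back), c("S", "f", "stderr"))
  meta <- jsonlite::read_json(f2)
  expect_equal(meta$I0, 1.5)
  expect_equal(meta$ensemble, 4)
})
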