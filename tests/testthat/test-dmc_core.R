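# Forward model: activation functions, drifts, first-passage simulation and
# the closed-form constant-drift oracles.

test_that("mean automatic activation matches its closed form", {
  p <- fig3_params()
  expect_equal(automatic_activation_mean(30, p), 20)   # peak value = amp
  expect_equal(automatic_activation_mean(0, p), 0)
  # direct high-precision evaluation: 20*exp(-2)*(60e/30) = 40/e
  expect_equal(automatic_activation_mean(60, p), 40 * exp(-1),
               tolerance = 1e-12)
  expect_error(automatic_activation_mean(-1, p), "non-negative")
})

test_that("activation is unimodal with argmax (a-1)*tau and max amp", {
  grid <- expand.grid(amp = c(5, 20, 50), tau = c(10, 30, 100),
                      aa_shape = c(1.5, 2, 3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- fig3_params(amp = g$amp, tau = g$tau, aa_shape = g$aa_shape)
    tt <- seq(0.01, 12 * g$tau, by = 0.01)
    v <- automatic_activation_mean(tt, p)
    expect_equal(tt[which.max(v)], (g$aa_shape - 1) * g$tau,
                 tolerance = 1e-3)
    expect_equal(max(v), g$amp, tolerance = 1e-4)
    # rises then falls: differences change sign exactly once
    expect_equal(sum(diff(sign(diff(v))) != 0), 1)
  }
})

test_that("automatic drift is the derivative of the mean activation", {
  p <- fig3_params()
  fd <- function(t, h = 1e-4)
    (automatic_activation_mean(t + h, p) -
       automatic_activation_mean(t - h, p)) / (2 * h)
  expect_equal(automatic_drift(30, p), 0, tolerance = 1e-12)  # at the peak
  expect_equal(automatic_drift(15, p), fd(15), tolerance = 1e-6)
  expect_equal(automatic_drift(15, p), 0.5495738, tolerance = 1e-6)
  expect_equal(automatic_drift(60, p), fd(60), tolerance = 1e-6)
  expect_equal(automatic_drift(60, p), -0.245253, tolerance = 1e-6)
  expect_gt(automatic_drift(15, p), 0)   # before the peak
  expect_lt(automatic_drift(60, p), 0)   # after the peak
  expect_error(automatic_drift(-5, p), "non-negative")
})

test_that("integrated automatic drift returns to baseline", {
  p <- fig3_params()
  for (T_end in c(200, 500, 2000)) {
    num <- stats::integrate(function(t) automatic_drift(t, p), 1e-8, T_end,
                            rel.tol = 1e-10)$value
    expect_lt(abs(num - automatic_activation_mean(T_end, p)), 1e-6)
  }
  expect_lt(abs(automatic_activation_mean(2000, fig3_params())), 1e-20)
})

test_that("total drift superimposes controlled and automatic components", {
  p <- fig3_params()
  expect_equal(total_drift(30, p, "congruent"), 0.5)  # automatic drift 0
  expect_equal(total_drift(15, p, "incongruent"),
               0.5 - automatic_drift(15, p))
  p0 <- fig3_params(amp = 0)
  for (cc in c("congruent", "incongruent"))
    expect_equal(total_drift(c(1, 50, 400), p0, cc), rep(0.5, 3))
  expect_error(total_drift(10, p, "neutral"), "congruency")
})

test_that("simulation is bit-reproducible and congruency-blind when amp=0", {
  p0 <- fig3_params(amp = 0)
  cfg <- simulation_config(n_trials = 500, seed = 42)
  a <- simulate_trials(p0, "congruent", cfg)
  b <- simulate_trials(p0, "congruent", cfg)
  expect_identical(a, b)
  # with no automatic process congruency only relabels the trials
  ci <- simulate_trials(p0, "incongruent", cfg)
  expect_identical(a[c("rt", "accuracy", "terminated")],
                   ci[c("rt", "accuracy", "terminated")])
  p <- fig3_params()
  expect_false(identical(
    simulate_trials(p, "congruent", cfg)$rt,
    simulate_trials(p, "incongruent", cfg)$rt))
})

test_that("trial records respect the rt/accuracy contracts", {
  p <- fig3_params(res = 250)
  tr <- simulate_trials(p, "congruent",
                        simulation_config(n_trials = 2000, seed = 9))
  done <- tr$terminated
  expect_true(all(tr$rt[done] >= 250 + 1))  # decision time at least one step
  expect_true(all(is.na(tr$rt[!done])))
  expect_true(all(is.na(tr$accuracy[!done])))
  expect_true(all(tr$accuracy[done] %in% 0:1))
  expect_error(simulation_config(n_trials = 0), "n_trials")
})

test_that("internal normal generator matches the standard normal", {
  z <- dmconflict:::cpp_znorm_sample(2e5, 20260101)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(stats::sd(z) - 1), 0.01)
  expect_lt(abs(mean(z^4) - 3), 0.08)  # kurtosis of N(0,1)
  ks <- suppressWarnings(stats::ks.test(z[1:5000], stats::pnorm))
  expect_gt(ks$p.value, 0.001)
})

test_that("closed-form oracles behave at their limits", {
  expect_equal(analytic_ddm_accuracy(0, 75, 4, 0), 0.5)
  expect_equal(analytic_ddm_accuracy(50, 75, 4, 0), 1, tolerance = 1e-10)
  expect_equal(analytic_ddm_accuracy(0.5, 75, 4, 0.5), {
    z <- 1.5 * 75; a <- 150; k <- 2 * 0.5 / 16
    (1 - exp(-k * z)) / (1 - exp(-k * a))
  })
  expect_equal(analytic_ddm_mean_dt(0, 75, 4), 75^2 / 16)
  expect_lt(analytic_ddm_mean_dt(100, 75, 4), 1)
})

test_that("amp=0 simulation agrees with both oracles (reduced n)", {
  p0 <- fig3_params(amp = 0)
  s <- simulate_trials(p0, "congruent",
                       simulation_config(dt = 0.1, n_trials = 20000,
                                         seed = 7))
  acc_hat <- mean(s$accuracy, na.rm = TRUE)
  acc <- analytic_ddm_accuracy(0.5, 75, 4, 0)
  expect_lt(abs(acc_hat - acc), 3 * sqrt(acc * (1 - acc) / 20000))
  dtm <- s$rt[s$terminated] - p0$res
  expect_lt(abs(mean(dtm) - analytic_ddm_mean_dt(0.5, 75, 4)),
            3 * stats::sd(dtm) / sqrt(length(dtm)))
})

test_that("raising the boundary raises accuracy and mean RT", {
  cfg <- simulation_config(n_trials = 50000, seed = 5)
  lo <- simulate_trials(fig3_params(bnds = 60), "incongruent", cfg)
  hi <- simulate_trials(fig3_params(bnds = 90), "incongruent", cfg)
  expect_gt(mean(hi$accuracy, na.rm = TRUE), mean(lo$accuracy, na.rm = TRUE))
  expect_gt(mean(hi$rt, na.rm = TRUE), mean(lo$rt, na.rm = TRUE))
})

test_that("trial tables round-trip through delimited text", {
  p <- fig3_params()
  tr <- simulate_trials(p, "congruent",
                        simulation_config(n_trials = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$rt, tr$rt)
  expect_equal(back$congruency, tr$congruency)
})

test_that("parameter invariants are enforced", {
  expect_error(dmc_parameters(tau = -1), "tau")
  expect_error(dmc_parameters(aa_shape = 1), "aa_shape")
  expect_error(dmc_parameters(sigma = 0), "sigma")
  expect_error(dmc_parameters(bnds = 0), "bnds")
  expect_error(dmc_parameters(strp = 1), "strp")
  expect_error(dmc_parameters(res = -10), "res")
})
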