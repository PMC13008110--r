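# Estimation engine: predicted proportions, chi-squared cost, differential
# evolution fits.

test_that("chi-squared cost matches the hand-computed example", {
  # N=100, p=(0.5,0.5), pi=(0.6,0.4): 100*(0.01/0.6 + 0.01/0.4)
  expect_equal(chi2_cost(list(c(0.5, 0.5)), list(c(0.6, 0.4)), N = 100),
               100 * (0.01 / 0.6 + 0.01 / 0.4))
  expect_equal(chi2_cost(list(c(0.5, 0.5)), list(c(0.6, 0.4)), N = 100),
               4.1667, tolerance = 1e-4)
})

test_that("chi-squared cost is zero at equality and linear in N", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(chi2_cost(list(p), list(p), N = 250), 0)
  c1 <- chi2_cost(list(c(0.5, 0.5)), list(c(0.55, 0.45)), N = 100)
  c2 <- chi2_cost(list(c(0.5, 0.5)), list(c(0.55, 0.45)), N = 200)
  expect_equal(c2, 2 * c1)
  expect_gt(c1, 0)
  # two conditions sum their weighted contributions
  expect_equal(
    chi2_cost(list(c(0.5, 0.5), c(0.5, 0.5)),
              list(c(0.6, 0.4), c(0.6, 0.4)), N = c(100, 100)),
    2 * chi2_cost(list(c(0.5, 0.5)), list(c(0.6, 0.4)), N = 100))
  expect_error(chi2_cost(list(c(0.5, 0.5)), list(c(0.3, 0.3, 0.4)),
                         N = 100), "bin structures")
  # audit form drops the square: 100*(-0.1/0.6 + 0.1/0.4)
  expect_equal(chi2_cost(list(c(0.5, 0.5)), list(c(0.6, 0.4)), N = 100,
                         form = "signed"),
               100 * (-0.1 / 0.6 + 0.1 / 0.4))
})

test_that("predicted proportions are self-consistent at the truth", {
  p <- fig3_params()
  obs_trials <- simulate_trials(p, "incongruent",
                                simulation_config(n_trials = 5000, seed = 1))
  obs <- bin_proportions(obs_trials, "incongruent")
  cfg <- fit_config(n_sim = 20000, max_time = 2000)
  pred <- predicted_proportions(p, obs, "incongruent", cfg, seed = 99)
  expect_equal(sum(pred), 1, tolerance = 1e-12)
  expect_lt(max(abs(pred - obs$proportions)), 0.03)
})

test_that("amp=0 predictions reproduce the analytic error rate", {
  p0 <- fig3_params(amp = 0, bnds = 50)
  obs_trials <- simulate_trials(p0, "congruent",
                                simulation_config(n_trials = 5000, seed = 2))
  obs <- bin_proportions(obs_trials, "congruent")
  cfg <- fit_config(n_sim = 50000, max_time = 2000)
  pred <- predicted_proportions(p0, obs, "congruent", cfg, seed = 17)
  err_pred <- sum(pred[grepl("error", names(pred))])
  err_true <- 1 - analytic_ddm_accuracy(p0$drc, p0$bnds, p0$sigma, p0$strp)
  expect_lt(abs(err_pred - err_true),
            3 * sqrt(err_true * (1 - err_true) / 50000))
})

test_that("the epsilon floor rescues empty predicted bins", {
  # overwhelming drift: essentially no simulated errors
  p <- fig3_params(amp = 0, drc = 1.5, bnds = 120)
  obs_trials <- data.frame(rt = c(380 + 1:30, 400, 410, 420),
                           accuracy = rep(c(1, 0), c(30, 3)),
                           congruency = "congruent")
  obs <- bin_proportions(obs_trials, "congruent")
  cfg <- fit_config(n_sim = 2000, max_time = 1500)
  pred <- predicted_proportions(p, obs, "congruent", cfg, seed = 3)
  err_bins <- pred[grepl("error", names(pred))]
  expect_true(all(err_bins > 0))
  expect_true(all(err_bins <= 2 * cfg$epsilon))  # floored, then renormalised
  expect_equal(sum(pred), 1, tolerance = 1e-12)
})

test_that("no-termination parameter vectors raise an informative error", {
  p <- fig3_params(amp = 0, drc = 0.05, bnds = 160, sigma = 4)
  obs_trials <- data.frame(rt = 400 + 1:40, accuracy = 1,
                           congruency = "congruent")
  obs <- bin_proportions(obs_trials, "congruent")
  cfg <- fit_config(n_sim = 1000, max_time = 40)  # absurdly short horizon
  expect_error(predicted_proportions(p, obs, "congruent", cfg, seed = 5),
               "terminated")
})

test_that("the cost is lowest near the generating parameters", {
  p <- fig3_params()
  trials <- simulate_condition_pair(p, n = 3000, seed = 11)
  observed <- list(congruent = bin_proportions(trials, "congruent"),
                   incongruent = bin_proportions(trials, "incongruent"))
  N <- vapply(observed, function(b) b$n_correct + b$n_error, numeric(1))
  cfg <- fit_config(n_sim = 5000, max_time = 2500)
  eval_at <- function(par, seed) {
    pred <- lapply(names(observed), function(cc)
      predicted_proportions(par, observed[[cc]], cc, cfg,
                            seed = seed + match(cc, names(observed))))
    chi2_cost(observed, pred, N)
  }
  wins <- 0L
  perturb <- c("amp", "tau", "drc", "bnds", "res")
  for (s in 1:2) {
    c_true <- eval_at(p, seed = 400 + 10 * s)
    for (nm in perturb) {
      args <- unclass(p)
      args$aa_shape <- NULL
      args[[nm]] <- args[[nm]] * 1.5
      c_pert <- eval_at(do.call(fig3_params, args), seed = 400 + 10 * s)
      wins <- wins + (c_true <= c_pert)
    }
  }
  expect_gte(wins, 8)  # majority across 2 seeds x 5 perturbations
})

test_that("fits are deterministic given a seed and respect bounds", {
  p <- fig3_params()
  trials <- simulate_condition_pair(p, n = 400, seed = 21)
  cfg <- test_fit_config(n_sim = 1000, max_gen = 4, np = 12)
  f1 <- fit_condition(trials, cfg, seed = 77)
  f2 <- fit_condition(trials, cfg, seed = 77)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$cost, f2$cost)
  est <- unlist(f1$par[c("amp", "tau", "drc", "bnds", "res")])
  expect_true(all(est >= cfg$bounds["lower", ] &
                    est <= cfg$bounds["upper", ]))
  expect_s3_class(f1, "dmc_fit")
  expect_equal(sort(unique(f1$obs_pred$congruency)),
               c("congruent", "incongruent"))
  expect_error(fit_condition(trials[trials$congruency == "congruent", ],
                             cfg), "incongruent")
})

test_that("fit_study covers every cell and reports skipped ones", {
  spec <- make_paper_like_spec("navon", n_subjects = 2, jitter_sd = 0,
                               seed = 41)
  spec$design <- subset_design(spec$design, sessions = "CZ", times = "pre")
  d <- generate_dataset(spec)
  # empty one cell's incongruent trials to exercise the skip path
  drop <- d$trials$subject == "S02" &
    d$trials$level_or_alignment == "local" &
    d$trials$congruency == "incongruent"
  trimmed <- d$trials[!drop, ]
  cfg <- test_fit_config(n_sim = 1000, max_gen = 2, np = 10)
  study <- fit_study(trimmed, cfg = cfg, seed = 10)
  # 2 subjects x 2 levels, one cell skipped
  expect_equal(nrow(study$parameters), 3L)
  expect_equal(nrow(study$skipped), 1L)
  expect_match(study$skipped$reason, "incongruent")
  expect_true(all(c("amp", "tau", "drc", "bnds", "res", "cost",
                    "converged") %in% names(study$parameters)))
  # identical rerun
  study2 <- fit_study(trimmed, cfg = cfg, seed = 10)
  expect_identical(study$parameters, study2$parameters)
})
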