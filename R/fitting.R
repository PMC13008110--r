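#' Fitting configuration
#'
#' Settings for the simulation-based quantile chi-squared fit. Three
#' parameters are fixed by convention: the diffusion constant `sigma = 4`
#' (the model's scaling parameter), the gamma shape `aa_shape = 2` (which
#' improves recovery of the remaining parameters), and the start point
#' `strp = 0` (midway between boundaries, accuracy coding). The five free
#' parameters `amp, tau, drc, bnds, res` are searched within box bounds by
#' differential evolution.
#'
#' Default bounds span the plausible range for conflict tasks on a 1 ms
#' time base: `amp` 0-60 evidence units, `tau` 5-300 ms, `drc` 0.05-1.5
#' per ms, `bnds` 20-160, `res` 100-600 ms.
#'
#' @param n_sim Simulated trials per congruency per objective evaluation.
#' @param dt Simulation step, ms.
#' @param max_time Decision-time horizon, ms.
#' @param bounds 2 x 5 matrix (rows `lower`, `upper`; columns `amp, tau,
#'   drc, bnds, res`).
#' @param fixed Named list of the fixed parameters.
#' @param de Differential-evolution settings: population size `np`
#'   (default 15 x dimension), mutation factor `F`, crossover rate `CR`,
#'   relative cost tolerance `tol`, and `max_gen` generations.
#' @param epsilon Floor for predicted bin proportions; default
#'   `1 / (2 * n_sim)`.
#' @param cost_form `"squared"` (chi-squared, default) or `"signed"`
#'   (audit mode: no square on the residual).
#' @param crossing Boundary-crossing detection mode for the prediction
#'   simulations; see [simulation_config()].
#' @return A list of class `dmc_fit_config`.
#' @export
fit_config <- function(n_sim = 50000, dt = 1, max_time = 4000,
                       bounds = NULL,
                       fixed = list(sigma = 4, aa_shape = 2, strp = 0),
                       de = list(), epsilon = NULL,
                       cost_form = c("squared", "signed"),
                       crossing = c("bridge", "step")) {
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  if (is.null(bounds)) {
    bounds <- rbind(lower = c(amp = 0, tau = 5, drc = 0.05, bnds = 20,
                              res = 100),
                    upper = c(amp = 60, tau = 300, drc = 1.5, bnds = 160,
                              res = 600))
  }
  if (!all(bounds["lower", ] < bounds["upper", ]))
    stop("each lower bound must be below its upper bound")
  de_defaults <- list(np = 15 * ncol(bounds), F = 0.8, CR = 0.9,
                      tol = 1e-6, max_gen = 200)
  de <- utils::modifyList(de_defaults, de)
  structure(list(n_sim = as.integer(n_sim), dt = dt, max_time = max_time,
                 bounds = bounds, fixed = fixed, de = de,
                 epsilon = if (is.null(epsilon)) 1 / (2 * n_sim) else epsilon,
                 cost_form = match.arg(cost_form),
                 crossing = match.arg(crossing)),
            class = "dmc_fit_config")
}

free_par_names <- c("amp", "tau", "drc", "bnds", "res")

params_from_theta <- function(theta, cfg) {
  dmc_parameters(drc = theta[["drc"]], amp = theta[["amp"]],
                 tau = theta[["tau"]], aa_shape = cfg$fixed$aa_shape,
                 sigma = cfg$fixed$sigma, bnds = theta[["bnds"]],
                 strp = cfg$fixed$strp, res = theta[["res"]])
}

# simulate n_sim trials at p and bin decision RTs into the observed edges;
# returns floored, condition-normalised predicted proportions
predict_props_raw <- function(p, observed, congruency, cfg, seed) {
  sgn <- congruency_sign(congruency)
  mu_dt <- drift_schedule(p, sgn, cfg$dt, cfg$max_time)
  cnt <- cpp_dmc_counts(mu_dt, p$sigma * sqrt(cfg$dt), p$strp * p$bnds,
                        p$bnds, cfg$dt, p$res, cfg$n_sim, as.double(seed),
                        observed$edges_correct, observed$edges_error,
                        identical(cfg$crossing, "bridge"))
  n_term <- cnt$n_correct + cnt$n_error
  if (n_term == 0L) return(NULL)
  pi_hat <- c(cnt$counts_correct, cnt$counts_error) / n_term
  pi_hat <- pmax(pi_hat, cfg$epsilon)
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- names(observed$proportions)
  pi_hat
}

#' Model-predicted bin proportions
#'
#' Simulates the model at parameters `p` and drops the simulated correct and
#' error RTs into the *observed* quantile-bin edges, returning proportions
#' normalised over the condition. Each proportion is floored at
#' `cfg$epsilon` and the vector renormalised, so the chi-squared cost never
#' divides by an empty predicted bin.
#'
#' @param p A [dmc_parameters()] object.
#' @param observed A `dmc_binning` from [bin_proportions()].
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param cfg A [fit_config()].
#' @param seed Simulation seed.
#' @return Named vector of predicted proportions (correct bins then error
#'   bins), summing to 1.
#' @export
predicted_proportions <- function(p, observed, congruency,
                                  cfg = fit_config(), seed = 1) {
  stopifnot(inherits(observed, "dmc_binning"))
  out <- predict_props_raw(p, observed, congruency, cfg, seed)
  if (is.null(out))
    stop("no simulated trial terminated for parameters: ",
         paste(sprintf("%s=%.4g", names(p), unlist(p)), collapse = ", "))
  out
}

#' Quantile chi-squared cost
#'
#' The adapted chi-squared cost
#' \deqn{\chi^2 = \sum_{i} N_i \sum_{j=1}^{m} \frac{(p_{ij} -
#'   \pi_{ij})^2}{\pi_{ij}},}
#' where `i` indexes the congruency conditions, `N_i` the number of data
#' points per condition, and `p`, `pi` the observed and predicted bin
#' proportions over correct and error RT bins jointly.
#'
#' @param observed List (one element per condition) of observed proportion
#'   vectors, or `dmc_binning` objects.
#' @param predicted List of predicted proportion vectors, matching
#'   `observed` in structure.
#' @param N Numeric vector of per-condition trial counts; defaults to the
#'   binning totals when `observed` holds `dmc_binning` objects.
#' @param form `"squared"` (default) or `"signed"` (audit form without the
#'   square; not a true chi-squared statistic).
#' @return Non-negative cost (0 iff observed = predicted under
#'   `"squared"`).
#' @export
chi2_cost <- function(observed, predicted, N = NULL,
                      form = c("squared", "signed")) {
  form <- match.arg(form)
  if (!is.list(observed) || inherits(observed, "dmc_binning"))
    observed <- list(observed)
  if (!is.list(predicted) || is.numeric(predicted))
    predicted <- list(predicted)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have one element per condition")
  if (is.null(N)) {
    if (!all(vapply(observed, inherits, TRUE, "dmc_binning")))
      stop("N must be supplied unless observed holds dmc_binning objects")
    N <- vapply(observed, function(b) b$n_correct + b$n_error, numeric(1))
  }
  if (length(N) != length(observed))
    stop("N must have one count per condition")
  total <- 0
  for (i in seq_along(observed)) {
    p <- if (inherits(observed[[i]], "dmc_binning"))
      observed[[i]]$proportions else as.numeric(observed[[i]])
    pi_hat <- as.numeric(predicted[[i]])
    if (length(p) != length(pi_hat))
      stop("bin structures differ in condition ", i, " (", length(p),
           " observed vs ", length(pi_hat), " predicted bins)")
    if (any(pi_hat <= 0))
      stop("predicted proportions must be positive (apply the epsilon floor)")
    resid <- if (form == "squared") (p - pi_hat)^2 else (p - pi_hat)
    total <- total + N[i] * sum(resid / pi_hat)
  }
  total
}

#' Fit the DMC to one design cell
#'
#' Estimates the five free parameters (`amp, tau, drc, bnds, res`) from the
#' trials of a single design cell (both congruency conditions jointly) by
#' minimising [chi2_cost()] between observed quantile-bin proportions and
#' simulation-based predictions, using differential evolution (best/1/bin).
#' One simulation seed per congruency is drawn once per fit and reused for
#' every candidate (common random numbers), making the objective — and the
#' whole fit — deterministic given `seed`.
#'
#' @param trials Data.frame with `rt`, `accuracy`, `congruency` columns,
#'   containing both congruency conditions (already preprocessed).
#' @param cfg A [fit_config()].
#' @param seed Integer seed controlling initialisation, DE proposals and the
#'   simulation streams.
#' @return An object of class `dmc_fit`: `par` (all eight parameters),
#'   `cost`, `n_evals`, `generations`, `converged`, `seed`, per-condition
#'   observed binnings, predicted proportions at the optimum, and an
#'   observed-vs-predicted long table (`obs_pred`).
#' @export
fit_condition <- function(trials, cfg = fit_config(), seed = 1) {
  stopifnot(inherits(cfg, "dmc_fit_config"))
  for (cc in c("congruent", "incongruent"))
    if (!any(trials$congruency == cc))
      stop("missing congruency condition: ", cc)
  observed <- list(
    congruent = bin_proportions(trials, "congruent"),
    incongruent = bin_proportions(trials, "incongruent"))
  N <- vapply(observed, function(b) b$n_correct + b$n_error, numeric(1))

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  sim_seeds <- sample.int(2147483647L, 2)

  lo <- cfg$bounds["lower", free_par_names]
  hi <- cfg$bounds["upper", free_par_names]
  d <- length(free_par_names)
  n_evals <- 0L

  objective <- function(theta) {
    names(theta) <- free_par_names
    p <- params_from_theta(theta, cfg)
    n_evals <<- n_evals + 1L
    pred <- list(
      congruent = predict_props_raw(p, observed$congruent, "congruent",
                                    cfg, sim_seeds[1]),
      incongruent = predict_props_raw(p, observed$incongruent,
                                      "incongruent", cfg, sim_seeds[2]))
    if (is.null(pred$congruent) || is.null(pred$incongruent))
      return(list(cost = Inf, pred = NULL))
    list(cost = chi2_cost(observed, pred, N, form = cfg$cost_form),
         pred = pred)
  }

  de <- cfg$de
  np <- de$np
  pop <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                nrow = np, ncol = d, dimnames = list(NULL, free_par_names))
  evals <- lapply(seq_len(np), function(i) objective(pop[i, ]))
  cost <- vapply(evals, `[[`, numeric(1), "cost")
  best_i <- which.min(cost)
  best_pred <- evals[[best_i]]$pred
  converged <- FALSE
  gen <- 0L
  while (gen < de$max_gen) {
    gen <- gen + 1L
    xb <- pop[best_i, ]
    for (i in seq_len(np)) {
      rr <- sample(seq_len(np)[-i], 2)
      v <- xb + de$F * (pop[rr[1], ] - pop[rr[2], ])
      jrand <- sample.int(d, 1)
      cross <- stats::runif(d) < de$CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, pop[i, ])
      u <- pmin(pmax(u, lo), hi)
      res_i <- objective(u)
      if (res_i$cost <= cost[i]) {
        pop[i, ] <- u
        cost[i] <- res_i$cost
        if (res_i$cost < cost[best_i]) {
          best_i <- i
          best_pred <- res_i$pred
        }
      }
    }
    spread <- max(cost) - min(cost)
    if (is.finite(spread) && spread <= de$tol * max(1e-12, abs(mean(cost)))) {
      converged <- TRUE
      break
    }
  }

  theta <- pop[best_i, ]
  par <- c(as.list(theta),
           sigma = cfg$fixed$sigma, aa_shape = cfg$fixed$aa_shape,
           strp = cfg$fixed$strp)
  obs_pred <- do.call(rbind, lapply(names(observed), function(cc) {
    data.frame(congruency = cc,
               bin = names(observed[[cc]]$proportions),
               observed = as.numeric(observed[[cc]]$proportions),
               predicted = as.numeric(best_pred[[cc]]),
               row.names = NULL)
  }))
  structure(list(par = par, cost = cost[best_i], n_evals = n_evals,
                 generations = gen, converged = converged, seed = seed,
                 sim_seeds = sim_seeds, N = N, observed = observed,
                 predicted = best_pred, obs_pred = obs_pred, cfg = cfg),
            class = "dmc_fit")
}

#' @export
print.dmc_fit <- function(x, ...) {
  cat("DMC fit (quantile chi-squared, differential evolution)\n")
  cat(sprintf("  cost = %.4f after %d evaluations (%d generations, %s)\n",
              x$cost, x$n_evals, x$generations,
              if (x$converged) "converged" else "generation limit"))
  est <- unlist(x$par[free_par_names])
  cat("  estimates:",
      paste(sprintf("%s=%.3g", names(est), est), collapse = "  "), "\n")
  invisible(x)
}

#' Fit the DMC across a study's design cells
#'
#' Splits a preprocessed trial table into design cells (subject x session x
#' time x level for hierarchical designs; subject x session x alignment for
#' composite designs — congruency pairs are always fitted jointly within a
#' cell) and runs [fit_condition()] in each. Cells emptied by preprocessing
#' or missing one congruency are reported in `skipped`, not silently
#' dropped.
#'
#' @param trials Preprocessed trial table.
#' @param task `"navon"` or `"composite"`; defaults to the table's single
#'   task label.
#' @param cfg A [fit_config()].
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return A list of class `dmc_study_fit` with `parameters` (tidy table:
#'   one row per cell with estimates and diagnostics), `fits` (named list
#'   of `dmc_fit` objects), `obs_pred` (long observed-vs-predicted table),
#'   and `skipped`.
#' @export
fit_study <- function(trials, task = NULL, cfg = fit_config(), seed = 1) {
  if (is.null(task)) {
    task <- unique(trials$task)
    if (length(task) != 1L)
      stop("trials mix tasks; pass task explicitly and subset")
  }
  cell_cols <- if (task == "navon")
    c("subject", "session", "time", "level_or_alignment")
  else c("subject", "session", "level_or_alignment")
  cell_cols <- intersect(cell_cols, names(trials))
  trials <- trials[trials$task == task, , drop = FALSE]
  if (!nrow(trials)) stop("no trials for task ", task)
  key <- interaction(trials[cell_cols], drop = TRUE, lex.order = TRUE)
  cells <- split(seq_len(nrow(trials)), key)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  cell_seeds <- sample.int(2147483647L, length(cells))

  rows <- list(); fits <- list(); skipped <- list(); obs_pred <- list()
  for (i in seq_along(cells)) {
    idx <- cells[[i]]
    cell_name <- names(cells)[i]
    cell_meta <- trials[idx[1], cell_cols, drop = FALSE]
    rownames(cell_meta) <- NULL
    sub <- trials[idx, , drop = FALSE]
    n_by_congr <- table(factor(sub$congruency,
                               c("congruent", "incongruent")))
    if (any(n_by_congr == 0)) {
      skipped[[cell_name]] <- cbind(cell_meta,
        reason = paste("missing", paste(names(n_by_congr)[n_by_congr == 0],
                                        collapse = "+")))
      next
    }
    fit <- fit_condition(sub, cfg, seed = cell_seeds[i])
    fits[[cell_name]] <- fit
    est <- as.data.frame(fit$par[free_par_names])
    rows[[cell_name]] <- cbind(cell_meta, est,
      data.frame(cost = fit$cost, converged = fit$converged,
                 n_congruent = as.integer(n_by_congr["congruent"]),
                 n_incongruent = as.integer(n_by_congr["incongruent"]),
                 seed = cell_seeds[i]))
    obs_pred[[cell_name]] <-
      cbind(cell_meta[rep(1L, nrow(fit$obs_pred)), , drop = FALSE],
            fit$obs_pred, row.names = NULL)
  }
  parameters <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(task = task,
                 parameters = parameters,
                 fits = fits,
                 obs_pred = do.call(rbind,
                                    c(obs_pred, list(make.row.names = FALSE))),
                 skipped = if (length(skipped))
                   do.call(rbind, c(skipped, list(make.row.names = FALSE)))
                 else NULL,
                 seed = seed),
            class = "dmc_study_fit")
}

#' Observed-vs-predicted diagnostic plot
#'
#' Scatter of observed against model-predicted bin proportions (correct and
#' error bins, all conditions pooled) with the identity line — points on the
#' diagonal indicate a faithful fit.
#'
#' @param x A `dmc_fit` or `dmc_study_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_observed_predicted <- function(x, ...) {
  op <- if (inherits(x, "dmc_study_fit")) x$obs_pred else x$obs_pred
  err <- grepl("^error", op$bin)
  graphics::plot(op$observed, op$predicted,
                 col = ifelse(err, "firebrick", "steelblue"), pch = 19,
                 xlab = "observed bin proportion",
                 ylab = "predicted bin proportion", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("correct bins", "error bins"),
                   col = c("steelblue", "firebrick"), pch = 19, bty = "n")
  invisible(op)
}
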