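#' Simulate DMC trials by Euler-Maruyama first-passage
#'
#' Integrates the decision process
#' \deqn{dX_t = [\mu_r + \mu_i(t)]\,dt + \sigma\,dW_t}
#' from \eqn{X_0 = strp \cdot bnds} with Gaussian increments of variance
#' \eqn{\sigma^2 dt}, terminating a trial at the first step where
#' \eqn{|X| \ge bnds}. The upper boundary codes the correct response
#' (accuracy coding); congruency enters only through the sign of the
#' automatic drift. RT is the crossing time plus the non-decision time `res`.
#' Trials still diffusing at `max_time` are returned with
#' `terminated = FALSE` and `NA` rt/accuracy.
#'
#' @param p A [dmc_parameters()] object.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param cfg A [simulation_config()] object.
#' @return A data.frame with columns `trial_index`, `congruency`, `rt`
#'   (ms), `accuracy` (0/1), `terminated`.
#' @examples
#' p <- dmc_parameters()
#' trials <- simulate_trials(p, "incongruent", simulation_config(n_trials = 500))
#' mean(trials$accuracy, na.rm = TRUE)
#' @export
simulate_trials <- function(p, congruency, cfg = simulation_config()) {
  stopifnot(inherits(p, "dmc_parameters"), inherits(cfg, "dmc_sim_config"))
  sgn <- congruency_sign(congruency)
  mu_dt <- drift_schedule(p, sgn, cfg$dt, cfg$max_time)
  sim <- cpp_dmc_simulate(mu_dt, p$sigma * sqrt(cfg$dt), p$strp * p$bnds,
                          p$bnds, cfg$n_trials, as.double(cfg$seed),
                          identical(cfg$crossing, "bridge"))
  term <- sim$step > 0L
  rt <- ifelse(term, sim$step * cfg$dt + p$res, NA_real_)
  acc <- ifelse(term, as.integer(sim$upper), NA_integer_)
  data.frame(trial_index = seq_len(cfg$n_trials),
             congruency = congruency,
             rt = rt, accuracy = acc, terminated = term,
             stringsAsFactors = FALSE)
}

# per-step total drift premultiplied by dt, evaluated at step start times
drift_schedule <- function(p, sgn, dt, max_time) {
  n_steps <- as.integer(ceiling(max_time / dt))
  t_start <- (seq_len(n_steps) - 1) * dt
  (p$drc + sgn * automatic_drift(t_start, p)) * dt
}

#' Write / read simulated trial tables
#'
#' Plain tab-delimited serialization of a trial table (simulated or
#' empirical) with a header row.
#'
#' @param trials A trial data.frame.
#' @param path File path.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Absorption probability of a constant-drift diffusion
#'
#' Closed-form probability that a Wiener process with drift `drc` and
#' diffusion constant `sigma`, started at `strp * bnds` between absorbing
#' boundaries at `-bnds` and `+bnds`, is absorbed at the upper boundary:
#' with `z = (strp + 1) * bnds` and `a = 2 * bnds`,
#' \deqn{P = \frac{1 - e^{-2\,drc\,z/\sigma^2}}{1 - e^{-2\,drc\,a/\sigma^2}},}
#' with the zero-drift limit `z / a`. Serves as an independent oracle for the
#' simulator in the `amp = 0` limit.
#'
#' @param drc Drift per ms.
#' @param bnds Boundary magnitude.
#' @param sigma Diffusion constant per sqrt(ms).
#' @param strp Relative start point in (-1, 1).
#' @return Probability of upper-boundary (correct) absorption.
#' @export
analytic_ddm_accuracy <- function(drc, bnds, sigma = 4, strp = 0) {
  stopifnot(sigma > 0, bnds > 0, abs(strp) < 1)
  z <- (strp + 1) * bnds
  a <- 2 * bnds
  k <- 2 * drc / sigma^2
  if (abs(k * a) < 1e-10) return(z / a)
  expm1(-k * z) / expm1(-k * a)
}

#' Mean decision time of a symmetric constant-drift diffusion
#'
#' For a symmetric start (`strp = 0`) between boundaries at `+/-bnds`, the
#' mean first-passage time is
#' \deqn{E[T] = \frac{bnds}{drc}\tanh\!\left(\frac{drc\,bnds}{\sigma^2}\right),}
#' with zero-drift limit \eqn{bnds^2/\sigma^2}. Second oracle for the
#' simulator in the `amp = 0`, `strp = 0` limit.
#'
#' @inheritParams analytic_ddm_accuracy
#' @return Mean decision time in ms (excludes non-decision time).
#' @export
analytic_ddm_mean_dt <- function(drc, bnds, sigma = 4) {
  stopifnot(sigma > 0, bnds > 0)
  if (drc == 0) return(bnds^2 / sigma^2)
  (bnds / drc) * tanh(drc * bnds / sigma^2)
}
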