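#' DMC parameter set
#'
#' Bundles the eight parameters of the diffusion model of conflict (DMC): a
#' controlled (task-relevant) diffusion process with constant drift is
#' superimposed with an automatic (task-irrelevant) process whose mean state
#' follows a scaled gamma function, rising to a transient peak and then
#' decaying back to baseline.
#'
#' @param drc Mean drift of the controlled process, in evidence units per ms.
#' @param amp Peak mean automatic activation (evidence units). `amp = 0`
#'   reduces the model to a constant-drift diffusion.
#' @param tau Time scale of the automatic activation, in ms. The mean
#'   activation peaks at `(aa_shape - 1) * tau`.
#' @param aa_shape Gamma shape parameter of the automatic activation
#'   (dimensionless, must exceed 1 so a peak at positive time exists).
#' @param sigma Diffusion constant, in evidence units per sqrt(ms).
#' @param bnds Decision boundary magnitude; boundaries sit at `+bnds`
#'   (correct response, accuracy coding) and `-bnds` (error).
#' @param strp Relative start point in (-1, 1); 0 starts the accumulator
#'   midway between the boundaries.
#' @param res Non-decision (residual) time in ms, added to the decision time.
#'
#' @return An object of class `dmc_parameters` (a named list).
#' @examples
#' p <- dmc_parameters(drc = 0.5, amp = 20, tau = 30, bnds = 75, res = 300)
#' automatic_activation_mean(30, p)  # peak value: amp
#' @export
dmc_parameters <- function(drc = 0.5, amp = 20, tau = 30, aa_shape = 2,
                           sigma = 4, bnds = 75, strp = 0, res = 300) {
  p <- list(drc = drc, amp = amp, tau = tau, aa_shape = aa_shape,
            sigma = sigma, bnds = bnds, strp = strp, res = res)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (tau <= 0) stop("tau must be positive")
  if (aa_shape <= 1) stop("aa_shape must exceed 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (bnds <= 0) stop("bnds must be positive")
  if (res < 0) stop("res must be non-negative")
  if (abs(strp) >= 1) stop("strp must lie strictly inside (-1, 1)")
  structure(p, class = "dmc_parameters")
}

#' @export
print.dmc_parameters <- function(x, ...) {
  cat("DMC parameters:\n")
  cat(sprintf("  drc=%.4g amp=%.4g tau=%.4g aa_shape=%.4g\n",
              x$drc, x$amp, x$tau, x$aa_shape))
  cat(sprintf("  sigma=%.4g bnds=%.4g strp=%.4g res=%.4g\n",
              x$sigma, x$bnds, x$strp, x$res))
  invisible(x)
}

#' Simulation settings for the DMC forward model
#'
#' @param dt Integration time step in ms. 1 ms is the model's native fitting
#'   resolution; smaller steps bound the discretisation bias in oracle checks.
#' @param max_time Decision-time horizon in ms; trials still diffusing at the
#'   horizon are flagged non-terminated (default mirrors a 4 s response
#'   window).
#' @param n_trials Number of simulated trials.
#' @param seed Integer seed; identical seed and settings reproduce trials
#'   bit-for-bit.
#' @param crossing Boundary-crossing detection: `"bridge"` (default) adds a
#'   Brownian-bridge test for within-step excursions past a boundary, which
#'   removes the O(sigma sqrt(dt)) detection-lag bias of grid-only checks
#'   while still reporting decision times on the step grid; `"step"` checks
#'   only at step ends (plain Euler first-passage).
#'
#' @return An object of class `dmc_sim_config`.
#' @export
simulation_config <- function(dt = 1, max_time = 4000, n_trials = 50000,
                              seed = 1, crossing = c("bridge", "step")) {
  if (dt <= 0) stop("dt must be positive")
  if (max_time <= 0) stop("max_time must be positive")
  if (n_trials < 1) stop("n_trials must be at least 1")
  structure(list(dt = dt, max_time = max_time,
                 n_trials = as.integer(n_trials), seed = seed,
                 crossing = match.arg(crossing)),
            class = "dmc_sim_config")
}

# normalize a congruency label to the sign of the automatic contribution
congruency_sign <- function(congruency) {
  if (!is.character(congruency) || length(congruency) != 1L ||
      !congruency %in% c("congruent", "incongruent"))
    stop("congruency must be \"congruent\" or \"incongruent\"")
  if (congruency == "congruent") 1 else -1
}
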