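#' Mean automatic activation at time t
#'
#' The expected state of the automatic (task-irrelevant) process follows a
#' scaled gamma function,
#' \deqn{E[X_a(t)] = A \, e^{-t/\tau} \left(\frac{t e}{(a-1)\tau}\right)^{a-1},}
#' which is 0 at \eqn{t = 0}, rises to its maximum \eqn{A} at
#' \eqn{t = (a-1)\tau}, and decays back toward 0. The pulse-then-decay shape
#' is what lets the model produce congruency effects that shrink (and can
#' reverse) in the slow tail of the RT distribution.
#'
#' @param t Time(s) since stimulus onset, ms; non-negative, vectorised.
#' @param p A [dmc_parameters()] object.
#' @return Mean activation at each `t`, in evidence units.
#' @examples
#' p <- dmc_parameters(amp = 20, tau = 30, aa_shape = 2)
#' automatic_activation_mean(c(0, 30, 60), p)
#' @export
automatic_activation_mean <- function(t, p) {
  stopifnot(inherits(p, "dmc_parameters"))
  if (any(t < 0)) stop("t must be non-negative")
  a <- p$aa_shape
  out <- p$amp * exp(-t / p$tau) * (t * exp(1) / ((a - 1) * p$tau))^(a - 1)
  out[t == 0] <- 0  # t^(a-1) factor vanishes for a > 1
  out
}

#' Drift of the automatic process at time t
#'
#' The automatic drift is the time derivative of
#' [automatic_activation_mean()]:
#' \deqn{\mu_i(t) = E[X_a(t)] \left(\frac{a-1}{t} - \frac{1}{\tau}\right).}
#' It is positive while activation builds, zero at the peak
#' \eqn{t = (a-1)\tau}, and negative afterwards — the later compensation that
#' produces negative-going delta functions. The right-limit at `t = 0` is 0
#' for `aa_shape > 1` (and for `aa_shape = 2` the limit of the product is
#' `amp * e / tau`; we return the continuous limit of the product).
#'
#' @inheritParams automatic_activation_mean
#' @return Automatic drift at each `t`, evidence units per ms.
#' @export
automatic_drift <- function(t, p) {
  stopifnot(inherits(p, "dmc_parameters"))
  if (any(t < 0)) stop("t must be non-negative")
  a <- p$aa_shape
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- automatic_activation_mean(tp, p) * ((a - 1) / tp - 1 / p$tau)
  if (any(!pos)) {
    # right-limit of E[Xa(t)]*((a-1)/t - 1/tau): t^(a-2) behaviour near 0
    out[!pos] <- if (a > 2) 0 else if (a == 2) p$amp * exp(1) / p$tau else Inf
  }
  out
}

#' Total drift of the decision process
#'
#' The superimposed drift `drc + mu_i(t)` on congruent trials and
#' `drc - mu_i(t)` on incongruent trials: under accuracy coding the automatic
#' process pushes toward the correct boundary when stimulus features agree
#' and toward the incorrect boundary when they conflict.
#'
#' @inheritParams automatic_activation_mean
#' @param congruency `"congruent"` or `"incongruent"`.
#' @return Total drift at each `t`, evidence units per ms.
#' @export
total_drift <- function(t, p, congruency) {
  sgn <- congruency_sign(congruency)
  p$drc + sgn * automatic_drift(t, p)
}

#' Peak of the mean automatic activation
#'
#' Closed-form location `(aa_shape - 1) * tau` and height `amp` of the
#' activation maximum; `grid = TRUE` instead locates the maximum numerically
#' on a 1 ms grid `t = 1..t_max`.
#'
#' @param p A [dmc_parameters()] object.
#' @param grid If `TRUE`, maximise numerically over a 1 ms grid.
#' @param t_max Upper end of the grid, ms.
#' @return A list with `time` (ms) and `value` (evidence units).
#' @export
activation_peak <- function(p, grid = FALSE, t_max = 500) {
  stopifnot(inherits(p, "dmc_parameters"))
  if (!grid)
    return(list(time = (p$aa_shape - 1) * p$tau, value = p$amp))
  tt <- seq(1, t_max, by = 1)
  v <- automatic_activation_mean(tt, p)
  i <- which.max(v)
  list(time = tt[i], value = v[i])
}
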