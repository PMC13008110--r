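#' Adaptive quantile set for a trial count
#'
#' The quantile probabilities used to bin an RT distribution, chosen by the
#' number of observations: `(0.1, 0.3, 0.5, 0.7, 0.9)` for 30 or more
#' trials, `(0.3, 0.5, 0.9)` for 15-29, `(0.5)` for 6-14, and none (a
#' single bin) for fewer than six.
#'
#' @param n Non-negative trial count.
#' @return Ordered quantile probabilities (possibly length 0).
#' @export
quantile_set_for_n <- function(n) {
  stopifnot(length(n) == 1L, n >= 0)
  if (n >= 30) c(0.1, 0.3, 0.5, 0.7, 0.9)
  else if (n >= 15) c(0.3, 0.5, 0.9)
  else if (n >= 6) 0.5
  else numeric(0)
}

#' Observed quantile-bin proportions for one congruency condition
#'
#' Splits the condition's terminated trials into correct and error subsets,
#' applies [quantile_set_for_n()] to each subset separately, takes bin edges
#' at the observed RT quantiles (linear interpolation of order statistics,
#' type 7), and counts trials per bin with right-closed bins
#' `(-Inf, e1], (e1, e2], ...`. Proportions are normalised over the whole
#' condition, so the error-bin proportions jointly encode the error rate and
#' all proportions sum to 1.
#'
#' @param trials Data.frame with `rt`, `accuracy` and (optionally)
#'   `congruency` and `terminated` columns.
#' @param congruency If given, subset `trials` to this congruency label.
#' @param normalize `"condition"` (default; proportions sum to 1 across
#'   correct + error bins) or `"subset"` (each subset sums to 1 on its own,
#'   a sensitivity-check mode).
#' @return An object of class `dmc_binning`: quantiles, edges and counts per
#'   subset, subset totals, and `proportions` (named vector, correct bins
#'   then error bins).
#' @export
bin_proportions <- function(trials, congruency = NULL,
                            normalize = c("condition", "subset")) {
  normalize <- match.arg(normalize)
  stopifnot(is.data.frame(trials), all(c("rt", "accuracy") %in% names(trials)))
  if (!is.null(congruency))
    trials <- trials[trials$congruency == congruency, , drop = FALSE]
  if ("terminated" %in% names(trials))
    trials <- trials[trials$terminated, , drop = FALSE]
  trials <- trials[!is.na(trials$rt), , drop = FALSE]
  if (nrow(trials) == 0L)
    stop("no terminated trials in condition",
         if (!is.null(congruency)) paste0(" '", congruency, "'") else "")
  rt_c <- trials$rt[trials$accuracy == 1]
  rt_e <- trials$rt[trials$accuracy == 0]
  sub <- function(rt) {
    q <- quantile_set_for_n(length(rt))
    edges <- if (length(q) && length(rt))
      stats::quantile(rt, q, names = FALSE, type = 7) else numeric(0)
    counts <- if (length(rt))
      tabulate(findInterval(rt, edges, left.open = TRUE) + 1L,
               nbins = length(edges) + 1L)
    else rep(0L, length(edges) + 1L)
    list(quantiles = q, edges = edges, counts = counts)
  }
  sc <- sub(rt_c); se <- sub(rt_e)
  n_c <- length(rt_c); n_e <- length(rt_e)
  denom_c <- if (normalize == "condition") n_c + n_e else max(n_c, 1L)
  denom_e <- if (normalize == "condition") n_c + n_e else max(n_e, 1L)
  props <- c(sc$counts / denom_c, se$counts / denom_e)
  names(props) <- c(paste0("correct", seq_along(sc$counts)),
                    paste0("error", seq_along(se$counts)))
  structure(list(quantiles_correct = sc$quantiles, edges_correct = sc$edges,
                 bin_counts_correct = sc$counts,
                 quantiles_error = se$quantiles, edges_error = se$edges,
                 bin_counts_error = se$counts,
                 n_correct = n_c, n_error = n_e,
                 normalize = normalize, proportions = props),
            class = "dmc_binning")
}

#' @export
print.dmc_binning <- function(x, ...) {
  cat(sprintf("Quantile binning: %d correct / %d error trials\n",
              x$n_correct, x$n_error))
  cat("  correct edges (ms):",
      paste(sprintf("%.0f", x$edges_correct), collapse = " "), "\n")
  cat("  error edges (ms):  ",
      paste(sprintf("%.0f", x$edges_error), collapse = " "), "\n")
  invisible(x)
}

#' Delta function of the congruency effect
#'
#' For each shared quantile q, the incongruent-minus-congruent difference of
#' the RT quantiles plotted against their mean. A negative-going delta
#' function (late quantile differences smaller than early ones) is the
#' signature of an automatic activation that builds and then decays.
#'
#' @param congruent,incongruent Data.frames of trials (or numeric RT
#'   vectors) for the two conditions; data.frames may carry `terminated`
#'   and `rt` columns.
#' @param quantiles Shared quantile probabilities.
#' @param correct_only If `TRUE` (default), use correct trials only, the
#'   usual convention for delta plots.
#' @return A data.frame of class `dmc_delta` with columns `prob`,
#'   `quantile_congruent`, `quantile_incongruent`, `mean_rt`, `delta` (ms).
#' @export
delta_function <- function(congruent, incongruent,
                           quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           correct_only = TRUE) {
  pull_rt <- function(x) {
    if (is.data.frame(x)) {
      if ("terminated" %in% names(x)) x <- x[x$terminated, , drop = FALSE]
      if (correct_only && "accuracy" %in% names(x))
        x <- x[x$accuracy == 1, , drop = FALSE]
      x$rt
    } else as.numeric(x)
  }
  rc <- pull_rt(congruent); ri <- pull_rt(incongruent)
  if (!length(rc) || !length(ri))
    stop("both congruency conditions must be non-empty")
  qc <- stats::quantile(rc, quantiles, names = FALSE, type = 7)
  qi <- stats::quantile(ri, quantiles, names = FALSE, type = 7)
  out <- data.frame(prob = quantiles,
                    quantile_congruent = qc,
                    quantile_incongruent = qi,
                    mean_rt = (qc + qi) / 2,
                    delta = qi - qc)
  class(out) <- c("dmc_delta", "data.frame")
  out
}

#' Plot a delta function
#'
#' Base-graphics delta plot: quantile differences against quantile means.
#'
#' @param delta A `dmc_delta` data.frame from [delta_function()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_delta <- function(delta, ...) {
  graphics::plot(delta$mean_rt, delta$delta, type = "b", pch = 19,
                 xlab = "mean RT quantile (ms)",
                 ylab = expression(Delta ~ "RT (incongruent - congruent, ms)"),
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(delta)
}
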