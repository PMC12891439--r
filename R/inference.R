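# Derived quantities: annual survival, fold differences, posterior
# probability of a difference between populations, covariate-slope
# summaries, and time-varying survival series.

#' Annual survival from monthly draws
#'
#' Raises each monthly apparent-survival draw to the 12th power (months per
#' year), propagating full posterior uncertainty into the annual scale.
#'
#' @param monthly_draws Numeric vector of monthly survival draws in [0, 1].
#' @return Vector of annual survival draws.
#' @examples
#' annual_survival(0.9)  # 0.2824295
#' @export
annual_survival <- function(monthly_draws) {
  check_prob(monthly_draws, "monthly survival")
  monthly_draws^12
}

#' Fold difference between two survival probabilities
#'
#' @param a,b Survival probabilities (scalars or draw vectors); `b > 0`.
#' @return `a / b`.
#' @examples
#' fold_difference(0.36, 0.15)  # 2.4
#' @export
fold_difference <- function(a, b) {
  if (any(b == 0)) stop("division by zero survival", call. = FALSE)
  a / b
}

#' Posterior probability that one population's survival exceeds another's
#'
#' Pairs draws from two (independently fitted) posteriors by index and
#' reports the Bayesian probability of a difference,
#' `P(A > B) = mean(draws_A > draws_B)` (strict inequality; ties count as
#' "not greater"), plus summaries of the paired difference.
#'
#' @param draws_A,draws_B Equal-length draw vectors.
#' @param labels Character vector of length 2 naming the populations.
#' @return List of class `comparison_result`: `prob_greater`, `diff_mean`,
#'   `diff_cri` (2.5 and 97.5 percent quantiles), `labels`.
#' @export
prob_difference <- function(draws_A, draws_B, labels = c("A", "B")) {
  if (length(draws_A) != length(draws_B))
    stop("draw vectors must have equal length to be paired by index",
         call. = FALSE)
  d <- draws_A - draws_B
  structure(list(
    prob_greater = mean(draws_A > draws_B),
    diff_mean = mean(d),
    diff_cri = stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7),
    labels = labels), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "P(%s > %s) = %.3f; difference mean %.4f, 95%% CrI [%.4f, %.4f]\n",
    x$labels[1], x$labels[2], x$prob_greater, x$diff_mean,
    x$diff_cri[1], x$diff_cri[2]))
  invisible(x)
}

#' Summarize a covariate slope posterior
#'
#' Mean, 95% credible interval, and whether the interval includes zero (the
#' study's criterion for an inconclusive covariate effect).
#'
#' @param beta_draws Numeric vector of slope draws.
#' @return List: `mean`, `cri` (2.5/97.5 percent), `crosses_zero`.
#' @export
slope_summary <- function(beta_draws) {
  if (!length(beta_draws)) stop("empty draw vector", call. = FALSE)
  cri <- stats::quantile(beta_draws, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(beta_draws), cri = cri,
       crosses_zero = cri[1] < 0 && 0 < cri[2])
}

#' Time-varying survival series
#'
#' For a fully time-varying fit, summarizes each monthly interval's survival
#' posterior and flags intervals where survival is confounded with
#' detection: the terminal interval (classical CJS confounding) and any
#' interval ending in an unsearched month (only the product of survival
#' across the gap is identified).
#'
#' @param draws A `posterior_draws` object from a `phi_time` fit.
#' @param searched Logical vector of length T (the effort mask); taken from
#'   the fit automatically when available.
#' @return Data frame with one row per interval: `interval`, `mean`, `q2.5`,
#'   `q97.5`, `identifiable`.
#' @export
survival_series <- function(draws, searched = NULL) {
  if (draws$spec$survival_structure != "phi_time")
    stop("survival_series requires a phi_time fit", call. = FALSE)
  phi_names <- grep("^phi\\[", draws$parameters, value = TRUE)
  n_int <- length(phi_names)
  T <- n_int + 1L
  if (is.null(searched)) searched <- rep(TRUE, T)
  if (length(searched) != T)
    stop("searched mask must have length T = ", T, call. = FALSE)
  rows <- lapply(seq_len(n_int), function(t) {
    v <- draws_of(draws, paste0("phi[", t, "]"))
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(interval = t, mean = mean(v), q2.5 = q[1], q97.5 = q[2],
               identifiable = t < n_int && searched[t + 1L])
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Compare two fitted populations under the constant-survival model
#'
#' Convenience wrapper: extracts the pooled `phi` draws from two `phi_dot`
#' fits, pairs them by (chain, iteration) index, and returns both the
#' monthly-scale comparison and the derived annual-scale comparison.
#'
#' @param fit_A,fit_B `posterior_draws` objects from `phi_dot` fits.
#' @param labels Population labels.
#' @return List with `monthly` and `annual` `comparison_result`s, plus
#'   `annual_mean_A`, `annual_mean_B` and their fold difference.
#' @export
compare_populations <- function(fit_A, fit_B, labels = c("A", "B")) {
  a <- draws_of(fit_A, "phi"); b <- draws_of(fit_B, "phi")
  ann_a <- annual_survival(a); ann_b <- annual_survival(b)
  list(monthly = prob_difference(a, b, labels),
       annual = prob_difference(ann_a, ann_b, labels),
       annual_mean_A = mean(ann_a), annual_mean_B = mean(ann_b),
       annual_fold = fold_difference(mean(ann_a), mean(ann_b)))
}
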