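# Marginalized Cormack-Jolly-Seber likelihood.
#
# Conventions used throughout:
#   phi_vec[t], t = 1..T-1  : survival over the interval (t, t+1)
#   p_vec[t],   t = 1..T-1  : detection at occasion t+1 (no detection
#                             parameter exists for the first occasion)
# Detection at unsearched occasions is fixed at exactly 0, which makes the
# likelihood flat in those entries.

#' Model structures for apparent survival
#'
#' The five survival structures fitted in the analysis, in classical CMR
#' notation: `phi_dot` (constant), `phi_site` (locality-dependent),
#' `phi_time` (fully time-varying), `phi_length` (logit-linear in body
#' length) and `phi_perf` (logit-linear in standard metabolic rate, the
#' physiological-performance covariate). Detection is always modeled with
#' full temporal variation, `p(t)`, to accommodate the irregular search
#' calendar; `p` is fixed at 0 in months with no search.
#'
#' @param survival One of `"phi_dot"`, `"phi_site"`, `"phi_time"`,
#'   `"phi_length"`, `"phi_perf"`. The corresponding classical labels are
#'   `dot`, `Po`, `t`, `L`, `F`; these are accepted as aliases.
#' @param standardize_covariate Center and scale the covariate over the
#'   individuals entering the fit (default `TRUE`); the slope is then per
#'   covariate standard deviation.
#' @return A `cjs_model_spec` object.
#' @export
cjs_model_spec <- function(survival = c("phi_dot", "phi_site", "phi_time",
                                        "phi_length", "phi_perf"),
                           standardize_covariate = TRUE) {
  aliases <- c(dot = "phi_dot", Po = "phi_site", t = "phi_time",
               L = "phi_length", F = "phi_perf")
  if (length(survival) == 1L && survival %in% names(aliases))
    survival <- aliases[[survival]]
  survival <- match.arg(survival)
  covariate_name <- switch(survival, phi_length = "length_mm",
                           phi_perf = "smr", NULL)
  structure(list(survival_structure = survival,
                 covariate_name = covariate_name,
                 standardize_covariate = standardize_covariate),
            class = "cjs_model_spec")
}

#' Probability of never being observed after each occasion
#'
#' Backward recursion marginalizing the unknown death time:
#' `chi[T] = 1`; `chi[t] = (1 - phi[t]) + phi[t] * (1 - p[t]) * chi[t+1]`
#' where `p[t]` here denotes detection at occasion `t+1`.
#'
#' @param phi_vec Survival probabilities, length T-1.
#' @param p_vec Detection probabilities for occasions 2..T, length T-1.
#' @return Numeric vector `chi` of length T.
#' @examples
#' chi_recursion(rep(0.8, 2), rep(0.5, 2))  # 0.44 0.60 1.00
#' @export
chi_recursion <- function(phi_vec, p_vec) {
  check_prob(phi_vec, "phi"); check_prob(p_vec, "p")
  stopifnot(length(phi_vec) == length(p_vec))
  T <- length(phi_vec) + 1L
  chi <- numeric(T)
  chi[T] <- 1
  for (t in (T - 1L):1L)
    chi[t] <- (1 - phi_vec[t]) + phi_vec[t] * (1 - p_vec[t]) * chi[t + 1L]
  chi
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
}

#' Log-likelihood of one encounter history
#'
#' Conditions on the release at first capture `f`; the contribution is the
#' product of survival and detection/non-detection factors up to the last
#' detection `l`, times `chi[l]`, the probability of never being seen after
#' `l`. An individual released at the final occasion contributes 0 on the
#' log scale.
#'
#' @param y_i Binary detection vector, length T.
#' @param f_i First-capture occasion (1-based).
#' @param phi_vec,p_vec As in [chi_recursion()].
#' @return Log-probability of the history given release at `f_i`.
#' @export
history_loglik <- function(y_i, f_i, phi_vec, p_vec) {
  if (!any(y_i == 1L)) stop("history has no detection", call. = FALSE)
  T <- length(y_i)
  l <- max(which(y_i == 1L))
  if (y_i[f_i] != 1L || (f_i > 1L && any(y_i[seq_len(f_i - 1L)] != 0L)))
    stop("f_i is not the first detection of y_i", call. = FALSE)
  chi <- chi_recursion(phi_vec, p_vec)
  ll <- log(chi[l])
  if (l > f_i) {
    for (t in f_i:(l - 1L)) {
      pt <- p_vec[t]  # detection at occasion t + 1
      ll <- ll + log(phi_vec[t]) +
        if (y_i[t + 1L] == 1L) log(pt) else log1p(-pt)
    }
  }
  ll
}

# Vectorized likelihood core shared by all structures.
# PHI: n x (T-1) matrix of per-individual, per-interval survival.
# p_vec: detection at occasions 2..T. Returns per-individual log-likelihood.
# Occasions with p = 0 must have no detections (validated upstream); their
# log p coefficient is always zero, so log p is substituted by 0 there to
# avoid 0 * -Inf.
cjs_loglik_core <- function(y, first, PHI, p_vec) {
  n <- nrow(y); T <- ncol(y)
  last <- max.col(y, ties.method = "last")
  CHI <- matrix(1, n, T)   # chi by backward recursion, vectorized over rows
  for (t in (T - 1L):1L)
    CHI[, t] <- (1 - PHI[, t]) + PHI[, t] * (1 - p_vec[t]) * CHI[, t + 1L]
  cols <- matrix(seq_len(T - 1L), n, T - 1L, byrow = TRUE)
  S <- cols >= first & cols <= last - 1L        # survival-interval mask
  Y2 <- y[, -1L, drop = FALSE]
  logp <- ifelse(p_vec > 0, log(p_vec), 0)
  log1mp <- log1p(-p_vec)
  log(CHI[cbind(seq_len(n), last)]) +
    rowSums(ifelse(S, log(PHI), 0)) +
    as.vector((S * Y2) %*% logp + (S * (1 - Y2)) %*% log1mp)
}

#' Dataset log-likelihood under a model structure
#'
#' Sums [history_loglik()] over individuals. For the covariate structures
#' (`phi_length`, `phi_perf`) each individual's survival is constant over
#' time with `logit(phi_i) = alpha + beta * x_i` (x standardized when the
#' spec says so); individuals with a missing covariate are excluded with a
#' message. `state` is a list with elements matching the structure:
#' \describe{
#'   \item{phi_dot}{`phi` scalar}
#'   \item{phi_site}{`phi` named vector, one entry per site (use
#'     [dataset_loglik()] per site with the matching scalar)}
#'   \item{phi_time}{`phi` vector length T-1}
#'   \item{phi_length / phi_perf}{`alpha`, `beta` scalars}
#' }
#' plus `p`, detection at occasions 2..T (length T-1), already carrying
#' zeros at masked occasions.
#'
#' @param histories An `encounter_histories` object.
#' @param spec A `cjs_model_spec`.
#' @param state Parameter state list (see Details).
#' @return Total log-likelihood (scalar).
#' @export
dataset_loglik <- function(histories, spec, state) {
  y <- histories$y; T <- ncol(y); n <- nrow(y)
  p_vec <- state$p
  if (length(p_vec) != T - 1L)
    stop("p must have length T-1 = ", T - 1L, call. = FALSE)
  check_prob(p_vec, "p")
  masked <- !histories$searched[-1L]
  if (any(p_vec[masked] != 0))
    stop("p must be exactly 0 at unsearched occasions", call. = FALSE)

  if (spec$survival_structure %in% c("phi_length", "phi_perf")) {
    prep <- covariate_design(histories, spec)
    phi_i <- stats::plogis(state$alpha + state$beta * prep$x)
    PHI <- matrix(phi_i, length(phi_i), T - 1L)
    return(sum(cjs_loglik_core(y[prep$keep, , drop = FALSE],
                               histories$first[prep$keep], PHI, p_vec)))
  }
  phi_vec <- if (spec$survival_structure == "phi_time") state$phi
             else rep(state$phi[[1]], T - 1L)
  if (length(phi_vec) != T - 1L)
    stop("phi must have length T-1 for phi_time", call. = FALSE)
  check_prob(phi_vec, "phi")
  PHI <- matrix(phi_vec, n, T - 1L, byrow = TRUE)
  sum(cjs_loglik_core(y, histories$first, PHI, p_vec))
}

# Covariate vector for phi_length / phi_perf: selects individuals with a
# non-missing covariate and standardizes over them when requested.
covariate_design <- function(histories, spec) {
  x <- histories$covariates[[spec$covariate_name]]
  if (is.null(x)) stop("histories carry no covariate '",
                       spec$covariate_name, "'", call. = FALSE)
  keep <- which(!is.na(x))
  if (!length(keep)) stop("all covariate values missing", call. = FALSE)
  dropped <- nrow(histories$y) - length(keep)
  if (dropped > 0L)
    message(dropped, " individual(s) with missing ", spec$covariate_name,
            " excluded from the covariate fit")
  x <- x[keep]
  if (isTRUE(spec$standardize_covariate)) {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  list(x = x, keep = keep)
}

#' m-array log-likelihood
#'
#' Product-multinomial cell probabilities over release cohorts: a release at
#' occasion `i` first recaptured at `j` contributes
#' `prod(phi[i..j-1]) * prod(1 - p[i+1..j-1]) * p[j]`, and a release never
#' seen again contributes `chi[i]`. The multinomial coefficient is omitted,
#' so the value matches [dataset_loglik()] exactly for the time-structured
#' models (`phi_dot`, `phi_site`, `phi_time`).
#'
#' @param marr An `m_array` object.
#' @param phi_vec,p_vec As in [chi_recursion()].
#' @return Log-likelihood (scalar).
#' @export
marray_loglik <- function(marr, phi_vec, p_vec) {
  validate_marray(marr)
  T <- marr$n_occasions
  stopifnot(length(phi_vec) == T - 1L, length(p_vec) == T - 1L)
  check_prob(phi_vec, "phi"); check_prob(p_vec, "p")
  chi <- chi_recursion(phi_vec, p_vec)
  # log nu[i, j] = sum_{k=i}^{j-1} log phi_k + sum_{t=i+1}^{j-1} log(1-p) + log p_j
  clphi <- c(0, cumsum(log(phi_vec)))          # clphi[t+1] = sum log phi_1..t
  cl1mp <- c(0, cumsum(log1p(-p_vec)))         # detection occs 2..T
  cells <- which(marr$recaptured > 0L, arr.ind = TRUE)
  i <- cells[, 1L]; j <- cells[, 2L]
  ll <- sum(marr$recaptured[cells] *
              (clphi[j] - clphi[i] + cl1mp[j - 1L] - cl1mp[i] +
                 log(p_vec[j - 1L])))
  ns <- which(marr$never_seen > 0L)
  ll + sum(marr$never_seen[ns] * log(chi[ns]))
}
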