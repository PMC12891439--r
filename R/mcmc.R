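# Posterior sampling: component-wise adaptive random-walk Metropolis on
# unconstrained scales (logit for probabilities, identity for logit-scale
# regression coefficients). For time-structured models the sampler evaluates
# the m-array likelihood, which equals the individual-level likelihood
# exactly (tested); covariate models use the individual-level likelihood.

#' MCMC configuration
#'
#' Defaults follow the study's settings: 3 chains of 10,000 iterations with
#' a burn-in of 1,000. Proposal scales adapt toward the target acceptance
#' rate during burn-in (diminishing-adaptation batches of 50) and are frozen
#' afterwards, so kept draws come from a fixed-kernel Markov chain.
#'
#' @param n_chains Number of chains (>= 2 for R-hat).
#' @param n_iter Iterations per chain, including burn-in.
#' @param n_burn Burn-in iterations discarded (and used for adaptation).
#' @param seed Integer seed; per-chain sub-seeds are derived from it.
#' @param target_acceptance Target acceptance rate for the component-wise
#'   random-walk proposals (0.44 is the scalar-update optimum).
#' @param adapt_during_burn_only Freeze proposal scales after burn-in.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 10000L, n_burn = 1000L,
                        seed = 1L, target_acceptance = 0.44,
                        adapt_during_burn_only = TRUE) {
  stopifnot(n_chains >= 2L, n_burn < n_iter, n_burn >= 0L,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), seed = as.integer(seed),
                 target_acceptance = target_acceptance,
                 adapt_during_burn_only = isTRUE(adapt_during_burn_only)),
            class = "mcmc_config")
}

#' Prior specification
#'
#' Uninformative priors: Uniform(0, 1) on every probability parameter
#' (survival and detection) and Normal(0, sd) on the logit-scale intercept
#' and slope of the covariate models.
#'
#' @param coef_sd Standard deviation of the normal prior on `alpha`, `beta`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(coef_sd = 10) {
  stopifnot(coef_sd > 0)
  structure(list(coef_sd = coef_sd), class = "prior_spec")
}

# ---- parameter layout -----------------------------------------------------

# Builds the free-parameter layout for a fit: names, type ("prob" or
# "coef"), and a closure evaluating the log-likelihood from the
# unconstrained vector theta. Masked detection parameters are not sampled.
param_layout <- function(histories, spec, priors) {
  if (spec$survival_structure == "phi_site")
    return(param_layout_two_site(histories, spec))
  T <- ncol(histories$y)
  searched <- histories$searched
  p_free <- which(searched[-1L])         # indices into p_vec (occasions 2..T)
  if (!length(p_free))
    stop("no searched occasion after the first: detection unidentifiable",
         call. = FALSE)
  p_names <- paste0("p[", p_free + 1L, "]")
  struct <- spec$survival_structure

  if (struct %in% c("phi_length", "phi_perf")) {
    prep <- covariate_design(histories, spec)
    y <- histories$y[prep$keep, , drop = FALSE]
    first <- histories$first[prep$keep]
    x <- prep$x
    names <- c("alpha", "beta", p_names)
    types <- c("coef", "coef", rep("prob", length(p_free)))
    loglik <- function(theta) {
      p_vec <- numeric(T - 1L)
      p_vec[p_free] <- stats::plogis(theta[-(1:2)])
      phi_i <- stats::plogis(theta[1] + theta[2] * x)
      PHI <- matrix(phi_i, length(phi_i), T - 1L)
      sum(cjs_loglik_core(y, first, PHI, p_vec))
    }
    make_state <- function(theta) {
      p_vec <- numeric(T - 1L)
      p_vec[p_free] <- stats::plogis(theta[-(1:2)])
      list(alpha = theta[1], beta = theta[2], p = p_vec)
    }
  } else {
    marr <- m_array(histories)
    n_phi <- if (struct == "phi_time") T - 1L else 1L
    phi_names <- if (struct == "phi_time")
      paste0("phi[", seq_len(T - 1L), "]") else "phi"
    names <- c(phi_names, p_names)
    types <- rep("prob", length(names))
    loglik <- function(theta) {
      phi_vec <- if (n_phi == 1L) rep(stats::plogis(theta[1]), T - 1L)
                 else stats::plogis(theta[seq_len(n_phi)])
      p_vec <- numeric(T - 1L)
      p_vec[p_free] <- stats::plogis(theta[-seq_len(n_phi)])
      marray_loglik(marr, phi_vec, p_vec)
    }
    make_state <- function(theta) {
      p_vec <- numeric(T - 1L)
      p_vec[p_free] <- stats::plogis(theta[-seq_len(n_phi)])
      list(phi = stats::plogis(theta[seq_len(n_phi)]), p = p_vec)
    }
  }
  list(names = names, types = types, loglik = loglik,
       make_state = make_state, p_free = p_free)
}

# Layout for the locality-dependent structure: a named list of two
# encounter-history sets on the same time grid, one survival scalar per
# site, and site-specific time-varying detection (the search calendars
# differ between sites, so detection cannot be shared).
param_layout_two_site <- function(histories, spec) {
  if (inherits(histories, "encounter_histories") || length(histories) != 2L)
    stop("phi_site requires a named list of two encounter-history sets",
         call. = FALSE)
  sites <- names(histories)
  if (is.null(sites)) sites <- vapply(histories, `[[`, "", "site")
  Ts <- vapply(histories, function(h) ncol(h$y), 0L)
  if (length(unique(Ts)) != 1L)
    stop("the two sites must share one occasion grid", call. = FALSE)
  T <- Ts[[1]]
  marrs <- lapply(histories, m_array)
  p_free <- lapply(histories, function(h) {
    idx <- which(h$searched[-1L])
    if (!length(idx)) stop("no searched occasion after the first for site ",
                           h$site, call. = FALSE)
    idx
  })
  names <- c(paste0("phi[", sites, "]"),
             unlist(lapply(seq_along(sites), function(s)
               paste0("p[", sites[s], ",", p_free[[s]] + 1L, "]"))))
  types <- rep("prob", length(names))
  n_p <- vapply(p_free, length, 0L)
  split_theta <- function(theta) {
    phi <- stats::plogis(theta[1:2])
    off <- 2L
    p <- vector("list", 2L)
    for (s in 1:2) {
      pv <- numeric(T - 1L)
      pv[p_free[[s]]] <- stats::plogis(theta[off + seq_len(n_p[s])])
      p[[s]] <- pv
      off <- off + n_p[s]
    }
    list(phi = phi, p = p)
  }
  loglik <- function(theta) {
    st <- split_theta(theta)
    sum(vapply(1:2, function(s)
      marray_loglik(marrs[[s]], rep(st$phi[s], T - 1L), st$p[[s]]), 0))
  }
  make_state <- function(theta) {
    st <- split_theta(theta)
    names(st$phi) <- sites
    names(st$p) <- sites
    st
  }
  list(names = names, types = types, loglik = loglik,
       make_state = make_state, p_free = p_free)
}

# Log prior on the unconstrained scale. Uniform(0,1) on a probability
# sampled through the logit transform contributes the standard-logistic
# log-density (the Jacobian); coefficients are Normal(0, coef_sd).
log_prior_unconstrained <- function(theta, types, priors) {
  sum(stats::dlogis(theta[types == "prob"], log = TRUE)) +
    sum(stats::dnorm(theta[types == "coef"], 0, priors$coef_sd, log = TRUE))
}

#' Log posterior density of a parameter state
#'
#' Likelihood plus log prior densities. `state` values outside the support
#' yield `-Inf` rather than an error, so samplers can reject freely.
#'
#' @param state Parameter state list as in [dataset_loglik()].
#' @param histories An `encounter_histories` object (may have 0-row `y` for
#'   the no-data limit, in which case only the prior contributes).
#' @param spec A `cjs_model_spec`.
#' @param priors A `prior_spec`.
#' @return Log posterior density (up to a constant), on the natural scale
#'   (no Jacobian; use the sampler for transformed-scale densities).
#' @export
log_posterior <- function(state, histories, spec, priors = prior_spec()) {
  probs <- c(if (!is.null(state$phi)) state$phi, state$p)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    return(-Inf)
  lp <- 0
  if (!is.null(state$alpha))
    lp <- lp + stats::dnorm(state$alpha, 0, priors$coef_sd, log = TRUE) +
      stats::dnorm(state$beta, 0, priors$coef_sd, log = TRUE)
  if (is.null(histories) || nrow(histories$y) == 0L) return(lp)
  lp + dataset_loglik(histories, spec, state)
}

# ---- sampler --------------------------------------------------------------

#' Sample the CJS posterior
#'
#' Component-wise adaptive random-walk Metropolis on unconstrained
#' transforms of all free parameters. Chains start from independent prior
#' draws (over-dispersed, so the Gelman-Rubin diagnostic is meaningful) with
#' per-chain sub-seeds derived from `config$seed`. Detection parameters for
#' unsearched months are fixed at zero and never sampled.
#'
#' @param histories An `encounter_histories` object.
#' @param spec A `cjs_model_spec`.
#' @param priors A `prior_spec`.
#' @param config An `mcmc_config`.
#' @return An object of class `posterior_draws`: list with `values`
#'   (chains x kept-iterations x parameters array), `parameters`, `config`,
#'   `spec`, and `accept_rate`.
#' @export
sample_posterior <- function(histories, spec, priors = prior_spec(),
                             config = mcmc_config()) {
  layout <- param_layout(histories, spec, priors)
  k <- length(layout$names)
  n_kept <- config$n_iter - config$n_burn
  values <- array(NA_real_,
                  dim = c(config$n_chains, n_kept, k),
                  dimnames = list(NULL, NULL, layout$names))
  accept <- matrix(0, config$n_chains, k)

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  logpost <- function(theta) {
    lp <- layout$loglik(theta) +
      log_prior_unconstrained(theta, layout$types, priors)
    if (is.na(lp)) -Inf else lp
  }

  for (ch in seq_len(config$n_chains)) {
    set.seed(sub_seeds[ch])
    theta <- init_theta(layout, priors, logpost)
    lp <- logpost(theta)
    log_scale <- rep(0, k)                 # proposal sd = exp(log_scale)
    batch <- 50L
    batch_accept <- numeric(k)
    n_batches <- 0L
    for (it in seq_len(config$n_iter)) {
      adapting <- it <= config$n_burn || !config$adapt_during_burn_only
      for (j in seq_len(k)) {
        prop <- theta
        prop[j] <- theta[j] + exp(log_scale[j]) * stats::rnorm(1)
        lp_prop <- logpost(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop; lp <- lp_prop
          batch_accept[j] <- batch_accept[j] + 1
          if (it > config$n_burn) accept[ch, j] <- accept[ch, j] + 1
        }
      }
      if (adapting && it %% batch == 0L) {
        n_batches <- n_batches + 1L
        delta <- min(0.05, 1 / sqrt(n_batches))
        rate <- batch_accept / batch
        log_scale <- log_scale +
          ifelse(rate > config$target_acceptance, delta, -delta)
        batch_accept[] <- 0
      }
      if (it > config$n_burn)
        values[ch, it - config$n_burn, ] <- theta
    }
  }
  # report draws on the natural scale
  prob <- layout$types == "prob"
  values[, , prob] <- stats::plogis(values[, , prob, drop = FALSE])
  structure(list(values = values, parameters = layout$names,
                 types = layout$types, config = config, spec = spec,
                 seed = config$seed,
                 accept_rate = accept / n_kept),
            class = "posterior_draws")
}

init_theta <- function(layout, priors, logpost) {
  k <- length(layout$names)
  for (attempt in seq_len(100L)) {
    theta <- numeric(k)
    pr <- layout$types == "prob"
    theta[pr] <- stats::qlogis(stats::runif(sum(pr)))
    theta[!pr] <- stats::rnorm(sum(!pr), 0, priors$coef_sd)
    if (is.finite(logpost(theta))) return(theta)
  }
  stop("could not find a finite initial posterior in 100 prior draws",
       call. = FALSE)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Posterior draws: %d chains x %d iterations x %d parameters (%s)\n",
              d[1], d[2], d[3], x$spec$survival_structure))
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' Concatenates kept iterations across chains (chain-major order), giving a
#' single vector suitable for derived quantities and comparisons.
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name.
#' @return Numeric vector of length chains x kept-iterations.
#' @export
draws_of <- function(draws, parameter) {
  if (!parameter %in% draws$parameters)
    stop("unknown parameter '", parameter, "'; available: ",
         paste(draws$parameters, collapse = ", "), call. = FALSE)
  as.vector(t(draws$values[, , parameter]))
}

# ---- diagnostics ----------------------------------------------------------

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half; with m half-chains of length n, W is the
#' mean within-half variance, B/n the variance of the half means, and
#' `R-hat = sqrt(((n - 1)/n * W + B/n) / W)`. Returns exactly 1 when W = 0
#' (all halves constant). Values below 1.1 were the study's convergence
#' criterion.
#'
#' @param draws A `posterior_draws` object, or a chains x iterations matrix.
#' @param parameter Parameter name (ignored for a matrix input).
#' @return The potential scale reduction factor (scalar).
#' @export
split_rhat <- function(draws, parameter = NULL) {
  mat <- if (inherits(draws, "posterior_draws"))
    draws$values[, , parameter] else as.matrix(draws)
  n_iter <- ncol(mat)
  if (nrow(mat) < 2L || n_iter < 4L)
    stop("need >= 2 chains and >= 4 kept iterations for split R-hat",
         call. = FALSE)
  half <- n_iter %/% 2L
  halves <- rbind(mat[, seq_len(half), drop = FALSE],
                  mat[, n_iter - half + seq_len(half), drop = FALSE])
  n <- half
  means <- rowMeans(halves)
  vars <- apply(halves, 1L, stats::var)
  W <- mean(vars)
  if (W == 0) return(1.0)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Maximum split R-hat over all parameters
#'
#' @param draws A `posterior_draws` object.
#' @return Named numeric: the largest split R-hat and which parameter.
#' @export
max_split_rhat <- function(draws) {
  r <- vapply(draws$parameters, function(p) split_rhat(draws, p), 0)
  r[which.max(r)]
}

#' Posterior summary table
#'
#' Per parameter: posterior mean, sd, 2.5/50/97.5 percent quantiles (type-7,
#' linear interpolation), split R-hat and effective sample size.
#'
#' @param draws A `posterior_draws` object.
#' @return Data frame with one row per parameter.
#' @export
summarize_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  rows <- lapply(draws$parameters, function(pn) {
    v <- draws_of(draws, pn)
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    ess <- tryCatch(
      sum(vapply(seq_len(dim(draws$values)[1]), function(ch)
        unname(coda::effectiveSize(coda::mcmc(draws$values[ch, , pn]))),
        0)),
      error = function(e) NA_real_)
    data.frame(parameter = pn, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], median = q[2], q97.5 = q[3],
               rhat = split_rhat(draws, pn), ess = ess)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Persist posterior draws
#'
#' Writes a long-format CSV (`chain,iteration,parameter,value`) plus a JSON
#' sidecar with the configuration, seed and parameter names.
#'
#' @param draws A `posterior_draws` object.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_draws <- function(draws, path) {
  d <- dim(draws$values)
  long <- data.frame(
    chain = rep(seq_len(d[1]), times = d[2] * d[3]),
    iteration = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(draws$parameters, each = d[1] * d[2]),
    value = as.vector(draws$values))
  utils::write.csv(long, path, row.names = FALSE)
  sidecar <- list(parameters = draws$parameters, seed = draws$seed,
                  config = unclass(draws$config),
                  survival_structure = draws$spec$survival_structure)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
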