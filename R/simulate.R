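# Synthetic-data generator: encounter histories with the generative
# structure the CJS model assumes (state-space survival process, detection
# only in searched months), covariate effects on logit survival, and
# site-profile environmental series. Defaults emulate the two-site field
# design: the study's search calendar and recruitment proportional to the
# observed monthly capture counts.

#' Truth configuration for history simulation
#'
#' @param site,species Population labels (used to pick the default search
#'   mask and recruitment weights from the study calendar).
#' @param n_individuals Number of individuals to simulate.
#' @param phi Monthly apparent survival: a scalar, a per-interval vector of
#'   length T-1, or a list `list(alpha=, beta=, cov_mean=, cov_sd=)` for
#'   logit-linear covariate survival.
#' @param p Detection probability on searched occasions: scalar or vector of
#'   length T-1 (occasions 2..T); entries at unsearched occasions are forced
#'   to zero.
#' @param calendar An `occasion_calendar` with effort attached; defaults to
#'   the study calendar.
#' @param recruitment Weights over occasions for first-capture entry;
#'   default: the study's monthly capture counts for this population,
#'   normalized (zero in unsearched months).
#' @param seed Integer seed.
#' @return List of class `truth_config`.
#' @export
truth_config <- function(site = "talcaruca", species = "chiton_granosus",
                         n_individuals = 300L, phi = 0.9, p = 0.4,
                         calendar = study_calendar(), recruitment = NULL,
                         seed = 1L) {
  site <- match_site(site); species <- match_species(species)
  key <- cell_key(site, species)
  searched <- calendar$searched[[key]]
  if (is.null(searched))
    stop("calendar has no effort for ", key, call. = FALSE)
  T <- calendar$n_occasions
  if (is.null(recruitment)) {
    cts <- calendar$counts[[key]]
    recruitment <- ifelse(is.na(cts), 0, as.numeric(cts))
    if (all(recruitment == 0)) recruitment <- as.numeric(searched)
  }
  if (length(recruitment) != T)
    stop("recruitment weights must have length T", call. = FALSE)
  recruitment[!searched] <- 0
  if (all(recruitment == 0))
    stop("no searched occasion with positive recruitment weight",
         call. = FALSE)
  if (is.numeric(phi)) check_prob(phi, "phi")
  if (length(p) == 1L) p <- rep(p, T - 1L)
  check_prob(p, "p")
  p[!searched[-1L]] <- 0
  structure(list(site = site, species = species,
                 n_individuals = as.integer(n_individuals), phi = phi,
                 p = p, calendar = calendar, searched = searched,
                 recruitment = recruitment, seed = as.integer(seed)),
            class = "truth_config")
}

#' Simulate encounter histories
#'
#' State-space generative process: each individual enters (is first
#' captured) at an occasion drawn from the recruitment weights, survives
#' each following monthly interval with its survival probability, and while
#' alive is detected with probability `p[t]` on searched occasions (never in
#' unsearched months). Individuals whose covariate-driven survival is
#' simulated also carry the covariate value used.
#'
#' @param truth A `truth_config`.
#' @return An `encounter_histories` object; for covariate truth the
#'   `covariates` table holds the simulated values in both covariate slots
#'   and attribute `true_phi` stores the per-individual survival.
#' @export
simulate_histories <- function(truth) {
  stopifnot(inherits(truth, "truth_config"))
  set.seed(truth$seed)
  T <- truth$calendar$n_occasions
  n <- truth$n_individuals
  entry <- sample.int(T, n, replace = TRUE, prob = truth$recruitment)

  if (is.list(truth$phi)) {
    x <- stats::rnorm(n, truth$phi$cov_mean, truth$phi$cov_sd)
    xs <- (x - mean(x)) / stats::sd(x)
    phi_i <- stats::plogis(truth$phi$alpha + truth$phi$beta * xs)
    PHI <- matrix(phi_i, n, T - 1L)
    covariates <- data.frame(length_mm = x, smr = x)
  } else {
    phi_vec <- if (length(truth$phi) == 1L) rep(truth$phi, T - 1L)
               else truth$phi
    stopifnot(length(phi_vec) == T - 1L)
    PHI <- matrix(phi_vec, n, T - 1L, byrow = TRUE)
    phi_i <- NULL
    covariates <- data.frame(length_mm = rep(NA_real_, n),
                             smr = rep(NA_real_, n))
  }

  y <- matrix(0L, n, T)
  y[cbind(seq_len(n), entry)] <- 1L
  alive <- matrix(FALSE, n, T)
  alive[cbind(seq_len(n), entry)] <- TRUE
  for (t in seq_len(T - 1L)) {
    at_risk <- alive[, t]
    if (!any(at_risk)) next
    surv <- at_risk & (stats::runif(n) < PHI[, t])
    alive[, t + 1L] <- alive[, t + 1L] | surv
    if (truth$p[t] > 0) {
      det <- surv & (stats::runif(n) < truth$p[t]) & entry <= t
      y[det, t + 1L] <- 1L
    }
  }
  h <- new_histories(y, entry, sprintf("sim%05d", seq_len(n)), truth$site,
                     truth$species, covariates, truth$searched)
  attr(h, "true_phi") <- if (is.null(phi_i)) truth$phi else phi_i
  attr(h, "alive") <- alive
  h
}

#' Simulate covariates and their survival effect
#'
#' Draws `x ~ Normal(mean, sd)` and maps it to per-individual monthly
#' survival through `logit(phi_i) = alpha + beta * x_std`.
#'
#' @param n Number of individuals.
#' @param cov_mean,cov_sd Covariate distribution (sd > 0).
#' @param alpha,beta Logit-scale intercept and slope (per covariate sd).
#' @return Data frame with `x`, `x_std`, `phi`.
#' @export
simulate_covariates <- function(n, cov_mean = 30, cov_sd = 5, alpha = 2,
                                beta = 0.8) {
  stopifnot(cov_sd > 0)
  x <- stats::rnorm(n, cov_mean, cov_sd)
  x_std <- (x - mean(x)) / stats::sd(x)
  data.frame(x = x, x_std = x_std,
             phi = stats::plogis(alpha + beta * x_std))
}

#' Site environmental profiles
#'
#' Presets for the two upwelling regimes. `semipermanent_site` (Talcaruca
#' type): warmer thermal peaks, larger SST variability, rare low-pH days
#' spread over the year. `seasonal_site` (Quintay type): intermittent
#' upwelling with spring-heavy low-pH events dropping below the 7.3
#' corrosive threshold.
#'
#' @param name `"semipermanent_site"` or `"seasonal_site"`.
#' @return List of profile parameters (amplitudes, AR(1) coefficient, noise
#'   sd, pH baseline, per-season daily event rates, event drop magnitude).
#' @export
site_profile <- function(name = c("semipermanent_site", "seasonal_site")) {
  name <- match.arg(name)
  base <- list(name = name, sst_mean = 13.1, sst_phase = 15L,
               ph_baseline = 8.0, ph_sd = 0.05, ph_event_drop = 0.85)
  if (name == "semipermanent_site")
    utils::modifyList(base, list(
      sst_amplitude = 4.4, sst_ar1 = 0.8, sst_sd = 0.9,
      event_rate = c(spring = 0.02, summer = 0.015, autumn = 0.015,
                     winter = 0.005)))
  else
    utils::modifyList(base, list(
      sst_amplitude = 3.8, sst_ar1 = 0.8, sst_sd = 0.45,
      event_rate = c(spring = 0.16, summer = 0.06, autumn = 0.10,
                     winter = 0.0)))
}

#' Simulate daily SST and pH series for a site profile
#'
#' SST is an annual sinusoid plus AR(1) noise with site-specific amplitude
#' and innovation variance; pH is a baseline with Gaussian jitter minus an
#' upwelling event process whose daily event rate is modulated by austral
#' season (spring-heavy for the seasonal profile), with event-day drops that
#' push pH below the corrosive 7.3 threshold.
#'
#' @param profile A [site_profile()] list.
#' @param n_days Number of days.
#' @param start_date First day (default 2020-01-01).
#' @param seed Integer seed.
#' @return Data frame with `date`, `sst`, `ph`, `event`.
#' @export
simulate_environment <- function(profile, n_days, start_date = "2020-01-01",
                                 seed = 1L) {
  stopifnot(n_days >= 1)
  set.seed(seed)
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.POSIXlt(dates)$yday
  seasonal <- profile$sst_amplitude *
    cos(2 * pi * (doy - profile$sst_phase) / 365.25)
  ar <- numeric(n_days)
  innov <- stats::rnorm(n_days, 0, profile$sst_sd)
  for (i in seq_len(n_days))
    ar[i] <- if (i == 1L) innov[1] else profile$sst_ar1 * ar[i - 1L] + innov[i]
  sst <- profile$sst_mean + seasonal + ar

  rate <- profile$event_rate[as.character(austral_season(dates))]
  event <- stats::runif(n_days) < rate
  ph <- profile$ph_baseline + stats::rnorm(n_days, 0, profile$ph_sd) -
    ifelse(event,
           profile$ph_event_drop * stats::runif(n_days, 0.8, 1.2), 0)
  data.frame(date = dates, sst = sst, ph = ph, event = event)
}
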