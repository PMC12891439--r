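# Independent oracles and fixture builders used across the test files.

# Brute-force probability of an encounter history by enumeration over the
# unknown death interval: the animal, released at f, dies in interval
# (d, d+1) for some d in f..T-1 or survives to T; detections after death
# have probability zero. Written directly from the generative model, with
# no chi recursion.
enum_history_prob <- function(y, f, phi_vec, p_vec) {
  T <- length(y)
  l <- max(which(y == 1L))
  total <- 0
  for (d in f:T) {            # d = last occasion alive
    pr <- 1
    if (d > f) for (t in f:(d - 1L)) pr <- pr * phi_vec[t]
    if (d < T) pr <- pr * (1 - phi_vec[d])
    # detection outcomes at occasions f+1 .. d while alive
    if (d > f) for (t in (f + 1L):d)
      pr <- pr * (if (y[t] == 1L) p_vec[t - 1L] else 1 - p_vec[t - 1L])
    # any detection after death is impossible
    if (l > d) pr <- 0
    total <- total + pr
  }
  total
}

# All binary post-release histories with a 1 at occasion f and zeros before.
all_post_release_histories <- function(T, f) {
  tail_len <- T - f
  out <- list()
  for (code in 0:(2^tail_len - 1)) {
    y <- integer(T)
    y[f] <- 1L
    if (tail_len > 0)
      y[(f + 1L):T] <- as.integer(intToBits(code))[seq_len(tail_len)]
    out[[length(out) + 1L]] <- y
  }
  out
}

# Small all-searched calendar for likelihood-level fixtures.
toy_calendar <- function(T, site = "talcaruca", species = "chiton_granosus") {
  cal <- build_calendar(c(2020, 1), c(2020 + (T - 1) %/% 12, (T - 1) %% 12 + 1))
  counts <- list(rep(1L, T))
  names(counts) <- paste(site, species, sep = ":")
  attach_effort(cal, counts)
}

# Encounter histories carrying no survival information: one individual
# first captured at the final occasion (its likelihood factor is 1), so the
# posterior equals the prior.
no_data_histories <- function(T = 4L) {
  y <- matrix(0L, 1L, T)
  y[1L, T] <- 1L
  upwellsurv:::new_histories(
    y, T, "ghost", "talcaruca", "chiton_granosus",
    data.frame(length_mm = NA_real_, smr = NA_real_), rep(TRUE, T))
}

# Shared large fit at the study's MCMC settings, computed once per test run
# (several acceptance checks reuse it).
.fit_cache <- new.env(parent = emptyenv())
cached_study_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    truth <- truth_config("talcaruca", "chiton_granosus",
                          n_individuals = 300L, phi = 0.9, p = 0.4, seed = 1L)
    h <- simulate_histories(truth)
    .fit_cache$fit <- sample_posterior(h, cjs_model_spec("phi_dot"),
                                       config = mcmc_config(seed = 1L))
  }
  .fit_cache$fit
}
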