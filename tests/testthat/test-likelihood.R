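test_that("chi recursion matches hand computation and limiting cases", {
  expect_equal(chi_recursion(rep(0.8, 2), rep(0.5, 2)), c(0.44, 0.6, 1))
  # certain survival and detection: being unseen again is impossible
  expect_equal(chi_recursion(rep(1, 3), rep(1, 3)), c(0, 0, 0, 1))
  # dead animals are never seen
  expect_equal(chi_recursion(rep(0, 3), rep(0.7, 3)), rep(1, 4))
  expect_error(chi_recursion(c(0.5, 1.2), c(0.5, 0.5)), "\\[0, 1\\]")
})

test_that("single-history likelihood matches worked examples", {
  phi <- rep(0.8, 2); p <- rep(0.5, 2)
  expect_equal(exp(history_loglik(c(1, 0, 1), 1, phi, p)), 0.16)
  expect_equal(exp(history_loglik(c(1, 0, 0), 1, phi, p)), 0.44)
  # detection fixed at 0 in the intermediate month
  expect_equal(exp(history_loglik(c(1, 0, 1), 1, phi, c(0, 0.5))), 0.32)
  # release at the final occasion carries no information
  expect_equal(history_loglik(c(0, 1), 2, 0.8, 0.5), 0)
  expect_error(history_loglik(c(0, 0, 0), 1, phi, p), "no detection")
})

test_that("likelihood equals brute-force enumeration and normalizes to 1", {
  set.seed(101)
  for (draw in 1:50) {
    T <- sample(3:8, 1)
    f <- sample.int(T - 1L, 1)
    phi <- runif(T - 1)
    p <- runif(T - 1)
    if (draw %% 2 == 0) p[sample.int(T - 1, 1)] <- 0  # masked occasion
    histories <- all_post_release_histories(T, f)
    total <- 0
    for (y in histories) {
      pr_enum <- enum_history_prob(y, f, phi, p)
      if (pr_enum > 0) {
        expect_equal(exp(history_loglik(y, f, phi, p)), pr_enum,
                     tolerance = 1e-12)
      }
      total <- total + pr_enum
    }
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("dataset likelihood is additive and exchangeable over individuals", {
  T <- 5L
  y <- c(1L, 0L, 1L, 1L, 0L)
  h2 <- upwellsurv:::new_histories(
    rbind(y, y), c(1L, 1L), c("a", "b"), "talcaruca", "chiton_granosus",
    data.frame(length_mm = c(NA_real_, NA_real_), smr = NA_real_),
    rep(TRUE, T))
  spec <- cjs_model_spec("phi_dot")
  state <- list(phi = 0.85, p = rep(0.45, T - 1L))
  single <- history_loglik(y, 1L, rep(0.85, T - 1L), state$p)
  expect_equal(dataset_loglik(h2, spec, state), 2 * single)

  y3 <- rbind(c(1L, 1L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L, 0L), y)
  h3 <- upwellsurv:::new_histories(
    y3, c(1L, 2L, 1L), c("a", "b", "c"), "talcaruca", "chiton_granosus",
    data.frame(length_mm = rep(NA_real_, 3), smr = NA_real_), rep(TRUE, T))
  perm <- c(3L, 1L, 2L)
  hp <- upwellsurv:::new_histories(
    y3[perm, ], c(1L, 2L, 1L)[perm], c("c", "a", "b"), "talcaruca",
    "chiton_granosus",
    data.frame(length_mm = rep(NA_real_, 3), smr = NA_real_), rep(TRUE, T))
  expect_equal(dataset_loglik(h3, spec, state),
               dataset_loglik(hp, spec, state))
})

test_that("m-array likelihood is exactly the individual-level likelihood", {
  # single history: algebraic identity
  h1 <- upwellsurv:::new_histories(
    matrix(c(1L, 0L, 1L), 1L), 1L, "x", "talcaruca", "chiton_granosus",
    data.frame(length_mm = NA_real_, smr = NA_real_), rep(TRUE, 3))
  expect_equal(marray_loglik(m_array(h1), rep(0.8, 2), rep(0.5, 2)),
               history_loglik(c(1, 0, 1), 1, rep(0.8, 2), rep(0.5, 2)))

  # empty recaptures: one release never seen again -> log chi_1
  h2 <- upwellsurv:::new_histories(
    matrix(c(1L, 0L, 0L), 1L), 1L, "x", "talcaruca", "chiton_granosus",
    data.frame(length_mm = NA_real_, smr = NA_real_), rep(TRUE, 3))
  expect_equal(marray_loglik(m_array(h2), rep(0.8, 2), rep(0.5, 2)),
               log(chi_recursion(rep(0.8, 2), rep(0.5, 2))[1]))

  # 500 simulated histories with the study search mask, 20 parameter draws
  truth <- truth_config(n_individuals = 500L, phi = 0.9, p = 0.4, seed = 11L)
  h <- simulate_histories(truth)
  marr <- m_array(h)
  T <- ncol(h$y)
  free <- which(h$searched[-1L])
  spec_dot <- cjs_model_spec("phi_dot")
  spec_time <- cjs_model_spec("phi_time")
  set.seed(202)
  for (draw in 1:20) {
    p <- numeric(T - 1L); p[free] <- runif(length(free))
    phi_c <- runif(1)
    expect_equal(dataset_loglik(h, spec_dot, list(phi = phi_c, p = p)),
                 marray_loglik(marr, rep(phi_c, T - 1L), p),
                 tolerance = 1e-10)
    phi_t <- runif(T - 1L)
    expect_equal(dataset_loglik(h, spec_time, list(phi = phi_t, p = p)),
                 marray_loglik(marr, phi_t, p),
                 tolerance = 1e-10)
  }
})

test_that("fixing p = 0 over a gap equals collapsing the gap", {
  # detection fixed at zero across occasions 3..4: the full-grid likelihood
  # must equal the reduced-grid likelihood where the gap intervals collapse
  # into one interval with the product of survival
  phi <- c(0.9, 0.85, 0.8, 0.95)          # T = 5
  p_full <- c(0.5, 0, 0, 0.6)             # occasions 2..5; 3 and 4 masked
  y_full <- c(1L, 1L, 0L, 0L, 1L)
  phi_red <- c(0.9, 0.85 * 0.8 * 0.95)    # T = 3: occasions 1, 2, 5
  p_red <- c(0.5, 0.6)
  y_red <- c(1L, 1L, 1L)
  expect_equal(history_loglik(y_full, 1L, phi, p_full),
               history_loglik(y_red, 1L, phi_red, p_red))
  # and an animal vanishing before the gap
  expect_equal(history_loglik(c(1L, 1L, 0L, 0L, 0L), 1L, phi, p_full),
               history_loglik(c(1L, 1L, 0L), 1L, phi_red, p_red))
})

test_that("masked detection parameters are never sampled", {
  truth <- truth_config(n_individuals = 60L, phi = 0.9, p = 0.4, seed = 4L)
  h <- simulate_histories(truth)
  layout <- upwellsurv:::param_layout(h, cjs_model_spec("phi_dot"),
                                      prior_spec())
  masked_occasions <- which(!h$searched)
  expect_false(any(paste0("p[", masked_occasions, "]") %in% layout$names))
  # all searched occasions after the first do have a parameter
  expect_setequal(grep("^p\\[", layout$names, value = TRUE),
                  paste0("p[", setdiff(which(h$searched), 1L), "]"))
})

test_that("inserting non-detection gaps cannot raise the likelihood", {
  # two detections separated by k unseen months: each inserted month
  # multiplies the probability by phi * (1 - p) <= 1
  for (pars in list(c(0.9, 0.4), c(0.7, 0.8), c(0.99, 0.1))) {
    ll <- vapply(0:4, function(k) {
      y <- c(1L, rep(0L, k), 1L)
      history_loglik(y, 1L, rep(pars[1], k + 1L), rep(pars[2], k + 1L))
    }, 0)
    expect_true(all(diff(ll) < 0))
    expect_equal(diff(ll),
                 rep(log(pars[1] * (1 - pars[2])), 4), tolerance = 1e-12)
  }
})

test_that("covariate survival enters through the logit link per individual", {
  T <- 6L
  set.seed(7)
  n <- 40L
  x <- rnorm(n, 30, 5)
  y <- matrix(0L, n, T); y[, 1] <- 1L
  y[sample.int(n, 25), 3] <- 1L
  h <- upwellsurv:::new_histories(
    y, rep(1L, n), sprintf("i%02d", 1:n), "talcaruca", "chiton_granosus",
    data.frame(length_mm = x, smr = NA_real_), rep(TRUE, T))
  spec <- cjs_model_spec("phi_length")
  state <- list(alpha = 1.5, beta = 0.6, p = rep(0.5, T - 1L))
  got <- dataset_loglik(h, spec, state)
  xs <- (x - mean(x)) / sd(x)
  manual <- sum(vapply(seq_len(n), function(i) {
    phi_i <- plogis(1.5 + 0.6 * xs[i])
    history_loglik(y[i, ], 1L, rep(phi_i, T - 1L), state$p)
  }, 0))
  expect_equal(got, manual, tolerance = 1e-12)

  # individuals with missing covariate are excluded with a message
  h$covariates$length_mm[1:3] <- NA
  expect_message(dataset_loglik(h, spec, state), "3 individual")
})
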