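test_that("initial grid fills the box deterministically", {
  rng <- np_ranges()
  expect_equal(nrow(np_grid_init(rng, 1)), 1L)
  mid <- np_grid_init(rng, 1)
  expect_equal(mid$ka, mean(rng$ka))
  g <- np_grid_init(rng, 60, seed = 5)
  expect_equal(nrow(g), 60L)
  expect_true(all(g$ka >= rng$ka[1] & g$ka <= rng$ka[2]))
  expect_true(all(g$ke >= rng$ke[1] & g$ke <= rng$ke[2]))
  expect_true(all(g$v >= rng$v[1] & g$v <= rng$v[2]))
  # the eight box corners are included
  expect_true(all(apply(expand.grid(rng$ka, rng$ke, rng$v), 1, function(cr) {
    any(g$ka == cr[1] & g$ke == cr[2] & g$v == cr[3])
  })))
  expect_identical(g, np_grid_init(rng, 60, seed = 5))
  expect_false(identical(g, np_grid_init(rng, 60, seed = 6)))
  expect_error(np_ranges(ka = c(2, 1)), "Invalid range")
})

test_that("subject log-likelihood matches direct Gaussian density evaluation", {
  em <- assay_error("ATR_ATRL")
  p <- pk_params(c(1.74, 0.9), c(0.135, 0.2), c(44.75, 30))
  record <- list(id = "X", doses = tibble::tibble(time_h = 0, amount_mg = 20),
                 obs_times = c(2, 4, 6), obs_conc = c(70, 55, 40), c_ini = 0)
  ll <- pkadherence:::subject_loglik(record, p, em)
  # oracle: predictions via the public profile function + dnorm by hand
  for (k in 1:2) {
    pred <- conc_profile(p[k, ], record$doses, record$obs_times)$conc_nmol_l
    ref <- sum(dnorm(record$obs_conc, pred, total_sd(em, record$obs_conc),
                     log = TRUE))
    expect_equal(ll[k], ref, tolerance = 1e-12)
  }
  # an observation equal to the prediction contributes log(1/(s*sqrt(2*pi)))
  pred <- conc_profile(p[1, ], record$doses, 2)$conc_nmol_l
  rec1 <- list(id = "Y", doses = record$doses, obs_times = 2,
               obs_conc = pred, c_ini = 0)
  s <- total_sd(em, pred)
  expect_equal(pkadherence:::subject_loglik(rec1, p[1, ], em),
               log(1 / (s * sqrt(2 * pi))), tolerance = 1e-12)
  # two observations add their log-likelihoods
  rec2 <- list(id = "Z", doses = record$doses, obs_times = c(2, 4),
               obs_conc = c(70, 55), c_ini = 0)
  reca <- list(id = "Za", doses = record$doses, obs_times = 2,
               obs_conc = 70, c_ini = 0)
  recb <- list(id = "Zb", doses = record$doses, obs_times = 4,
               obs_conc = 55, c_ini = 0)
  expect_equal(pkadherence:::subject_loglik(rec2, p[1, ], em),
               pkadherence:::subject_loglik(reca, p[1, ], em) +
                 pkadherence:::subject_loglik(recb, p[1, ], em),
               tolerance = 1e-12)
})

test_that("EM weight optimization is monotone and matches brute force", {
  set.seed(11)
  # single point gets all the weight
  o1 <- np_optimize_weights(matrix(c(-3, -4, -5), ncol = 1))
  expect_identical(o1$weights, 1)
  # dominated point loses all weight
  L <- cbind(rnorm(5, -10), rnorm(5, -10) - 100)
  od <- np_optimize_weights(L, tol = 1e-14, max_iter = 1e5)
  expect_lt(od$weights[2], 1e-6)
  # random 2-point problems match the brute-force simplex oracle
  for (rep in 1:20) {
    L <- matrix(rnorm(6, -5, 2), nrow = 3, ncol = 2)
    o <- np_optimize_weights(L, tol = 1e-15, max_iter = 5e5)
    bf <- brute_force_weights(L)
    expect_true(all(diff(o$trace) >= -1e-9))  # monotone objective
    expect_gte(o$objective, bf$grid_objective - 1e-8)
    expect_lt(abs(o$weights[1] - bf$w1), 1e-6)
  }
  # impossible subject raises an informative error
  Lbad <- rbind(c(-1, -2), c(-Inf, -Inf))
  rownames(Lbad) <- c("ok", "S99")
  expect_error(np_optimize_weights(Lbad), "S99")
})

test_that("posteriors are proper and match direct Bayes computation", {
  set.seed(21)
  L <- matrix(rnorm(12, -8, 3), nrow = 3, ncol = 4)
  w <- c(0.4, 0.3, 0.2, 0.1)
  post <- pkadherence:::posterior_matrix(L, w)
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-12)
  direct <- t(apply(L, 1, function(l) {
    p <- w * exp(l)
    p / sum(p)
  }))
  expect_equal(post, direct, tolerance = 1e-10)
  # flat weights + equal likelihoods give a uniform posterior
  flat <- pkadherence:::posterior_matrix(matrix(-5, 2, 4), rep(0.25, 4))
  expect_equal(flat, matrix(0.25, 2, 4), tolerance = 1e-12)
})

test_that("noise-free single-mode data collapse the fit onto the truth", {
  fx <- fixture_fit()
  fit <- fx$fit
  s <- fit$support
  heavy <- s[s$weight > 0.01, ]
  expect_lte(nrow(heavy), 2L)
  expect_lt(max(rel_err(heavy$ka, 1.74)), 0.05)
  expect_lt(max(rel_err(heavy$ke, 0.135)), 0.05)
  expect_lt(max(rel_err(heavy$v, 44.75)), 0.05)
  expect_equal(sum(s$weight), 1, tolerance = 1e-9)
  # recorded log-likelihood trace never decreases (prune + refine monotone)
  expect_true(all(diff(fit$trace$loglik) >= -1e-9))
  # posterior weights per subject sum to one
  expect_equal(unname(rowSums(fit$posteriors)),
               rep(1, length(fit$records)), tolerance = 1e-9)
})

test_that("refitting with an identical seed reproduces the log-likelihood", {
  fx <- fixture_fit()
  refit <- np_fit(fx$cohort$data, "ATR_ATRL", seed = 7, n_grid = 120,
                  n_explore = 200)
  expect_equal(refit$loglik, fx$fit$loglik, tolerance = 1e-10)
  expect_equal(refit$support, fx$fit$support, tolerance = 1e-10)
})

test_that("tidy and glance expose the support and fit statistics", {
  fx <- fixture_fit()
  td <- tidy(fx$fit)
  expect_true(all(c("ka", "ke", "v", "weight", "v_over_f") %in% names(td)))
  expect_equal(td$v_over_f, td$v / td$f)
  g <- glance(fx$fit)
  k <- g$n_support
  expect_equal(g$aic, -2 * g$loglik + 2 * (4 * k - 1))
  expect_equal(g$bic, -2 * g$loglik + (4 * k - 1) * log(g$n_obs))
  expect_s3_class(np_posterior(fx$fit), "tbl_df")
  expect_equal(nrow(np_posterior(fx$fit)), 12L)
})
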