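test_that("dose conversion uses the atorvastatin molar mass", {
  expect_equal(signif(mg_to_nmol(20) / 1000, 3), 35.8)
  expect_equal(signif(mg_to_nmol(5) / 1000, 3), 8.95)
  expect_equal(signif(mg_to_nmol(40) / 1000, 3), 71.6)
  expect_identical(mg_to_nmol(0), 0)
  expect_error(mg_to_nmol(-1), "non-negative")
  # doubling dose doubles the amount
  expect_equal(mg_to_nmol(2 * 7.3), 2 * mg_to_nmol(7.3))
})

test_that("half-life arithmetic and monotonicity", {
  expect_equal(round(half_life(0.135), 1), 5.1)
  expect_equal(round(half_life(0.110), 1), 6.3)
  expect_equal(half_life(log(2)), 1.0)
  expect_error(half_life(0), "positive")
  ke <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(diff(half_life(ke)) < 0))
})

test_that("parameter validation enforces positivity and bioavailability", {
  expect_s3_class(pk_params(1.74, 0.135, 44.75), "tbl_df")
  expect_equal(pk_params(1, 0.1, 10)$f, 0.125)
  expect_error(pk_params(-1, 0.1, 10), "positive")
  expect_error(pk_params(1, 0.1, 10, f = 1.2), "0, 1")
})

test_that("single-dose concentration is zero at t = 0, non-negative, vanishing", {
  p <- pk_params(1.74, 0.135, 44.75)
  prof <- conc_single_dose(p, 20, c(0, seq(0.5, 200, by = 0.5)))
  expect_identical(prof$conc_nmol_l[1], 0)
  expect_true(all(prof$conc_nmol_l >= 0))
  expect_lt(dplyr::last(prof$conc_nmol_l), 1e-6 * max(prof$conc_nmol_l))
})

test_that("closed form matches the ODE oracle for single doses", {
  skip_if_not_installed("deSolve")
  pars <- random_params(20, seed = 301)
  times <- c(0.5, 1, 2, 6, 12, 24, 48)
  ev <- tibble::tibble(time_h = 0, amount_mg = 20)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    cf <- conc_single_dose(p, 20, times)$conc_nmol_l
    oc <- ode_conc_oracle(p, ev, times)
    expect_lt(max(rel_err(cf, oc)), 1e-6)
  }
})

test_that("near-degenerate ka ~ ke switches to the analytic limit smoothly", {
  tt <- c(0.5, 2, 5, 20)
  lim <- conc_single_dose(pk_params(0.2, 0.2, 44.75), 20, tt)$conc_nmol_l
  near <- conc_single_dose(pk_params(0.2 + 1e-9, 0.2, 44.75), 20,
                           tt)$conc_nmol_l
  expect_lt(max(rel_err(lim, near)), 1e-5)
})

test_that("profiles superpose dose contributions linearly", {
  p <- pk_params(1.2, 0.2, 30)
  d1 <- tibble::tibble(time_h = 0, amount_mg = 20)
  d2 <- tibble::tibble(time_h = 24, amount_mg = 20)
  both <- conc_profile(p, dplyr::bind_rows(d1, d2), c(30, 40))$conc_nmol_l
  sep <- conc_profile(p, d1, c(30, 40))$conc_nmol_l +
    conc_profile(p, d2, c(30, 40))$conc_nmol_l
  expect_equal(both, sep, tolerance = 1e-12)
})

test_that("repeat-dose profile matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  ev14 <- tibble::tibble(time_h = (0:13) * 24, amount_mg = 20)
  times <- 312 + c(1, 6, 12, 24, 48, 96)
  pars <- random_params(6, seed = 302)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    cf <- conc_profile(p, ev14, times)$conc_nmol_l
    oc <- ode_conc_oracle(p, ev14, times)
    expect_lt(max(rel_err(cf, oc)), 1e-6)
  }
})

test_that("c_ini acts as a decaying initial condition and excludes history", {
  p <- pk_params(1.5, 0.1, 40)
  none <- tibble::tibble(time_h = numeric(), amount_mg = numeric())
  prof <- conc_profile(p, none, c(0, 10), c_ini = 1.0)
  expect_equal(prof$conc_nmol_l, c(1.0, exp(-0.1 * 10)))
  hist <- tibble::tibble(time_h = -36, amount_mg = 20)
  expect_error(conc_profile(p, hist, 2, c_ini = 0.5), "Ambiguous history")
  skip_if_not_installed("deSolve")
  oc <- ode_conc_oracle(p, tibble::tibble(time_h = 0, amount_mg = 0),
                        c(0, 10), c_ini = 1.0)
  expect_lt(max(rel_err(prof$conc_nmol_l, oc)), 1e-6)
})

test_that("dose normalization divides by dose and is scale invariant", {
  expect_equal(dose_normalize(12.48, 40), 0.312)
  expect_identical(dose_normalize(0, 20), 0)
  expect_equal(dose_normalize(2 * 3.3, 2 * 11), dose_normalize(3.3, 11))
  expect_error(dose_normalize(1, 0), "positive")
  # dose-normalized profiles are identical across doses (linear kinetics)
  p <- pk_params(1.74, 0.135, 44.75)
  c20 <- conc_single_dose(p, 20, 1:6)$conc_nmol_l / 20
  c80 <- conc_single_dose(p, 80, 1:6)$conc_nmol_l / 80
  expect_equal(c20, c80, tolerance = 1e-12)
})

test_that("assay error models carry the published coefficients", {
  atrl <- assay_error("ATR_ATRL")
  met <- assay_error("ATR_MET")
  expect_equal(error_sd(atrl, 0), 8.26e-5)
  expect_equal(error_sd(met, 0), 3.86e-5)
  expect_equal(atrl$lam, 0.01)
  expect_equal(obs_weight(atrl, 1), 1 / (0.01 + 8.26e-5 + 3.53e-2))
  expect_equal(total_sd(met, 2), 0.01 + 3.86e-5 + 3.32e-2 * 2)
  expect_error(error_sd(atrl, -1), "non-negative")
  expect_error(assay_error(c0 = -1, c1 = 0.1), "non-negative")
})
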