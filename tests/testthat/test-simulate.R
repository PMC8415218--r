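truth1 <- function() dplyr::mutate(pk_params(1.74, 0.135, 44.75), weight = 1)

test_that("parameter draws follow the support weights deterministically", {
  single <- sample_params(truth1(), 50, seed = 3)
  expect_true(all(single$ka == 1.74 & single$v == 44.75))
  two <- default_true_distribution("ATR_ATRL")[1:2, ]
  two$weight <- c(0.5, 0.5)
  draws <- sample_params(two, 1e5, seed = 4)
  expect_lt(abs(mean(draws$ka == two$ka[1]) - 0.5), 0.01)
  expect_identical(sample_params(two, 100, seed = 9),
                   sample_params(two, 100, seed = 9))
  expect_error(sample_params(two[0, ], 5), "Empty")
})

test_that("scenario values are repeat-dose model concentrations", {
  g <- simulate_scenarios(truth1(), n_per_dose = 3, doses_mg = 20,
                          fst_grid_h = c(1, 12, 24), seed = 1)
  # single support point: every virtual subject equals the closed form
  ev <- tibble::tibble(time_h = (0:13) * 24, amount_mg = 20)
  p <- pk_params(1.74, 0.135, 44.75)
  for (sc in c("adherent", "partial", "nonadherent")) {
    off <- c(adherent = 0, partial = 24, nonadherent = 72)[[sc]]
    for (fst in c(1, 12, 24)) {
      want <- conc_profile(p, ev, 312 + fst + off)$conc_nmol_l / 20
      got <- g$conc_norm[g$scenario == sc & g$fst_h == fst]
      expect_equal(got, rep(want, 3), tolerance = 1e-12)
    }
  }
  # oracle: steady-state accumulation closed form (geometric series)
  acc <- function(k, n, tau) (1 - exp(-n * k * tau)) / (1 - exp(-k * tau))
  D <- mg_to_nmol(20)
  coef <- 0.125 * D * 1.74 / (44.75 * (1.74 - 0.135))
  want1 <- coef * (exp(-0.135 * (312 + 1)) * exp(0.135 * 312) *
                     acc(0.135, 14, 24) -
                   exp(-1.74 * (312 + 1)) * exp(1.74 * 312) *
                     acc(1.74, 14, 24)) / 20
  expect_equal(g$conc_norm[g$scenario == "adherent" & g$fst_h == 1][1],
               want1, tolerance = 1e-9)
  skip_if_not_installed("deSolve")
  oc <- ode_conc_oracle(p, ev, 312 + c(1, 12, 24))
  expect_equal(g$conc_norm[g$scenario == "adherent" & g$subject == 1],
               oc / 20, tolerance = 1e-6)
})

test_that("partial-scenario values equal adherent values 24 h later", {
  # extend the FST grid so the shifted sampling times are directly on it
  g1 <- simulate_scenarios(truth1(), n_per_dose = 1, doses_mg = 20,
                           fst_grid_h = 1:96, seed = 3)
  a <- g1[g1$scenario == "adherent", ]
  p1 <- g1[g1$scenario == "partial", ]
  n1 <- g1[g1$scenario == "nonadherent", ]
  for (f in c(1, 7, 16, 24)) {
    expect_equal(p1$conc_norm[p1$fst_h == f],
                 a$conc_norm[a$fst_h == f + 24], tolerance = 1e-12)
    expect_equal(n1$conc_norm[n1$fst_h == f],
                 a$conc_norm[a$fst_h == f + 72], tolerance = 1e-12)
  }
})

test_that("scenario medians are ordered and nonadherence is near-zero", {
  dist <- default_true_distribution("ATR_ATRL")
  g <- simulate_scenarios(dist, n_per_dose = 500, doses_mg = c(20, 40),
                          seed = 5)
  med <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(g), fst_h, scenario),
    m = stats::median(conc_norm), .groups = "drop")
  wide <- tidyr::pivot_wider(med, names_from = "scenario",
                             values_from = "m")
  expect_true(all(wide$adherent > wide$partial))
  expect_true(all(wide$partial > wide$nonadherent))
  # nonadherent concentrations are < 1% of the matched adherent value
  # subject-by-subject (the decay over 72 h dominates any absorption)
  wide2 <- tidyr::pivot_wider(tibble::as_tibble(g),
                              names_from = "scenario",
                              values_from = "conc_norm")
  expect_true(all(wide2$nonadherent <= 0.01 * wide2$adherent))
})

test_that("dose-normalized distributions are dose-invariant and complete", {
  dist <- default_true_distribution("ATR_ATRL")
  g <- simulate_scenarios(dist, n_per_dose = 10000,
                          doses_mg = c(5, 80), fst_grid_h = c(6, 24),
                          seed = 6)
  a5 <- g$conc_norm[g$dose_mg == 5 & g$fst_h == 6 &
                      g$scenario == "adherent"]
  a80 <- g$conc_norm[g$dose_mg == 80 & g$fst_h == 6 &
                       g$scenario == "adherent"]
  ks <- suppressWarnings(stats::ks.test(a5, a80)$statistic)
  expect_lt(unname(ks), 0.02)
  # total rows = subjects x fst x scenarios
  expect_equal(nrow(g), 2 * 10000 * 2 * 3)
  expect_true(all(g$conc_norm >= 0))
})
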