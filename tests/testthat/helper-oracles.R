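# Independent oracles and shared fixtures for the test suite.

# Numerical ODE oracle for the one-compartment oral model: two states
# (gut amount, central amount), doses as impulsive additions of F * dose to
# the gut. Independent of the closed-form production path.
ode_conc_oracle <- function(params, doses, times, c_ini = 0,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  rhs <- function(t, y, p) {
    list(c(-params$ka * y[1], params$ka * y[1] - params$ke * y[2]))
  }
  t0 <- min(0, doses$time_h)
  grid <- sort(unique(c(t0, doses$time_h, times)))
  ev <- data.frame(var = "gut", time = doses$time_h,
                   value = params$f * mg_to_nmol(doses$amount_mg),
                   method = "add")
  out <- deSolve::lsoda(c(gut = 0, cen = c_ini * params$v), grid, rhs,
                        parms = NULL, events = list(data = ev),
                        rtol = rtol, atol = atol)
  out[match(times, out[, "time"]), "cen"] / params$v
}

# Brute-force oracle for the two-point mixture weight problem: dense grid
# scan over w1 followed by golden-section refinement of the 1-D objective.
brute_force_weights <- function(L) {
  stopifnot(ncol(L) == 2)
  obj <- function(w1) {
    sum(log(w1 * exp(L[, 1]) + (1 - w1) * exp(L[, 2])))
  }
  grid <- seq(0, 1, by = 1e-4)
  vals <- vapply(grid, obj, numeric(1))
  best <- grid[which.max(vals)]
  o <- stats::optimize(obj, c(max(0, best - 2e-4), min(1, best + 2e-4)),
                       maximum = TRUE, tol = 1e-12)
  list(w1 = o$maximum, objective = o$objective, grid_objective = max(vals))
}

# Relative error with an absolute floor so that concentrations near the
# integrator's absolute tolerance do not dominate the comparison.
rel_err <- function(x, ref) {
  floor <- 1e-8 * max(abs(ref), 1)
  abs(x - ref) / pmax(abs(ref), floor)
}

# Random one-compartment parameter sets away from the ka/ke degeneracy.
random_params <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    ka = exp(runif(n, log(0.2), log(8))),
    ke = exp(runif(n, log(0.02), log(0.5))),
    v = runif(n, 10, 90),
    f = 0.125
  )
}

# Two-mode noisy fixture whose posterior parameter means vary between
# subjects (needed by covariate-screening tests), memoized per run.
fixture_fit2 <- function() {
  if (is.null(.fixture_env$fit2)) {
    truth2 <- pk_params(c(1.74, 0.87), c(0.135, 0.2), c(44.75, 30))
    truth2$weight <- c(0.5, 0.5)
    tc <- synth_training_cohort(
      "ATR_ATRL", truth = truth2,
      allocation_naive = c("20" = 8, "40" = 2),
      allocation_prior = c("20" = 1, "40" = 1),
      noise = TRUE, seed = 8
    )
    .fixture_env$fit2 <- np_fit(tc$data, "ATR_ATRL", seed = 8, n_grid = 120,
                                n_explore = 200)
  }
  .fixture_env$fit2
}

# Small shared fit fixture: noiseless single-mode cohort, memoized per run.
.fixture_env <- new.env(parent = emptyenv())
fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    tc <- synth_training_cohort(
      "ATR_ATRL",
      truth = dplyr::mutate(pk_params(1.74, 0.135, 44.75), weight = 1),
      allocation_naive = c("20" = 8, "40" = 2),
      allocation_prior = c("20" = 1, "40" = 1),
      noise = FALSE, seed = 7
    )
    .fixture_env$cohort <- tc
    .fixture_env$fit <- np_fit(tc$data, "ATR_ATRL", seed = 7, n_grid = 120,
                               n_explore = 200)
  }
  list(fit = .fixture_env$fit, cohort = .fixture_env$cohort)
}
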