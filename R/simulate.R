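# Coerce an np_fit or a support tibble (ka, ke, v, f, weight) to a
# validated discrete parameter distribution.
as_support <- function(dist) {
  if (inherits(dist, "np_fit")) dist <- dist$support
  dist <- tibble::as_tibble(dist)
  abort_if(nrow(dist) == 0, "Empty parameter distribution.")
  if (!"weight" %in% names(dist)) dist$weight <- 1 / nrow(dist)
  validate_pk_params(dist)
  abort_if(any(dist$weight < 0), "Weights must be non-negative.")
  abort_if(abs(sum(dist$weight) - 1) > 1e-8,
           "Weights must sum to 1.")
  dist
}

#' Draw parameter vectors from a fitted population distribution
#'
#' Categorical draw of support points by probability weight. Optional
#' multivariate-normal jitter around the drawn point (off by default; the
#' discrete NPML distribution is the fitted object) with SD a fraction of
#' each parameter range, truncated to the parameter box.
#'
#' @param dist An [np_fit()] object or a support tibble with columns `ka`,
#'   `ke`, `v`, `f`, `weight`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param jitter `"off"` (default) or `"mvn"`.
#' @param jitter_sd Jitter SD as a fraction of each parameter range.
#' @param ranges Truncation box for jittered draws.
#' @return A tibble of `n` parameter rows.
#' @export
sample_params <- function(dist, n, seed = 1L, jitter = c("off", "mvn"),
                          jitter_sd = 0.05, ranges = np_ranges()) {
  jitter <- match.arg(jitter)
  dist <- as_support(dist)
  set.seed(seed)
  idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$weight)
  out <- dist[idx, c("ka", "ke", "v", "f")]
  if (jitter == "mvn") {
    for (nm in c("ka", "ke", "v")) {
      span <- ranges[[nm]][2] - ranges[[nm]][1]
      out[[nm]] <- pmin(pmax(out[[nm]] + stats::rnorm(n, 0, jitter_sd * span),
                             ranges[[nm]][1]), ranges[[nm]][2])
    }
  }
  tibble::as_tibble(out)
}

#' Simulate adherence scenarios for a virtual cohort
#'
#' Monte Carlo simulation of the dose-normalized concentrations that
#' adherent, partially adherent and nonadherent patients would present at a
#' range of first sampling times (FST). For each virtual subject a once-daily
#' loading regimen of `n_loading` doses is simulated with the closed-form
#' one-compartment model; the sample is drawn `fst` hours after the last dose
#' for the adherent scenario, and `fst + 24` / `fst + 72` hours after it for
#' the partial (last dose omitted) and nonadherent (last three doses omitted)
#' scenarios. Concentrations are normalized to the dose in mg, which makes
#' the scenario distributions dose-invariant under linear kinetics; the
#' per-dose cohorts are pooled for downstream ROC and attainment analysis.
#'
#' @param dist An [np_fit()] object or support tibble (see [sample_params()]).
#' @param n_per_dose Virtual subjects per dose (default 10000).
#' @param doses_mg Simulated doses in mg (default `c(5, 10, 20, 40, 80)`).
#' @param n_loading Number of once-daily loading doses (default 14).
#' @param interval_h Dosing interval in hours (default 24).
#' @param fst_grid_h First-sampling-time grid in hours after the last dose.
#' @param offsets_h Named scenario offsets in hours added to the FST.
#' @param seed Integer seed.
#' @param jitter Passed to [sample_params()].
#' @return A `scenario_grid` tibble with columns `subject`, `dose_mg`,
#'   `fst_h`, `scenario`, `conc_norm` and the simulation settings attached as
#'   attributes.
#' @export
simulate_scenarios <- function(dist, n_per_dose = 10000L,
                               doses_mg = c(5, 10, 20, 40, 80),
                               n_loading = 14L, interval_h = 24,
                               fst_grid_h = 1:24,
                               offsets_h = c(adherent = 0, partial = 24,
                                             nonadherent = 72),
                               seed = 1L, jitter = "off") {
  abort_if(n_per_dose < 1, "`n_per_dose` must be at least 1.")
  abort_if(is.unsorted(fst_grid_h, strictly = TRUE),
           "`fst_grid_h` must be strictly increasing.")
  abort_if(is.unsorted(offsets_h, strictly = TRUE),
           "`offsets_h` must be strictly increasing.")
  dist <- as_support(dist)
  dose_times <- (seq_len(n_loading) - 1) * interval_h
  last_dose <- dose_times[n_loading]
  scen <- names(offsets_h)
  # sampling times relative to the first dose, one per (fst, scenario)
  design <- tidyr::expand_grid(scenario = scen, fst_h = fst_grid_h)
  design$offset <- offsets_h[design$scenario]
  times_abs <- last_dose + design$fst_h + design$offset

  out <- vector("list", length(doses_mg))
  for (d in seq_along(doses_mg)) {
    params <- sample_params(dist, n_per_dose, seed = seed + d - 1L,
                            jitter = jitter)
    cm <- conc_matrix(params, dose_times,
                      mg_to_nmol(doses_mg[d]), times_abs)
    grid <- tidyr::expand_grid(
      subject = (d - 1L) * n_per_dose + seq_len(n_per_dose),
      design[c("scenario", "fst_h")]
    )
    grid$dose_mg <- doses_mg[d]
    grid$conc_norm <- dose_normalize(as.vector(t(cm)), doses_mg[d])
    out[[d]] <- grid[c("subject", "dose_mg", "fst_h", "scenario",
                       "conc_norm")]
  }
  grid <- dplyr::bind_rows(out)
  structure(grid,
            class = c("scenario_grid", class(grid)),
            settings = list(n_per_dose = n_per_dose, doses_mg = doses_mg,
                            n_loading = n_loading, interval_h = interval_h,
                            fst_grid_h = fst_grid_h, offsets_h = offsets_h,
                            seed = seed, jitter = jitter))
}
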