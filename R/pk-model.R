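# Molar mass of atorvastatin (free acid), g/mol. Doses are prescribed in mg
# but the assay reports nmol/L, so dose amounts are carried in nmol internally.
ATORVASTATIN_MOLAR_MASS <- 558.64

#' Convert an atorvastatin dose from mg to nmol
#'
#' @param dose_mg Dose in milligrams (vectorized, must be non-negative).
#' @param molar_mass Molar mass in g/mol; defaults to atorvastatin, 558.64.
#' @return Dose amount in nmol.
#' @export
#' @examples
#' mg_to_nmol(20) / 1000 # 35.8 umol
mg_to_nmol <- function(dose_mg, molar_mass = ATORVASTATIN_MOLAR_MASS) {
  abort_if(any(dose_mg < 0, na.rm = TRUE), "`dose_mg` must be non-negative.")
  abort_if(molar_mass <= 0, "`molar_mass` must be positive.")
  dose_mg / molar_mass * 1e6
}

#' Elimination half-life
#'
#' t1/2 = ln(2) / Ke for first-order elimination.
#'
#' @param ke Elimination rate constant, 1/h (vectorized, must be positive).
#' @return Half-life in hours.
#' @export
#' @examples
#' half_life(0.135) # about 5.1 h
half_life <- function(ke) {
  abort_if(any(ke <= 0, na.rm = TRUE), "`ke` must be positive.")
  log(2) / ke
}

#' Pharmacokinetic parameter set
#'
#' Builds (and validates) a tibble of one-compartment oral absorption
#' parameters. Each row is one parameter vector: absorption rate constant
#' `ka` (1/h), elimination rate constant `ke` (1/h), volume of distribution
#' `v` (L) and fixed oral bioavailability `f`. The apparent volume commonly
#' reported for oral dosing is `v / f`.
#'
#' @param ka,ke Rate constants, 1/h; strictly positive.
#' @param v Volume of distribution, L; strictly positive.
#' @param f Oral bioavailability in (0, 1]; fixed at 0.125 by default.
#' @return A tibble with columns `ka`, `ke`, `v`, `f`.
#' @export
#' @examples
#' pk_params(ka = 1.74, ke = 0.135, v = 44.75)
pk_params <- function(ka, ke, v, f = 0.125) {
  out <- tibble::tibble(ka = as.numeric(ka), ke = as.numeric(ke),
                        v = as.numeric(v), f = as.numeric(f))
  validate_pk_params(out)
  out
}

validate_pk_params <- function(params) {
  abort_if(!all(c("ka", "ke", "v") %in% names(params)),
           "`params` needs columns ka, ke, v.")
  if (!"f" %in% names(params)) params$f <- 0.125
  abort_if(any(params$ka <= 0) || any(params$ke <= 0) || any(params$v <= 0),
           "ka, ke and v must all be strictly positive.")
  abort_if(any(params$f <= 0) || any(params$f > 1),
           "Bioavailability f must lie in (0, 1].")
  invisible(params)
}

# Single-dose concentration terms for aligned vectors of parameters and
# elapsed times. `dt` is time since the dose; negative dt contributes 0.
# Near ka == ke the Bateman form cancels catastrophically, so within a
# relative tolerance the analytic limit f*D*ke*dt*exp(-ke*dt)/v is used.
bateman <- function(ka, ke, v, f, dose_nmol, dt, tol = 1e-6) {
  dt <- pmax(dt, 0)
  degen <- abs(ka - ke) < tol * pmax(ka, ke)
  out <- numeric(length(dt))
  if (any(!degen)) {
    i <- !degen
    out[i] <- (f * dose_nmol * ka / (v * (ka - ke)) *
                 (exp(-ke * dt) - exp(-ka * dt)))[i]
  }
  if (any(degen)) {
    i <- degen
    out[i] <- (f * dose_nmol * ke * dt * exp(-ke * dt) / v)[i]
  }
  out
}

#' Concentration after a single oral dose
#'
#' Closed-form one-compartment model with first-order absorption and
#' elimination. When `ka` and `ke` are within a relative tolerance of each
#' other the analytic limit is used to avoid cancellation.
#'
#' @param params A one-row parameter tibble from [pk_params()].
#' @param dose_mg Dose in mg.
#' @param times Sampling times in hours since the dose (non-negative).
#' @param tol Relative `ka`/`ke` degeneracy tolerance.
#' @return A tibble with columns `time_h` and `conc_nmol_l`.
#' @export
#' @examples
#' conc_single_dose(pk_params(1.74, 0.135, 44.75), dose_mg = 20, times = 0:6)
conc_single_dose <- function(params, dose_mg, times, tol = 1e-6) {
  validate_pk_params(params)
  abort_if(nrow(params) != 1L, "`params` must have exactly one row.")
  abort_if(any(times < 0), "`times` must be non-negative.")
  d <- mg_to_nmol(dose_mg)
  conc <- bateman(params$ka, params$ke, params$v, params$f, d, times, tol)
  tibble::tibble(time_h = as.numeric(times), conc_nmol_l = conc)
}

#' Concentration profile under a dosing history
#'
#' Superposition of single-dose contributions for an arbitrary sequence of
#' oral doses, with two mutually exclusive ways to encode prior exposure:
#' dose events at negative times, or a measured pre-dose concentration
#' `c_ini` that decays mono-exponentially from time zero (no residual
#' absorption depot). Supplying both is ambiguous and raises an error.
#'
#' @param params A one-row parameter tibble from [pk_params()].
#' @param doses A data frame of dose events with columns `time_h` (hours,
#'   may be negative for prior history) and `amount_mg`.
#' @param times Sampling times in hours (non-negative).
#' @param c_ini Pre-dose concentration in nmol/L used as the initial
#'   condition of the central compartment; default 0.
#' @param tol Relative `ka`/`ke` degeneracy tolerance.
#' @return A tibble with columns `time_h` and `conc_nmol_l`.
#' @export
conc_profile <- function(params, doses, times, c_ini = 0, tol = 1e-6) {
  validate_pk_params(params)
  abort_if(nrow(params) != 1L, "`params` must have exactly one row.")
  abort_if(any(times < 0), "`times` must be non-negative.")
  abort_if(c_ini < 0, "`c_ini` must be non-negative.")
  if (is.null(doses) || nrow(doses) == 0L) {
    doses <- tibble::tibble(time_h = numeric(), amount_mg = numeric())
  }
  abort_if(!all(c("time_h", "amount_mg") %in% names(doses)),
           "`doses` needs columns time_h and amount_mg.")
  abort_if(any(doses$amount_mg < 0), "Dose amounts must be non-negative.")
  abort_if(c_ini > 0 && any(doses$time_h < 0),
           paste("Ambiguous history: supply either prior dose events",
                 "(negative times) or `c_ini`, not both."))
  conc <- c_ini * exp(-params$ke * times)
  for (i in seq_len(nrow(doses))) {
    conc <- conc + bateman(params$ka, params$ke, params$v, params$f,
                           mg_to_nmol(doses$amount_mg[i]),
                           times - doses$time_h[i], tol)
  }
  tibble::tibble(time_h = as.numeric(times), conc_nmol_l = conc)
}

# Vectorized repeat-dose evaluation used by the fitter and the simulator:
# one regimen (dose times in h, single amount in nmol), many parameter rows,
# many sampling times. Returns an nrow(params) x length(times) matrix.
conc_matrix <- function(params, dose_times, dose_nmol, times, c_ini = 0,
                        tol = 1e-6) {
  ka <- params$ka; ke <- params$ke; v <- params$v; f <- params$f
  n <- length(ka)
  out <- outer(ke, times, function(k, t) exp(-k * t)) * c_ini
  for (td in dose_times) {
    dt <- outer(rep(1, n), times - td)
    dt[dt < 0] <- 0
    ek <- exp(-ke * dt)  # recycles ke down columns
    ea <- exp(-ka * dt)
    coef <- f * dose_nmol * ka / (v * (ka - ke))
    term <- coef * (ek - ea)
    degen <- abs(ka - ke) < tol * pmax(ka, ke)
    if (any(degen)) {
      lim <- (f * dose_nmol * ke / v) * dt * ek
      term[degen, ] <- lim[degen, , drop = FALSE]
    }
    term[dt == 0] <- 0
    out <- out + term
  }
  out
}

#' Dose-normalized concentration
#'
#' @param conc Concentration in nmol/L.
#' @param dose_mg Prescribed dose in mg (strictly positive).
#' @return Concentration per mg of dose, nmol (mg dose)^-1 L^-1.
#' @export
#' @examples
#' dose_normalize(12.48, 40)
dose_normalize <- function(conc, dose_mg) {
  abort_if(any(dose_mg <= 0), "`dose_mg` must be strictly positive.")
  conc / dose_mg
}
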