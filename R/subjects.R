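#' Read and validate subject dosing-observation data
#'
#' Subject data are exchanged in a long CSV format with one row per dose
#' event or observation: columns `subject`, `event_type` (`"dose"` or
#' `"obs"`), `time_h` (decimal hours), `amount_mg` (dose rows), `conc_nmol_l`
#' (observation rows), `analyte` (`"ATR_ATRL"` or `"ATR_MET"`), and
#' `c_ini_nmol_l` (optional pre-dose concentration, constant within subject).
#' Any additional columns are treated as subject-level covariates and must be
#' constant within subject.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_subjects <- function(path) {
  abort_if(!file.exists(path), paste0("No such file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_subjects(data)
}

#' @rdname read_subjects
#' @param data A subject data frame in the long format described above.
#' @export
write_subjects <- function(data, path) {
  validate_subjects(data)
  readr::write_csv(data, path)
  invisible(path)
}

subject_core_cols <- c("subject", "event_type", "time_h", "amount_mg",
                       "conc_nmol_l", "analyte", "c_ini_nmol_l")

#' @rdname read_subjects
#' @export
validate_subjects <- function(data) {
  need <- c("subject", "event_type", "time_h")
  missing_cols <- setdiff(need, names(data))
  abort_if(length(missing_cols) > 0,
           paste("Missing required columns:",
                 paste(missing_cols, collapse = ", ")))
  if (!"amount_mg" %in% names(data)) data$amount_mg <- NA_real_
  if (!"conc_nmol_l" %in% names(data)) data$conc_nmol_l <- NA_real_
  if (!"analyte" %in% names(data)) data$analyte <- "ATR_ATRL"
  if (!"c_ini_nmol_l" %in% names(data)) data$c_ini_nmol_l <- NA_real_
  bad_type <- !data$event_type %in% c("dose", "obs")
  abort_if(any(bad_type),
           paste0("Unknown event_type in rows: ",
                  paste(utils::head(which(bad_type), 5), collapse = ", "),
                  " (must be 'dose' or 'obs')."))
  bad_an <- !is.na(data$analyte) & !data$analyte %in% c("ATR_ATRL", "ATR_MET")
  abort_if(any(bad_an),
           "Unknown analyte label; valid labels are ATR_ATRL, ATR_MET.")
  abort_if(any(!is.finite(data$time_h)), "All times must be finite.")
  obs <- data[data$event_type == "obs", ]
  abort_if(any(is.na(obs$conc_nmol_l)) || any(obs$conc_nmol_l < 0),
           "Observation rows need a non-negative conc_nmol_l.")
  dose <- data[data$event_type == "dose", ]
  abort_if(any(is.na(dose$amount_mg)) || any(dose$amount_mg < 0),
           "Dose rows need a non-negative amount_mg.")
  no_obs <- setdiff(unique(data$subject), unique(obs$subject))
  abort_if(length(no_obs) > 0,
           paste("Subjects without observations:",
                 paste(no_obs, collapse = ", ")))
  tibble::as_tibble(data)
}

# Split a long subject table into per-subject records used by the fitter:
# a list of lists with id, doses, obs (times/concs), c_ini, covariates.
split_subjects <- function(data, analyte = NULL) {
  data <- validate_subjects(data)
  if (!is.null(analyte)) {
    keep <- data$event_type == "dose" | data$analyte == analyte
    data <- data[keep, , drop = FALSE]
  }
  extra <- setdiff(names(data), subject_core_cols)
  ids <- unique(data$subject)
  lapply(ids, function(id) {
    rows <- data[data$subject == id, , drop = FALSE]
    doses <- rows[rows$event_type == "dose", c("time_h", "amount_mg")]
    obs <- rows[rows$event_type == "obs", c("time_h", "conc_nmol_l")]
    abort_if(nrow(obs) == 0,
             paste0("Subject ", id, " has no observations for this analyte."))
    c_ini <- rows$c_ini_nmol_l[!is.na(rows$c_ini_nmol_l)]
    c_ini <- if (length(c_ini)) c_ini[1] else 0
    abort_if(c_ini > 0 && any(doses$time_h < 0),
             paste0("Subject ", id, ": both prior-history dose events and ",
                    "c_ini supplied; use one history mode only."))
    covs <- if (length(extra)) {
      vals <- lapply(extra, function(cl) {
        u <- unique(rows[[cl]][!is.na(rows[[cl]])])
        if (length(u) == 1) u else NA
      })
      stats::setNames(vals, extra)
    } else list()
    list(id = id, doses = doses,
         obs_times = obs$time_h, obs_conc = obs$conc_nmol_l,
         c_ini = c_ini, covariates = covs)
  })
}

# Model-predicted concentrations for one subject at its observation times,
# for many candidate parameter rows at once. Returns K x n_obs matrix.
predict_subject <- function(record, params, tol = 1e-6) {
  pred <- outer(params$ke, record$obs_times,
                function(k, t) exp(-k * pmax(t, 0))) * record$c_ini
  for (i in seq_len(nrow(record$doses))) {
    pred <- pred + conc_matrix(
      params,
      dose_times = record$doses$time_h[i],
      dose_nmol = mg_to_nmol(record$doses$amount_mg[i]),
      times = record$obs_times, c_ini = 0, tol = tol)
  }
  pred
}
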