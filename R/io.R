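#' Serialize a fitted population model to JSON
#'
#' Writes the support points and weights, configuration, convergence state,
#' per-subject posterior parameter means and diagnostics in a
#' human-auditable JSON layout. [read_np_fit()] restores the parts needed by
#' the simulation and evaluation stages (the support distribution and the
#' error model); it does not reconstruct the raw subject records.
#'
#' @param fit An [np_fit()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_np_fit <- function(fit, path) {
  stopifnot(inherits(fit, "np_fit"))
  obj <- list(
    analyte = fit$analyte,
    f = fit$f,
    support = fit$support,
    loglik = fit$loglik,
    n_cycles = fit$n_cycles,
    converged = fit$converged,
    n_obs = fit$n_obs,
    seed = fit$seed,
    ranges = fit$ranges,
    error_model = unclass(fit$error_model),
    config = fit$config,
    post_params = fit$post_params,
    glance = glance(fit)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_np_fit
#' @export
read_np_fit <- function(path) {
  abort_if(!file.exists(path), paste0("No such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  support <- tibble::as_tibble(obj$support)
  validate_pk_params(support)
  obj$support <- support
  obj$post_params <- tibble::as_tibble(obj$post_params)
  obj$error_model <- structure(obj$error_model, class = "assay_error")
  structure(obj, class = "np_fit_summary")
}

#' Read and write simulated scenario grids
#'
#' Long CSV with columns `subject`, `dose_mg`, `fst_h`, `scenario`,
#' `conc_norm`.
#'
#' @param grid A [simulate_scenarios()] result.
#' @param path CSV file path.
#' @return `write_scenario_grid()` returns `path` invisibly;
#'   `read_scenario_grid()` returns a `scenario_grid` tibble.
#' @export
write_scenario_grid <- function(grid, path) {
  readr::write_csv(tibble::as_tibble(grid), path)
  invisible(path)
}

#' @rdname write_scenario_grid
#' @export
read_scenario_grid <- function(path) {
  abort_if(!file.exists(path), paste0("No such file: ", path))
  grid <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject", "dose_mg", "fst_h", "scenario", "conc_norm")
  miss <- setdiff(need, names(grid))
  abort_if(length(miss) > 0,
           paste("Grid file missing columns:", paste(miss, collapse = ", ")))
  structure(grid, class = c("scenario_grid", class(grid)))
}

read_config <- function(path) {
  abort_if(!file.exists(path), paste0("No such file: ", path))
  if (grepl("\\.ya?ml$", path)) {
    abort_if(!requireNamespace("yaml", quietly = TRUE),
             "Reading YAML configs requires the yaml package.")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full adherence-monitoring pipeline
#'
#' Executes the workflow end to end: (optionally) generate synthetic
#' training and testing cohorts, fit the nonparametric population model per
#' analyte, simulate adherence scenarios, tabulate per-FST ROC performance
#' for both scenario comparisons, and classify the testing patients. All
#' outputs are written under `out_dir` together with a manifest recording
#' seeds, configuration and file hashes, so that a rerun from the manifest
#' seeds reproduces the outputs.
#'
#' @param config A named list (or path to a YAML/JSON file) with optional
#'   entries: `seed` (default 1), `out_dir` (default `tempfile()`),
#'   `analytes`, `n_grid`, `max_cycles`, `n_per_dose`, `doses_mg`,
#'   `fst_grid_h`,
#'   `theta1`, `theta2`, `data` (named per-analyte paths to training CSVs;
#'   when absent synthetic cohorts are generated), `patients` (path to a
#'   patient CSV; when absent a synthetic testing cohort is generated).
#' @return A list with the fits, grids, ROC summaries, the classification
#'   report and the manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("pkadherence_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analytes <- config$analytes %||% c("ATR_ATRL", "ATR_MET")
  n_grid <- config$n_grid %||% 300L
  max_cycles <- config$max_cycles %||% 5000L
  n_per_dose <- config$n_per_dose %||% 1000L
  doses_mg <- config$doses_mg %||% c(5, 10, 20, 40, 80)
  fst_grid_h <- config$fst_grid_h %||% 1:24
  theta1 <- config$theta1 %||% 0.85
  theta2 <- config$theta2 %||% 0.85

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  fits <- list(); grids <- list(); roc_tabs <- list()
  for (an in analytes) {
    suffix <- if (an == "ATR_ATRL") "atrl" else "met"
    data <- stage(paste0("data/", an), {
      if (!is.null(config$data[[an]])) {
        read_subjects(config$data[[an]])
      } else {
        synth_training_cohort(analyte = an, seed = seed)$data
      }
    })
    fits[[an]] <- stage(paste0("fit/", an),
                        np_fit(data, analyte = an, n_grid = n_grid,
                               max_cycles = max_cycles, seed = seed))
    write_np_fit(fits[[an]], file.path(out_dir,
                                       paste0("fit_", suffix, ".json")))
    grids[[an]] <- stage(paste0("simulate/", an),
                         simulate_scenarios(fits[[an]],
                                            n_per_dose = n_per_dose,
                                            doses_mg = doses_mg,
                                            fst_grid_h = fst_grid_h,
                                            seed = seed))
    roc_tabs[[an]] <- stage(paste0("roc/", an), dplyr::bind_rows(
      roc_summary(grids[[an]], "full_vs_partial"),
      roc_summary(grids[[an]], "partial_vs_non")))
    readr::write_csv(roc_tabs[[an]],
                     file.path(out_dir, paste0("roc_", suffix, ".csv")))
  }

  patients <- stage("patients", {
    if (!is.null(config$patients)) {
      readr::read_csv(config$patients, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      synth_testing_cohort(seed = seed)$patients
    }
  })
  report <- stage("classify", attainment_report(
    patients,
    grid_atrl = grids[["ATR_ATRL"]],
    grid_met = grids[["ATR_MET"]],
    theta1 = theta1, theta2 = theta2))
  readr::write_csv(report, file.path(out_dir, "adherence_report.csv"))

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "pkadherence",
    version = as.character(utils::packageVersion("pkadherence")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    settings = list(analytes = analytes, n_grid = n_grid,
                    n_per_dose = n_per_dose, doses_mg = doses_mg,
                    theta1 = theta1, theta2 = theta2),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fits = fits, grids = grids, roc = roc_tabs,
                 report = report, manifest = manifest, out_dir = out_dir))
}
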