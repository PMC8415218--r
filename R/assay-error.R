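#' Assay error model
#'
#' Residual-error model combining the LC-MS/MS assay error polynomial with an
#' additive process-noise term. The assay standard deviation is linear in the
#' concentration, `sd = c0 + c1 * conc`, and the total observation SD used in
#' likelihoods and simulation is `lambda + c0 + c1 * conc`, where `lambda`
#' absorbs clinical and preanalytical noise. Observation weights are the
#' reciprocal of the total SD.
#'
#' Built-in coefficient sets exist for the two lumped analytes:
#' `"ATR_ATRL"` (atorvastatin + its lactone, `sd = 8.26e-5 + 3.53e-2 * c`)
#' and `"ATR_MET"` (atorvastatin + all measured metabolites,
#' `sd = 3.86e-5 + 3.32e-2 * c`), both with `lambda = 0.01` nmol/L.
#'
#' @param analyte `"ATR_ATRL"` or `"ATR_MET"`, or `NULL` when supplying
#'   coefficients directly.
#' @param c0 Assay SD intercept, nmol/L.
#' @param c1 Proportional assay SD slope (dimensionless).
#' @param lam Additive process-noise SD, nmol/L.
#' @return An object of class `assay_error`: a list with `analyte`, `c0`,
#'   `c1`, `lam`.
#' @export
#' @examples
#' em <- assay_error("ATR_ATRL")
#' error_sd(em, 1)
#' obs_weight(em, 1)
assay_error <- function(analyte = c("ATR_ATRL", "ATR_MET"),
                        c0 = NULL, c1 = NULL, lam = 0.01) {
  if (is.null(c0) || is.null(c1)) {
    analyte <- match.arg(analyte)
    coefs <- switch(analyte,
      ATR_ATRL = c(c0 = 8.26e-5, c1 = 3.53e-2),
      ATR_MET  = c(c0 = 3.86e-5, c1 = 3.32e-2)
    )
    c0 <- c0 %||% unname(coefs["c0"])
    c1 <- c1 %||% unname(coefs["c1"])
  } else {
    analyte <- if (is.character(analyte)) analyte[1] else "custom"
  }
  abort_if(c0 < 0 || c1 < 0 || lam < 0,
           "Error-model coefficients must be non-negative.")
  abort_if(lam + c0 <= 0 && c1 <= 0,
           "Total SD must be positive for all concentrations.")
  structure(list(analyte = analyte, c0 = c0, c1 = c1, lam = lam),
            class = "assay_error")
}

#' @rdname assay_error
#' @param em An `assay_error` object.
#' @param conc Concentration(s) in nmol/L, non-negative.
#' @export
error_sd <- function(em, conc) {
  abort_if(any(conc < 0), "`conc` must be non-negative.")
  em$c0 + em$c1 * conc
}

# Total observation SD entering Gaussian likelihoods and simulation noise.
#' @rdname assay_error
#' @export
total_sd <- function(em, conc) {
  abort_if(any(conc < 0), "`conc` must be non-negative.")
  em$lam + em$c0 + em$c1 * conc
}

#' @rdname assay_error
#' @export
obs_weight <- function(em, conc) 1 / total_sd(em, conc)

#' @export
print.assay_error <- function(x, ...) {
  cat(sprintf("<assay_error> %s: sd = %.3g + %.3g * conc, lambda = %.3g\n",
              x$analyte, x$c0, x$c1, x$lam))
  invisible(x)
}
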