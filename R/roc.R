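comparison_groups <- list(
  full_vs_partial = c(more = "adherent", less = "partial"),
  partial_vs_non = c(more = "partial", less = "nonadherent")
)

#' ROC curve for discriminating adherence levels
#'
#' Builds the ROC curve over a fixed grid of dose-normalized cutoff
#' concentrations for one first sampling time. A subject screens positive
#' (reduced adherence) when its concentration falls strictly below the
#' cutoff, so `TPR(c)` is the fraction of the less-adherent group below `c`
#' and `FPR(c)` the fraction of the more-adherent group below `c`;
#' sensitivity is the TPR and specificity `1 - FPR`.
#'
#' @param grid A [simulate_scenarios()] result.
#' @param fst_h First sampling time (must be on the simulated grid).
#' @param comparison `"full_vs_partial"` (adherent vs partial) or
#'   `"partial_vs_non"` (partial vs nonadherent).
#' @param cutoffs Cutoff grid in nmol (mg dose)^-1 L^-1; default 0.002 to 10
#'   in steps of 0.002.
#' @return An `adherence_roc` tibble with columns `cutoff`, `tpr`, `fpr`,
#'   `sensitivity`, `specificity`; the trapezoid AUC, the comparison and the
#'   FST are attached as attributes (see [roc_auc()], [optimal_cutoff()]).
#' @export
roc_curve <- function(grid, fst_h, comparison = c("full_vs_partial",
                                                  "partial_vs_non"),
                      cutoffs = seq(0.002, 10, by = 0.002)) {
  comparison <- match.arg(comparison)
  groups <- comparison_groups[[comparison]]
  rows <- grid$fst_h == fst_h
  abort_if(!any(rows), paste0("FST ", fst_h, " h is not on the grid."))
  less <- grid$conc_norm[rows & grid$scenario == groups["less"]]
  more <- grid$conc_norm[rows & grid$scenario == groups["more"]]
  abort_if(length(less) == 0 || length(more) == 0,
           "Both scenario groups must be present at this FST.")
  count_below <- function(values, c) {
    findInterval(c, sort(values), left.open = TRUE) / length(values)
  }
  out <- tibble::tibble(
    cutoff = cutoffs,
    tpr = count_below(less, cutoffs),
    fpr = count_below(more, cutoffs)
  )
  out$sensitivity <- out$tpr
  out$specificity <- 1 - out$fpr
  structure(out, class = c("adherence_roc", class(out)),
            comparison = comparison, fst_h = fst_h,
            n_less = length(less), n_more = length(more))
}

#' Trapezoid area under an ROC curve
#'
#' Integrates TPR over FPR by the trapezoid rule, anchoring the curve at
#' (0, 0) and (1, 1).
#'
#' @param roc An [roc_curve()] result.
#' @return The AUC, a number in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  abort_if(nrow(roc) < 2, "Need at least two cutoffs.")
  fpr <- c(0, roc$fpr, 1)
  tpr <- c(0, roc$tpr, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Cutoff with the smallest sensitivity-specificity difference
#'
#' Selects the cutoff concentration minimizing `|specificity - sensitivity|`
#' over the ROC grid ("optimal difference"); ties are broken toward the
#' smallest cutoff.
#'
#' @param roc An [roc_curve()] result.
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `difference`.
#' @export
optimal_cutoff <- function(roc) {
  d <- abs(roc$specificity - roc$sensitivity)
  i <- which.min(d)  # which.min returns the first (smallest-cutoff) minimum
  tibble::tibble(cutoff = roc$cutoff[i],
                 sensitivity = roc$sensitivity[i],
                 specificity = roc$specificity[i],
                 difference = d[i])
}

#' Per-FST summary of ROC performance
#'
#' Runs [roc_curve()] at every simulated first sampling time and collects the
#' AUC and the optimal-difference cutoff with its sensitivity and
#' specificity: the tabular analog of plotting estimation performance
#' against sampling time.
#'
#' @inheritParams roc_curve
#' @return A tibble with one row per FST: `fst_h`, `comparison`,
#'   `opt_cutoff`, `sensitivity`, `specificity`, `auc`.
#' @export
roc_summary <- function(grid, comparison = c("full_vs_partial",
                                             "partial_vs_non"),
                        cutoffs = seq(0.002, 10, by = 0.002)) {
  comparison <- match.arg(comparison)
  purrr::map_dfr(sort(unique(grid$fst_h)), function(fst) {
    roc <- roc_curve(grid, fst, comparison, cutoffs)
    opt <- optimal_cutoff(roc)
    tibble::tibble(fst_h = fst, comparison = comparison,
                   opt_cutoff = opt$cutoff,
                   sensitivity = opt$sensitivity,
                   specificity = opt$specificity,
                   auc = roc_auc(roc))
  })
}
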