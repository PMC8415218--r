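#' Observed versus predicted concentrations
#'
#' Per-observation table of population predictions (prior-weighted mean over
#' the support points) and individual posterior predictions (posterior-
#' weighted mean), with the observation weight `1/(lambda + c0 + c1 * conc)`.
#'
#' @param fit An [np_fit()] object.
#' @return A tibble with columns `subject`, `time_h`, `obs`, `pred_pop`,
#'   `pred_post`, `weight`.
#' @export
np_obs_pred <- function(fit) {
  stopifnot(inherits(fit, "np_fit"))
  params <- fit$support
  w <- fit$support$weight
  purrr::imap_dfr(fit$records, function(r, i) {
    pred <- predict_subject(r, params)  # K x n_obs
    tibble::tibble(
      subject = as.character(r$id),
      time_h = r$obs_times,
      obs = r$obs_conc,
      pred_pop = as.vector(crossprod(pred, w)),
      pred_post = as.vector(crossprod(pred, fit$posteriors[i, ])),
      weight = obs_weight(fit$error_model, r$obs_conc)
    )
  })
}

#' Model-evaluation diagnostics for a nonparametric population fit
#'
#' Computes the standard pharmacometric evaluation battery: weighted
#' prediction errors `e = (obs - pred) * weight` from the individual
#' posterior predictions, their mean (MWPE, bias) and mean square (MWSPE), a
#' t-test of the bias against zero, linear regressions of observed versus
#' population and versus posterior predictions, a Shapiro-Wilk test of the
#' weighted residuals, information criteria, and the eta-shrinkage of each
#' random effect (`100 * (1 - SD(posterior means) / SD(population
#' marginal))`).
#'
#' @param fit An [np_fit()] object.
#' @return A one-row tibble. Regressions are skipped (with a warning) when
#'   fewer than three observations are available.
#' @export
np_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "np_fit"))
  op <- np_obs_pred(fit)
  e <- (op$obs - op$pred_post) * op$weight
  mwpe <- mean(e)
  mwspe <- mean(e^2)
  bias_t_p <- if (length(e) >= 2 && stats::sd(e) > 0) {
    stats::t.test(e)$p.value
  } else {
    NA_real_
  }
  norm_p <- if (length(e) >= 3 && stats::sd(e) > 0) {
    stats::shapiro.test(e)$p.value
  } else {
    NA_real_
  }
  reg <- function(pred) {
    if (length(pred) < 3) {
      warning("Fewer than 3 observations; regression skipped.")
      return(c(slope = NA_real_, intercept = NA_real_, r = NA_real_))
    }
    fitlm <- stats::lm(op$obs ~ pred)
    c(slope = unname(stats::coef(fitlm)[2]),
      intercept = unname(stats::coef(fitlm)[1]),
      r = stats::cor(op$obs, pred))
  }
  pop <- reg(op$pred_pop)
  post <- reg(op$pred_post)
  g <- glance(fit)
  shrink <- function(param) {
    sd_pop <- sqrt(weighted_var(fit$support[[param]], fit$support$weight))
    if (sd_pop == 0) return(NA_real_)
    100 * (1 - stats::sd(fit$post_params[[param]]) / sd_pop)
  }
  tibble::tibble(
    mwpe = mwpe, mwspe = mwspe, bias_t_p = bias_t_p,
    resid_normality_p = norm_p,
    slope_pop = unname(pop["slope"]),
    intercept_pop = unname(pop["intercept"]),
    r_pop = unname(pop["r"]),
    slope_post = unname(post["slope"]),
    intercept_post = unname(post["intercept"]),
    r_post = unname(post["r"]),
    aic = g$aic, bic = g$bic, neg2ll = g$neg2ll, n_support = g$n_support,
    shrinkage_ka_pct = shrink("ka"),
    shrinkage_ke_pct = shrink("ke"),
    shrinkage_v_pct = shrink("v")
  )
}

#' Covariate screening against posterior parameter estimates
#'
#' Screens candidate covariates for inclusion in the population model the way
#' sparse-data pharmacometric analyses do: numeric covariates are tested by
#' Pearson correlation with each posterior parameter (flagged when
#' `|r| >= r_threshold`); two-level covariates (e.g. dose group, gender) by
#' Wilcoxon rank-sum with the normal approximation (flagged when
#' `p < p_threshold`). Constant covariates are reported as not screenable.
#'
#' @param fit An [np_fit()] object.
#' @param covariates A data frame with a `subject` column and one column per
#'   covariate. If omitted, covariates carried in the fitted data are used.
#' @param r_threshold Correlation flag threshold (default 0.7).
#' @param p_threshold Rank-sum flag threshold (default 0.010).
#' @return A tibble with one row per (parameter, covariate) pair: the test
#'   used, its statistic (`r` or `p`), and a `flagged` logical.
#' @export
covariate_screen <- function(fit, covariates = NULL, r_threshold = 0.7,
                             p_threshold = 0.010) {
  stopifnot(inherits(fit, "np_fit"))
  post <- fit$post_params
  if (is.null(covariates)) {
    covs <- purrr::map_dfr(fit$records, function(r) {
      tibble::as_tibble(c(list(subject = as.character(r$id)), r$covariates))
    })
  } else {
    covs <- tibble::as_tibble(covariates)
    covs$subject <- as.character(covs$subject)
  }
  abort_if(!"subject" %in% names(covs) || ncol(covs) < 2,
           "No covariates to screen.")
  covs <- dplyr::left_join(post["subject"], covs, by = "subject")
  out <- list()
  for (param in c("ka", "ke", "v")) {
    y <- post[[param]]
    for (cv in setdiff(names(covs), "subject")) {
      x <- covs[[cv]]
      n_lvl <- length(unique(x[!is.na(x)]))
      if (n_lvl < 2) {
        row <- tibble::tibble(parameter = param, covariate = cv,
                              test = "none", statistic = NA_real_,
                              flagged = NA)
      } else if (is.numeric(x) && n_lvl > 2) {
        r <- stats::cor(y, x, use = "complete.obs")
        row <- tibble::tibble(parameter = param, covariate = cv,
                              test = "pearson_r", statistic = r,
                              flagged = is.finite(r) && abs(r) >= r_threshold)
      } else if (n_lvl == 2) {
        grp <- as.factor(x)
        p <- stats::wilcox.test(y ~ grp, exact = FALSE)$p.value
        row <- tibble::tibble(parameter = param, covariate = cv,
                              test = "wilcoxon_p", statistic = p,
                              flagged = is.finite(p) && p < p_threshold)
      } else {
        row <- tibble::tibble(parameter = param, covariate = cv,
                              test = "none", statistic = NA_real_,
                              flagged = NA)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  dplyr::bind_rows(out)
}
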