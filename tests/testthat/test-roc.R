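# Minimal scenario grids built by hand for ROC unit tests.
toy_grid <- function(adherent, partial, nonadherent = NULL, fst = 12) {
  make <- function(vals, sc) {
    tibble::tibble(subject = seq_along(vals), dose_mg = 20, fst_h = fst,
                   scenario = sc, conc_norm = vals)
  }
  out <- dplyr::bind_rows(make(adherent, "adherent"),
                          make(partial, "partial"),
                          if (!is.null(nonadherent)) {
                            make(nonadherent, "nonadherent")
                          })
  structure(out, class = c("scenario_grid", class(out)))
}

test_that("TPR/FPR count strictly-below fractions per group", {
  g <- toy_grid(adherent = c(0.5, 0.7), partial = c(0.1, 0.3))
  roc <- roc_curve(g, 12, "full_vs_partial",
                   cutoffs = c(0.05, 0.2, 0.4, 0.6, 1))
  expect_equal(roc$tpr, c(0, 0.5, 1, 1, 1))
  expect_equal(roc$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(roc$sensitivity, roc$tpr)
  expect_equal(roc$specificity, 1 - roc$fpr)
  # cutoff below/above everything
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$tpr[length(roc$tpr)], 1)
  # strictly-less comparison: a cutoff equal to a value does not count it
  roc2 <- roc_curve(g, 12, "full_vs_partial", cutoffs = c(0.3, 0.300001))
  expect_equal(roc2$tpr, c(0.5, 1))
  # monotone step functions
  full <- roc_curve(g, 12, "full_vs_partial")
  expect_true(all(diff(full$tpr) >= 0))
  expect_true(all(diff(full$fpr) >= 0))
  expect_error(roc_curve(g, 5, "full_vs_partial"), "not on the grid")
  expect_error(roc_curve(g, 12, "partial_vs_non"), "present")
})

test_that("trapezoid AUC matches hand arithmetic and edge cases", {
  sep <- toy_grid(adherent = c(0.5, 0.6, 0.7), partial = c(0.1, 0.2, 0.3))
  expect_equal(roc_auc(roc_curve(sep, 12, "full_vs_partial")), 1)
  set.seed(31)
  same_vals <- rlnorm(20000, 0, 1)
  same <- toy_grid(adherent = same_vals[1:10000],
                   partial = same_vals[10001:20000])
  auc_same <- roc_auc(roc_curve(same, 12, "full_vs_partial"))
  expect_lt(abs(auc_same - 0.5), 0.02)
  # three-point toy, trapezoid sum done by hand:
  # anchors (0,0),(1,1); points (0,.2),(.1,.5),(.4,1)
  # area = .1*(.2+.5)/2 + .3*(.5+1)/2 + .6*(1+1)/2 = .035+.225+.6 = .86
  toy <- tibble::tibble(cutoff = 1:3, tpr = c(0.2, 0.5, 1),
                        fpr = c(0, 0.1, 0.4),
                        sensitivity = c(0.2, 0.5, 1),
                        specificity = 1 - c(0, 0.1, 0.4))
  expect_equal(roc_auc(toy), 0.86)
  expect_error(roc_auc(toy[1, ]), "two cutoffs")
})

test_that("AUC is invariant under monotone transformation of both groups", {
  set.seed(32)
  g <- toy_grid(adherent = rlnorm(500, 0.5), partial = rlnorm(500, -0.5))
  cuts <- seq(0.002, 40, by = 0.002)
  a1 <- roc_auc(roc_curve(g, 12, "full_vs_partial", cutoffs = cuts))
  g2 <- g
  g2$conc_norm <- sqrt(g2$conc_norm)  # strictly monotone, also on cutoffs
  a2 <- roc_auc(roc_curve(g2, 12, "full_vs_partial", cutoffs = sqrt(cuts)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("optimal cutoff minimizes |spec - sens| with smallest-cutoff ties", {
  gap <- toy_grid(adherent = c(0.5, 0.6), partial = c(0.1, 0.2))
  roc <- roc_curve(gap, 12, "full_vs_partial")
  opt <- optimal_cutoff(roc)
  # every cutoff in (0.2, 0.5] gives sens = spec = 1; smallest grid value
  # above 0.2 is 0.202
  expect_equal(opt$cutoff, 0.202)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  set.seed(33)
  same_vals <- rlnorm(2000)
  same <- toy_grid(adherent = same_vals[1:1000], partial = same_vals[1001:2000])
  opt2 <- optimal_cutoff(roc_curve(same, 12, "full_vs_partial",
                                   cutoffs = seq(0.002, 20, by = 0.002)))
  qs <- stats::quantile(same_vals, c(0.25, 0.75))
  expect_gt(opt2$cutoff, qs[1])
  expect_lt(opt2$cutoff, qs[2])
})

test_that("per-FST summary collects cutoff and AUC rows", {
  g <- dplyr::bind_rows(toy_grid(c(0.5, 0.6), c(0.1, 0.2), fst = 2),
                        toy_grid(c(0.4, 0.5), c(0.05, 0.1), fst = 3))
  summ <- roc_summary(g, "full_vs_partial")
  expect_equal(summ$fst_h, c(2, 3))
  expect_equal(summ$auc, c(1, 1))
  expect_true(all(c("opt_cutoff", "sensitivity", "specificity") %in%
                    names(summ)))
})
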