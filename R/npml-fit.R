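#' Default population parameter ranges
#'
#' Box constraints for the three random effects of the one-compartment oral
#' model. Defaults cover the fitted ranges reported for atorvastatin lumped
#' analytes once the apparent volume is rescaled by the fixed bioavailability
#' (`v = 0.125 * V/F`).
#'
#' @param ka,ke,v Length-2 numeric vectors `c(lo, hi)`.
#' @return A named list of ranges.
#' @export
np_ranges <- function(ka = c(0.01, 9), ke = c(0.01, 0.6), v = c(5, 100)) {
  rng <- list(ka = as.numeric(ka), ke = as.numeric(ke), v = as.numeric(v))
  for (nm in names(rng)) {
    abort_if(length(rng[[nm]]) != 2 || rng[[nm]][1] >= rng[[nm]][2] ||
               rng[[nm]][1] <= 0,
             paste0("Invalid range for ", nm, ": need 0 < lo < hi."))
  }
  rng
}

# Seeded log-uniform sample of the parameter box. Rate constants and
# volumes are scale parameters spanning decades, so candidate points are
# drawn uniformly on the log scale to cover the low decades as densely as
# the high ones.
sample_box <- function(ranges, n, seed) {
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rand <- vapply(seq_along(lo),
                 function(j) exp(stats::runif(n, log(lo[j]), log(hi[j]))),
                 numeric(n))
  matrix(rand, ncol = 3L, dimnames = list(NULL, names(lo)))
}

#' Initial support-point grid
#'
#' Seeded log-uniform filling of the parameter box, augmented with the eight
#' box corners when at least eight points are requested. With `n_points = 1`
#' the box midpoint is returned. Identical seeds give identical grids.
#'
#' @param ranges Parameter box from [np_ranges()].
#' @param n_points Number of grid points.
#' @param seed Integer seed.
#' @param f Fixed bioavailability attached to every point.
#' @return A tibble of parameter rows (`ka`, `ke`, `v`, `f`).
#' @export
np_grid_init <- function(ranges = np_ranges(), n_points = 80L, seed = 1L,
                         f = 0.125) {
  abort_if(n_points < 1, "`n_points` must be at least 1.")
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  if (n_points == 1L) {
    mid <- (lo + hi) / 2
    return(pk_params(mid["ka"], mid["ke"], mid["v"], f))
  }
  corners <- as.matrix(expand.grid(ka = ranges$ka, ke = ranges$ke,
                                   v = ranges$v))
  n_rand <- if (n_points >= 8L) n_points - 8L else n_points
  rand <- sample_box(ranges, n_rand, seed)
  pts <- if (n_points >= 8L) rbind(corners, rand) else rand
  pk_params(pts[, "ka"], pts[, "ke"], pts[, "v"], f)
}

#' Per-subject log-likelihood at candidate parameter points
#'
#' Gaussian observation model: each observed concentration is normal around
#' the model prediction with total SD `lambda + c0 + c1 * conc`. By default
#' the SD is evaluated at the observed concentration, matching the published
#' weighting `1/(lambda + C0 + C1 * conc)`; set `sd_on = "predicted"` to
#' evaluate it at the model prediction instead.
#'
#' @param record A parsed subject record (internal; see [split_subjects()]).
#' @param params Candidate parameter tibble (one row per support point).
#' @param em An [assay_error()] model.
#' @param sd_on Where the error SD is evaluated.
#' @return Numeric vector of log-likelihoods, one per parameter row.
#' @keywords internal
subject_loglik <- function(record, params, em, sd_on = c("observed", "predicted")) {
  sd_on <- match.arg(sd_on)
  pred <- predict_subject(record, params)
  obs <- record$obs_conc
  sd <- if (sd_on == "observed") {
    matrix(total_sd(em, obs), nrow = nrow(pred), ncol = length(obs),
           byrow = TRUE)
  } else {
    total_sd(em, pmax(pred, 0))
  }
  ll <- stats::dnorm(matrix(obs, nrow = nrow(pred), ncol = length(obs),
                            byrow = TRUE),
                     mean = pred, sd = sd, log = TRUE)
  ll[!is.finite(ll)] <- -Inf
  rowSums(ll)
}

# Subjects x points log-likelihood matrix.
loglik_matrix <- function(records, params, em, sd_on = "observed") {
  t(vapply(records, subject_loglik, numeric(nrow(params)),
           params = params, em = em, sd_on = sd_on))
}

#' Mixture-weight optimization
#'
#' Maximizes the nonparametric mixture log-likelihood
#' `sum_i log sum_k w_k exp(L_ik)` over the probability simplex using EM
#' multiplicative updates with log-sum-exp stabilization. The objective is
#' non-decreasing at every iteration.
#'
#' @param L Subjects-by-points matrix of log-likelihoods (finite or `-Inf`).
#' @param tol Stop when the objective improves by less than this.
#' @param max_iter Iteration cap.
#' @param w0 Optional starting weights (defaults to uniform).
#' @return A list with `weights`, `objective`, `iterations`, and the
#'   per-iteration objective `trace`.
#' @export
np_optimize_weights <- function(L, tol = 1e-12, max_iter = 20000L, w0 = NULL) {
  L <- as.matrix(L)
  abort_if(ncol(L) < 1, "Need at least one support point.")
  impossible <- !is.finite(logsumexp_rows(L))
  abort_if(any(impossible),
           paste0("Subject(s) ", paste(rownames(L)[impossible] %||%
                    which(impossible), collapse = ", "),
                  " have zero likelihood at every support point."))
  n <- nrow(L); k <- ncol(L)
  if (k == 1L) {
    return(list(weights = 1, objective = sum(L), iterations = 0L,
                trace = sum(L)))
  }
  w <- w0 %||% rep(1 / k, k)
  w <- w / sum(w)
  # row-wise max shift reused across iterations
  m <- apply(L, 1L, max)
  E <- exp(L - m)  # n x k, rows scaled so max is 1
  obj_of <- function(w) sum(m + log(as.vector(E %*% w)))
  obj <- obj_of(w)
  trace <- obj
  for (it in seq_len(max_iter)) {
    denom <- as.vector(E %*% w)
    # responsibilities averaged over subjects
    w_new <- w * as.vector(crossprod(E, 1 / denom)) / n
    w_new <- w_new / sum(w_new)
    obj_new <- obj_of(w_new)
    trace <- c(trace, obj_new)
    if (obj_new < obj - 1e-9) break  # numerical guard; EM is monotone
    w <- w_new
    if (obj_new - obj < tol) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(weights = w, objective = obj, iterations = length(trace) - 1L,
       trace = trace)
}

# One refinement pass: perturb each support point by +/- delta * range in
# each coordinate, clip to the box, drop duplicates.
propose_points <- function(params, ranges, delta) {
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  span <- hi - lo
  base <- as.matrix(params[, c("ka", "ke", "v")])
  props <- list()
  for (j in 1:3) {
    for (s in c(-1, 1)) {
      p <- base
      p[, j] <- pmin(pmax(p[, j] + s * delta * span[j], lo[j]), hi[j])
      props[[length(props) + 1L]] <- p
    }
  }
  all <- do.call(rbind, props)
  all <- all[!duplicated(round(log(all), 10)), , drop = FALSE]
  # drop proposals that coincide with existing points
  key <- function(m) apply(round(log(m), 10), 1, paste, collapse = "|")
  all <- all[!key(all) %in% key(base), , drop = FALSE]
  if (nrow(all) == 0) return(NULL)
  pk_params(all[, "ka"], all[, "ke"], all[, "v"], params$f[1])
}

# Condense a weighted point set: points whose coordinates all lie within
# `radius` (a fraction of each parameter range) of a heavier point are merged
# into it, their weights summed. Keeps the support compact between
# refinement cycles, as adaptive-grid NPML implementations do.
condense_points <- function(params, w, L, ranges, radius) {
  span <- vapply(ranges, function(r) r[2] - r[1], numeric(1))
  base <- as.matrix(params[, c("ka", "ke", "v")])
  ord <- order(-w)
  reps <- integer(0)
  assigned <- integer(length(w))
  for (i in ord) {
    near <- integer(0)
    if (length(reps)) {
      d <- abs(sweep(base[reps, , drop = FALSE], 2L, base[i, ], `-`))
      ok <- d <= matrix(radius * span, nrow = length(reps), ncol = 3L,
                        byrow = TRUE)
      near <- which(rowSums(ok) == 3L)
    }
    if (length(near)) {
      assigned[i] <- reps[near[1L]]
    } else {
      reps <- c(reps, i)
      assigned[i] <- i
    }
  }
  keep <- sort(reps)
  w_new <- vapply(keep, function(r) sum(w[assigned == r]), numeric(1))
  list(params = params[keep, , drop = FALSE],
       w = w_new / sum(w_new),
       L = L[, keep, drop = FALSE])
}

# Lean single-point subject log-likelihood used inside numerical optimizers
# (no tibble construction on the hot path).
point_loglik <- function(record, ka, ke, v, f, em, sd_on) {
  t <- record$obs_times
  pred <- record$c_ini * exp(-ke * pmax(t, 0))
  d <- record$doses
  for (i in seq_len(nrow(d))) {
    pred <- pred + bateman(ka, ke, v, f, mg_to_nmol(d$amount_mg[i]),
                           t - d$time_h[i])
  }
  obs <- record$obs_conc
  sd <- if (sd_on == "observed") {
    total_sd(em, obs)
  } else {
    total_sd(em, pmax(pred, 0))
  }
  sum(stats::dnorm(obs, pred, sd, log = TRUE))
}

# EM location M-step: move each support point to (locally) maximize its
# responsibility-weighted log-likelihood over the subjects it serves.
# Returns improved candidate locations to be screened with the other
# proposals; together with the weight EM this is a generalized EM on the
# full mixture, and it homes support points in on the per-subject optima
# that flat likelihood ridges (e.g. in ka) would otherwise leave arbitrary.
mstep_proposals <- function(params, L, w, records, em, sd_on, ranges,
                            w_min = 1e-3, r_min = 0.05, maxit = 60L) {
  post <- posterior_matrix(L, w)
  lo <- log(vapply(ranges, `[`, numeric(1), 1L))
  hi <- log(vapply(ranges, `[`, numeric(1), 2L))
  idx <- which(w > w_min)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    k <- idx[j]
    subs <- which(post[, k] > r_min)
    if (!length(subs)) next
    r <- post[subs, k]
    qfun <- function(lth) {
      lth <- pmin(pmax(lth, lo), hi)
      th <- exp(lth)
      val <- 0
      for (ii in seq_along(subs)) {
        val <- val + r[ii] * point_loglik(records[[subs[ii]]], th[1], th[2],
                                          th[3], params$f[1], em, sd_on)
      }
      val
    }
    start <- log(as.numeric(params[k, c("ka", "ke", "v")]))
    o <- stats::optim(start, qfun, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = maxit))
    th <- exp(pmin(pmax(o$par, lo), hi))
    out[[j]] <- th
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  pk_params(m[, 1], m[, 2], m[, 3], params$f[1])
}

# Per-subject polish: a short Nelder-Mead maximization of each subject's own
# log-likelihood, started from the subject's current best support point.
# The resulting candidates let the adaptive grid reach the near-interpolating
# structure of the NPML optimum quickly when the data are rich enough to
# support one point per subject.
subject_polish <- function(params, L, w, records, em, sd_on, ranges,
                           maxit = 50L) {
  post <- posterior_matrix(L, w)
  lo <- log(vapply(ranges, `[`, numeric(1), 1L))
  hi <- log(vapply(ranges, `[`, numeric(1), 2L))
  out <- matrix(NA_real_, length(records), 3L)
  for (i in seq_along(records)) {
    k0 <- which.max(post[i, ])
    start <- log(as.numeric(params[k0, c("ka", "ke", "v")]))
    nll <- function(lth) {
      lth <- pmin(pmax(lth, lo), hi)
      th <- exp(lth)
      -point_loglik(records[[i]], th[1], th[2], th[3], params$f[1], em,
                    sd_on)
    }
    o <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit))
    o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit))
    out[i, ] <- exp(pmin(pmax(o$par, lo), hi))
  }
  out <- out[!duplicated(round(out, 8)), , drop = FALSE]
  pk_params(out[, 1], out[, 2], out[, 3], params$f[1])
}

# Guarded sparsification: EM leaves dominated support points with small but
# nonzero weights; drop points far below the heaviest, re-run EM, and keep
# the reduced set only when the objective does not decrease.
sparsify_support <- function(params, L, w, obj, em_tol, em_max_iter,
                             eps = 1e-6, passes = 3L) {
  for (pass in seq_len(passes)) {
    keep <- w > eps * max(w)
    if (all(keep)) break
    w2 <- w[keep] / sum(w[keep])
    opt <- np_optimize_weights(L[, keep, drop = FALSE], tol = em_tol,
                               max_iter = em_max_iter, w0 = w2)
    if (opt$objective < obj) break
    params <- params[keep, , drop = FALSE]
    L <- L[, keep, drop = FALSE]
    w <- opt$weights
    obj <- opt$objective
  }
  list(params = params, L = L, w = w, obj = obj)
}

#' Fit a nonparametric population pharmacokinetic model
#'
#' Estimates the nonparametric maximum-likelihood (NPML) population
#' distribution of `(ka, ke, v)` as a discrete set of support points with
#' probability weights, using an adaptive-grid scheme: a seeded initial grid
#' is iteratively reweighted by EM, pruned of negligible-weight points, and
#' refined by local perturbation of the surviving points with a step that
#' halves whenever a cycle fails to improve the log-likelihood. Convergence
#' is declared when a full cycle at the smallest step improves the objective
#' by less than `tol`.
#'
#' @param data Long-format subject data (see [read_subjects()]).
#' @param analyte Which analyte's observations to fit.
#' @param ranges Parameter box, from [np_ranges()].
#' @param error_model An [assay_error()] model; defaults to the built-in
#'   coefficients for `analyte`.
#' @param n_grid Initial grid size.
#' @param seed Integer seed for grid initialization.
#' @param tol Objective-gain convergence criterion (default 1e-4).
#' @param max_cycles Cycle cap (default 5000).
#' @param prune_tol Weight threshold below which points are dropped,
#'   as a fraction of total weight.
#' @param delta0 Initial refinement step as a fraction of each range.
#' @param delta_floor Smallest refinement step fraction.
#' @param f Fixed oral bioavailability.
#' @param sd_on Whether the likelihood SD is evaluated at the observed or
#'   the predicted concentration.
#' @param em_tol,em_max_iter Effort of the inner EM weight optimization run
#'   within each adaptive cycle; a final high-precision EM pass polishes the
#'   weights after convergence.
#' @param n_explore Size of the fresh log-uniform candidate batch screened
#'   each cycle by the mixture directional derivative (gradient) before
#'   being admitted to the support. The NPML objective is convex in the
#'   mixing distribution, so gradient-screened global candidates steer the
#'   adaptive grid toward the global optimum instead of a local basin.
#' @param d_tol Directional-derivative threshold: candidates whose gradient
#'   exceeds `d_tol` can still improve the fit, so convergence additionally
#'   requires the best scanned candidate to fall below it.
#' @param verbose Print cycle progress.
#' @return An object of class `np_fit` with the support distribution,
#'   log-likelihood trace, per-subject posteriors, and inputs needed by
#'   downstream diagnostics and simulation. Use [tidy()] for the support
#'   points, [glance()] for fit statistics, [np_posterior()] for individual
#'   parameter estimates, and [np_diagnostics()] for model evaluation.
#' @export
np_fit <- function(data, analyte = c("ATR_ATRL", "ATR_MET"),
                   ranges = np_ranges(),
                   error_model = NULL,
                   n_grid = 300L, seed = 1L,
                   tol = 1e-4, max_cycles = 5000L,
                   prune_tol = 1e-8, delta0 = 0.1, delta_floor = 1e-4,
                   f = 0.125, sd_on = c("observed", "predicted"),
                   em_tol = 1e-8, em_max_iter = 1000L,
                   n_explore = 500L, d_tol = 0.01,
                   verbose = FALSE) {
  analyte <- match.arg(analyte)
  sd_on <- match.arg(sd_on)
  em <- error_model %||% assay_error(analyte)
  records <- split_subjects(data, analyte = analyte)
  abort_if(length(records) < 1, "No subjects to fit.")

  params <- np_grid_init(ranges, n_points = n_grid, seed = seed, f = f)
  L <- loglik_matrix(records, params, em, sd_on)
  rownames(L) <- vapply(records, function(r) as.character(r$id), character(1))

  delta <- delta0
  opt <- np_optimize_weights(L, tol = em_tol, max_iter = em_max_iter)
  sp <- sparsify_support(params, L, opt$weights, opt$objective,
                         em_tol, em_max_iter)
  params <- sp$params; L <- sp$L; w <- sp$w; obj <- sp$obj
  trace <- list(tibble::tibble(cycle = 0L, loglik = obj,
                               n_support = ncol(L), delta = delta))
  converged <- FALSE
  stall <- 0L
  cycle <- 0L
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    snapshot <- list(params = params, L = L, w = w)
    # prune negligible weights (always keep the heaviest point)
    keep <- w > prune_tol
    keep[which.max(w)] <- TRUE
    params <- params[keep, , drop = FALSE]
    L <- L[, keep, drop = FALSE]
    w <- w[keep] / sum(w[keep])
    # condense clusters within the current refinement step so that
    # reweighted proposal neighborhoods collapse onto their heaviest member
    cd <- condense_points(params, w, L, ranges, radius = 1.01 * delta)
    params <- cd$params; L <- cd$L; w <- cd$w

    # candidates: local perturbations of the surviving points plus a fresh
    # global log-uniform batch, screened by the directional derivative
    # D(theta) = sum_i f_i(theta)/mix_i - n of the mixture likelihood; only
    # candidates that can increase the (convex) objective are admitted
    props <- propose_points(params, ranges, delta)
    glob <- sample_box(ranges, n_explore, seed = seed + 7L * cycle)
    glob <- pk_params(glob[, "ka"], glob[, "ke"], glob[, "v"], f)
    mstep <- if (cycle %% 3L == 0L) {
      mstep_proposals(params, L, w, records, em, sd_on, ranges,
                      w_min = 5e-3, maxit = 40L)
    } else {
      NULL
    }
    pol <- subject_polish(params, L, w, records, em, sd_on, ranges)
    cand <- dplyr::bind_rows(props, glob, mstep, pol)
    Lc <- loglik_matrix(records, cand, em, sd_on)
    logmix <- logsumexp_rows(sweep(L, 2L, log(w), `+`))
    d_score <- colSums(exp(Lc - logmix)) - length(records)
    max_d <- max(d_score)
    admit <- which(d_score > 0)
    if (length(admit) > 40L) {
      admit <- admit[order(-d_score[admit])[1:40]]
    }
    if (length(admit)) {
      L_cand <- cbind(L, Lc[, admit, drop = FALSE])
      w_cand <- c(0.8 * w, rep(0.2 / length(admit), length(admit)))
      opt <- np_optimize_weights(L_cand, tol = em_tol,
                                 max_iter = em_max_iter, w0 = w_cand)
    } else {
      opt <- np_optimize_weights(L, tol = em_tol, max_iter = em_max_iter,
                                 w0 = w)
    }
    # the whole prune-condense-admit move is reverted if it fails to
    # improve, so the recorded objective never decreases
    if (opt$objective >= obj) {
      if (length(admit)) {
        params <- rbind(params, cand[admit, , drop = FALSE])
        L <- L_cand
      }
      sp <- sparsify_support(params, L, opt$weights, opt$objective,
                             em_tol, em_max_iter)
      params <- sp$params; L <- sp$L
      w <- sp$w
      obj_new <- sp$obj
    } else {
      params <- snapshot$params
      L <- snapshot$L
      w <- snapshot$w
      obj_new <- obj
    }
    gain <- obj_new - obj
    obj <- obj_new
    trace[[length(trace) + 1L]] <- tibble::tibble(
      cycle = cycle, loglik = obj, n_support = sum(w > prune_tol),
      delta = delta, max_d = max_d)
    if (verbose) {
      message(sprintf(
        "cycle %d: loglik %.6f, %d support, delta %.2g, max D %.3g",
        cycle, obj, sum(w > prune_tol), delta, max_d))
    }
    # coarse-to-fine: contract the refinement step as soon as gains at the
    # current resolution become small; declare convergence only at the floor
    # resolution, when the objective gain falls below `tol` and either no
    # scanned candidate has a positive-enough gradient or the fit has
    # stalled for several consecutive cycles
    if (delta > delta_floor) {
      if (gain < max(tol, 0.02)) delta <- max(delta / 2, delta_floor)
    } else {
      stall <- if (gain < tol) stall + 1L else 0L
      if (gain < tol && (max_d < d_tol || stall >= 5L)) {
        converged <- TRUE
        break
      }
    }
  }

  # final high-precision weight polish, then prune and posteriors
  opt <- np_optimize_weights(L, tol = 1e-12, max_iter = 50000L, w0 = w)
  if (opt$objective >= obj) {
    w <- opt$weights
    obj <- opt$objective
  }
  trace <- dplyr::bind_rows(trace)
  keep <- w > prune_tol
  keep[which.max(w)] <- TRUE
  params <- params[keep, , drop = FALSE]
  L <- L[, keep, drop = FALSE]
  w <- w[keep] / sum(w[keep])
  # reporting condensation: merge points within 0.5% of each range, so that
  # clusters of numerically distinct but scientifically identical points
  # appear as single support points
  cd <- condense_points(params, w, L, ranges, radius = 0.005)
  params <- cd$params; L <- cd$L; w <- cd$w
  ord <- order(-w)
  params <- params[ord, , drop = FALSE]
  L <- L[, ord, drop = FALSE]
  w <- w[ord]

  support <- dplyr::mutate(params, weight = w)
  post <- posterior_matrix(L, w)
  post_params <- tibble::tibble(
    subject = vapply(records, function(r) as.character(r$id), character(1)),
    ka = as.vector(post %*% params$ka),
    ke = as.vector(post %*% params$ke),
    v = as.vector(post %*% params$v)
  )

  fit <- structure(list(
    support = support,
    loglik = obj,
    n_cycles = cycle,
    converged = converged,
    trace = trace,
    posteriors = post,
    post_params = post_params,
    records = records,
    error_model = em,
    analyte = analyte,
    ranges = ranges,
    f = f,
    sd_on = sd_on,
    n_obs = sum(vapply(records, function(r) length(r$obs_times), integer(1))),
    seed = seed,
    config = list(n_grid = n_grid, tol = tol, max_cycles = max_cycles,
                  prune_tol = prune_tol, n_explore = n_explore,
                  d_tol = d_tol, delta0 = delta0,
                  delta_floor = delta_floor)
  ), class = "np_fit")
  fit
}

# Posterior membership probabilities p_ik proportional to w_k exp(L_ik).
posterior_matrix <- function(L, w) {
  logp <- sweep(L, 2L, log(w), `+`)
  m <- apply(logp, 1L, max)
  abort_if(any(!is.finite(m)), "A subject has zero posterior mass everywhere.")
  p <- exp(logp - m)
  p / rowSums(p)
}

#' Individual Bayesian posterior parameter estimates
#'
#' Posterior weights over the fitted support points for each subject
#' (`p_k` proportional to `w_k * exp(L_k)`), and the posterior-mean
#' parameters.
#'
#' @param fit An [np_fit()] object.
#' @return A tibble with one row per subject: posterior-mean `ka`, `ke`, `v`.
#'   The full subject-by-point posterior matrix is in `fit$posteriors`.
#' @export
np_posterior <- function(fit) {
  stopifnot(inherits(fit, "np_fit"))
  fit$post_params
}

#' @export
print.np_fit <- function(x, ...) {
  cat(sprintf(
    "<np_fit> %s: %d subjects, %d observations\n", x$analyte,
    length(x$records), x$n_obs))
  cat(sprintf("  log-likelihood %.4f after %d cycles (%s)\n", x$loglik,
              x$n_cycles, if (x$converged) "converged" else "not converged"))
  cat(sprintf("  %d support points; weighted medians: ka %.3g, ke %.3g, v %.3g\n",
              nrow(x$support),
              weighted_median(x$support$ka, x$support$weight),
              weighted_median(x$support$ke, x$support$weight),
              weighted_median(x$support$v, x$support$weight)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the support distribution of a nonparametric population fit
#'
#' @param x An [np_fit()] object.
#' @param ... Unused.
#' @return A tibble of support points (`ka`, `ke`, `v`, `f`, `weight`),
#'   heaviest first, with the apparent oral volume `v_over_f` added.
#' @method tidy np_fit
#' @export
tidy.np_fit <- function(x, ...) {
  dplyr::mutate(x$support, v_over_f = .data$v / .data$f)
}

#' One-row summary of a nonparametric population fit
#'
#' @param x An [np_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble: support count, log-likelihood, `-2LL`, AIC and
#'   BIC (parameter count `4K - 1`: three coordinates per point plus `K - 1`
#'   free weights), cycles, and convergence flag.
#' @method glance np_fit
#' @export
glance.np_fit <- function(x, ...) {
  k <- nrow(x$support)
  p <- 4 * k - 1
  tibble::tibble(
    n_subjects = length(x$records),
    n_obs = x$n_obs,
    n_support = k,
    loglik = x$loglik,
    neg2ll = -2 * x$loglik,
    aic = -2 * x$loglik + 2 * p,
    bic = -2 * x$loglik + p * log(x$n_obs),
    n_cycles = x$n_cycles,
    converged = x$converged
  )
}
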