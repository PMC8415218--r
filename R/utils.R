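# Internal numeric helpers.

# log(sum(exp(x))) along rows of a matrix, guarding -Inf rows.
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

#' Weighted median
#'
#' Lower weighted median: the smallest value whose cumulative weight reaches
#' one half. Used to summarize discrete population parameter distributions.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (recycled to `length(x)` if scalar).
#' @return A single numeric value.
#' @export
#' @examples
#' weighted_median(c(1, 2, 3), c(0.2, 0.5, 0.3))
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= 0.5)[1L]]
}

# Weighted variance of a discrete distribution (population form).
weighted_var <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sum(w * (x - mu)^2)
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
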