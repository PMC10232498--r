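#' Probability and transform utilities
#'
#' Small helpers shared across the decoding and linking stages: the logit and
#' its inverse, probability clipping, the multinomial-logit transform, and
#' Fisher's z.
#'
#' @param p numeric vector of probabilities.
#' @return `logit()` and `inv_logit()` return numeric vectors.
#' @examples
#' logit(0.5)          # 0
#' inv_logit(logit(.2))
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @param x numeric vector on the logit scale.
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Clip classifier probabilities away from 0 and 1
#'
#' Class probabilities are constrained to `[lo, hi]` (default
#' `[0.00001, 0.99999]`) so that subsequent logit-scale modelling is finite.
#' Clipping is applied after any renormalisation and clipped vectors are not
#' renormalised again, so sums may deviate from 1 by at most a few 1e-5.
#'
#' @param p numeric vector or matrix of probabilities.
#' @param lo,hi clip bounds.
#' @return object like `p` with entries forced into `[lo, hi]`.
#' @export
clip_probs <- function(p, lo = 1e-5, hi = 1 - 1e-5) {
  pmin(pmax(p, lo), hi)
}

#' Multinomial-logit transform of class probabilities
#'
#' For class c the transform is the mean log-odds of c against every other
#' class: `mlogit(P_c) = mean_j( log(P_c / P_j) )` over `j != c`. For the
#' uniform distribution every class maps to 0.
#'
#' @param p numeric matrix (rows = observations, columns = classes) or a
#'   single probability vector.
#' @return matrix (or vector) of the same shape on the unbounded scale.
#' @examples
#' mlogit_probs(c(0.5, 0.25, 0.25))[1]  # log(2)
#' @export
mlogit_probs <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  k <- ncol(p)
  lp <- log(p)
  out <- lp - (rowSums(lp) - lp) / (k - 1)
  if (nrow(out) == 1L) drop(out) else out
}

#' Fisher z-transform of a correlation
#' @param r correlation(s) in (-1, 1).
#' @return `atanh(r)`, i.e. `0.5 * log((1 + r) / (1 - r))`.
#' @export
fisher_z <- function(r) atanh(r)

# z-score a numeric vector; constant vectors map to 0 rather than NaN.
zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Deterministic sub-seed derivation, kept below 2^31.
subseed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + 104729 * stage) %% 2147483629L)
}

#' Truncated exponential sampler with a stated mean
#'
#' Samples from an exponential distribution restricted to `[lo, hi]` by
#' inverse-CDF sampling, with the rate chosen numerically so that the
#' truncated mean equals `mean`. Feasible means lie strictly between `lo`
#' and `(lo + hi) / 2` (the mean of the flat limiting case).
#'
#' @param n number of draws.
#' @param mean target mean of the truncated distribution.
#' @param lo,hi truncation bounds.
#' @return numeric vector of draws in `[lo, hi]`.
#' @export
rtrunc_exp <- function(n, mean, lo, hi) {
  rate <- texp_rate(mean, lo, hi)
  u <- stats::runif(n)
  # inverse CDF of exp(rate) truncated to [lo, hi]
  lo + (-log(1 - u * (1 - exp(-rate * (hi - lo))))) / rate
}

# mean of exp(rate) truncated to [lo, hi]
texp_mean <- function(rate, lo, hi) {
  w <- hi - lo
  lo + 1 / rate - w * exp(-rate * w) / (1 - exp(-rate * w))
}

texp_rate <- function(mean, lo, hi) {
  stopifnot(mean > lo, mean < (lo + hi) / 2)
  stats::uniroot(function(r) texp_mean(r, lo, hi) - mean,
                 lower = 1e-6, upper = 1e3, tol = 1e-12)$root
}
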