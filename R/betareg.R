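# Maximum-likelihood beta regression with a logit mean link and a constant
# precision parameter phi (log link). Classifier probabilities live on (0,1)
# and are modelled directly on that scale; no beta-family GLM engine is
# available in the dependency stack, so the likelihood is maximized here
# with analytic gradients (BFGS). Subject effects enter as fixed intercepts.

betareg_nll <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- inv_logit(eta)
  phi <- exp(par[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

betareg_grad <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- inv_logit(eta)
  phi <- exp(par[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(a) - digamma(b)
  dldeta <- phi * (ystar - mustar) * mu * (1 - mu)
  gbeta <- -drop(crossprod(X, dldeta))
  dldphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * log(y) + (1 - mu) * log1p(-y)
  c(gbeta, -sum(dldphi) * phi)
}

#' Beta regression by maximum likelihood
#'
#' Fits `y ~ Beta(mu * phi, (1 - mu) * phi)` with `logit(mu) = X beta` and a
#' common precision `phi`. Used for modelling clipped classifier
#' probabilities; likelihood-ratio tests between nested fits use
#' [stats::logLik()] / [stats::AIC()] as usual.
#'
#' @param formula model formula.
#' @param data data.frame; the response must lie strictly in (0, 1).
#' @return object of class `cv_betareg` with `coefficients`, `phi`,
#'   `logLik`, `df`, `fitted`, `converged`.
#' @export
betareg_ml <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y <= 0 | y >= 1)) stop("response must lie strictly in (0, 1)")
  X <- stats::model.matrix(formula, mf)
  keep <- !duplicated(colnames(X)) & c(TRUE, colSums(abs(X[, -1, drop = FALSE])) > 0)
  X <- X[, keep, drop = FALSE]
  # drop aliased columns
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  ly <- log(y / (1 - y))
  beta0 <- tryCatch(stats::lm.fit(X, ly)$coefficients, error = function(e) rep(0, ncol(X)))
  beta0[is.na(beta0)] <- 0
  mu0 <- inv_logit(drop(X %*% beta0))
  v <- stats::var(y - mu0)
  phi0 <- max(1, min(1e4, mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1))
  par0 <- c(beta0, log(phi0))
  opt <- stats::optim(par0, betareg_nll, betareg_grad, X = X, y = y,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  p <- ncol(X)
  structure(list(coefficients = stats::setNames(opt$par[seq_len(p)], colnames(X)),
                 phi = exp(opt$par[p + 1]),
                 logLik = -opt$value, df = p + 1L,
                 nobs = length(y),
                 fitted = inv_logit(drop(X %*% opt$par[seq_len(p)])),
                 converged = opt$convergence == 0,
                 formula = formula),
            class = "cv_betareg")
}

#' @export
logLik.cv_betareg <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
coef.cv_betareg <- function(object, ...) object$coefficients

#' @export
print.cv_betareg <- function(x, ...) {
  cat("Beta regression (logit link), phi =", signif(x$phi, 4),
      ", logLik =", signif(x$logLik, 6), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

# Wald standard errors via numerical Hessian (only computed on demand)
betareg_se <- function(object, data) {
  X <- stats::model.matrix(object$formula, stats::model.frame(object$formula, data))
  X <- X[, names(object$coefficients), drop = FALSE]
  y <- stats::model.response(stats::model.frame(object$formula, data))
  par <- c(object$coefficients, log(object$phi))
  H <- stats::optimHess(par, betareg_nll, betareg_grad, X = X, y = y)
  se <- sqrt(diag(solve(H)))
  stats::setNames(se[seq_along(object$coefficients)], names(object$coefficients))
}
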