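# Synthetic per-trial multivoxel patterns for a single value-sensitive ROI.
#
# A trial's pattern mixes three codes: a graded value code for the relevant
# expected value u_rel(EV), a graded value code for the background expected
# value u_back(EV_back) (2D trials only), and a binary context code c(ctx),
# plus heteroscedastic, spatially correlated voxel noise. Value codes of
# nearby reward levels are more similar (corr rho^(|dv|/20)); relevant and
# background channels overlap by omega. Competition: the background gain
# suppresses the relevant gain with strength lambda, and a strong trial-wise
# context signal attenuates that suppression with strength m:
#
#   g_EV = max(0, a_EV - lambda * exp(-m * g_ctx) * g_back)

#' Construct value, background and context codebooks
#'
#' Value codes are unit-norm voxel vectors with exact pairwise inner products
#' `rho^(|dv|/20)` over levels 30/50/70. The background codebook equals
#' `omega * u_rel + sqrt(1-omega^2) * w` with `w` an independent codebook of
#' the same internal structure, so channel overlap is `omega` (1 duplicates
#' the relevant codebook). Two unit-norm context codes are exactly
#' orthogonal to all value codes and to each other.
#'
#' @param n_voxels number of voxels (>= 8).
#' @param rho similarity of adjacent value levels, in [0, 1).
#' @param omega overlap between relevant and background channels, in [0, 1].
#' @param seed integer seed.
#' @return object of class `cv_codebook` with matrices `u_rel`, `u_back`
#'   (voxels x 3, columns "30","50","70") and `ctx` (voxels x 2, columns
#'   "color","motion").
#' @export
make_codebook <- function(n_voxels, rho = 0.5, omega = 0.7, seed = 1L) {
  if (n_voxels < 8L) stop("infeasible: need at least 8 voxels for 8 codes")
  stopifnot(rho >= 0, rho < 1, omega >= 0, omega <= 1)
  set.seed(subseed(seed, 6L))
  levels <- c(30, 50, 70)
  C <- outer(levels, levels, function(a, b) rho^(abs(a - b) / 20))
  L <- chol(C)  # C = t(L) %*% L
  Z <- matrix(stats::rnorm(n_voxels * 8L), n_voxels, 8L)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))  # orthonormal columns
  u_rel <- Q[, 1:3] %*% L
  w <- Q[, 4:6] %*% L
  u_back <- omega * u_rel + sqrt(1 - omega^2) * w
  ctx <- Q[, 7:8]
  colnames(u_rel) <- colnames(u_back) <- as.character(levels)
  colnames(ctx) <- c("color", "motion")
  structure(list(u_rel = u_rel, u_back = u_back, ctx = ctx,
                 rho = rho, omega = omega, n_voxels = n_voxels),
            class = "cv_codebook")
}

#' Parameters of the pattern generative model
#'
#' @param a_ev,a_back,a_ctx signal amplitudes (>= 0) of the relevant value,
#'   background value and context codes.
#' @param lambda competition strength: background gain suppresses the
#'   relevant gain (>= 0).
#' @param m moderation strength: the trial-wise context gain attenuates the
#'   competition (>= 0).
#' @param s_back linear increase of background gain with EV_back level
#'   (per 20 points, relative).
#' @param ctx_gain_sd log-scale SD of the trial-wise (log-normal) context gain.
#' @param noise_sd median voxel noise SD; per-voxel SDs are log-normal around
#'   it (heteroscedastic by construction).
#' @param noise_sdlog log-scale SD of the voxel noise SDs.
#' @param noise_ar spatial AR(1) correlation between neighbouring voxels.
#' @param n_voxels,n_runs ROI size and number of runs.
#' @return list of class `cv_neural_params`.
#' @export
neural_params <- function(a_ev = 1, a_back = 1.0, a_ctx = 1.5, lambda = 2.0,
                          m = 1.2, s_back = 0.8, ctx_gain_sd = 0.8,
                          noise_sd = 0.5, noise_sdlog = 0.3, noise_ar = 0.3,
                          n_voxels = 200L, n_runs = 4L) {
  p <- as.list(environment())
  if (any(c(p$a_ev, p$a_back, p$a_ctx, p$lambda, p$m) < 0))
    stop("amplitude, competition and moderation parameters must be >= 0")
  stopifnot(p$noise_sd > 0, p$n_runs >= 2)
  structure(p, class = "cv_neural_params")
}

#' @rdname neural_params
#' @details `null_neural_params()` zeroes every signal amplitude and
#'   mechanism, leaving pure noise patterns (the end-to-end negative
#'   control).
#' @param ... overrides passed to `neural_params()`.
#' @export
null_neural_params <- function(...) {
  neural_params(a_ev = 0, a_back = 0, a_ctx = 0, lambda = 0, m = 0,
                s_back = 0, ...)
}

# AR(1) spatially correlated, heteroscedastic noise matrix (n x v)
noise_matrix <- function(n, sds, ar) {
  v <- length(sds)
  z <- matrix(stats::rnorm(n * v), n, v)
  if (ar > 0) {
    for (j in 2:v) z[, j] <- ar * z[, j - 1] + sqrt(1 - ar^2) * z[, j]
  }
  sweep(z, 2, sds, `*`)
}

#' Simulate per-trial voxel patterns for one subject
#'
#' For every run (block) of the design, builds a trials x voxels response
#' matrix from the codebook and the competition model, plus a matched
#' residual matrix drawn from the same heteroscedastic noise model
#' (de-meaned per voxel). The per-trial ground-truth gains are exported so
#' every planted quantity can be recomputed without re-simulation.
#'
#' @param design `cv_design`.
#' @param behavior one subject's rows of a `cv_behavior` table (used for the
#'   accuracy labels carried on the pattern rows); may be NULL, in which case
#'   all trials count as accurate.
#' @param codebook `cv_codebook`.
#' @param params `cv_neural_params`.
#' @param seed integer seed.
#' @return object of class `cv_patterns`: list of runs, each with `X`
#'   (trials x voxels), `residuals`, and `labels` (EV, EV_back, context, dim,
#'   accuracy, gains).
#' @export
simulate_patterns <- function(design, behavior = NULL, codebook, params,
                              seed) {
  stopifnot(inherits(design, "cv_design"), inherits(codebook, "cv_codebook"),
            inherits(params, "cv_neural_params"))
  if (codebook$n_voxels != params$n_voxels)
    stop("codebook and params disagree on n_voxels")
  set.seed(subseed(seed, 7L))
  tr <- design$trials
  if (!is.null(behavior)) {
    stopifnot(nrow(behavior) == nrow(tr))
    acc <- behavior$accuracy
    acc[is.na(acc)] <- 0L
  } else acc <- rep(1L, nrow(tr))
  sds <- params$noise_sd * stats::rlnorm(params$n_voxels, 0, params$noise_sdlog)
  runs <- list()
  for (b in sort(unique(tr$block))) {
    i <- which(tr$block == b)
    tb <- tr[i, ]
    n <- nrow(tb)
    g_ctx <- params$a_ctx *
      stats::rlnorm(n, -params$ctx_gain_sd^2 / 2, params$ctx_gain_sd)
    is2d <- tb$dim == "2D"
    g_back <- ifelse(is2d,
                     params$a_back * (1 + params$s_back * (tb$EV_back - 50) / 20),
                     0)
    g_back <- pmax(g_back, 0)
    g_ev <- pmax(0, params$a_ev - params$lambda * exp(-params$m * g_ctx) * g_back)
    X <- matrix(0, n, params$n_voxels)
    X <- X + g_ctx * t(codebook$ctx[, tb$context])
    X <- X + g_ev * t(codebook$u_rel[, as.character(tb$EV)])
    bk <- matrix(0, n, params$n_voxels)
    if (any(is2d))
      bk[is2d, ] <- g_back[is2d] *
        t(codebook$u_back[, as.character(tb$EV_back[is2d])])
    X <- X + bk + noise_matrix(n, sds, params$noise_ar)
    res <- noise_matrix(n, sds, params$noise_ar)
    res <- sweep(res, 2, colMeans(res))
    labels <- data.frame(gtrial = tb$gtrial, block = b, trial = tb$trial,
                         EV = tb$EV, EV_back = tb$EV_back,
                         context = tb$context, dim = tb$dim,
                         target_side = tb$target_side,
                         accuracy = acc[i],
                         g_ctx = g_ctx, g_back = g_back, g_ev = g_ev)
    runs[[length(runs) + 1L]] <- list(run = b, X = X, residuals = res,
                                      labels = labels)
  }
  structure(list(runs = runs, params = params, voxel_sds = sds,
                 seed = as.integer(seed)), class = "cv_patterns")
}

#' @export
print.cv_patterns <- function(x, ...) {
  cat("Simulated patterns:", length(x$runs), "runs x",
      nrow(x$runs[[1]]$X), "trials x", ncol(x$runs[[1]]$X), "voxels\n")
  invisible(x)
}

#' Ground-truth gain table of simulated patterns
#'
#' @param patterns `cv_patterns`.
#' @return data.frame with one row per trial: labels plus the planted gains
#'   `g_ctx`, `g_back`, `g_ev` and the suppression `a_ev - g_ev`.
#' @export
ground_truth <- function(patterns) {
  gt <- do.call(rbind, lapply(patterns$runs, `[[`, "labels"))
  gt$suppression <- patterns$params$a_ev - gt$g_ev
  gt
}
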