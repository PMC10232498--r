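# Cross-run representational similarity analysis over the 9 (EV x EV_back)
# conditions of 2D trials. Condition-mean patterns are noise-normalized with
# the run's residuals (per-voxel SD by default, or shrinkage-covariance
# whitening, after which Euclidean distances are Mahalanobis distances),
# mean-pattern subtracted, and compared across runs only, which keeps the
# diagonal unbiased: the 9x9 matrix holds the mean distance between each
# condition pair taken from different runs.

rdm_condition_label <- function(ev, evback) paste0(ev, "_", evback)

#' Condition-mean patterns with multivariate noise normalization
#'
#' Per run, averages the patterns of behaviourally accurate 2D trials within
#' each (EV, EV_back) condition, normalizes voxels using the run's residual
#' matrix -- dividing each voxel by its residual SD (`mode = "diagonal"`) or
#' whitening with a Ledoit-Wolf shrinkage-regularized residual covariance
#' (`mode = "shrinkage"`) -- and subtracts the across-condition mean pattern.
#' Conditions with no accurate trial in a run are flagged missing.
#'
#' @param patterns `cv_patterns`.
#' @param mode `"diagonal"` or `"shrinkage"`.
#' @return list of class `cv_condition_patterns`: per run a 9 x voxels
#'   matrix `M` (rows are conditions, NA rows for missing conditions),
#'   `n_trials` per condition, and the shared condition `labels`.
#' @export
prepare_condition_patterns <- function(patterns, mode = c("diagonal", "shrinkage")) {
  mode <- match.arg(mode)
  stopifnot(inherits(patterns, "cv_patterns"))
  levels <- c(30, 50, 70)
  labels <- expand.grid(EV = levels, EV_back = levels)
  labels$condition <- rdm_condition_label(labels$EV, labels$EV_back)
  runs <- lapply(patterns$runs, function(r) {
    keep <- r$labels$dim == "2D" & r$labels$accuracy == 1
    X <- r$X[keep, , drop = FALSE]
    cond <- rdm_condition_label(r$labels$EV[keep], r$labels$EV_back[keep])
    W <- whitener(r$residuals, mode)
    Xw <- X %*% W
    M <- matrix(NA_real_, nrow(labels), ncol(X))
    n_tr <- integer(nrow(labels))
    for (ci in seq_len(nrow(labels))) {
      rows <- which(cond == labels$condition[ci])
      n_tr[ci] <- length(rows)
      if (length(rows) > 0)
        M[ci, ] <- colMeans(Xw[rows, , drop = FALSE])
    }
    ok <- !is.na(M[, 1])
    M[ok, ] <- sweep(M[ok, , drop = FALSE], 2, colMeans(M[ok, , drop = FALSE]))
    list(run = r$run, M = M, n_trials = n_tr)
  })
  structure(list(runs = runs, labels = labels, mode = mode),
            class = "cv_condition_patterns")
}

# Whitening matrix from a residual matrix: diagonal (1/SD per voxel) or
# inverse square root of a Ledoit-Wolf shrinkage covariance (target: scaled
# identity).
whitener <- function(res, mode) {
  v <- ncol(res)
  if (mode == "diagonal") {
    sds <- apply(res, 2, stats::sd)
    return(diag(1 / sds, v))
  }
  n <- nrow(res)
  xc <- scale(res, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, v))^2)
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  gamma <- if (d2 > 0) b2 / d2 else 1
  Sigma <- (1 - gamma) * S + gamma * diag(mu, v)
  e <- eigen(Sigma, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
}

#' Cross-run representational dissimilarity matrix
#'
#' `d[i, j]` is the mean Euclidean distance between condition i in run r and
#' condition j in run s over all ordered run pairs r != s; within-run pairs
#' are excluded, so the diagonal holds same-condition cross-run distances
#' rather than zeros.
#'
#' @param conds `cv_condition_patterns` with at least two runs.
#' @return object of class `cv_rdm`: 9x9 symmetric matrix `D`, condition
#'   `labels` and per-condition trial counts `freq` (summed over runs).
#' @export
crossrun_rdm <- function(conds) {
  stopifnot(inherits(conds, "cv_condition_patterns"))
  R <- length(conds$runs)
  if (R < 2) stop("cross-run distances need at least 2 runs")
  nc <- nrow(conds$labels)
  # per run, the exact null variance factor of each mean-subtracted condition
  # mean (unit-variance voxels): a_i = ((k-1)/k)^2 / n_i + (1/k^2) sum_{j!=i} 1/n_j
  avar <- lapply(conds$runs, function(run) {
    n <- run$n_trials
    ok <- n > 0
    k <- sum(ok)
    inv <- ifelse(ok, 1 / n, 0)
    a <- ((k - 1) / k)^2 * inv + (sum(inv) - inv) / k^2
    a[!ok] <- NA_real_
    a
  })
  acc <- matrix(0, nc, nc); cnt <- matrix(0, nc, nc); nsc <- matrix(0, nc, nc)
  for (r in seq_len(R)) for (s in seq_len(R)) {
    if (r == s) next
    Mr <- conds$runs[[r]]$M; Ms <- conds$runs[[s]]$M
    for (i in seq_len(nc)) {
      if (is.na(Mr[i, 1])) next
      dif <- sweep(Ms, 2, Mr[i, ], `-`)
      d <- sqrt(rowSums(dif^2))
      ok <- !is.na(d)
      acc[i, ok] <- acc[i, ok] + d[ok]
      cnt[i, ok] <- cnt[i, ok] + 1
      nsc[i, ok] <- nsc[i, ok] + sqrt(avar[[r]][i] + avar[[s]][ok])
    }
  }
  D <- acc / cnt
  D[cnt == 0] <- NA_real_
  D <- (D + t(D)) / 2
  NS <- nsc / cnt
  NS[cnt == 0] <- NA_real_
  NS <- (NS + t(NS)) / 2
  dimnames(D) <- dimnames(NS) <- list(conds$labels$condition,
                                      conds$labels$condition)
  freq <- Reduce(`+`, lapply(conds$runs, `[[`, "n_trials"))
  structure(list(D = D, noise_scale = NS, labels = conds$labels,
                 freq = stats::setNames(freq, conds$labels$condition)),
            class = "cv_rdm")
}

#' @export
print.cv_rdm <- function(x, ...) {
  cat("Cross-run RDM over", nrow(x$D), "(EV, EV_back) conditions\n")
  print(round(x$D, 3))
  invisible(x)
}

#' Long-format cell table of an RDM with model covariates
#'
#' One row per unique cell (upper triangle plus diagonal, 45 cells for 9
#' conditions) with the similarity covariates: `diag_ev` / `diag_evback` are
#' 0 when the two conditions share the same EV / EV_back and 1 otherwise,
#' `vd_ev` / `vd_evback` are the absolute value differences (0, 20 or 40),
#' and `freq_level` is the unordered pair of the two conditions' design trial
#' frequencies.
#'
#' @param rdm `cv_rdm`.
#' @return data.frame with 45 rows.
#' @export
build_rdm_design <- function(rdm) {
  stopifnot(inherits(rdm, "cv_rdm"))
  lb <- rdm$labels
  idx <- which(upper.tri(rdm$D, diag = TRUE), arr.ind = TRUE)
  data.frame(
    cond_i = lb$condition[idx[, 1]], cond_j = lb$condition[idx[, 2]],
    d = rdm$D[idx],
    diag_ev = as.integer(lb$EV[idx[, 1]] != lb$EV[idx[, 2]]),
    diag_evback = as.integer(lb$EV_back[idx[, 1]] != lb$EV_back[idx[, 2]]),
    vd_ev = abs(lb$EV[idx[, 1]] - lb$EV[idx[, 2]]),
    vd_evback = abs(lb$EV_back[idx[, 1]] - lb$EV_back[idx[, 2]]),
    freq_level = apply(cbind(rdm$freq[idx[, 1]], rdm$freq[idx[, 2]]), 1,
                       function(z) paste(sort(z), collapse = "_")),
    noise_scale = rdm$noise_scale[idx],
    stringsAsFactors = FALSE
  )
}

#' Fit the similarity-structure models to RDM cells
#'
#' Models the cross-run dissimilarities as a function of the similarity
#' covariates, in two model families: the diagonal model (same-vs-different
#' EV, then EV_back) and the value-difference model (|dEV|, then
#' |dEV_back|). Cells are first divided by their exactly computable null
#' noise scale (`noise_scale` from [crossrun_rdm()]): the design frequencies
#' of the (EV, EV_back) conditions are functions of the EV_back levels, so
#' the noisier means of low-frequency conditions would otherwise masquerade
#' as EV_back similarity structure. After this equalization the expected
#' null dissimilarity is constant across cells.
#'
#' The default engine is two-stage: per subject, a Gamma regression with an
#' inverse link of the noise-equalized dissimilarity on the (z-scaled)
#' covariates, then a one-sample t-test of each coefficient across subjects.
#' Cells within a subject share condition means and are therefore
#' correlated; the two-stage route is the only engine whose tests calibrate
#' for every covariate (and note that over the unique upper-triangle cells
#' |dEV_back| is exactly additive in condition effects, so engines that
#' absorb additive condition structure cannot test it at all).
#' `engine = "pooled_lr"` fits the pooled Gamma ladder with subject
#' intercepts and likelihood-ratio tests instead; its p-values inherit the
#' cell dependence and are conservative for most terms.
#'
#' With the inverse link a positive dissimilarity effect (larger distance
#' for different values) appears as a negative coefficient.
#'
#' @param cells row-bound cell tables (see [build_rdm_design()]) with a
#'   `subject` column; at least 2 subjects.
#' @param engine `"two_stage"` (default) or `"pooled_lr"`.
#' @return `cv_effect_table` (rows for both ladders; AIC totals per model).
#' @export
fit_rdm_models <- function(cells, engine = c("two_stage", "pooled_lr")) {
  engine <- match.arg(engine)
  stopifnot(length(unique(cells$subject)) >= 2)
  d <- cells[!is.na(cells$d), ]
  if (any(d$d <= 0)) {
    warning("non-positive dissimilarities shifted by machine epsilon")
    d$d <- d$d + .Machine$double.eps - min(d$d, 0)
  }
  d$dstd <- d$d / d$noise_scale
  fam <- stats::Gamma(link = "inverse")
  if (engine == "two_stage") {
    per <- lapply(split(d, d$subject), function(s) {
      s$y <- s$dstd / mean(s$dstd)
      s$z_diag_ev <- zscale(s$diag_ev)
      s$z_diag_evback <- zscale(s$diag_evback)
      s$z_vd_ev <- zscale(s$vd_ev)
      s$z_vd_evback <- zscale(s$vd_evback)
      m1 <- stats::glm(y ~ z_diag_ev + z_diag_evback, family = fam, data = s)
      m2 <- stats::glm(y ~ z_vd_ev + z_vd_evback, family = fam, data = s)
      c(diag_ev = unname(stats::coef(m1)["z_diag_ev"]),
        diag_evback = unname(stats::coef(m1)["z_diag_evback"]),
        vd_ev = unname(stats::coef(m2)["z_vd_ev"]),
        vd_evback = unname(stats::coef(m2)["z_vd_evback"]),
        aic_diag = stats::AIC(m1), aic_vd = stats::AIC(m2))
    })
    co <- do.call(rbind, per)
    row <- function(term, model, ladder, aic) {
      x <- co[, term]
      tt <- stats::t.test(x)
      data.frame(model = model, term = term, estimate = mean(x),
                 se = stats::sd(x) / sqrt(length(x)), chisq = NA_real_,
                 df = unname(tt$parameter), p = tt$p.value,
                 AIC = aic, t = unname(tt$statistic), ladder = ladder)
    }
    tab <- rbind(
      row("diag_ev", "+Diagonal_EV", "diagonal", sum(co[, "aic_diag"])),
      row("diag_evback", "+Diagonal_EVback", "diagonal", sum(co[, "aic_diag"])),
      row("vd_ev", "+VD_EV", "value_difference", sum(co[, "aic_vd"])),
      row("vd_evback", "+VD_EVback", "value_difference", sum(co[, "aic_vd"])))
    return(new_effect_table(tab, "two-stage Gamma(inverse) + t-test"))
  }
  d$d2 <- d$dstd / mean(d$dstd)
  d$subject <- factor(d$subject)
  d$z_diag_ev <- zscale(d$diag_ev)
  d$z_diag_evback <- zscale(d$diag_evback)
  d$z_vd_ev <- zscale(d$vd_ev)
  d$z_vd_evback <- zscale(d$vd_evback)
  base <- stats::glm(d2 ~ subject, family = fam, data = d)
  m1 <- stats::update(base, . ~ . + z_diag_ev)
  m2 <- stats::update(m1, . ~ . + z_diag_evback)
  v1 <- stats::update(base, . ~ . + z_vd_ev)
  v2 <- stats::update(v1, . ~ . + z_vd_evback)
  coefs <- stats::coef
  ses <- function(m) sqrt(diag(stats::vcov(m)))
  t1 <- ladder_table(list(base = base, `+Diagonal_EV` = m1,
                          `+Diagonal_EVback` = m2),
                     c(NA, "z_diag_ev", "z_diag_evback"),
                     "glm Gamma(inverse)", coefs, ses)
  t2 <- ladder_table(list(base = base, `+VD_EV` = v1, `+VD_EVback` = v2),
                     c(NA, "z_vd_ev", "z_vd_evback"),
                     "glm Gamma(inverse)", coefs, ses)
  tab <- rbind(as.data.frame(t1),
               as.data.frame(t2)[-1, ])
  tab$t <- NA_real_
  tab$ladder <- c("diagonal", "diagonal", "diagonal", "value_difference",
                  "value_difference")
  new_effect_table(tab, "glm Gamma(inverse), pooled")
}
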