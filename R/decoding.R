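# Leave-one-run-out decoding of value, context and background value from
# multivoxel patterns: balanced up-sampled training sets, an L2-penalized
# multinomial logistic classifier fitted by damped Newton iterations (convex,
# deterministic given the data), probability clipping, logit/multinomial-
# logit transforms, balanced accuracy, and nuisance-cell aggregation.

#' Up-sample a training set to equalize balancing-key cells
#'
#' Every cell of the crossed balancing keys is filled up to the size of the
#' largest cell by duplicating randomly chosen members of the same cell,
#' preferring members from blocks that currently contribute fewer examples
#' (block-wise balance). Test sets are never up-sampled.
#'
#' @param data data.frame of training examples with a `block` column.
#' @param keys character vector of balancing column names.
#' @param seed integer seed.
#' @return `data` with duplicated rows appended; attribute `n_added` gives
#'   the number of duplicates.
#' @export
balance_upsample <- function(data, keys, seed) {
  set.seed(subseed(seed, 8L))
  cell <- interaction(data[keys], drop = FALSE)
  if (any(table(cell) == 0)) {
    empty <- names(which(table(cell) == 0))
    stop("empty balancing cell(s): ", paste(empty, collapse = ", "))
  }
  target <- max(table(cell))
  added <- list()
  for (lv in levels(cell)) {
    members <- which(cell == lv)
    need <- target - length(members)
    if (need <= 0) next
    blk_now <- table(data$block[members])
    for (j in seq_len(need)) {
      cand_blocks <- names(blk_now)[blk_now == min(blk_now)]
      pool <- members[data$block[members] %in% as.integer(cand_blocks) |
                        as.character(data$block[members]) %in% cand_blocks]
      pick <- pool[sample.int(length(pool), 1L)]
      added[[length(added) + 1L]] <- pick
      b <- as.character(data$block[pick])
      blk_now[b] <- blk_now[b] + 1
    }
  }
  out <- if (length(added)) rbind(data, data[unlist(added), , drop = FALSE]) else data
  rownames(out) <- NULL
  attr(out, "n_added") <- length(added)
  out
}

# penalized multinomial negative log-likelihood, gradient and Hessian with
# reference-class coding; intercepts unpenalized, penalty strength 1/C.
multinom_objective <- function(B, X1, Y, w, C) {
  eta <- X1 %*% B
  m <- pmax(apply(eta, 1, max), 0)
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  ll <- sum(w * (rowSums(Y * eta) - lse))
  pen <- sum(B[-1, , drop = FALSE]^2) / (2 * C)
  -ll + pen
}

multinom_probs_ref <- function(B, X1) {
  eta <- X1 %*% B
  m <- pmax(apply(eta, 1, max), 0)
  den <- exp(-m) + rowSums(exp(eta - m))
  P <- exp(eta - m) / den          # classes 2..K
  cbind(exp(-m) / den, P)          # reference class first
}

#' Fit an L2-penalized multinomial logistic classifier
#'
#' Minimizes the weighted multinomial negative log-likelihood plus an L2
#' penalty of strength `1/C` on the non-intercept weights (reference-class
#' coding) by damped Newton iterations until the gradient infinity-norm of
#' the penalized objective falls below `tol`. The problem is strictly convex,
#' so refits on identical data reproduce identical weights.
#'
#' @param X numeric matrix, examples x features.
#' @param y factor of class labels (>= 2 levels present).
#' @param weights optional positive example weights.
#' @param C inverse penalty strength (default 1.0).
#' @param tol gradient tolerance (default 1e-6).
#' @param max_iter Newton iteration cap.
#' @return object of class `cv_multinom` with `B` ((features+1) x (K-1)
#'   weight matrix), `levels`, `converged`, `grad_norm`, `objective`.
#' @export
fit_multinomial <- function(X, y, weights = NULL, C = 1.0, tol = 1e-6,
                            max_iter = 100L) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes present")
  n <- nrow(X); p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0), length(weights) == n, length(y) == n)
  X1 <- cbind(1, X)
  Y <- matrix(0, n, K - 1)
  for (k in 2:K) Y[, k - 1] <- as.numeric(y == levels(y)[k])
  B <- matrix(0, p + 1, K - 1)
  pen_diag <- rep(c(0, rep(1 / C, p)), K - 1)
  obj <- multinom_objective(B, X1, Y, weights, C)
  converged <- FALSE; it <- 0L; gnorm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    P <- multinom_probs_ref(B, X1)[, -1, drop = FALSE]
    G <- crossprod(X1, weights * (P - Y)) +
      rbind(0, B[-1, , drop = FALSE] / C)
    gnorm <- max(abs(G))
    if (gnorm < tol) { converged <- TRUE; break }
    d <- (p + 1) * (K - 1)
    H <- matrix(0, d, d)
    for (a in seq_len(K - 1)) for (b in seq_len(K - 1)) {
      s <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      blk <- crossprod(X1, (weights * s) * X1)
      H[((a - 1) * (p + 1) + 1):(a * (p + 1)),
        ((b - 1) * (p + 1) + 1):(b * (p + 1))] <- blk
    }
    diag(H) <- diag(H) + pen_diag + 1e-10
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) as.vector(G) / max(diag(H)))
    lam <- 1
    repeat {
      Bn <- B - lam * matrix(step, p + 1, K - 1)
      on <- multinom_objective(Bn, X1, Y, weights, C)
      if (on <= obj + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    if (on > obj && lam < 1e-8) break
    B <- Bn; obj <- on
  }
  if (!converged && gnorm >= tol) {
    P <- multinom_probs_ref(B, X1)[, -1, drop = FALSE]
    G <- crossprod(X1, weights * (P - Y)) + rbind(0, B[-1, , drop = FALSE] / C)
    gnorm <- max(abs(G))
    converged <- gnorm < tol
    if (!converged)
      stop("multinomial fit did not converge: gradient norm ", signif(gnorm, 3),
           " after ", it, " iterations")
  }
  structure(list(B = B, levels = levels(y), C = C, converged = converged,
                 n_iter = it, grad_norm = gnorm, objective = obj),
            class = "cv_multinom")
}

#' @rdname fit_multinomial
#' @param object fitted `cv_multinom`.
#' @param newdata matrix of examples to predict.
#' @return `predict_multinomial()` returns an examples x classes probability
#'   matrix (columns named by class).
#' @export
predict_multinomial <- function(object, newdata) {
  P <- multinom_probs_ref(object$B, cbind(1, newdata))
  colnames(P) <- object$levels
  P
}

# assemble one data.frame of trials x (labels, voxel matrix) from patterns;
# each voxel is z-scored within run, mirroring the standard per-block
# time-series normalization applied before classification.
patterns_frame <- function(patterns, scale_runs = TRUE) {
  lab <- do.call(rbind, lapply(patterns$runs, `[[`, "labels"))
  X <- do.call(rbind, lapply(patterns$runs, function(r)
    if (scale_runs) scale(r$X) else r$X))
  list(labels = lab, X = X)
}

#' Leave-one-run-out decoding of value or context from 1D trials
#'
#' For each fold, a classifier is trained on the behaviourally accurate 1D
#' trials of the remaining runs -- up-sampled to balance EV x context x
#' chosen side -- and predicts class probabilities for every trial (1D and
#' 2D) of the held-out run, so each trial is predicted exactly once.
#' Probabilities are clipped to [0.00001, 0.99999]. The value classifier
#' ignores context as a label and vice versa.
#'
#' @param patterns `cv_patterns` with >= 2 runs.
#' @param target `"value"` (classes 30/50/70) or `"context"`
#'   (color/motion).
#' @param C inverse penalty strength.
#' @param seed integer seed (up-sampling).
#' @param subject subject id stored on the output rows.
#' @return data.frame of class `cv_probs`: one row per trial with labels,
#'   `fold`, and clipped probability columns `prob_<class>`; attribute
#'   `target` and `classes`.
#' @export
loro_decode <- function(patterns, target = c("value", "context"), C = 1.0,
                        seed = 1L, subject = 1L) {
  target <- match.arg(target)
  pf <- patterns_frame(patterns)
  lab <- pf$labels
  runs <- sort(unique(lab$block))
  out <- list()
  for (r in runs) {
    tr_idx <- which(lab$block != r & lab$dim == "1D" & lab$accuracy == 1)
    td <- lab[tr_idx, ]
    td$row <- tr_idx
    td$chosen_side <- td$target_side  # accurate trials: choice = target
    cls <- if (target == "value") factor(td$EV) else factor(td$context)
    miss <- setdiff(levels(cls), unique(as.character(cls)))
    if (length(miss))
      stop("fold ", r, ": class ", paste(miss, collapse = ","),
           " missing from training set")
    td$.y <- cls
    bal <- balance_upsample(td, c("EV", "context", "chosen_side"),
                            seed = subseed(seed, 100L + r))
    fit <- fit_multinomial(pf$X[bal$row, , drop = FALSE], bal$.y, C = C)
    te_idx <- which(lab$block == r)
    P <- clip_probs(predict_multinomial(fit, pf$X[te_idx, , drop = FALSE]))
    rec <- lab[te_idx, c("gtrial", "block", "trial", "EV", "EV_back",
                         "context", "dim", "target_side", "accuracy")]
    rec$subject <- subject
    rec$fold <- r
    colnames(P) <- paste0("prob_", colnames(P))
    out[[length(out) + 1L]] <- cbind(rec, as.data.frame(P))
  }
  res <- do.call(rbind, out)
  res$truth <- if (target == "value") as.character(res$EV) else res$context
  attr(res, "target") <- target
  attr(res, "classes") <- sub("^prob_", "", grep("^prob_", names(res), value = TRUE))
  class(res) <- c("cv_probs", "data.frame")
  res
}

#' One-vs-rest decoding of the background value from 2D trials
#'
#' Three binary L2-penalized logistic classifiers (one per EV_back level)
#' are trained leave-one-run-out on behaviourally accurate 2D trials,
#' up-sampled to balance EV x context x EV_back, with sample weights that
#' equalize the total weight of the positive and the rest class within each
#' binary problem. The three per-trial probabilities are renormalized to sum
#' to one and then clipped.
#'
#' @inheritParams loro_decode
#' @return `cv_probs` table over 2D trials with `prob_30`, `prob_50`,
#'   `prob_70`; `truth` is the trial's EV_back.
#' @export
ovr_evback_decode <- function(patterns, C = 1.0, seed = 1L, subject = 1L) {
  pf <- patterns_frame(patterns)
  lab <- pf$labels
  runs <- sort(unique(lab$block))
  levelsb <- c(30, 50, 70)
  out <- list()
  for (r in runs) {
    tr_idx <- which(lab$block != r & lab$dim == "2D" & lab$accuracy == 1)
    td <- lab[tr_idx, ]
    td$row <- tr_idx
    miss <- setdiff(levelsb, unique(td$EV_back))
    if (length(miss))
      stop("fold ", r, ": EV_back class ", paste(miss, collapse = ","),
           " missing from training set")
    bal <- balance_upsample(td, c("EV", "context", "EV_back"),
                            seed = subseed(seed, 200L + r))
    Xtr <- pf$X[bal$row, , drop = FALSE]
    te_idx <- which(lab$block == r & lab$dim == "2D")
    Xte <- pf$X[te_idx, , drop = FALSE]
    P <- matrix(NA_real_, length(te_idx), length(levelsb))
    for (li in seq_along(levelsb)) {
      ybin <- factor(ifelse(bal$EV_back == levelsb[li], "one", "rest"),
                     levels = c("rest", "one"))
      npos <- sum(ybin == "one"); nneg <- sum(ybin == "rest")
      w <- ifelse(ybin == "one", 0.5 * length(ybin) / npos,
                  0.5 * length(ybin) / nneg)
      fit <- fit_multinomial(Xtr, ybin, weights = w, C = C)
      P[, li] <- predict_multinomial(fit, Xte)[, "one"]
    }
    P <- P / rowSums(P)
    P <- clip_probs(P)
    colnames(P) <- paste0("prob_", levelsb)
    rec <- lab[te_idx, c("gtrial", "block", "trial", "EV", "EV_back",
                         "context", "dim", "target_side", "accuracy")]
    rec$subject <- subject
    rec$fold <- r
    out[[length(out) + 1L]] <- cbind(rec, as.data.frame(P))
  }
  res <- do.call(rbind, out)
  res$truth <- as.character(res$EV_back)
  attr(res, "target") <- "evback"
  attr(res, "classes") <- as.character(levelsb)
  class(res) <- c("cv_probs", "data.frame")
  res
}

#' Add logit / multinomial-logit transforms to a probability table
#'
#' For three-class tables, adds `mlogit_<class>` columns (mean log-odds of a
#' class against each other class); for two-class tables, adds
#' `logit_<class>`. Transforms are computed on the clipped probabilities and
#' are therefore finite.
#'
#' @param recs `cv_probs` table.
#' @return `recs` with transform columns appended.
#' @export
transform_probs <- function(recs) {
  cls <- attr(recs, "classes")
  if (is.null(cls)) cls <- sub("^prob_", "", grep("^prob_", names(recs), value = TRUE))
  P <- as.matrix(recs[paste0("prob_", cls)])
  if (length(cls) == 2) {
    for (c1 in cls) recs[[paste0("logit_", c1)]] <- logit(recs[[paste0("prob_", c1)]])
  } else {
    M <- mlogit_probs(P)
    for (i in seq_along(cls)) recs[[paste0("mlogit_", cls[i])]] <- M[, i]
  }
  recs
}

#' Balanced decoding accuracy per subject
#'
#' A prediction is correct iff the unique arg-max class equals the true
#' label; ties count as incorrect. Accuracy is averaged within (subject,
#' fold, label) first, then across labels within fold, then across folds, so
#' test-set label imbalance cannot bias the score.
#'
#' @param recs `cv_probs` table (any subset of rows, e.g. 1D trials only).
#' @return data.frame with `subject`, `balanced_accuracy`, `n_ties`.
#' @export
balanced_accuracy <- function(recs) {
  cls <- attr(recs, "classes")
  if (is.null(cls)) cls <- sub("^prob_", "", grep("^prob_", names(recs), value = TRUE))
  P <- as.matrix(recs[paste0("prob_", cls)])
  mx <- apply(P, 1, max)
  is_max <- P == mx
  tie <- rowSums(is_max) > 1
  pred <- cls[max.col(P, ties.method = "first")]
  correct <- !tie & pred == recs$truth
  cell <- stats::aggregate(correct,
                           by = list(subject = recs$subject, fold = recs$fold,
                                     label = recs$truth),
                           FUN = mean)
  by_fold <- stats::aggregate(cell$x,
                              by = list(subject = cell$subject, fold = cell$fold),
                              FUN = mean)
  out <- stats::aggregate(by_fold$x, by = list(subject = by_fold$subject),
                          FUN = mean)
  names(out)[2] <- "balanced_accuracy"
  out$n_ties <- as.vector(tapply(tie, recs$subject, sum)[as.character(out$subject)])
  out
}

#' Average 2D-trial probabilities over nuisance cells
#'
#' Per subject, averages the class probabilities of behaviourally accurate
#' 2D trials within each combination of EV (3 levels) and the ordered pair
#' (irrelevant value on the chosen side, irrelevant value on the unchosen
#' side) (12 levels), yielding 36 combinations. EV_back and Congruency are
#' recomputed per cell.
#'
#' @param recs `cv_probs` table of 2D trials (value classifier).
#' @param design `cv_design` supplying the irrelevant values per trial.
#' @return data.frame with up to 36 rows per subject.
#' @export
aggregate_combinations <- function(recs, design) {
  cls <- attr(recs, "classes")
  if (is.null(cls)) cls <- sub("^prob_", "", grep("^prob_", names(recs), value = TRUE))
  tr <- design$trials[, c("gtrial", "irr_left", "irr_right")]
  d <- merge(recs[recs$dim == "2D" & recs$accuracy == 1, ], tr, by = "gtrial")
  chosen <- d$target_side  # accurate trials
  d$irr_chosen <- ifelse(chosen == "left", d$irr_left, d$irr_right)
  d$irr_unchosen <- ifelse(chosen == "left", d$irr_right, d$irr_left)
  pcols <- paste0("prob_", cls)
  agg <- stats::aggregate(d[pcols],
                          by = list(subject = d$subject, EV = d$EV,
                                    irr_chosen = d$irr_chosen,
                                    irr_unchosen = d$irr_unchosen),
                          FUN = mean)
  n <- stats::aggregate(list(n = d$gtrial),
                        by = list(subject = d$subject, EV = d$EV,
                                  irr_chosen = d$irr_chosen,
                                  irr_unchosen = d$irr_unchosen),
                        FUN = length)
  agg <- merge(agg, n)
  agg$EV_back <- pmax(agg$irr_chosen, agg$irr_unchosen)
  agg$congruency <- ifelse(agg$irr_chosen > agg$irr_unchosen,
                           "congruent", "incongruent")
  agg
}

#' Map a stimulus onset to the analysed volume index
#'
#' Real pipelines analyse the volume nearest the haemodynamic peak, about
#' 5 s after stimulus onset. This utility implements that selection as
#' `floor(round(onset + 5) / tr)` with volumes counted from 0. The rounding
#' convention (seconds before division by the repetition time) is ambiguous
#' in common descriptions and documented here as this package's convention;
#' the simulated patterns are trial-level, so the mapping is informational.
#'
#' @param onset stimulus onset in seconds from run start.
#' @param tr repetition time in seconds (default 1.25).
#' @return integer volume index (0-based).
#' @export
onset_to_volume <- function(onset, tr = 1.25) {
  as.integer(floor(round(onset + 5) / tr))
}
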