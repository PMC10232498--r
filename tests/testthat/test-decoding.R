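# Balancing, the penalized multinomial classifier, the leave-one-run-out
# protocol, probability transforms and balanced accuracy.

test_that("balance_upsample equalizes cells by duplicating existing members", {
  df <- data.frame(EV = c(30, 30, 30, 30, 30, 50, 50, 50),
                   block = c(1, 1, 2, 3, 4, 1, 2, 2),
                   id = 1:8)
  out <- balance_upsample(df, "EV", seed = 1)
  expect_equal(as.vector(table(out$EV)), c(5L, 5L))
  expect_equal(attr(out, "n_added"), 2)
  # duplicates are exact copies of existing members
  added <- out[9:10, ]
  expect_true(all(added$id %in% df$id[df$EV == 50]))
  # block priority: cell 50 has block counts (1: 1, 2: 2); the first
  # duplicate must come from block 1
  expect_equal(added$block[1], 1)
  # already balanced input is returned unchanged
  bal <- df[c(1:3, 6:8), ]
  rownames(bal) <- NULL
  expect_identical(balance_upsample(bal, "EV", 1)[, names(bal)], bal)
  # a crossed key combination with no members is an explicit failure
  expect_error(balance_upsample(data.frame(EV = c(30, 50), block = 1,
                                           k = c("a", "b")), c("EV", "k"),
                                seed = 1),
               regexp = "empty", ignore.case = TRUE)
})

test_that("penalized multinomial optimum passes a finite-difference gradient check", {
  set.seed(2)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(sample(c(30, 50, 70), n, replace = TRUE))
  w <- runif(n, 0.5, 2)
  fit <- fit_multinomial(X, y, weights = w, C = 1.0)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)
  # finite-difference oracle on the penalized objective at the optimum
  X1 <- cbind(1, X)
  Y <- sapply(levels(y)[-1], function(l) as.numeric(y == l))
  f <- function(b) contextval:::multinom_objective(matrix(b, p + 1), X1, Y, w, 1.0)
  b0 <- as.vector(fit$B)
  eps <- 1e-6
  g_fd <- sapply(seq_along(b0), function(i) {
    e <- rep(0, length(b0)); e[i] <- eps
    (f(b0 + e) - f(b0 - e)) / (2 * eps)
  })
  expect_lt(max(abs(g_fd)), 1e-4)
  # objective at optimum below objective at zero weights
  expect_lte(fit$objective, f(rep(0, length(b0))))
  # convex problem: refits reproduce probabilities exactly
  fit2 <- fit_multinomial(X, y, weights = w, C = 1.0)
  expect_lt(max(abs(predict_multinomial(fit, X) - predict_multinomial(fit2, X))),
            1e-8)
})

test_that("separable toy data are classified perfectly", {
  X <- matrix(c(rep(0, 10), rep(5, 10), rnorm(20, sd = .1)), ncol = 2)
  y <- factor(rep(c("a", "b"), each = 10))
  fit <- fit_multinomial(X, y)
  P <- predict_multinomial(fit, X)
  expect_equal(colnames(P)[max.col(P)], as.character(y))
})

test_that("leave-one-run-out decoding predicts every trial exactly once", {
  co <- fixture_cohort()
  pv <- co$value[co$value$subject == 1, ]
  d <- co$design
  expect_setequal(pv$gtrial, d$trials$gtrial)
  expect_false(anyDuplicated(pv$gtrial) > 0)
  # each trial predicted by the fold of its own run
  expect_true(all(pv$fold == pv$block))
  # probabilities clipped
  P <- as.matrix(pv[paste0("prob_", c(30, 50, 70))])
  expect_true(all(P >= 1e-5 & P <= 1 - 1e-5))
})

test_that("decoding recovers planted signal and stays at chance on noise", {
  co <- fixture_cohort()
  ba_v <- balanced_accuracy(co$value[co$value$dim == "1D" & co$value$accuracy == 1, ])
  ba_c <- balanced_accuracy(co$context[co$context$dim == "1D" &
                                         co$context$accuracy == 1, ])
  expect_gt(mean(ba_v$balanced_accuracy), 1 / 3 + 0.05)
  expect_gt(mean(ba_c$balanced_accuracy), 1 / 2 + 0.05)
  # pure-noise world: both classifiers within binomial CI of chance
  d <- fixture_design()
  accs <- sapply(1:3, function(s) {
    cb <- make_codebook(48, seed = 40 + s)
    ps <- simulate_patterns(d, NULL, cb, null_neural_params(n_voxels = 48),
                            40 + s)
    pv <- loro_decode(ps, "value", seed = s)
    pc <- loro_decode(ps, "context", seed = s)
    c(balanced_accuracy(pv[pv$dim == "1D", ])$balanced_accuracy,
      balanced_accuracy(pc[pc$dim == "1D", ])$balanced_accuracy)
  })
  n1 <- 3 * 144  # pooled 1D trials
  expect_lt(abs(mean(accs[1, ]) - 1 / 3), 3 * sqrt(1 / 9 * 2 / 3) / sqrt(n1) + 0.02)
  expect_lt(abs(mean(accs[2, ]) - 1 / 2), 3 * 0.5 / sqrt(n1) + 0.02)
})

test_that("monotone sensitivity: stronger value code, better value decoding", {
  d <- fixture_design()
  acc_at <- sapply(c(0.4, 1.0, 2.5), function(a) {
    cb <- make_codebook(48, seed = 77)
    np <- neural_params(n_voxels = 48, a_ev = a, a_back = 0, lambda = 0,
                        s_back = 0)
    ps <- simulate_patterns(d, NULL, cb, np, 77)
    pv <- loro_decode(ps, "value", seed = 7)
    balanced_accuracy(pv[pv$dim == "1D", ])$balanced_accuracy
  })
  expect_true(all(diff(acc_at) > 0))
})

test_that("value classifier probabilities are graded in |EV - class|", {
  co <- fixture_cohort()
  pv <- co$value[co$value$dim == "1D" & co$value$accuracy == 1, ]
  lev <- c(30, 50, 70)
  P <- as.matrix(pv[paste0("prob_", lev)])
  dist_mean <- sapply(c(0, 20, 40), function(dl) {
    sel <- abs(outer(pv$EV, lev, "-")) == dl
    mean(P[sel])
  })
  expect_true(all(diff(dist_mean) < 0))
})

test_that("one-vs-rest background decoding renormalizes and balances weights", {
  co <- fixture_cohort()
  pe <- co$evback[co$evback$subject == 1, ]
  P <- as.matrix(pe[paste0("prob_", c(30, 50, 70))])
  # renormalized before clipping: sums deviate from 1 by at most ~6e-5
  expect_true(all(abs(rowSums(P) - 1) < 6e-5))
  expect_true(all(pe$dim == "2D"))
  # weighting rule: equal total weight for the one and the rest class
  n <- 30
  ybin <- factor(rep(c("one", "rest"), c(10, 20)), levels = c("rest", "one"))
  w <- ifelse(ybin == "one", 0.5 * n / 10, 0.5 * n / 20)
  expect_equal(sum(w[ybin == "one"]), sum(w[ybin == "rest"]))
})

test_that("probability transforms match their closed forms", {
  expect_equal(unname(mlogit_probs(c(1, 1, 1) / 3)), c(0, 0, 0))
  expect_equal(unname(mlogit_probs(c(0.5, 0.25, 0.25)))[1], log(2))
  expect_equal(logit(0.5), 0)
  expect_equal(clip_probs(c(0, 1, 0.5)), c(1e-5, 1 - 1e-5, 0.5))
  co <- fixture_cohort()
  tp <- transform_probs(co$value[1:10, ])
  expect_equal(tp$mlogit_30,
               0.5 * (log(tp$prob_30 / tp$prob_50) + log(tp$prob_30 / tp$prob_70)))
  tc <- transform_probs(co$context[1:10, ])
  expect_equal(tc$logit_color, logit(tc$prob_color))
})

test_that("balanced accuracy is immune to test-set imbalance", {
  # 2:1 imbalanced toy set, majority-class predictor -> 1/2, raw accuracy 2/3
  recs <- data.frame(subject = 1, fold = 1,
                     truth = rep(c("a", "b"), c(20, 10)),
                     prob_a = 0.9, prob_b = 0.1)
  attr(recs, "classes") <- c("a", "b")
  out <- balanced_accuracy(recs)
  expect_equal(out$balanced_accuracy, 0.5)
  # all-correct predictions
  recs2 <- data.frame(subject = 1, fold = rep(1:2, 5),
                      truth = rep(c("a", "b"), 5),
                      prob_a = rep(c(0.9, 0.1), 5),
                      prob_b = rep(c(0.1, 0.9), 5))
  attr(recs2, "classes") <- c("a", "b")
  expect_equal(balanced_accuracy(recs2)$balanced_accuracy, 1)
  # argmax ties count as incorrect
  recs3 <- data.frame(subject = 1, fold = 1, truth = "a",
                      prob_a = 0.5, prob_b = 0.5)
  attr(recs3, "classes") <- c("a", "b")
  expect_equal(balanced_accuracy(recs3)$balanced_accuracy, 0)
  expect_equal(balanced_accuracy(recs3)$n_ties, 1)
})

test_that("aggregation over nuisance cells yields 36 combinations", {
  co <- fixture_cohort()
  agg <- aggregate_combinations(co$value, co$design)
  a1 <- agg[agg$subject == 1, ]
  expect_lte(nrow(a1), 36)
  expect_gte(nrow(a1), 30)   # near-ceiling accuracy can empty the odd cell
  expect_true(all(a1$irr_chosen != a1$irr_unchosen))
  # averaging preserves sum-to-one up to clipping tolerance
  S <- rowSums(a1[paste0("prob_", c(30, 50, 70))])
  expect_true(all(abs(S - 1) < 1e-4))
  expect_equal(a1$EV_back, pmax(a1$irr_chosen, a1$irr_unchosen))
})

test_that("onset-to-volume mapping follows the documented convention", {
  expect_equal(onset_to_volume(0), 4L)          # floor(5 / 1.25)
  expect_equal(onset_to_volume(10.3), 12L)      # floor(round(15.3) / 1.25)
  expect_equal(onset_to_volume(c(0, 2.6), tr = 2), c(2L, 4L))
})
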