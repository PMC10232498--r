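# Behavioural simulation and the RT/accuracy model-comparison ladders.

test_that("simulated behaviour has the planted structure", {
  d <- fixture_design()
  bh <- simulate_behavior(d, behavior_params(), 6, 1)
  expect_true(all(bh$rt > 0))
  expect_gt(mean(bh$accuracy, na.rm = TRUE), 0.8)   # near ceiling
  # positive congruency coefficient -> incongruent slower in expectation
  tw <- bh[bh$dim == "2D", ]
  expect_gt(mean(log(tw$rt[tw$congruency == "incongruent"])),
            mean(log(tw$rt[tw$congruency == "congruent"])))
  # null world: condition means equal within noise
  b0 <- simulate_behavior(d, null_behavior_params(), 6, 1)
  t0 <- b0[b0$dim == "2D", ]
  expect_lt(abs(mean(log(t0$rt[t0$congruency == "incongruent"])) -
                  mean(log(t0$rt[t0$congruency == "congruent"]))), 0.02)
})

test_that("RT ladder detects the planted congruency effects with correct signs", {
  co <- fixture_cohort()
  tab <- as.data.frame(fit_rt_ladder(co$behavior))
  expect_equal(tab$model[1:4], c("baseline_EV", "+Congruency", "+EV_back",
                                 "+Congruency:EV_back"))
  expect_gt(tab$estimate[tab$model == "+Congruency"], 0)
  expect_lt(tab$p[tab$model == "+Congruency"], 0.01)
  expect_gt(tab$estimate[tab$model == "+Congruency:EV_back"], 0)
  expect_lt(tab$p[tab$model == "+Congruency:EV_back"], 0.05)
  # alternative overall-irrelevant-value model is reported with an AIC
  expect_true("alt_overall_irrelevant" %in% tab$model)
  expect_true(is.finite(tab$AIC[tab$model == "alt_overall_irrelevant"]))
})

test_that("planted Congruency x EV_back is recovered without bias", {
  d <- fixture_design()
  truth <- behavior_params()$beta_cong_evback
  est <- sapply(1:25, function(r) {
    bh <- simulate_behavior(d, behavior_params(), 8, 900 + r)
    tab <- as.data.frame(fit_rt_ladder(bh))
    tab$estimate[tab$model == "+Congruency:EV_back"]
  })
  # mean estimate within Monte-Carlo error of the planted value
  expect_lt(abs(mean(est) - truth), 3 * sd(est) / sqrt(length(est)) + 1e-3)
})

test_that("model specification is idempotent", {
  co <- fixture_cohort()
  b <- co$behavior[co$behavior$dim == "2D" & co$behavior$answered &
                     co$behavior$accuracy == 1, ]
  b$lrt <- log(b$rt)
  b <- contextval:::add_behavior_regressors(b)
  f1 <- lm(lrt ~ zEV + cong, data = b)
  f2 <- lm(lrt ~ zEV + cong + cong, data = b)
  expect_equal(deviance(f1), deviance(f2))
})

test_that("accuracy ladder recovers planted signs and flags separation", {
  co <- fixture_cohort()
  tab <- as.data.frame(fit_accuracy_ladder(co$behavior))
  expect_lt(tab$estimate[tab$model == "+Congruency"], 0)
  expect_lt(tab$estimate[tab$model == "+Congruency:EV_back"], 0)
  expect_lt(tab$p[tab$model == "+Congruency:EV_back"], 0.05)
  # all-correct data: separation flagged, penalized intercept reported
  allc <- co$behavior
  allc$accuracy <- 1L
  expect_warning(sep <- fit_accuracy_ladder(allc), "separation")
  expect_true(attr(sep, "separation"))
  expect_true(is.finite(sep$estimate[1]))
})

test_that("congruency contrasts: degenerate equality and planted ordering", {
  # identical condition means per subject -> t = 0, p = 1
  d <- fixture_design()
  bh <- simulate_behavior(d, null_behavior_params(), 4, 2)
  bh$rt <- 1                               # constant RTs
  out <- congruency_contrasts(bh)
  expect_equal(out$t, rep(0, 3))
  expect_equal(out$p, rep(1, 3))
  # planted ordering incongruent > 1D > congruent
  co <- fixture_cohort()
  oc <- congruency_contrasts(co$behavior)
  expect_gt(oc$estimate[oc$contrast == "incongruent vs oneD"], 0)
  expect_lt(oc$estimate[oc$contrast == "congruent vs oneD"], 0)
  expect_gt(oc$estimate[oc$contrast == "incongruent vs congruent"], 0)
  expect_true(all(oc$p_adj < 0.05))
})

test_that("Benjamini-Hochberg adjustment matches a brute-force oracle", {
  p <- c(0.01, 0.02, 0.9)
  # oracle: p_(i) * m / i, cumulative minimum from the largest down
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  expected <- pmin(1, adj)[order(o)]
  expect_equal(p.adjust(p, "BH"), expected)
  expect_equal(expected, c(0.03, 0.03, 0.9))
})
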