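# Linking classifier probabilities to design variables and behaviour.

test_that("link records derive the class-probability quantities correctly", {
  recs <- fixture_links()
  lev <- c(30, 50, 70)
  i <- which(recs$dim == "2D" & recs$EV == 50 & recs$EV_back == 70)[1]
  expect_equal(recs$P_EV[i], recs$v_prob_50[i])
  expect_equal(recs$P_EVback[i], recs$v_prob_70[i])
  expect_equal(recs$P_other[i], recs$v_prob_30[i])
  expect_equal(recs$other_value[i], 30)
  # P_other undefined when EV = EV_back
  j <- recs$dim == "2D" & recs$EV == recs$EV_back
  expect_true(all(is.na(recs$P_other[j])))
  # filters commute: EV != EV_back then other-on-screen equals the reverse
  f1 <- recs[recs$dim == "2D" & !is.na(recs$P_other), ]
  f1 <- f1[f1$other_on_screen, ]
  f2 <- recs[recs$dim == "2D" & recs$other_on_screen %in% TRUE, ]
  f2 <- f2[!is.na(f2$P_other), ]
  expect_equal(paste(f1$subject, f1$gtrial), paste(f2$subject, f2$gtrial))
  # Fisher z of zero correlation is zero
  expect_equal(fisher_z(0), 0)
})

test_that("value-similarity model recovers the graded code; 1D perceptual = value", {
  recs <- fixture_links()
  tab <- as.data.frame(fit_value_similarity(recs))
  expect_lt(tab$estimate[tab$model == "+|EV-class|"], 0)  # closer class, higher P
  expect_lt(tab$p[tab$model == "+|EV-class|"], 0.001)
  expect_true(is.finite(tab$AIC[tab$model == "perceptual_similarity"]))
  # perceptual similarity equals value similarity on 1D trials
  lev <- c(30, 50, 70)
  d1 <- recs[recs$dim == "1D", ][1:50, ]
  for (cl in lev) {
    ov <- (abs(d1$EV - cl) == 0) * 2 + (abs(d1$EV - cl) == 20) * 1
    expect_equal(20 * (2 - ov), abs(d1$EV - cl))
  }
})

test_that("P_EV models recover planted competition and context coupling", {
  recs <- fixture_links()
  tab <- as.data.frame(fit_pev_models(recs))
  expect_lt(tab$estimate[tab$model == "+EV_back"], 0)
  expect_lt(tab$p[tab$model == "+EV_back"], 0.01)
  expect_true(all(is.finite(tab$AIC)))
})

test_that("competition correlations: flat-Dirichlet null is symmetric, planted world is not", {
  # Monte-Carlo null: under exchangeable probabilities the EV/EV_back and
  # EV/other correlations coincide
  set.seed(10)
  n <- 10000
  g <- matrix(rgamma(3 * n, 2), ncol = 3)
  P <- g / rowSums(g)
  M <- mlogit_probs(P)
  r12 <- cor(M[, 1], M[, 2], method = "spearman")
  r13 <- cor(M[, 1], M[, 3], method = "spearman")
  expect_lt(abs(r12 - r13), 0.05)
  # planted overlap: corr(P_EV, P_EVback) more negative than corr(P_EV, P_other)
  recs <- fixture_links()
  cc <- competition_correlation(recs)
  expect_lt(cc$paired_test$mean_z_back, cc$paired_test$mean_z_other)
  expect_lt(cc$paired_test$p, 0.05)
  expect_equal(nrow(cc$per_subject), 8)
  # regression twin prefers the EV_back term
  expect_lt(cc$aic$AIC[cc$aic$model == "mlogit_P_EVback"],
            cc$aic$AIC[cc$aic$model == "mlogit_P_other"])
  # subjects with too few qualifying trials are dropped with a message
  small <- recs[recs$subject != 1 | recs$gtrial <= 30, ]
  expect_message(competition_correlation(small, min_trials = 10), "excluded")
})

test_that("full P_EV model recovers the planted context moderation", {
  recs <- fixture_links()
  tab <- as.data.frame(fit_pev_full(recs))
  expect_gt(tab$estimate[tab$model == "+P_context:P_EVback_2D"], 0)
  # nesting check (gaussian engine): adding a constant to logit(P_EV) within
  # one EV_back level leaves the slope terms unchanged
  g1 <- as.data.frame(fit_pev_full(recs, engine = "gaussian"))
  shifted <- recs
  i <- shifted$dim == "2D" & shifted$EV_back == 50
  shifted$P_EV[i] <- inv_logit(logit(clip_probs(shifted$P_EV[i])) + 0.8)
  g2 <- as.data.frame(fit_pev_full(shifted, engine = "gaussian"))
  expect_equal(g1$estimate[2:3], g2$estimate[2:3], tolerance = 1e-8)
})

test_that("behaviour links run and the accuracy selection reports LR steps", {
  recs <- fixture_links()
  out <- fit_behavior_links(recs)
  ptab <- as.data.frame(out$pevback_model)
  expect_equal(ptab$model, c("base", "+EV:EV_back", "+Congruency:Accuracy"))
  expect_true(all(is.finite(ptab$AIC)))
  am <- out$accuracy_models
  expect_true(all(c("congruent", "incongruent") %in% am$subset))
  expect_true(all(am$chisq >= 0))
  expect_equal(sum(am$step == 1), 6)  # 3 candidate terms per subset
})

test_that("between-subject coupling is recovered from a hierarchical simulation", {
  d <- fixture_design()
  S <- 16
  set.seed(42)
  lam <- 1.0 * exp(rnorm(S, 0, 0.6))
  vs <- list(); cx <- list(); eb <- list(); beh <- list()
  for (k in 1:S) {
    sd0 <- 6000 + k
    bp <- behavior_params()
    bp$beta_cong <- bp$beta_cong + 0.06 * (lam[k] - 1)
    bp$beta_cong_evback <- bp$beta_cong_evback + 0.03 * (lam[k] - 1)
    bh <- simulate_behavior(d, bp, 1, sd0); bh$subject <- k
    cb <- make_codebook(96, 0.5, 0.7, sd0 + 1)
    np <- neural_params(n_voxels = 96); np$lambda <- lam[k]
    ps <- simulate_patterns(d, bh, cb, np, sd0 + 2)
    vs[[k]] <- loro_decode(ps, "value", seed = sd0, subject = k)
    cx[[k]] <- loro_decode(ps, "context", seed = sd0, subject = k)
    eb[[k]] <- ovr_evback_decode(ps, seed = sd0, subject = k)
    beh[[k]] <- bh
  }
  behav <- do.call(rbind, beh)
  class(behav) <- c("cv_behavior", "data.frame")
  recs <- make_link_records(rbind_probs_list(vs), rbind_probs_list(cx),
                            rbind_probs_list(eb), d, behav)
  se <- subject_effects(behav, recs)
  expect_equal(nrow(se), S)
  sc <- subject_correlations(se)
  r <- sc$r[sc$neural == "slope_evback_pev" & sc$behavioural == "slope_cong_rt"]
  expect_lt(r, 0)   # stronger competition: more negative neural slope, larger RT effect
  # identical columns correlate perfectly
  se2 <- se
  se2$slope_ctx_pev <- se2$slope_cong_rt
  sc2 <- subject_correlations(se2)
  expect_equal(sc2$r[sc2$neural == "slope_ctx_pev" &
                       sc2$behavioural == "slope_cong_rt"], 1)
  # constant column -> NA with n reported
  se3 <- se
  se3$slope_p2d_pev <- 0
  sc3 <- subject_correlations(se3)
  expect_true(is.na(sc3$r[sc3$neural == "slope_p2d_pev" &
                            sc3$behavioural == "slope_cong_rt"]))
  # permuted subject labels: coupling destroyed
  set.seed(1)
  perm_r <- replicate(20, {
    sp <- se
    sp$slope_cong_rt <- sample(sp$slope_cong_rt)
    subject_correlations(sp)$r[1]
  })
  expect_lt(mean(abs(perm_r) >= abs(r)), 0.2)
})
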