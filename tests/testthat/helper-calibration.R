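# Null-calibration harnesses for the type-I-error suites. Each returns a
# matrix of p-values (tests x replicates) from data generated under the
# all-null world. Sizes are reduced (small cohorts, few voxels) so that 800
# replicates run in minutes; the replicate index seeds every draw.

# RT ladder: null behavioural world on a 1-block design, 8 subjects
calib_rt_ladder <- function(n_reps, design, n_subjects = 8) {
  p0 <- null_behavior_params()
  sapply(seq_len(n_reps), function(r) {
    bh <- simulate_behavior(design, p0, n_subjects, 200000 + r)
    tab <- as.data.frame(fit_rt_ladder(bh))
    tab$p[2:4]
  })
}

# Accuracy ladder on the same generator
calib_acc_ladder <- function(n_reps, design, n_subjects = 8) {
  p0 <- null_behavior_params()
  sapply(seq_len(n_reps), function(r) {
    bh <- simulate_behavior(design, p0, n_subjects, 300000 + r)
    tab <- as.data.frame(fit_accuracy_ladder(bh))
    tab$p[2:4]
  })
}

# RDM model tests on pure-noise patterns, 5 subjects x 48 voxels
calib_rdm <- function(n_reps, n_subjects = 5, v = 48) {
  np <- null_neural_params(n_voxels = v)
  sapply(seq_len(n_reps), function(r) {
    cells <- sim_rdm_cells(np, n_subjects, 400000 + 10 * r, v)
    as.data.frame(fit_rdm_models(cells))$p
  })
}

# Linking models on a record-level null: class probabilities drawn from
# subject-heterogeneous flat Dirichlets, independent of every covariate --
# the dependence structure the zero-signal pipeline induces, at a fraction
# of the cost of decoding 800 cohorts.
null_link_records <- function(design, S, seed) {
  set.seed(seed)
  tr <- design$trials
  do.call(rbind, lapply(seq_len(S), function(k) {
    x <- tr
    conc <- exp(stats::rnorm(1, log(2), 0.3))
    g <- matrix(stats::rgamma(nrow(x) * 3, conc), ncol = 3)
    P <- clip_probs(g / rowSums(g))
    lev <- c(30, 50, 70)
    x$subject <- k
    for (i in 1:3) x[[paste0("v_prob_", lev[i])]] <- P[, i]
    M <- mlogit_probs(P)
    for (i in 1:3) x[[paste0("v_mlogit_", lev[i])]] <- M[, i]
    x$P_EV <- P[cbind(seq_len(nrow(x)), match(x$EV, lev))]
    x$mlogit_P_EV <- M[cbind(seq_len(nrow(x)), match(x$EV, lev))]
    ib <- match(x$EV_back, lev)
    x$P_EVback <- ifelse(is.na(ib), NA, P[cbind(seq_len(nrow(x)), ib)])
    x$mlogit_P_EVback <- ifelse(is.na(ib), NA, M[cbind(seq_len(nrow(x)), ib)])
    other <- ifelse(is.na(x$EV_back) | x$EV_back == x$EV, NA,
                    150 - x$EV - x$EV_back)
    # other level: {30,50,70} sums to 150
    io <- match(other, lev)
    x$P_other <- ifelse(is.na(io), NA, P[cbind(seq_len(nrow(x)), io)])
    x$mlogit_P_other <- ifelse(is.na(io), NA, M[cbind(seq_len(nrow(x)), io)])
    x$P_context <- clip_probs(stats::rbeta(nrow(x), 3, 2))
    x$logit_P_context <- logit(x$P_context)
    x$P_EVback_2D <- ifelse(x$dim == "2D",
                            clip_probs(stats::rbeta(nrow(x), 2, 2)), NA)
    x$other_value <- other
    x$other_on_screen <- !is.na(other) &
      (other == x$rel_left | other == x$rel_right |
         (!is.na(x$irr_left) & (other == x$irr_left | other == x$irr_right)))
    x$similarity_back <- ifelse(is.na(x$EV_back), NA,
                                as.integer(x$EV_back %in% c(x$EV - 20, x$EV)))
    x$ev_match <- as.integer(!is.na(x$EV_back) & x$EV == x$EV_back)
    x$accuracy <- 1L
    for (cn in c("logit_P_context", "mlogit_P_EV", "mlogit_P_EVback",
                 "P_EVback_2D")) {
      z <- x[[cn]]
      ok <- !is.na(z)
      z[ok] <- (z[ok] - mean(z[ok])) / stats::sd(z[ok])
      x[[paste0("z_", cn)]] <- z
    }
    x
  })) -> out
  class(out) <- c("cv_link", "data.frame")
  out
}

calib_linking <- function(n_reps, design, S = 8) {
  sapply(seq_len(n_reps), function(r) {
    recs <- null_link_records(design, S, 500000 + r)
    vs <- as.data.frame(fit_value_similarity(recs))
    pev <- as.data.frame(fit_pev_models(recs))
    pf <- as.data.frame(fit_pev_full(recs))
    c(value_sim = vs$p[vs$model == "+|EV-class|"],
      value_sim_evback = vs$p[vs$model == "+|EV-class|:EV_back"],
      evback = pev$p[pev$model == "+EV_back"],
      pctx = pev$p[pev$model == "+logit(P_context)"],
      p2d = pf$p[pf$model == "+P_EVback_2D"],
      moderation = pf$p[pf$model == "+P_context:P_EVback_2D"])
  })
}
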