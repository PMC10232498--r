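# Linking classifier read-outs to design variables and behaviour: the value
# similarity model, the models of P_EV (competition by EV_back, coupling to
# the context signal, moderation by the background classifier), the
# EV/EV_back/Other correlation asymmetry, the models of behavioural accuracy
# from neural probabilities, and the between-subject couplings.

#' Assemble per-trial linking records from the three classifiers
#'
#' Joins the value-classifier, context-classifier and background-classifier
#' probability tables on (subject, trial) and derives: `P_EV` (probability
#' of the trial's objective value class), `P_EVback` and `P_other` (value
#' classifier probabilities of the background value and of the third value,
#' the latter defined only when EV != EV_back), `P_context` (probability of
#' the true context) with its logit, `P_EVback_2D` (background classifier,
#' correct class), multinomial-logit transforms, within-subject z-scaled
#' versions (prefix `z_`), the value/perceptual similarity scores per class
#' and the `other_on_screen` filter flag.
#'
#' @param value_probs,context_probs `cv_probs` from [loro_decode()].
#' @param evback_probs `cv_probs` from [ovr_evback_decode()] or NULL.
#' @param design `cv_design`.
#' @param behavior `cv_behavior` or NULL; adds `rt` and nuisance regressors.
#' @return data.frame of class `cv_link`, one row per predicted trial.
#' @export
make_link_records <- function(value_probs, context_probs, evback_probs = NULL,
                              design, behavior = NULL) {
  lev <- c(30, 50, 70)
  d <- transform_probs(value_probs)
  names(d)[names(d) %in% paste0("prob_", lev)] <-
    paste0("v_prob_", lev)
  names(d)[names(d) %in% paste0("mlogit_", lev)] <-
    paste0("v_mlogit_", lev)
  cp <- transform_probs(context_probs)
  d$P_context <- ifelse(d$context == "color", cp$prob_color[match(
    paste(d$subject, d$gtrial), paste(cp$subject, cp$gtrial))],
    cp$prob_motion[match(paste(d$subject, d$gtrial),
                         paste(cp$subject, cp$gtrial))])
  d$logit_P_context <- logit(d$P_context)
  if (!is.null(evback_probs)) {
    key <- paste(evback_probs$subject, evback_probs$gtrial)
    i <- match(paste(d$subject, d$gtrial), key)
    pb <- as.matrix(evback_probs[paste0("prob_", lev)])
    d$P_EVback_2D <- ifelse(is.na(i) | is.na(d$EV_back), NA_real_,
                            pb[cbind(i, match(d$EV_back, lev))])
  } else d$P_EVback_2D <- NA_real_
  vp <- as.matrix(d[paste0("v_prob_", lev)])
  vm <- as.matrix(d[paste0("v_mlogit_", lev)])
  d$P_EV <- vp[cbind(seq_len(nrow(d)), match(d$EV, lev))]
  d$mlogit_P_EV <- vm[cbind(seq_len(nrow(d)), match(d$EV, lev))]
  ib <- match(d$EV_back, lev)
  d$P_EVback <- ifelse(is.na(ib), NA_real_, vp[cbind(seq_len(nrow(d)), ib)])
  d$mlogit_P_EVback <- ifelse(is.na(ib), NA_real_, vm[cbind(seq_len(nrow(d)), ib)])
  other <- ifelse(is.na(d$EV_back) | d$EV_back == d$EV, NA_real_,
                  vapply(seq_len(nrow(d)), function(i) {
                    o <- setdiff(lev, c(d$EV[i], d$EV_back[i]))
                    if (length(o) == 1) o else NA_real_
                  }, numeric(1)))
  d$other_value <- other
  io <- match(other, lev)
  d$P_other <- ifelse(is.na(io), NA_real_, vp[cbind(seq_len(nrow(d)), io)])
  d$mlogit_P_other <- ifelse(is.na(io), NA_real_, vm[cbind(seq_len(nrow(d)), io)])
  # design columns: irrelevant values, switch distance, side
  tr <- design$trials[, c("gtrial", "irr_left", "irr_right", "rel_left",
                          "rel_right", "switch_distance")]
  d <- merge(d, tr, by = "gtrial", sort = FALSE)
  d$other_on_screen <- !is.na(d$other_value) &
    (d$other_value == d$rel_left | d$other_value == d$rel_right |
       (!is.na(d$irr_left) & d$other_value == d$irr_left) |
       (!is.na(d$irr_right) & d$other_value == d$irr_right))
  d$similarity_back <- ifelse(is.na(d$EV_back), NA_integer_,
                              as.integer(d$EV_back %in% c(d$EV - 20, d$EV)))
  d$ev_match <- as.integer(!is.na(d$EV_back) & d$EV == d$EV_back)
  if (!is.null(behavior)) {
    bh <- behavior[, c("subject", "gtrial", "rt", "accuracy", "answered")]
    names(bh)[names(bh) == "accuracy"] <- "beh_accuracy"
    d <- merge(d, bh, by = c("subject", "gtrial"), sort = FALSE)
  }
  # within-subject z-scaled transforms, as used by the linking models
  for (cn in c("logit_P_context", "mlogit_P_EV", "mlogit_P_EVback",
               "P_EVback_2D")) {
    d[[paste0("z_", cn)]] <- stats::ave(d[[cn]], d$subject, FUN = function(x) {
      x[!is.na(x)] <- zscale(x[!is.na(x)]); x
    })
  }
  d <- d[order(d$subject, d$gtrial), ]
  class(d) <- c("cv_link", "data.frame")
  d
}

# shared z-scaled design regressors on a linking subset
add_link_regressors <- function(d) {
  d$zEVback <- zscale(d$EV_back)
  d$zEV <- zscale(d$EV)
  # congruency from the design: irrelevant max on target side = congruent (-1)
  irr_ts <- ifelse(d$target_side == "left", d$irr_left, d$irr_right)
  d$cong <- ifelse(d$dim == "2D",
                   ifelse(!is.na(irr_ts) & irr_ts == pmax(d$irr_left, d$irr_right),
                          -1, 1), 0)
  d$congruency <- ifelse(d$dim == "2D",
                         ifelse(d$cong == 1, "incongruent", "congruent"),
                         NA_character_)
  d$zt <- zscale(d$gtrial)
  d$side_c <- ifelse(d$target_side == "right", 1, -1)
  d$zswitch <- zscale(d$switch_distance)
  d$ctx_c <- ifelse(d$context == "motion", 1, -1)
  d$subject <- factor(d$subject)
  d
}

#' Value-similarity model of the classifier probabilities
#'
#' Stacks the three class probabilities per trial and fits beta regressions
#' of `P(class)` on the absolute difference |EV - class| and its interaction
#' with EV_back. Because the three probabilities of a trial sum to one, the
#' stacked rows are dependent and a pooled likelihood is anticonservative;
#' inference is therefore two-stage (per-subject fits, one-sample t-tests of
#' the coefficients across subjects) with per-subject AICs summed for model
#' comparison. A perceptual control replaces the value distance with a
#' feature-overlap distance between the test trial's displayed features and
#' the training exemplars of each class (identical to the value distance on
#' 1D trials); both AICs are reported.
#'
#' @param recs `cv_link` records.
#' @return `cv_effect_table`.
#' @export
fit_value_similarity <- function(recs) {
  lev <- c(30, 50, 70)
  d <- recs[recs$accuracy == 1, ]
  long <- do.call(rbind, lapply(seq_along(lev), function(i) {
    x <- d
    x$class <- lev[i]
    x$P <- clip_probs(x[[paste0("v_prob_", lev[i])]])
    x$value_sim <- abs(x$EV - x$class)
    # feature overlap between displayed features and class exemplars
    ov_rel <- (abs(x$EV - x$class) == 0) * 2 + (abs(x$EV - x$class) == 20) * 1
    ov_irr <- ifelse(x$dim == "2D",
                     (!is.na(x$irr_left) & (x$irr_left == x$class | x$irr_left == x$class - 20)) +
                       (!is.na(x$irr_right) & (x$irr_right == x$class | x$irr_right == x$class - 20)),
                     0)
    x$perc_sim <- 20 * (2 - (ov_rel + ov_irr))
    x
  }))
  long <- add_link_regressors(long)
  long$zvs <- zscale(long$value_sim)
  long$zperc <- zscale(long$perc_sim)
  long$zEVb0 <- ifelse(is.na(long$EV_back), 0, zscale_na(long$EV_back))
  # two-stage inference: the three class probabilities of a trial sum to one,
  # so the stacked rows are dependent and a pooled likelihood-ratio test is
  # anticonservative; per-subject fits + cross-subject t-tests calibrate.
  per <- two_stage_beta(long, P ~ zvs + zvs:zEVb0, c("zvs", "zvs:zEVb0"))
  perp <- two_stage_beta(long, P ~ zperc, "zperc")
  tab <- rbind(
    two_stage_row(per, "zvs", "+|EV-class|"),
    two_stage_row(per, "zvs:zEVb0", "+|EV-class|:EV_back"),
    two_stage_row(perp, "zperc", "perceptual_similarity"))
  new_effect_table(tab, "two-stage betareg_ml + t-test")
}

# fit a beta regression per subject, return coefficient matrix + summed AIC
two_stage_beta <- function(data, formula, terms) {
  per <- lapply(split(data, data$subject, drop = TRUE), function(s) {
    fit <- betareg_ml(formula, s)
    cf <- stats::coef(fit)
    # interaction names may be order-reversed by the terms machinery
    get1 <- function(tm) {
      if (tm %in% names(cf)) return(cf[[tm]])
      rev_tm <- paste(rev(strsplit(tm, ":")[[1]]), collapse = ":")
      if (rev_tm %in% names(cf)) cf[[rev_tm]] else NA_real_
    }
    c(vapply(terms, get1, numeric(1)), .aic = stats::AIC(fit))
  })
  do.call(rbind, per)
}

two_stage_row <- function(per, term, model) {
  x <- per[, term]
  x <- x[is.finite(x)]
  tt <- if (length(x) >= 2 && stats::sd(x) > 0) stats::t.test(x)
  else list(statistic = c(t = 0), parameter = c(df = length(x) - 1),
            p.value = 1)
  data.frame(model = model, term = term, estimate = mean(x),
             se = stats::sd(x) / sqrt(length(x)),
             chisq = NA_real_, df = unname(tt$parameter), p = tt$p.value,
             AIC = sum(per[, ".aic"]), t = unname(tt$statistic))
}

zscale_na <- function(x) {
  z <- rep(0, length(x))
  ok <- !is.na(x)
  z[ok] <- zscale(x[ok])
  z
}

#' Models of the decoded value probability P_EV
#'
#' On behaviourally accurate 2D trials, models P_EV on EV_back and
#' logit(P_context) (beta regression per subject, coefficients t-tested
#' across subjects; per-subject AICs summed), plus AIC-compared controls:
#' minimum irrelevant value instead of EV_back, added Congruency terms, the
#' perceptual presence of the EV_back feature in the training class, and an
#' EV = EV_back match indicator.
#'
#' @param recs `cv_link` records.
#' @return `cv_effect_table`.
#' @export
fit_pev_models <- function(recs) {
  d <- recs[recs$dim == "2D" & recs$accuracy == 1, ]
  d <- add_link_regressors(d)
  d$P <- clip_probs(d$P_EV)
  d$zmin_irr <- zscale(pmin(d$irr_left, d$irr_right))
  per <- two_stage_beta(d, P ~ zEVback + z_logit_P_context,
                        c("zEVback", "z_logit_P_context"))
  tab <- rbind(two_stage_row(per, "zEVback", "+EV_back"),
               two_stage_row(per, "z_logit_P_context", "+logit(P_context)"))
  ctrls <- list(
    ctrl_min_irrelevant = P ~ zmin_irr + z_logit_P_context,
    ctrl_congruency = P ~ zEVback + z_logit_P_context + cong + cong:zEVback,
    ctrl_perceptual_back = P ~ similarity_back + z_logit_P_context,
    ctrl_ev_match = P ~ zEVback + z_logit_P_context + ev_match)
  ctr <- do.call(rbind, lapply(names(ctrls), function(nm) {
    aics <- two_stage_beta(d, ctrls[[nm]], character(0))[, ".aic"]
    data.frame(model = nm, term = NA_character_, estimate = NA_real_,
               se = NA_real_, chisq = NA_real_, df = NA_integer_,
               p = NA_real_, AIC = sum(aics), t = NA_real_)
  }))
  new_effect_table(rbind(tab, ctr), "two-stage betareg_ml + t-test")
}

#' EV vs EV_back vs Other competition correlations
#'
#' On accurate 2D trials with EV != EV_back and the third ("other") value's
#' feature on screen, the three value-classifier probabilities are
#' multinomial-logit transformed and, per subject, Spearman rank
#' correlations corr(P_EV, P_EVback) and corr(P_EV, P_other) are computed,
#' Fisher z-transformed, and compared by a paired t-test. A regression twin
#' adds mlogit(P_EVback) or mlogit(P_other) to the P_EV model and compares
#' AICs. Subjects with fewer than `min_trials` qualifying trials are
#' excluded.
#'
#' @param recs `cv_link` records.
#' @param min_trials minimum qualifying trials per subject (default 10).
#' @return list with `per_subject` (Fisher-z correlations), `paired_test`,
#'   and `aic` (regression twin).
#' @export
competition_correlation <- function(recs, min_trials = 10L) {
  d <- recs[recs$dim == "2D" & recs$accuracy == 1 &
              !is.na(recs$P_other) & recs$other_on_screen, ]
  counts <- table(d$subject)
  keep <- names(counts)[counts >= min_trials]
  if (length(keep) < length(counts))
    message(length(counts) - length(keep),
            " subject(s) excluded: fewer than ", min_trials, " qualifying trials")
  d <- d[d$subject %in% keep, ]
  per <- do.call(rbind, lapply(split(d, d$subject, drop = TRUE), function(s) {
    r_back <- stats::cor(s$mlogit_P_EV, s$mlogit_P_EVback, method = "spearman")
    r_other <- stats::cor(s$mlogit_P_EV, s$mlogit_P_other, method = "spearman")
    data.frame(subject = s$subject[1], n = nrow(s),
               z_back = fisher_z(r_back), z_other = fisher_z(r_other))
  }))
  tt <- if (nrow(per) >= 2 && stats::sd(per$z_back - per$z_other) > 0)
    stats::t.test(per$z_back, per$z_other, paired = TRUE)
  else list(statistic = c(t = 0), parameter = c(df = nrow(per) - 1), p.value = 1)
  dd <- add_link_regressors(d)
  dd$P <- clip_probs(dd$P_EV)
  dd$zml_back <- zscale(dd$mlogit_P_EVback)
  dd$zml_other <- zscale(dd$mlogit_P_other)
  mb <- betareg_ml(P ~ subject + zEVback + z_logit_P_context + zml_back, dd)
  mo <- betareg_ml(P ~ subject + zEVback + z_logit_P_context + zml_other, dd)
  list(per_subject = per,
       paired_test = data.frame(t = unname(tt$statistic),
                                df = unname(tt$parameter), p = tt$p.value,
                                mean_z_back = mean(per$z_back),
                                mean_z_other = mean(per$z_other)),
       aic = data.frame(model = c("mlogit_P_EVback", "mlogit_P_other"),
                        AIC = c(stats::AIC(mb), stats::AIC(mo))))
}

#' Full model of P_EV with background-classifier moderation
#'
#' Models P_EV on logit(P_context), the background classifier's probability
#' of the correct class (P_EVback_2D) and their interaction, with EV_back
#' intercepts per subject (which absorb the EV_back main effect). The
#' default engine fits the beta regression per subject and t-tests the
#' P_EVback_2D and interaction coefficients across subjects;
#' `engine = "gaussian"` fits a pooled least-squares ladder on logit(P_EV)
#' with likelihood-ratio tests (used for the intercept-absorption
#' invariance check).
#'
#' @param recs `cv_link` records with background-classifier probabilities.
#' @param engine `"beta"` or `"gaussian"`.
#' @return `cv_effect_table`.
#' @export
fit_pev_full <- function(recs, engine = c("beta", "gaussian")) {
  engine <- match.arg(engine)
  d <- recs[recs$dim == "2D" & recs$accuracy == 1 & !is.na(recs$P_EVback_2D), ]
  d <- add_link_regressors(d)
  d$P <- clip_probs(d$P_EV)
  d$nest <- factor(d$EV_back)   # within subject: EV_back-level intercepts
  d$zp2d <- d$z_P_EVback_2D
  if (engine == "beta") {
    per <- two_stage_beta(d, P ~ nest + z_logit_P_context + zp2d +
                            z_logit_P_context:zp2d,
                          c("zp2d", "z_logit_P_context:zp2d"))
    tab <- rbind(two_stage_row(per, "zp2d", "+P_EVback_2D"),
                 two_stage_row(per, "z_logit_P_context:zp2d",
                               "+P_context:P_EVback_2D"))
    return(new_effect_table(tab,
                            "two-stage betareg_ml + t-test (nested EV_back intercepts)"))
  }
  d$ly <- logit(d$P)
  d$snest <- interaction(d$subject, d$nest)
  m0 <- stats::lm(ly ~ snest + z_logit_P_context, d)
  m1 <- stats::update(m0, . ~ . + zp2d)
  m2 <- stats::update(m1, . ~ . + z_logit_P_context:zp2d)
  ladder_table(list(base = m0, `+P_EVback_2D` = m1,
                    `+P_context:P_EVback_2D` = m2),
               c(NA, "zp2d", "z_logit_P_context:zp2d"),
               "gaussian (nested EV_back intercepts)",
               function(m) stats::coef(m),
               function(m) rep(NA_real_, length(stats::coef(m))))
}

#' Neural probabilities and behavioural outcomes
#'
#' Two analyses: (a) a beta-regression model of the value classifier's
#' P_EVback on 2D trials including behaviourally wrong ones, testing the
#' EV x EV_back interaction and the Congruency x Accuracy interaction on top
#' of the nuisance baseline; (b) per congruency subset, logistic models of
#' accuracy with a two-step term selection: main effects of logit(P_context),
#' mlogit(P_EV) and mlogit(P_EVback) are LR-tested one at a time, the
#' significant ones adopted, and pairwise interactions tested in a second
#' step.
#'
#' @param recs `cv_link` records (with behavioural accuracy on the rows).
#' @param alpha adoption threshold of the selection procedure.
#' @return list with `pevback_model` (`cv_effect_table`) and `accuracy_models`
#'   (data.frame of LR tests per subset/step).
#' @export
fit_behavior_links <- function(recs, alpha = 0.05) {
  d <- recs[recs$dim == "2D", ]
  d <- add_link_regressors(d)
  d$P <- clip_probs(d$P_EVback)
  d$acc <- d$accuracy
  m0 <- betareg_ml(P ~ subject + zt + side_c + zswitch + ctx_c, d)
  m1 <- betareg_ml(P ~ subject + zt + side_c + zswitch + ctx_c + zEV:zEVback, d)
  m2 <- betareg_ml(P ~ subject + zt + side_c + zswitch + ctx_c + zEV:zEVback +
                     cong:acc, d)
  ptab <- ladder_table(list(base = m0, `+EV:EV_back` = m1,
                            `+Congruency:Accuracy` = m2),
                       c(NA, "zEV:zEVback", "cong:acc"), "betareg_ml",
                       function(m) stats::coef(m),
                       function(m) rep(NA_real_, length(stats::coef(m))))
  sel <- list()
  for (side in c("congruent", "incongruent")) {
    s <- d[!is.na(d$congruency) & d$congruency == side, ]
    if (length(unique(s$acc)) < 2) {
      message("subset ", side, ": no behaviourally wrong trials; accuracy model skipped")
      next
    }
    base <- stats::glm(acc ~ zEV + zt + side_c + zswitch + ctx_c + subject,
                       family = stats::binomial(), data = s)
    cand <- c("z_logit_P_context", "z_mlogit_P_EV", "z_mlogit_P_EVback")
    step1 <- lapply(cand, function(tm) {
      m <- stats::update(base, stats::as.formula(paste(". ~ . +", tm)))
      lt <- lr_test(base, m)
      data.frame(subset = side, step = 1L, term = tm, chisq = lt$chisq,
                 df = lt$df, p = lt$p)
    })
    step1 <- do.call(rbind, step1)
    adopted <- step1$term[step1$p < alpha]
    f1 <- if (length(adopted))
      stats::update(base, stats::as.formula(paste(". ~ . +",
                                                  paste(adopted, collapse = "+"))))
    else base
    pairs <- utils::combn(cand, 2, simplify = FALSE)
    step2 <- lapply(pairs, function(pr) {
      tm <- paste(pr, collapse = ":")
      m <- stats::update(f1, stats::as.formula(paste(". ~ . +", tm)))
      lt <- lr_test(f1, m)
      data.frame(subset = side, step = 2L, term = tm, chisq = lt$chisq,
                 df = lt$df, p = lt$p)
    })
    sel[[side]] <- rbind(step1, do.call(rbind, step2))
  }
  list(pevback_model = ptab,
       accuracy_models = if (length(sel)) do.call(rbind, sel) else NULL)
}

#' Per-subject neural and behavioural effect estimates
#'
#' Behavioural slopes (Congruency and Congruency x EV_back on log RT) come
#' from a mixed model with subject random slopes (BLUP + fixed effect).
#' Neural slopes (EV_back, logit(P_context) and P_EVback_2D on logit(P_EV))
#' come from per-subject least-squares fits -- the two-stage engine, since
#' no beta-family random-slope engine is available -- and the per-subject
#' Fisher-z competition correlation is taken from
#' [competition_correlation()].
#'
#' @param behavior `cv_behavior` records.
#' @param recs `cv_link` records.
#' @return data.frame with one row per subject.
#' @export
subject_effects <- function(behavior, recs) {
  b <- behavior[behavior$dim == "2D" & behavior$answered & behavior$accuracy == 1, ]
  b$lrt <- log(b$rt)
  b <- add_behavior_regressors(b)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  fm <- lme4::lmer(lrt ~ zEV + zt + side_c + zswitch + ctx_c + cong +
                     cong:zEVback + (1 + cong + cong:zEVback | subject),
                   data = b, REML = FALSE, control = ctrl)
  re <- lme4::ranef(fm)$subject
  fe <- lme4::fixef(fm)
  beh <- data.frame(subject = as.integer(rownames(re)),
                    slope_cong_rt = fe["cong"] + re[, "cong"],
                    slope_cong_evback_rt = fe["cong:zEVback"] + re[, "cong:zEVback"])
  d <- recs[recs$dim == "2D" & recs$accuracy == 1, ]
  d <- add_link_regressors(d)
  d$ly <- logit(clip_probs(d$P_EV))
  neu <- do.call(rbind, lapply(split(d, d$subject, drop = TRUE), function(s) {
    m <- stats::lm(ly ~ zEVback + z_logit_P_context, s)
    p2 <- if (all(is.na(s$P_EVback_2D))) NA_real_ else
      stats::coef(stats::lm(ly ~ zEVback + z_P_EVback_2D, s))["z_P_EVback_2D"]
    data.frame(subject = as.integer(as.character(s$subject[1])),
               slope_evback_pev = stats::coef(m)["zEVback"],
               slope_ctx_pev = stats::coef(m)["z_logit_P_context"],
               slope_p2d_pev = unname(p2))
  }))
  cc <- competition_correlation(recs)$per_subject
  cc$subject <- as.integer(as.character(cc$subject))
  out <- merge(merge(beh, neu, by = "subject"),
               cc[, c("subject", "z_back", "z_other")], by = "subject",
               all.x = TRUE)
  names(out)[names(out) == "z_back"] <- "corr_pev_pevback_z"
  names(out)[names(out) == "z_other"] <- "corr_pev_pother_z"
  rownames(out) <- NULL
  out
}

#' Between-subject correlations of neural and behavioural effects
#'
#' Pearson correlations with Spearman rank-based p-values between each
#' neural column and each behavioural column of a subject-effects table.
#' Constant columns yield NA with a note.
#'
#' @param effects output of [subject_effects()].
#' @param neural,behavioural column names to correlate.
#' @return data.frame with `neural`, `behavioural`, `r`, `p_spearman`, `n`.
#' @export
subject_correlations <- function(effects,
                                 neural = c("slope_evback_pev", "slope_ctx_pev",
                                            "slope_p2d_pev", "corr_pev_pevback_z"),
                                 behavioural = c("slope_cong_rt",
                                                 "slope_cong_evback_rt")) {
  stopifnot(nrow(effects) >= 10)
  out <- list()
  for (nv in neural) for (bv in behavioural) {
    x <- effects[[nv]]; y <- effects[[bv]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      out[[length(out) + 1L]] <- data.frame(neural = nv, behavioural = bv,
                                            r = NA_real_, p_spearman = NA_real_,
                                            n = length(x))
      next
    }
    r <- stats::cor(x, y)
    p <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE)$p.value)
    out[[length(out) + 1L]] <- data.frame(neural = nv, behavioural = bv,
                                          r = r, p_spearman = p, n = length(x))
  }
  do.call(rbind, out)
}
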