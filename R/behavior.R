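# Trial-wise behaviour: a generative twin of the reaction-time and accuracy
# models, and the hierarchical model-comparison ladders used to analyse them.
#
# log RT is linear in EV, Congruency, Congruency x EV_back (and optionally
# Congruency x EV) plus nuisance terms (trial index, target side, trials
# since context switch, context), with a Gaussian subject random intercept
# and Gaussian residual. Accuracy is Bernoulli with a logit-linear predictor
# of the same shape, where the fourth term is Congruency x switch. All
# regressors are z-scaled before fitting, and the simulator applies the same
# scaling so planted coefficients are on the fitted scale. Congruency is
# effects-coded: incongruent = +1, congruent = -1 (0 on 1D trials), so a
# positive coefficient means slower/less accurate incongruent trials.

#' Parameters of the behavioural generative model
#'
#' Coefficients are on the scale of z-scored regressors; RT coefficients in
#' log-seconds, accuracy coefficients in logits. Defaults plant a near-ceiling
#' accuracy (~0.9), a small EV speed-up, a congruency slow-down and a
#' Congruency x EV_back interaction of the sign reported for this task family.
#'
#' @param beta0 RT intercept (log-seconds).
#' @param beta_ev,beta_cong,beta_cong_evback,beta_cong_ev RT effect slopes.
#' @param nu_trial,nu_side,nu_switch,nu_context RT nuisance slopes.
#' @param subject_sd SD of the subject random intercept (log-seconds).
#' @param sigma residual SD (log-seconds).
#' @param acc_beta0 accuracy intercept (logit).
#' @param acc_ev,acc_cong,acc_cong_evback,acc_cong_switch accuracy slopes.
#' @param acc_nu_trial,acc_nu_side,acc_nu_switch,acc_nu_context accuracy nuisances.
#' @param acc_subject_sd SD of the subject intercept on the logit scale.
#' @param p_noanswer probability of a missing response.
#' @return list of class `cv_behavior_params`.
#' @export
behavior_params <- function(beta0 = log(0.9), beta_ev = -0.03, beta_cong = 0.03,
                            beta_cong_evback = 0.015, beta_cong_ev = 0,
                            nu_trial = 0.01, nu_side = 0.005,
                            nu_switch = -0.01, nu_context = 0.005,
                            subject_sd = 0.1, sigma = 0.15,
                            acc_beta0 = 2.2, acc_ev = 0.1, acc_cong = -0.3,
                            acc_cong_evback = -0.2, acc_cong_switch = 0.15,
                            acc_nu_trial = 0, acc_nu_side = 0,
                            acc_nu_switch = 0.15, acc_nu_context = 0,
                            acc_subject_sd = 0.3, p_noanswer = 0.01) {
  p <- as.list(environment())
  stopifnot(p$sigma > 0, p$subject_sd >= 0, p$acc_subject_sd >= 0,
            p$p_noanswer >= 0, p$p_noanswer < 1)
  structure(p, class = "cv_behavior_params")
}

#' @rdname behavior_params
#' @details `null_behavior_params()` keeps the intercepts and variance
#'   components but sets every effect and nuisance slope to zero; it is the
#'   null generative model used for type-I-error calibration.
#' @export
null_behavior_params <- function() {
  behavior_params(beta_ev = 0, beta_cong = 0, beta_cong_evback = 0,
                  beta_cong_ev = 0, nu_trial = 0, nu_side = 0, nu_switch = 0,
                  nu_context = 0, acc_ev = 0, acc_cong = 0,
                  acc_cong_evback = 0, acc_cong_switch = 0, acc_nu_trial = 0,
                  acc_nu_side = 0, acc_nu_switch = 0, acc_nu_context = 0,
                  p_noanswer = 0)
}

# z-scaled regressors used by both the simulator and the fitting ladders.
add_behavior_regressors <- function(df) {
  is2d <- df$dim == "2D"
  df$cong <- ifelse(is2d, ifelse(df$congruency == "incongruent", 1, -1), 0)
  df$zEV <- zscale(df$EV)
  zb <- rep(0, nrow(df))
  if (any(is2d)) zb[is2d] <- zscale(df$EV_back[is2d])
  df$zEVback <- zb
  zim <- rep(0, nrow(df))
  if (any(is2d)) zim[is2d] <- zscale((df$irr_left[is2d] + df$irr_right[is2d]) / 2)
  df$zirrmean <- zim
  df$zt <- zscale(df$gtrial)
  df$side_c <- ifelse(df$target_side == "right", 1, -1)
  df$zswitch <- zscale(df$switch_distance)
  df$ctx_c <- ifelse(df$context == "motion", 1, -1)
  df
}

#' Simulate trial-wise reaction times and accuracy
#'
#' Draws, per subject, a random intercept and generates log-normal RTs and
#' Bernoulli accuracy from the behavioural generative model applied to the
#' design's trials. Regressors are standardized exactly as the fitting
#' functions standardize them.
#'
#' @param design `cv_design`.
#' @param params `cv_behavior_params`.
#' @param n_subjects number of simulated participants.
#' @param seed integer seed.
#' @return data.frame of class `cv_behavior`: one row per subject x trial
#'   with the design columns plus `subject`, `rt`, `accuracy`, `answered`,
#'   `choice_side`.
#' @export
simulate_behavior <- function(design, params = behavior_params(),
                              n_subjects, seed) {
  stopifnot(inherits(design, "cv_design"), inherits(params, "cv_behavior_params"))
  set.seed(subseed(seed, 5L))
  tr <- add_behavior_regressors(design$trials)
  n <- nrow(tr)
  out <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    g_rt <- stats::rnorm(1, 0, params$subject_sd)
    g_acc <- stats::rnorm(1, 0, params$acc_subject_sd)
    lp_rt <- params$beta0 + g_rt +
      params$beta_ev * tr$zEV + params$beta_cong * tr$cong +
      params$beta_cong_evback * tr$cong * tr$zEVback +
      params$beta_cong_ev * tr$cong * tr$zEV +
      params$nu_trial * tr$zt + params$nu_side * tr$side_c +
      params$nu_switch * tr$zswitch + params$nu_context * tr$ctx_c
    lp_acc <- params$acc_beta0 + g_acc +
      params$acc_ev * tr$zEV + params$acc_cong * tr$cong +
      params$acc_cong_evback * tr$cong * tr$zEVback +
      params$acc_cong_switch * tr$cong * tr$zswitch +
      params$acc_nu_trial * tr$zt + params$acc_nu_side * tr$side_c +
      params$acc_nu_switch * tr$zswitch + params$acc_nu_context * tr$ctx_c
    d <- tr
    d$subject <- k
    d$rt <- exp(lp_rt + stats::rnorm(n, 0, params$sigma))
    d$answered <- stats::runif(n) >= params$p_noanswer
    d$accuracy <- ifelse(d$answered,
                         as.integer(stats::runif(n) < inv_logit(lp_acc)),
                         NA_integer_)
    d$choice_side <- ifelse(!d$answered, NA_character_,
                            ifelse(d$accuracy == 1L, d$target_side,
                                   ifelse(d$target_side == "left", "right", "left")))
    out[[k]] <- d
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_behavior", class(res))
  res
}

new_effect_table <- function(df, engine) {
  attr(df, "engine") <- engine
  class(df) <- c("cv_effect_table", "data.frame")
  df
}

#' @export
print.cv_effect_table <- function(x, ...) {
  cat("Model-comparison table (engine:", attr(x, "engine"), ")\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) signif(v, 4))
  print(y, row.names = FALSE)
  invisible(x)
}

# LR test between two nested fits with a logLik method
lr_test <- function(m0, m1) {
  ll0 <- stats::logLik(m0); ll1 <- stats::logLik(m1)
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  df <- attr(ll1, "df") - attr(ll0, "df")
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

ladder_table <- function(fits, terms, engine, coef_fun, se_fun) {
  rows <- list()
  final <- fits[[length(fits)]]
  for (i in seq_along(fits)) {
    lt <- if (i == 1) list(chisq = NA_real_, df = NA_integer_, p = NA_real_)
    else lr_test(fits[[i - 1]], fits[[i]])
    tname <- terms[i]
    if (!is.na(tname) && !(tname %in% names(coef_fun(final))) &&
        grepl(":", tname)) {
      rev_name <- paste(rev(strsplit(tname, ":")[[1]]), collapse = ":")
      if (rev_name %in% names(coef_fun(final))) tname <- rev_name
    }
    est <- if (is.na(tname)) NA_real_ else coef_fun(final)[tname]
    se <- if (is.na(tname)) NA_real_ else se_fun(final)[tname]
    rows[[i]] <- data.frame(model = names(fits)[i], term = terms[i],
                            estimate = unname(est), se = unname(se),
                            chisq = lt$chisq, df = lt$df, p = lt$p,
                            AIC = stats::AIC(fits[[i]]))
  }
  new_effect_table(do.call(rbind, rows), engine)
}

#' Hierarchical comparison of 2D-trial log-RT models
#'
#' On correct, answered 2D trials with log RTs within 3 SD of the mean, fits
#' the nested mixed-model sequence baseline+EV -> +Congruency -> +EV_back ->
#' +Congruency:EV_back, each with the four nuisance terms and a subject
#' random intercept (ML fits), and reports likelihood-ratio tests between
#' adjacent models plus AICs. An alternative model replacing the EV_back
#' terms with the overall (mean) irrelevant value is fitted for AIC
#' comparison.
#'
#' @param records `cv_behavior` data.
#' @return `cv_effect_table` with one row per model.
#' @export
fit_rt_ladder <- function(records) {
  d <- records[records$dim == "2D" & records$answered & records$accuracy == 1, ]
  if (any(d$rt <= 0)) stop("non-positive RTs")
  d$lrt <- log(d$rt)
  d <- d[abs(d$lrt - mean(d$lrt)) <= 3 * stats::sd(d$lrt), ]
  d <- add_behavior_regressors(d)
  d$subject <- factor(d$subject)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  f0 <- lme4::lmer(lrt ~ zEV + zt + side_c + zswitch + ctx_c + (1 | subject),
                   data = d, REML = FALSE, control = ctrl)
  f1 <- stats::update(f0, . ~ . + cong)
  f2 <- stats::update(f1, . ~ . + zEVback)
  f3 <- stats::update(f2, . ~ . + cong:zEVback)
  falt <- stats::update(f1, . ~ . + zirrmean + cong:zirrmean)
  fits <- list(baseline_EV = f0, `+Congruency` = f1, `+EV_back` = f2,
               `+Congruency:EV_back` = f3, alt_overall_irrelevant = falt)
  terms <- c(NA, "cong", "zEVback", "cong:zEVback", NA)
  coefs <- function(m) lme4::fixef(m)
  ses <- function(m) {
    v <- sqrt(diag(as.matrix(stats::vcov(m))))
    stats::setNames(v, names(lme4::fixef(m)))
  }
  tab <- ladder_table(fits[1:4], terms[1:4], "lmer(ML)", coefs, ses)
  alt <- data.frame(model = "alt_overall_irrelevant", term = NA,
                    estimate = NA_real_, se = NA_real_, chisq = NA_real_,
                    df = NA_integer_, p = NA_real_, AIC = stats::AIC(falt))
  new_effect_table(rbind(as.data.frame(tab), alt), "lmer(ML)")
}

#' Hierarchical comparison of 2D-trial accuracy models
#'
#' Binomial ladder mirroring the RT ladder with the fourth term replaced by
#' Congruency x switch: baseline+EV -> +Congruency -> +Congruency:EV_back ->
#' +Congruency:switch, on answered 2D trials. The default engine uses fixed
#' subject intercepts (fast, and its likelihood-ratio tests are the
#' quantities calibrated by the package tests); `engine = "glmer"` uses a
#' subject random intercept instead. Complete separation (e.g. an
#' all-correct dataset) is flagged and a Haldane-corrected intercept-only
#' summary returned.
#'
#' @param records `cv_behavior` data.
#' @param engine `"glm"` (fixed subject intercepts) or `"glmer"`.
#' @return `cv_effect_table`; attribute `separation` is TRUE for degenerate
#'   input.
#' @export
fit_accuracy_ladder <- function(records, engine = c("glm", "glmer")) {
  engine <- match.arg(engine)
  d <- records[records$dim == "2D" & records$answered, ]
  d <- add_behavior_regressors(d)
  d$subject <- factor(d$subject)
  if (length(unique(d$accuracy)) < 2L) {
    n <- nrow(d); s <- sum(d$accuracy)
    tab <- new_effect_table(data.frame(
      model = "intercept_only", term = "(Intercept)",
      estimate = logit((s + 0.5) / (n + 1)), se = NA_real_, chisq = NA_real_,
      df = NA_integer_, p = NA_real_, AIC = NA_real_), engine)
    attr(tab, "separation") <- TRUE
    warning("complete separation: all responses identical; penalized intercept fit")
    return(tab)
  }
  if (engine == "glm") {
    f0 <- stats::glm(accuracy ~ zEV + zt + side_c + zswitch + ctx_c + subject,
                     family = stats::binomial(), data = d)
    coefs <- stats::coef
    ses <- function(m) sqrt(diag(stats::vcov(m)))
    eng <- "glm(fixed subject intercepts)"
  } else {
    f0 <- lme4::glmer(accuracy ~ zEV + zt + side_c + zswitch + ctx_c + (1 | subject),
                      family = stats::binomial(), data = d)
    coefs <- function(m) lme4::fixef(m)
    ses <- function(m) stats::setNames(sqrt(diag(as.matrix(stats::vcov(m)))),
                                       names(lme4::fixef(m)))
    eng <- "glmer"
  }
  f1 <- stats::update(f0, . ~ . + cong)
  f2 <- stats::update(f1, . ~ . + cong:zEVback)
  f3 <- stats::update(f2, . ~ . + cong:zswitch)
  sep <- any(abs(stats::predict(f3, type = "response") - 0.5) > 0.49999)
  fits <- list(baseline_EV = f0, `+Congruency` = f1,
               `+Congruency:EV_back` = f2, `+Congruency:switch` = f3)
  tab <- ladder_table(fits, c(NA, "cong", "cong:zEVback", "cong:zswitch"),
                      eng, coefs, ses)
  attr(tab, "separation") <- sep
  tab
}

#' Paired congruency contrasts on log RT
#'
#' Per subject, mean log RT is computed for congruent, incongruent and 1D
#' trials (correct answers only); paired t-tests compare incongruent vs 1D,
#' congruent vs 1D and incongruent vs congruent, with Benjamini-Hochberg
#' adjusted p-values. Subjects missing a condition are dropped with a
#' message.
#'
#' @param records `cv_behavior` data.
#' @return data.frame with one row per contrast: estimate (mean paired
#'   difference in log-seconds), t, df, p, p_adj.
#' @export
congruency_contrasts <- function(records) {
  d <- records[records$answered & records$accuracy == 1, ]
  d$condition <- ifelse(d$dim == "1D", "oneD", d$congruency)
  m <- tapply(log(d$rt), list(d$subject, d$condition), mean)
  need <- c("congruent", "incongruent", "oneD")
  m <- m[, need, drop = FALSE]
  keep <- stats::complete.cases(m)
  if (any(!keep)) message(sum(!keep), " subject(s) dropped: missing condition")
  m <- m[keep, , drop = FALSE]
  pair <- function(a, b) {
    dd <- m[, a] - m[, b]
    if (stats::sd(dd) == 0) return(data.frame(
      contrast = paste(a, "vs", b), estimate = mean(dd), t = 0,
      df = length(dd) - 1, p = 1))
    tt <- stats::t.test(m[, a], m[, b], paired = TRUE)
    data.frame(contrast = paste(a, "vs", b), estimate = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  out <- rbind(pair("incongruent", "oneD"), pair("congruent", "oneD"),
               pair("incongruent", "congruent"))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
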