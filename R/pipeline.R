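# End-to-end orchestration: design -> staircase -> behaviour -> patterns ->
# RSA / decoding -> linking, with deterministic per-stage sub-seeds derived
# from one master seed, CSV outputs per stage and a consolidated report.

#' Pipeline configuration
#'
#' All module parameters with their defaults. `subject_lambda_sd` makes the
#' competition strength lambda vary log-normally across subjects, and
#' `coupling_rt` couples that subject-level competition to the subject's
#' behavioural Congruency (and Congruency x EV_back) slopes -- the generative
#' route by which neural competition and behaviour covary across subjects.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param n_subjects simulated cohort size.
#' @param n_blocks,n_candidates design generator settings.
#' @param behavior `cv_behavior_params`.
#' @param neural `cv_neural_params`.
#' @param rho,omega codebook similarity and channel-overlap parameters.
#' @param subject_lambda_sd log-scale SD of per-subject competition strength.
#' @param coupling_rt slope linking a subject's (lambda_k - lambda) to their
#'   behavioural Congruency and Congruency x EV_back coefficients.
#' @param normalization RSA noise-normalization mode.
#' @param staircase_a_sd between-feature SD of observer RT offsets (seconds).
#' @param out_dir output directory or NULL (no files written).
#' @return list of class `cv_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 35L, n_blocks = 4L,
                       n_candidates = 1000L,
                       behavior = behavior_params(),
                       neural = neural_params(),
                       rho = 0.5, omega = 0.7,
                       subject_lambda_sd = 0.4, coupling_rt = 0.04,
                       normalization = c("diagonal", "shrinkage"),
                       staircase_a_sd = 0.06,
                       out_dir = NULL) {
  normalization <- match.arg(normalization)
  structure(as.list(environment()), class = "cv_config")
}

write_stage <- function(obj, name, dir) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(obj), file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

rbind_probs <- function(lst) {
  out <- do.call(rbind, lst)
  attr(out, "target") <- attr(lst[[1]], "target")
  attr(out, "classes") <- attr(lst[[1]], "classes")
  class(out) <- c("cv_probs", "data.frame")
  out
}

#' Run the full simulation and analysis pipeline
#'
#' Executes all stages in dependency order with per-stage sub-seeds derived
#' from the master seed, writes every intermediate table to `config$out_dir`
#' (when set) and returns a consolidated report. Any stage failure halts the
#' pipeline with the failing stage named; tables written by earlier stages
#' are preserved.
#'
#' @param config `cv_config` (see [run_config()]).
#' @return list of class `cv_report` with per-stage results, the qualitative
#'   sign-pattern checklist and the design validation flags.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "cv_config"))
  dir <- config$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(seed = config$seed, n_subjects = config$n_subjects)

  design <- stage("design", {
    d <- generate_design(config$seed, config$n_blocks, config$n_candidates)
    d <- sample_timings(d, config$seed)
    d
  })
  write_stage(design$trials, "design", dir)
  if (!is.null(dir))
    jsonlite::write_json(lapply(unclass(design$mapping), as.list),
                         file.path(dir, "mapping.json"), auto_unbox = TRUE)
  report$design_checks <- as.list(validate_design(design))
  vif <- stage("vif", check_estimability(design))
  write_stage(vif, "vif", dir)
  report$vif <- list(max = max(vif$vif), mean = mean(vif$vif))

  sc <- stage("staircase", {
    set.seed(subseed(config$seed, 9L))
    a <- stats::setNames(pmax(0.15, stats::rnorm(8, 0.35, config$staircase_a_sd)),
                         default_features())
    obs <- make_observer(a = a)
    list(obs = obs, run = run_staircase(obs, config$seed))
  })
  write_stage(sc$run$trace, "staircase_trace", dir)
  report$staircase <- list(
    n_adjustments = sum(sc$run$adjustments$block == 2),
    rt_var_before = stats::var(expected_rt(sc$obs, sc$obs$theta0)),
    rt_var_after = stats::var(expected_rt(sc$obs, sc$run$theta_final)))

  # per-subject competition strengths and coupled behavioural slopes
  set.seed(subseed(config$seed, 10L))
  lam <- config$neural$lambda *
    exp(stats::rnorm(config$n_subjects, 0, config$subject_lambda_sd))
  cohort <- stage("behavior", {
    lapply(seq_len(config$n_subjects), function(k) {
      bp <- config$behavior
      dl <- lam[k] - config$neural$lambda
      bp$beta_cong <- bp$beta_cong + config$coupling_rt * dl
      bp$beta_cong_evback <- bp$beta_cong_evback + config$coupling_rt * dl / 2
      bh <- simulate_behavior(design, bp, 1L, subseed(config$seed, 20L + k))
      bh$subject <- k
      bh
    })
  })
  behavior <- do.call(rbind, cohort)
  class(behavior) <- c("cv_behavior", "data.frame")
  write_stage(behavior[, c("subject", "gtrial", "block", "trial", "rt",
                           "accuracy", "answered", "choice_side")],
              "behavior", dir)

  report$rt_ladder <- stage("rt_ladder", as.data.frame(fit_rt_ladder(behavior)))
  report$acc_ladder <- stage("acc_ladder",
                             as.data.frame(fit_accuracy_ladder(behavior)))
  report$contrasts <- stage("contrasts", congruency_contrasts(behavior))
  if (!is.null(dir)) {
    write_stage(report$rt_ladder, "rt_ladder", dir)
    write_stage(report$acc_ladder, "acc_ladder", dir)
    write_stage(report$contrasts, "contrasts", dir)
  }

  sims <- stage("patterns", {
    lapply(seq_len(config$n_subjects), function(k) {
      cb <- make_codebook(config$neural$n_voxels, config$rho, config$omega,
                          seed = subseed(config$seed, 300L + k))
      np <- config$neural
      np$lambda <- lam[k]
      simulate_patterns(design, cohort[[k]], cb, np,
                        seed = subseed(config$seed, 400L + k))
    })
  })

  cells <- stage("rsa", {
    do.call(rbind, lapply(seq_len(config$n_subjects), function(k) {
      cp <- prepare_condition_patterns(sims[[k]], config$normalization)
      cl <- build_rdm_design(crossrun_rdm(cp))
      cl$subject <- k
      cl
    }))
  })
  write_stage(cells, "rdm_cells", dir)
  report$rdm_effects <- stage("rsa_fit", as.data.frame(fit_rdm_models(cells)))
  write_stage(report$rdm_effects, "rdm_effects", dir)

  probs <- stage("decoding", {
    v <- list(); cx <- list(); eb <- list()
    for (k in seq_len(config$n_subjects)) {
      sk <- subseed(config$seed, 500L + k)
      v[[k]] <- loro_decode(sims[[k]], "value", seed = sk, subject = k)
      cx[[k]] <- loro_decode(sims[[k]], "context", seed = sk, subject = k)
      eb[[k]] <- ovr_evback_decode(sims[[k]], seed = sk, subject = k)
    }
    list(value = rbind_probs(v), context = rbind_probs(cx),
         evback = rbind_probs(eb))
  })
  if (!is.null(dir)) {
    write_stage(probs$value, "probs_value", dir)
    write_stage(probs$context, "probs_context", dir)
    write_stage(probs$evback, "probs_evback", dir)
  }
  ba <- rbind(
    cbind(target = "value",
          balanced_accuracy(probs$value[probs$value$dim == "1D" &
                                          probs$value$accuracy == 1, ])),
    cbind(target = "context",
          balanced_accuracy(probs$context[probs$context$dim == "1D" &
                                            probs$context$accuracy == 1, ])),
    cbind(target = "evback",
          balanced_accuracy(probs$evback[probs$evback$accuracy == 1, ])))
  write_stage(ba, "balanced_accuracy", dir)
  report$balanced_accuracy <- stats::aggregate(
    balanced_accuracy ~ target, data = ba, FUN = mean)

  links <- stage("linking", {
    recs <- make_link_records(probs$value, probs$context, probs$evback,
                              design, behavior)
    agg <- aggregate_combinations(probs$value, design)
    list(recs = recs, agg = agg,
         value_similarity = as.data.frame(fit_value_similarity(recs)),
         pev = as.data.frame(fit_pev_models(recs)),
         competition = competition_correlation(recs),
         pev_full = as.data.frame(fit_pev_full(recs)),
         behavior_links = fit_behavior_links(recs))
  })
  write_stage(links$agg, "probs_aggregated", dir)
  report$value_similarity <- links$value_similarity
  report$pev <- links$pev
  report$competition <- links$competition[c("paired_test", "aic")]
  report$pev_full <- links$pev_full
  report$behavior_links <- lapply(links$behavior_links, as.data.frame)
  if (!is.null(dir)) {
    write_stage(rbind(cbind(analysis = "value_similarity", links$value_similarity),
                      cbind(analysis = "pev", links$pev),
                      cbind(analysis = "pev_full", links$pev_full)),
                "link_effects", dir)
  }

  se <- stage("subject_effects", subject_effects(behavior, links$recs))
  write_stage(se, "subject_effects", dir)
  report$subject_correlations <- stage(
    "subject_correlations",
    if (nrow(se) >= 10) subject_correlations(se) else NULL)
  if (!is.null(dir) && !is.null(report$subject_correlations))
    write_stage(report$subject_correlations, "subject_correlations", dir)

  report$sign_checklist <- list(
    rt_congruency_positive =
      report$rt_ladder$estimate[report$rt_ladder$model == "+Congruency"] > 0,
    rt_cong_evback_positive =
      report$rt_ladder$estimate[report$rt_ladder$model == "+Congruency:EV_back"] > 0,
    pev_evback_negative =
      report$pev$estimate[report$pev$model == "+EV_back"] < 0,
    corr_back_more_negative =
      report$competition$paired_test$mean_z_back <
      report$competition$paired_test$mean_z_other,
    moderation_positive =
      report$pev_full$estimate[report$pev_full$model == "+P_context:P_EVback_2D"] > 0)

  if (!is.null(dir)) {
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    jsonlite::write_json(config_to_list(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  class(report) <- "cv_report"
  report
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$behavior <- unclass(out$behavior)
  out$neural <- unclass(out$neural)
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("contextval pipeline report (seed", x$seed, ",", x$n_subjects, "subjects)\n")
  cat("  design checks passed:", sum(unlist(x$design_checks)), "/",
      length(x$design_checks), "\n")
  cat("  max stimulus VIF:", round(x$vif$max, 3), "\n")
  cat("  balanced accuracy:\n")
  print(x$balanced_accuracy, row.names = FALSE)
  cat("  sign checklist:\n")
  for (nm in names(x$sign_checklist))
    cat("   ", nm, ":", unlist(x$sign_checklist[[nm]]), "\n")
  invisible(x)
}

#' Validate the files written by a pipeline run
#'
#' Re-verifies the design invariants and basic schema contracts of a
#' completed run directory. Idempotent; missing files appear as named
#' failures rather than errors.
#'
#' @param dir run directory.
#' @return named logical vector of checks.
#' @export
validate_outputs <- function(dir) {
  checks <- c()
  need <- c("design.csv", "mapping.json", "vif.csv", "behavior.csv",
            "rdm_cells.csv", "probs_value.csv", "probs_context.csv",
            "probs_evback.csv", "balanced_accuracy.csv", "report.json")
  for (f in need) checks[paste0("exists_", f)] <- file.exists(file.path(dir, f))
  if (checks["exists_design.csv"]) {
    tr <- utils::read.csv(file.path(dir, "design.csv"))
    bt <- table(tr$block, tr$dim)
    checks["design_block_counts"] <- all(bt[, "1D"] == 36) && all(bt[, "2D"] == 72)
    checks["design_rel_diff"] <- all(abs(tr$rel_left - tr$rel_right) == 20)
    checks["design_context_runs"] <- all(unlist(lapply(
      split(tr$context, tr$block), function(x) {
        r <- rle(x)$lengths; all(r >= 4 & r <= 7)
      })))
    checks["design_onsets_sorted"] <- all(unlist(lapply(
      split(tr$stim_onset, tr$block), function(x) !is.unsorted(x))))
  }
  if (checks["exists_probs_value.csv"]) {
    pv <- utils::read.csv(file.path(dir, "probs_value.csv"))
    pc <- as.matrix(pv[grep("^prob_", names(pv))])
    checks["probs_clipped"] <- all(pc >= 1e-5 & pc <= 1 - 1e-5)
    checks["probs_unique_trials"] <-
      !anyDuplicated(pv[, c("subject", "gtrial")])
  }
  if (checks["exists_vif.csv"]) {
    vf <- utils::read.csv(file.path(dir, "vif.csv"))
    checks["vif_count"] <- nrow(vf) == 108 * length(unique(vf$block))
    checks["vif_bound"] <- all(vf$vif < 5)
  }
  checks
}
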