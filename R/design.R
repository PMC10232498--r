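# Experimental design generation for the context-dependent value task.
#
# A session has 4 blocks (fMRI runs). Each block mixes 36 one-dimensional
# (1D) trials, where only the cued feature dimension is shown, with 72
# two-dimensional (2D) trials, where both a colour and a motion feature are
# present on each side. The two task-relevant values always differ by 20
# points and come from {10,30,50,70}, so the expected value of a correct
# choice (EV) is 30, 50 or 70. On 2D trials the two irrelevant features take
# any ordered pairing of distinct values, making the background expected
# value (EV_back, the max irrelevant value) 30, 50 or 70 as well.

VALUE_LEVELS <- c(10, 30, 50, 70)
REL_PAIRS <- list(c(10, 30), c(30, 50), c(50, 70))
COLOR_FEATURES <- c("pink", "green", "orange", "purple")
MOTION_FEATURES <- c("m0", "m45", "m90", "m135")

# all permutations of seq_len(n), rows = permutations
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# A motion assignment is excluded when the reward levels ascend monotonically
# around the axis order 0, 45, 90, 135 degrees in either direction, i.e. the
# cyclic sequence of values equals (10,30,50,70) up to rotation or reversal.
motion_order_excluded <- function(values) {
  asc <- VALUE_LEVELS
  for (r in 0:3) {
    rot <- asc[((seq_len(4) - 1 + r) %% 4) + 1]
    if (all(values == rot) || all(values == rev(rot))) return(TRUE)
  }
  FALSE
}

#' Draw a feature-to-value mapping
#'
#' Assigns the reward levels 10, 30, 50 and 70 points bijectively to the four
#' colour features and to the four motion axes. All 24 colour permutations
#' are admissible; motion permutations whose values ascend clockwise or
#' counter-clockwise around the axis order (0, 45, 90, 135 degrees) are
#' excluded, and the mapping is drawn uniformly from the remaining ones.
#'
#' @param seed integer seed; the same seed always yields the same mapping.
#' @return object of class `cv_mapping`: a list with named numeric vectors
#'   `color` and `motion` (feature -> points).
#' @export
make_value_mapping <- function(seed) {
  set.seed(as.integer(seed))
  col_perm <- sample(VALUE_LEVELS)
  pm <- perms(4)
  keep <- !apply(pm, 1, function(idx) motion_order_excluded(VALUE_LEVELS[idx]))
  mot_perm <- VALUE_LEVELS[pm[sample(which(keep), 1L), ]]
  structure(list(color = stats::setNames(col_perm, COLOR_FEATURES),
                 motion = stats::setNames(mot_perm, MOTION_FEATURES)),
            class = "cv_mapping")
}

#' @export
print.cv_mapping <- function(x, ...) {
  cat("Feature-value mapping (points)\n")
  cat("  color :", paste(names(x$color), x$color, sep = "=", collapse = " "), "\n")
  cat("  motion:", paste(names(x$motion), x$motion, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the irrelevant-feature pairings of a 2D trial
#'
#' For a relevant value pair differing by 20 points, every ordered pairing
#' (left, right) of the four irrelevant feature values with distinct values
#' on the two sides is admissible: 4 x 3 = 12 pairings.
#'
#' @param relevant_pair numeric length-2, relevant values differing by 20.
#' @return data.frame with columns `irr_left`, `irr_right` (12 rows).
#' @export
enumerate_2d_conditions <- function(relevant_pair) {
  stopifnot(length(relevant_pair) == 2)
  if (abs(diff(relevant_pair)) != 20 || !all(relevant_pair %in% VALUE_LEVELS))
    stop("relevant pair must be two levels of {10,30,50,70} differing by 20")
  g <- expand.grid(irr_left = VALUE_LEVELS, irr_right = VALUE_LEVELS)
  g[g$irr_left != g$irr_right, , drop = FALSE][, c("irr_left", "irr_right")]
}

#' Derive EV, EV_back and Congruency labels for trials
#'
#' EV is the maximum relevant value; on 2D trials EV_back is the maximum
#' irrelevant value and a trial is congruent when the side holding the
#' relevant maximum also holds the irrelevant maximum. On 1D trials EV_back
#' and Congruency are undefined (NA).
#'
#' @param trials data.frame with columns `rel_left`, `rel_right` and, for 2D
#'   trials, `irr_left`, `irr_right`.
#' @return `trials` with columns `EV`, `EV_back`, `congruency` (re)computed.
#' @export
classify_trial <- function(trials) {
  trials$EV <- pmax(trials$rel_left, trials$rel_right)
  is2d <- !is.na(trials$irr_left) & !is.na(trials$irr_right)
  trials$EV_back <- ifelse(is2d, pmax(trials$irr_left, trials$irr_right), NA_real_)
  rel_side <- ifelse(trials$rel_left > trials$rel_right, "left", "right")
  irr_side <- ifelse(trials$irr_left > trials$irr_right, "left", "right")
  trials$congruency <- ifelse(is2d,
                              ifelse(rel_side == irr_side, "congruent", "incongruent"),
                              NA_character_)
  trials
}

# ---- block construction -----------------------------------------------------

# The 108-trial multiset of one block. For each context and relevant pair:
# 6 1D trials (3 target-left, 3 target-right) and 12 2D trials. The 12 are
# the 6 unordered irrelevant pairs x both left/right orders; for a random 3
# of the 6 unordered pairs the target sits left in both orders, for the
# other 3 right, which balances target side (6L/6R) and makes Congruency
# exactly orthogonal to both EV and EV_back.
block_multiset <- function() {
  rows <- list()
  for (ctx in c("color", "motion")) {
    for (pair in REL_PAIRS) {
      ev <- max(pair)
      for (side in c("left", "right")) {
        rl <- if (side == "left") ev else ev - 20
        rows[[length(rows) + 1L]] <- data.frame(
          context = ctx, dim = "1D",
          rel_left = rep(rl, 3), rel_right = ev + (ev - 20) - rl,
          irr_left = NA_real_, irr_right = NA_real_,
          target_side = side, stringsAsFactors = FALSE)
      }
      upairs <- utils::combn(VALUE_LEVELS, 2)
      left_pairs <- sample(ncol(upairs), 3L)
      for (j in seq_len(ncol(upairs))) {
        a <- upairs[1, j]; b <- upairs[2, j]
        side <- if (j %in% left_pairs) "left" else "right"
        rl <- if (side == "left") ev else ev - 20
        rows[[length(rows) + 1L]] <- data.frame(
          context = ctx, dim = "2D",
          rel_left = rl, rel_right = ev + (ev - 20) - rl,
          irr_left = c(a, b), irr_right = c(b, a),
          target_side = side, stringsAsFactors = FALSE)
      }
    }
  }
  classify_trial(do.call(rbind, rows))
}

# Alternating context run lengths in [4, 7] summing to 54 per context.
sample_context_runs <- function(max_tries = 200L) {
  comp54 <- function() {
    for (i in seq_len(max_tries)) {
      parts <- integer(0); rem <- 54L
      while (rem > 7L) {
        p <- sample(4:7, 1L)
        parts <- c(parts, p); rem <- rem - p
      }
      if (rem >= 4L) return(c(parts, rem))
    }
    stop("design generation failed: context run-length composition")
  }
  for (i in seq_len(max_tries)) {
    a <- comp54(); b <- comp54()
    if (abs(length(a) - length(b)) > 1L) next
    ctxs <- sample(c("color", "motion"))
    if (length(a) == length(b)) {
      lens <- as.vector(rbind(a, b))
      labs <- rep(ctxs, length(a))
    } else {
      if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
      lens <- c(rbind(a, c(b, NA)))
      lens <- lens[!is.na(lens)]
      labs <- rep(ctxs, length.out = length(lens))
    }
    return(data.frame(context = labs, len = lens, stringsAsFactors = FALSE))
  }
  stop("design generation failed: context run interleaving")
}

# Sequentially fill one block under all running constraints; NULL on dead
# end. Works on pre-extracted atomic vectors for speed (pv = pool vectors).
try_block_sequence <- function(pv) {
  runs <- sample_context_runs()
  ctx_seq <- rep(runs$context, runs$len)
  run_id <- rep(seq_len(nrow(runs)), runs$len)
  n <- length(ctx_seq)
  remaining <- split(seq_along(pv$context), pv$context)
  ord <- integer(n)
  prev_ctx <- ""; prev_ev <- -1
  dim_run_val <- ""; dim_run_len <- 0L       # global 1D/2D streak
  dim_ctxrun_len <- 0L                        # streak within current context run
  side_val <- ""; side_len <- 0L
  cong_val <- ""; cong_len <- 0L
  prev_run <- 0L; prev_dim <- ""
  for (t in seq_len(n)) {
    ctx <- ctx_seq[t]
    cand <- remaining[[ctx]]
    if (length(cand) == 0L) return(NULL)
    cd <- pv$dim[cand]; cs <- pv$side[cand]
    cev <- pv$EV[cand]; cg <- pv$cong[cand]
    ok <- if (prev_ctx == ctx) cev != prev_ev else rep(TRUE, length(cand))
    if (dim_run_len >= 5L) ok <- ok & cd != dim_run_val
    in_same_run <- run_id[t] == prev_run
    if (in_same_run && dim_ctxrun_len >= 3L) ok <- ok & cd != dim_run_val
    if (side_len >= 4L) ok <- ok & cs != side_val
    if (cong_len >= 3L) ok <- ok & cg != cong_val
    cand <- cand[ok]
    if (length(cand) == 0L) return(NULL)
    pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    ord[t] <- pick
    rem <- remaining[[ctx]]
    remaining[[ctx]] <- rem[rem != pick]
    d <- pv$dim[pick]
    if (d == dim_run_val) dim_run_len <- dim_run_len + 1L else { dim_run_val <- d; dim_run_len <- 1L }
    if (in_same_run && d == prev_dim) dim_ctxrun_len <- dim_ctxrun_len + 1L else dim_ctxrun_len <- 1L
    s <- pv$side[pick]
    if (s == side_val) side_len <- side_len + 1L else { side_val <- s; side_len <- 1L }
    g <- pv$cong[pick]
    if (g == "none") { cong_val <- ""; cong_len <- 0L }
    else if (g == cong_val) cong_len <- cong_len + 1L
    else { cong_val <- g; cong_len <- 1L }
    prev_ctx <- ctx; prev_ev <- pv$EV[pick]; prev_run <- run_id[t]; prev_dim <- d
  }
  list(ord = ord, run_id = run_id)
}

generate_block <- function(max_attempts = 10000L) {
  pool <- block_multiset()
  pv <- list(context = pool$context, dim = pool$dim, side = pool$target_side,
             EV = pool$EV,
             cong = ifelse(is.na(pool$congruency), "none", pool$congruency))
  for (i in seq_len(max_attempts)) {
    res <- try_block_sequence(pv)
    if (!is.null(res)) {
      out <- pool[res$ord, , drop = FALSE]
      out$switch_distance <- stats::ave(seq_along(res$run_id), res$run_id,
                                        FUN = seq_along)
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("design generation failed: no constraint-satisfying sequence after ",
       max_attempts, " attempts (sequencing constraints)")
}

# Fraction of trials whose predecessor (consecutive trial, within block) had
# the same target value; computed overall and among congruent, incongruent
# and 1D trials.
repeat_fractions <- function(trials) {
  rep_flag <- with(trials, ave(EV, block, FUN = function(v) {
    c(FALSE, v[-1] == v[-length(v)])
  })) == 1
  f <- function(idx) if (!any(idx)) 0 else mean(rep_flag[idx])
  c(overall = mean(rep_flag),
    congruent = f(!is.na(trials$congruency) & trials$congruency == "congruent"),
    incongruent = f(!is.na(trials$congruency) & trials$congruency == "incongruent"),
    oneD = f(trials$dim == "1D"))
}

#' Generate a complete pseudo-randomized task design
#'
#' Builds `n_blocks` blocks of 36 1D + 72 2D trials each under the sequencing
#' constraints: cued context stays for 4-7 trials, at most 3 consecutive
#' same-dimensionality trials within a context run and 5 overall, target side
#' at most 4 in a row, congruent/incongruent at most 3 in a row, and no
#' target feature repeated on consecutive trials (so EV repeats at most
#' once). From `n_candidates` constraint-satisfying candidate designs, those
#' in which the target value repeats on more than 10% of trials (overall, or
#' among congruent, incongruent or 1D trials) are discarded and one of the
#' remaining designs is selected by the seed.
#'
#' @param seed integer seed.
#' @param n_blocks number of blocks (default 4).
#' @param n_candidates candidate designs generated before the repeat filter
#'   (default 1000, as in a full optimisation run; smaller values are fine
#'   for interactive use).
#' @param mapping optional `cv_mapping`; drawn from `seed` when missing.
#' @return object of class `cv_design`: list with `trials` (one row per
#'   trial), `mapping`, `seed`.
#' @export
generate_design <- function(seed, n_blocks = 4L, n_candidates = 1000L,
                            mapping = NULL) {
  stopifnot(n_blocks >= 1L)
  if (is.null(mapping)) mapping <- make_value_mapping(subseed(seed, 1L))
  set.seed(subseed(seed, 2L))
  accepted <- list()
  for (cand in seq_len(n_candidates)) {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      blk <- generate_block()
      blk$block <- b
      blk$trial <- seq_len(nrow(blk))
      blk
    })
    trials <- do.call(rbind, blocks)
    if (all(repeat_fractions(trials) <= 0.10)) {
      accepted[[length(accepted) + 1L]] <- trials
    }
  }
  if (length(accepted) == 0L)
    stop("design generation failed: no candidate met the 10% ",
         "target-value repeat criterion")
  trials <- accepted[[(as.integer(seed) %% length(accepted)) + 1L]]
  trials$gtrial <- seq_len(nrow(trials))
  # target feature name under the mapping (feature whose value is EV in context)
  feat_of <- function(ctx, v) {
    m <- if (ctx == "color") mapping$color else mapping$motion
    names(m)[match(v, m)]
  }
  trials$target_feature <- mapply(feat_of, trials$context, trials$EV)
  cols <- c("gtrial", "block", "trial", "context", "dim", "rel_left",
            "rel_right", "irr_left", "irr_right", "target_side",
            "switch_distance", "EV", "EV_back", "congruency", "target_feature")
  structure(list(trials = trials[, cols], mapping = mapping,
                 seed = as.integer(seed), n_blocks = n_blocks),
            class = "cv_design")
}

#' @export
print.cv_design <- function(x, ...) {
  tr <- x$trials
  cat("Task design:", x$n_blocks, "block(s),", nrow(tr), "trials",
      sprintf("(%d 1D / %d 2D)\n", sum(tr$dim == "1D"), sum(tr$dim == "2D")))
  cat("  EV levels:", paste(sort(unique(tr$EV)), collapse = ", "),
      "| seed:", x$seed, "\n")
  if (!is.null(tr$stim_onset)) cat("  timings sampled\n")
  invisible(x)
}

#' Sample inter-event timings for a design
#'
#' The cue, stimulus and outcome last 0.6, 1.6 and 0.8 s. The fixation gaps
#' are drawn from truncated exponential distributions: cue-to-stimulus mean
#' 0.6 s on [0.5, 2.5], stimulus-to-outcome mean 3.4 s on [1.5, 9] and
#' outcome-to-next-cue mean 1.25 s on [0.7, 6]. Onsets are seconds from the
#' start of each block.
#'
#' @param design `cv_design`.
#' @param seed integer seed.
#' @return the design with onset columns (`cue_onset`, `stim_onset`,
#'   `outcome_onset`) and gap columns filled in.
#' @export
sample_timings <- function(design, seed) {
  stopifnot(inherits(design, "cv_design"))
  tr <- design$trials
  set.seed(subseed(seed, 3L))
  if (nrow(tr) == 0L) {
    design$trials <- cbind(tr, cue_onset = numeric(0), stim_onset = numeric(0),
                           outcome_onset = numeric(0))
    return(design)
  }
  n <- nrow(tr)
  g1 <- rtrunc_exp(n, 0.6, 0.5, 2.5)
  g2 <- rtrunc_exp(n, 3.4, 1.5, 9)
  g3 <- rtrunc_exp(n, 1.25, 0.7, 6)
  tr$gap_cue_stim <- g1; tr$gap_stim_out <- g2; tr$gap_out_cue <- g3
  tr$cue_onset <- NA_real_; tr$stim_onset <- NA_real_; tr$outcome_onset <- NA_real_
  for (b in unique(tr$block)) {
    i <- which(tr$block == b)
    t0 <- 0
    for (j in i) {
      tr$cue_onset[j] <- t0
      tr$stim_onset[j] <- tr$cue_onset[j] + 0.6 + tr$gap_cue_stim[j]
      tr$outcome_onset[j] <- tr$stim_onset[j] + 1.6 + tr$gap_stim_out[j]
      t0 <- tr$outcome_onset[j] + 0.8 + tr$gap_out_cue[j]
    }
  }
  design$trials <- tr
  design
}

# SPM-style canonical double-gamma HRF sampled at resolution dt.
canonical_hrf <- function(dt, len = 32) {
  t <- seq(0, len, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Check trial-wise estimability of a timed design (VIF)
#'
#' Builds, per block, a design matrix with one boxcar regressor per stimulus
#' (duration 1.6 s), two cue regressors split by context and three outcome
#' regressors split by EV, convolves every column with a canonical
#' double-gamma HRF, samples it at the repetition time, and returns the
#' variance inflation factor of every stimulus column. A VIF of 1 is ideal;
#' 5 is a conservative bound for problematic collinearity. Singular designs
#' yield infinite VIFs rather than an error.
#'
#' @param design timed `cv_design` (see [sample_timings()]).
#' @param tr repetition time in seconds (default 1.25).
#' @param dt microtime resolution in seconds used for convolution.
#' @return data.frame with one row per stimulus regressor: `block`, `trial`,
#'   `vif`.
#' @export
check_estimability <- function(design, tr = 1.25, dt = 0.125) {
  stopifnot(inherits(design, "cv_design"))
  trl <- design$trials
  if (is.null(trl$stim_onset)) stop("design has no timings; run sample_timings() first")
  h <- canonical_hrf(dt)
  out <- list()
  for (b in unique(trl$block)) {
    tb <- trl[trl$block == b, ]
    dur_total <- max(tb$outcome_onset) + 0.8 + 16
    grid_n <- ceiling(dur_total / dt)
    box <- function(onsets, durs) {
      x <- numeric(grid_n)
      for (k in seq_along(onsets)) {
        i0 <- floor(onsets[k] / dt) + 1L
        i1 <- min(grid_n, ceiling((onsets[k] + durs[k]) / dt))
        x[i0:i1] <- 1
      }
      x
    }
    cols <- c(
      lapply(seq_len(nrow(tb)), function(i) box(tb$stim_onset[i], 1.6)),
      lapply(c("color", "motion"), function(cx)
        box(tb$cue_onset[tb$context == cx], rep(0.6, sum(tb$context == cx)))),
      lapply(sort(unique(tb$EV)), function(v)
        box(tb$outcome_onset[tb$EV == v], rep(0.8, sum(tb$EV == v))))
    )
    X <- vapply(cols, function(x) {
      cv <- stats::convolve(x, rev(h), type = "open")[seq_along(x)]
      cv[seq(1L, grid_n, by = round(tr / dt))]
    }, numeric(length(seq(1L, grid_n, by = round(tr / dt)))))
    ns <- nrow(tb)
    keep <- apply(X, 2, stats::sd) > 0
    Xc <- scale(X[, keep, drop = FALSE])
    R <- crossprod(Xc) / (nrow(Xc) - 1)
    vifs_kept <- tryCatch(diag(solve(R)), error = function(e) rep(Inf, ncol(R)))
    vifs <- rep(Inf, ncol(X))
    vifs[keep] <- vifs_kept
    out[[length(out) + 1L]] <- data.frame(block = b, trial = tb$trial,
                                          vif = vifs[seq_len(ns)])
  }
  do.call(rbind, out)
}

#' Validate every sequencing constraint of a design
#'
#' Re-checks the full constraint set independently of the generator: exact
#' trial multisets per block and per (EV, context) cell, the relevant-pair
#' difference of 20, context run lengths, dimensionality/side/congruency
#' streak bounds, the no-feature-repeat rule, the 10% target-value repeat
#' criterion and the exact orthogonality of EV, EV_back and Congruency over
#' the 2D trial set.
#'
#' @param design `cv_design`.
#' @return named logical vector, one entry per check.
#' @export
validate_design <- function(design) {
  tr <- design$trials
  by_block <- split(tr, tr$block)
  streak_max <- function(x) if (length(x) == 0) 0L else max(rle(x)$lengths)
  ctx_runs_ok <- all(vapply(by_block, function(b)
    all(rle(b$context)$lengths >= 4 & rle(b$context)$lengths <= 7), logical(1)))
  dim_global_ok <- all(vapply(by_block, function(b) streak_max(b$dim) <= 5, logical(1)))
  dim_within_ok <- all(vapply(by_block, function(b) {
    rid <- cumsum(c(1, b$context[-1] != b$context[-nrow(b)]))
    all(vapply(split(b$dim, rid), streak_max, integer(1)) <= 3)
  }, logical(1)))
  side_ok <- all(vapply(by_block, function(b) streak_max(b$target_side) <= 4, logical(1)))
  cong_ok <- all(vapply(by_block, function(b) {
    g <- ifelse(is.na(b$congruency), paste0("brk", seq_len(nrow(b))), b$congruency)
    all(rle(g)$lengths[rle(g)$values %in% c("congruent", "incongruent")] <= 3)
  }, logical(1)))
  feat_ok <- all(vapply(by_block, function(b) {
    f <- paste(b$context, b$EV)
    !any(f[-1] == f[-nrow(b)])
  }, logical(1)))
  tw <- tr[tr$dim == "2D", ]
  cg <- ifelse(tw$congruency == "congruent", -1, 1)
  orth_ok <- isTRUE(all.equal(stats::cor(tw$EV, tw$EV_back), 0)) &&
    isTRUE(all.equal(stats::cor(tw$EV, cg), 0)) &&
    isTRUE(all.equal(stats::cor(tw$EV_back, cg), 0))
  cell <- table(tr$block, tr$EV, tr$context, tr$dim)
  c(
    block_counts = all(vapply(by_block, function(b)
      sum(b$dim == "1D") == 36 && sum(b$dim == "2D") == 72, logical(1))),
    cell_counts = all(cell[, , , "1D"] == 6) && all(cell[, , , "2D"] == 12),
    rel_diff_20 = all(abs(tr$rel_left - tr$rel_right) == 20),
    irr_distinct = all(tr$irr_left[tr$dim == "2D"] != tr$irr_right[tr$dim == "2D"]),
    context_runs = ctx_runs_ok,
    dim_streak_within = dim_within_ok,
    dim_streak_global = dim_global_ok,
    side_streak = side_ok,
    congruency_streak = cong_ok,
    no_feature_repeat = feat_ok,
    repeat_criterion = all(repeat_fractions(tr) <= 0.10),
    orthogonality = orth_ok
  )
}
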