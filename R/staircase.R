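# Adaptive staircase that equalises detection speed across perceptual
# features before value learning. Each feature i carries an adjustable
# intensity parameter theta (motion coherence in (0, 1], or colour speed in
# arbitrary positive units) that is moved proportionally to the relative
# deviation of the feature's recent mean RT from an anchor RT:
#
#   theta' = theta + alpha * theta * (meanRT - anchorRT) / anchorRT
#
# Slow features (meanRT > anchor) are made easier (theta up), fast features
# harder, pulling per-feature response times toward a common anchor.

#' One staircase adjustment of a perceptual parameter
#'
#' @param theta current parameter value (> 0).
#' @param mean_rt mean reaction time of the feature's recent correct trials
#'   (seconds).
#' @param anchor_rt anchor reaction time (seconds, > 0).
#' @param alpha step size.
#' @param type `"motion"` (theta clamped to (1e-4, 1]) or `"color"`
#'   (theta >= 1e-4, unbounded above).
#' @return updated theta.
#' @examples
#' update_theta(0.7, 1.2, 1.0, 1)  # 0.84
#' @export
update_theta <- function(theta, mean_rt, anchor_rt, alpha,
                         type = c("motion", "color")) {
  type <- match.arg(type)
  if (any(c(theta, mean_rt, anchor_rt, alpha) <= 0))
    stop("theta, mean_rt, anchor_rt and alpha must be positive")
  new <- theta + alpha * theta * (mean_rt - anchor_rt) / anchor_rt
  new <- max(new, 1e-4)
  if (type == "motion") new <- min(new, 1)
  new
}

#' Step-size schedule of the staircase
#'
#' In adjustment block 1 every feature is adjusted once with alpha = 1. In
#' block 2 alpha decreases from 0.6 to 0.1 in steps of 0.1 over a feature's
#' successive adjustments and stays at 0.1 thereafter.
#'
#' @param block 1 or 2.
#' @param step ordinal adjustment number for the feature (>= 1).
#' @return alpha.
#' @export
alpha_schedule <- function(block, step) {
  stopifnot(block %in% c(1, 2), step >= 1)
  if (block == 1) return(1.0)
  max(0.7 - 0.1 * step, 0.1)
}

#' Construct a simulated observer for the staircase
#'
#' The observer responds to a feature with intensity theta with
#' `RT = a_i + b / theta + eps`, Gaussian eps, so RT decreases in theta, and
#' is correct with a fixed probability. The per-feature offsets `a` are the
#' heterogeneity the staircase is meant to remove; the analytic equilibrium
#' is `theta* = b / (anchor - a_i)`.
#'
#' @param a named numeric vector of RT offsets (seconds), one per feature;
#'   names define the 8 features (4 motion, 4 color).
#' @param b scaling of the 1/theta term (seconds).
#' @param accuracy probability of a correct answer.
#' @param rt_sd SD of the RT noise (seconds).
#' @param theta0 named numeric vector of starting parameter values.
#' @return object of class `cv_observer`.
#' @export
make_observer <- function(a = stats::setNames(rep(0.35, 8), default_features()),
                          b = 0.3, accuracy = 0.95, rt_sd = 0.08,
                          theta0 = stats::setNames(rep(0.7, 8), default_features())) {
  stopifnot(length(a) == 8, all(a > 0), b > 0, rt_sd > 0,
            accuracy > 0, accuracy <= 1)
  structure(list(a = a, b = b, accuracy = accuracy, rt_sd = rt_sd,
                 theta0 = theta0[names(a)]), class = "cv_observer")
}

#' @rdname make_observer
#' @export
default_features <- function() {
  c(paste0("motion", 1:4), paste0("color", 1:4))
}

feature_type <- function(f) ifelse(grepl("^motion", f), "motion", "color")

observer_trial <- function(obs, feature, theta) {
  rt <- obs$a[[feature]] + obs$b / theta + stats::rnorm(1, 0, obs$rt_sd)
  list(rt = max(rt, 0.05), correct = stats::runif(1) < obs$accuracy)
}

# balanced cue sequence over features, no feature more than twice in a row
cue_sequence <- function(features, reps) {
  pool <- rep(features, reps)
  for (try in 1:1000) {
    s <- sample(pool)
    r <- rle(s)
    if (max(r$lengths) <= 2) return(s)
  }
  s
}

#' Simulate the two-stage staircasing procedure
#'
#' Adjustment block 1 presents 72 trials (36 per context, each of the 8
#' features cued 9 times). The anchor RT is the mean of the last 48 correct
#' trials; every feature is then adjusted once with alpha = 1 using its own
#' mean correct RT. Block 2 starts with 24 motion-cued trials from which a
#' new anchor is computed; then over 144 trials (72 motion-cued followed by
#' 72 color-cued, 18 per feature) every three correct answers for a feature
#' trigger one adjustment using the mean RT of those three trials and the
#' motion anchor, for a maximum of six adjustments per feature with alpha
#' falling from 0.6 to 0.1.
#'
#' @param observer `cv_observer`.
#' @param seed integer seed.
#' @return object of class `cv_staircase`: list with `trace` (per-trial RTs
#'   and thetas), `adjustments` (one row per adjustment), `theta_final`,
#'   `anchors`, and `warning_no_adjustment`.
#' @export
run_staircase <- function(observer, seed) {
  stopifnot(inherits(observer, "cv_observer"))
  set.seed(subseed(seed, 4L))
  theta <- observer$theta0
  feats <- names(theta)
  motion <- feats[feature_type(feats) == "motion"]
  colorf <- feats[feature_type(feats) == "color"]
  trace <- list(); adj <- list()
  n_adj <- stats::setNames(integer(length(feats)), feats)

  play <- function(seq_feats, block) {
    for (f in seq_feats) {
      tr <- observer_trial(observer, f, theta[[f]])
      trace[[length(trace) + 1L]] <<- data.frame(
        block = block, trial = length(trace) + 1L, feature = f,
        theta = theta[[f]], rt = tr$rt, correct = tr$correct)
    }
  }

  # block 1: 72 trials, 9 cues per feature, contexts interleaved
  seq1 <- cue_sequence(feats, 9L)
  play(seq1, 1L)
  tr1 <- do.call(rbind, trace)
  acc1 <- tr1[tr1$correct, ]
  anchor1 <- if (nrow(acc1) == 0) NA_real_ else
    mean(utils::tail(acc1$rt, 48L))
  if (!is.na(anchor1)) {
    for (f in feats) {
      rts <- acc1$rt[acc1$feature == f]
      if (length(rts) == 0) next
      old <- theta[[f]]
      theta[[f]] <- update_theta(old, mean(rts), anchor1,
                                 alpha_schedule(1, 1), feature_type(f))
      n_adj[[f]] <- n_adj[[f]] + 1L
      adj[[length(adj) + 1L]] <- data.frame(
        block = 1L, feature = f, step = 1L, alpha = 1,
        mean_rt = mean(rts), anchor = anchor1,
        theta_before = old, theta_after = theta[[f]])
    }
  }

  # block 2 anchor: 24 motion-cued trials
  n0 <- length(trace)
  play(cue_sequence(motion, 6L), 2L)
  tr_anchor <- do.call(rbind, trace[(n0 + 1L):length(trace)])
  acc_anchor <- tr_anchor[tr_anchor$correct, ]
  anchor2 <- if (nrow(acc_anchor) == 0) anchor1 else mean(acc_anchor$rt)

  # block 2: 72 motion-cued then 72 color-cued, all adjustments vs anchor2
  n_adj2 <- stats::setNames(integer(length(feats)), feats)
  streak <- stats::setNames(replicate(length(feats), numeric(0), simplify = FALSE), feats)
  seq2 <- c(cue_sequence(motion, 18L), cue_sequence(colorf, 18L))
  for (f in seq2) {
    tr <- observer_trial(observer, f, theta[[f]])
    trace[[length(trace) + 1L]] <- data.frame(
      block = 2L, trial = length(trace) + 1L, feature = f,
      theta = theta[[f]], rt = tr$rt, correct = tr$correct)
    if (tr$correct) {
      streak[[f]] <- c(streak[[f]], tr$rt)
      if (length(streak[[f]]) == 3L && n_adj2[[f]] < 6L && !is.na(anchor2)) {
        step <- n_adj2[[f]] + 1L
        a <- alpha_schedule(2, step)
        old <- theta[[f]]
        theta[[f]] <- update_theta(old, mean(streak[[f]]), anchor2, a,
                                   feature_type(f))
        n_adj2[[f]] <- n_adj2[[f]] + 1L
        n_adj[[f]] <- n_adj[[f]] + 1L
        adj[[length(adj) + 1L]] <- data.frame(
          block = 2L, feature = f, step = step, alpha = a,
          mean_rt = mean(streak[[f]]), anchor = anchor2,
          theta_before = old, theta_after = theta[[f]])
        streak[[f]] <- numeric(0)
      } else if (length(streak[[f]]) >= 3L) {
        streak[[f]] <- numeric(0)
      }
    }
  }

  adj_df <- if (length(adj)) do.call(rbind, adj) else
    data.frame(block = integer(0), feature = character(0), step = integer(0),
               alpha = numeric(0), mean_rt = numeric(0), anchor = numeric(0),
               theta_before = numeric(0), theta_after = numeric(0))
  structure(list(
    trace = do.call(rbind, trace),
    adjustments = adj_df,
    theta_final = theta,
    anchors = c(block1 = anchor1, block2 = anchor2),
    n_adjustments_block2 = n_adj2,
    warning_no_adjustment = nrow(adj_df) == 0
  ), class = "cv_staircase")
}

#' @export
print.cv_staircase <- function(x, ...) {
  cat("Staircase run:", nrow(x$trace), "trials,",
      nrow(x$adjustments), "adjustments\n")
  cat("  anchors: block1 =", round(x$anchors[1], 3),
      "s, block2 =", round(x$anchors[2], 3), "s\n")
  print(round(x$theta_final, 3))
  invisible(x)
}

#' Expected per-feature mean RT of an observer at given parameter values
#'
#' Noise-free evaluation of the observer RT law, used to quantify the
#' between-feature RT dispersion before and after staircasing.
#'
#' @param observer `cv_observer`.
#' @param theta named parameter vector.
#' @return named numeric vector of expected RTs.
#' @export
expected_rt <- function(observer, theta) {
  observer$a + observer$b / theta[names(observer$a)]
}
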