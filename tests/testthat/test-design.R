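# Design generation: value mappings, condition enumeration, trial labels,
# sequencing constraints, timings and estimability.

test_that("value mappings cover all color permutations and exclude cyclic motion orders", {
  # brute-force oracle: enumerate all 24 assignments, flag those whose values
  # ascend around the axis order in either direction (4 rotations x 2)
  perms <- contextval:::perms(4)
  vals <- c(10, 30, 50, 70)
  excluded <- apply(perms, 1, function(idx) {
    v <- vals[idx]
    any(sapply(0:3, function(r) {
      rot <- vals[((seq_len(4) - 1 + r) %% 4) + 1]
      all(v == rot) || all(v == rev(rot))
    }))
  })
  expect_equal(nrow(perms), 24)
  expect_equal(sum(excluded), 8)
  # sampled motion mappings never hit an excluded order, colors hit all 24
  motion_seen <- character(0)
  color_seen <- character(0)
  for (s in 1:300) {
    m <- make_value_mapping(s)
    expect_false(contextval:::motion_order_excluded(unname(m$motion)))
    motion_seen <- union(motion_seen, paste(m$motion, collapse = "-"))
    color_seen <- union(color_seen, paste(m$color, collapse = "-"))
    expect_setequal(unname(m$color), vals)
    expect_setequal(unname(m$motion), vals)
  }
  expect_equal(length(motion_seen), 16)  # 24 - 8 admissible
  expect_equal(length(color_seen), 24)
  expect_identical(make_value_mapping(5), make_value_mapping(5))
})

test_that("2D condition enumeration yields 12 distinct-ordered pairings", {
  for (pair in list(c(10, 30), c(30, 50), c(50, 70))) {
    g <- enumerate_2d_conditions(pair)
    expect_equal(nrow(g), 12)
    expect_true(all(g$irr_left != g$irr_right))
    expect_equal(nrow(unique(g)), 12)
  }
  # 3 relevant pairs x 2 contexts x 12 = 72 2D trials per block
  expect_equal(3 * 2 * 12, 72)
  expect_error(enumerate_2d_conditions(c(10, 50)), "differing by 20")
})

test_that("classify_trial derives EV, EV_back and congruency", {
  tr <- data.frame(rel_left = c(30, 50, 30), rel_right = c(50, 30, 50),
                   irr_left = c(70, 70, NA), irr_right = c(10, 10, NA))
  out <- classify_trial(tr)
  expect_equal(out$EV, c(50, 50, 50))
  expect_equal(out$EV_back, c(70, 70, NA))
  expect_equal(out$congruency, c("incongruent", "congruent", NA))
})

test_that("generated designs satisfy every sequencing constraint", {
  d <- fixture_design()
  checks <- validate_design(d)
  expect_true(all(checks), info = paste(names(which(!checks)), collapse = ", "))
  tr <- d$trials
  expect_equal(nrow(tr), 4 * 108)
  # exact cell multiset: 6 1D and 12 2D per (block, EV, context)
  cell <- table(tr$block, tr$EV, tr$context, tr$dim)
  expect_true(all(cell[, , , "1D"] == 6))
  expect_true(all(cell[, , , "2D"] == 12))
  # exact orthogonality over the 2D set
  tw <- tr[tr$dim == "2D", ]
  cg <- ifelse(tw$congruency == "congruent", -1, 1)
  expect_equal(cor(tw$EV, tw$EV_back), 0)
  expect_equal(cor(tw$EV, cg), 0)
  expect_equal(cor(tw$EV_back, cg), 0)
})

test_that("design generation is deterministic in the seed", {
  d1 <- generate_design(3, n_blocks = 1, n_candidates = 2)
  d2 <- generate_design(3, n_blocks = 1, n_candidates = 2)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$mapping, d2$mapping)
})

test_that("timings respect the truncated-exponential ranges and means", {
  d <- fixture_timed_design()
  tr <- d$trials
  g1 <- tr$stim_onset - (tr$cue_onset + 0.6)
  g2 <- tr$outcome_onset - (tr$stim_onset + 1.6)
  expect_true(all(g1 >= 0.5 & g1 <= 2.5))
  expect_true(all(g2 >= 1.5 & g2 <= 9))
  expect_true(all(tr$gap_out_cue >= 0.7 & tr$gap_out_cue <= 6))
  # large-sample mean of the stimulus->outcome gap distribution
  set.seed(1)
  draws <- rtrunc_exp(10000, 3.4, 1.5, 9)
  expect_true(all(draws >= 1.5 & draws <= 9))
  expect_lt(abs(mean(draws) - 3.4), 3 * sd(draws) / sqrt(10000))
  # empty design -> empty timing table
  d0 <- d
  d0$trials <- d$trials[0, setdiff(names(d$trials),
                                   c("cue_onset", "stim_onset", "outcome_onset",
                                     "gap_cue_stim", "gap_stim_out", "gap_out_cue"))]
  expect_equal(nrow(sample_timings(d0, 1)$trials), 0)
})

test_that("timing determinism", {
  t1 <- sample_timings(fixture_design(), 9)$trials$stim_onset
  t2 <- sample_timings(fixture_design(), 9)$trials$stim_onset
  expect_identical(t1, t2)
})

test_that("non-overlapping regressors have VIF near 1", {
  # every event separated by >= 25 s: after HRF convolution no regressor
  # shares variance with any other, so stimulus VIFs are ~1
  d <- fixture_design()
  d$trials <- d$trials[1:2, ]
  d$trials$block <- 1L
  d$trials$context <- c("color", "motion")
  d$trials$EV <- c(30, 50)
  d$trials$cue_onset <- c(0, 100)
  d$trials$stim_onset <- c(25, 125)
  d$trials$outcome_onset <- c(50, 150)
  v <- check_estimability(d)
  expect_equal(nrow(v), 2)
  expect_true(all(v$vif < 1.05))
})
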