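# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code; sizes are scaled down from the full
# experiment (fewer candidate designs, fewer voxels, small cohorts) to keep
# the suite fast.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# canonical 4-block design used across modules
fixture_design <- function() {
  cached("design", generate_design(1, n_blocks = 4, n_candidates = 3))
}

fixture_timed_design <- function() {
  cached("timed_design", sample_timings(fixture_design(), 1))
}

# a decoded cohort in the default (planted-mechanism) world
fixture_cohort <- function(S = 8, v = 96) {
  cached("cohort", {
    d <- fixture_design()
    vs <- list(); cx <- list(); eb <- list(); beh <- list(); pats <- list()
    for (k in seq_len(S)) {
      sd0 <- 7000 + k
      bh <- simulate_behavior(d, behavior_params(), 1, sd0)
      bh$subject <- k
      cb <- make_codebook(v, 0.5, 0.7, sd0 + 1)
      ps <- simulate_patterns(d, bh, cb, neural_params(n_voxels = v), sd0 + 2)
      vs[[k]] <- loro_decode(ps, "value", seed = sd0, subject = k)
      cx[[k]] <- loro_decode(ps, "context", seed = sd0, subject = k)
      eb[[k]] <- ovr_evback_decode(ps, seed = sd0, subject = k)
      beh[[k]] <- bh
      if (k <= 2) pats[[k]] <- ps
    }
    behav <- do.call(rbind, beh)
    class(behav) <- c("cv_behavior", "data.frame")
    list(design = d, behavior = behav,
         value = rbind_probs_list(vs), context = rbind_probs_list(cx),
         evback = rbind_probs_list(eb), patterns = pats)
  })
}

fixture_links <- function() {
  cached("links", {
    co <- fixture_cohort()
    make_link_records(co$value, co$context, co$evback, co$design, co$behavior)
  })
}

rbind_probs_list <- function(lst) {
  out <- do.call(rbind, lst)
  attr(out, "target") <- attr(lst[[1]], "target")
  attr(out, "classes") <- attr(lst[[1]], "classes")
  class(out) <- c("cv_probs", "data.frame")
  out
}

# simulate patterns and return RDM cell table for one small cohort
sim_rdm_cells <- function(np, S, base, v) {
  d <- fixture_design()
  do.call(rbind, lapply(seq_len(S), function(k) {
    bh <- simulate_behavior(d, behavior_params(), 1, base + k)
    bh$subject <- k
    cb <- make_codebook(v, 0.5, 0.7, base + k + 1)
    ps <- simulate_patterns(d, bh, cb, np, base + k + 2)
    cl <- build_rdm_design(crossrun_rdm(prepare_condition_patterns(ps)))
    cl$subject <- k
    cl
  }))
}

# hand-constructed toy condition-pattern object (2 conditions, known values)
toy_condition_patterns <- function(M_by_run, n_trials = NULL) {
  nc <- nrow(M_by_run[[1]])
  labels <- data.frame(EV = rep(50, nc), EV_back = seq_len(nc) * 10)
  labels$condition <- paste0(labels$EV, "_", labels$EV_back)
  runs <- lapply(seq_along(M_by_run), function(r) {
    list(run = r, M = M_by_run[[r]],
         n_trials = if (is.null(n_trials)) rep(1L, nc) else n_trials[[r]])
  })
  structure(list(runs = runs, labels = labels, mode = "diagonal"),
            class = "cv_condition_patterns")
}
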