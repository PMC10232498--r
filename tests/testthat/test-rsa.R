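# Condition patterns, cross-run distances and the similarity-structure models.

test_that("condition preparation centers, normalizes and flags missing cells", {
  co <- fixture_cohort()
  cp <- prepare_condition_patterns(co$patterns[[1]])
  for (r in cp$runs) {
    ok <- !is.na(r$M[, 1])
    expect_lt(max(abs(colMeans(r$M[ok, , drop = FALSE]))), 1e-10)
    expect_equal(sum(r$n_trials), sum(ok * r$n_trials))
  }
  # diagonal mode with exactly unit-SD residuals only centers the patterns
  d <- fixture_design()
  cb <- make_codebook(16, seed = 3)
  ps <- simulate_patterns(d, NULL, cb, neural_params(n_voxels = 16), 3)
  ps$runs <- lapply(ps$runs, function(r) {
    r$residuals <- apply(r$residuals, 2, function(x) (x - mean(x)) / sd(x))
    r
  })
  cpu <- prepare_condition_patterns(ps, "diagonal")
  raw <- ps$runs[[1]]$X
  keep <- ps$runs[[1]]$labels$dim == "2D"
  cond <- paste0(ps$runs[[1]]$labels$EV, "_", ps$runs[[1]]$labels$EV_back)[keep]
  m30 <- colMeans(raw[keep, ][cond == "30_30", , drop = FALSE])
  ok <- !is.na(cpu$runs[[1]]$M[, 1])
  grand <- colMeans(do.call(rbind, lapply(cpu$labels$condition[ok], function(cn)
    colMeans(raw[keep, ][cond == cn, , drop = FALSE]))))
  expect_equal(cpu$runs[[1]]$M[1, ], m30 - grand, tolerance = 1e-10)
})

test_that("shrinkage whitening moves the residual covariance toward identity", {
  set.seed(8)
  res <- matrix(rnorm(40 * 12), 40, 12) %*% matrix(rnorm(144, sd = 0.5), 12, 12)
  W <- contextval:::whitener(res, "shrinkage")
  S <- stats::cov(res) * (39 / 40)
  frob <- function(A) sqrt(sum((A - diag(ncol(A)))^2))
  expect_lt(frob(t(W) %*% S %*% W), frob(S / mean(diag(S))))
})

test_that("cross-run distances match a brute-force oracle on toy input", {
  # two runs, 2 conditions, 1 voxel: values (1, 3) in both runs
  cp <- toy_condition_patterns(list(matrix(c(1, 3), 2, 1),
                                    matrix(c(1, 3), 2, 1)))
  rdm <- crossrun_rdm(cp)
  expect_equal(unname(rdm$D[1, 2]), 2)   # mean(|1-3|, |3-1|)
  expect_equal(unname(rdm$D[1, 1]), 0)
  # general oracle: 3 conditions, 2 runs, 4 voxels, random values
  set.seed(9)
  M1 <- matrix(rnorm(12), 3, 4); M2 <- matrix(rnorm(12), 3, 4)
  cp2 <- toy_condition_patterns(list(M1, M2))
  rdm2 <- crossrun_rdm(cp2)
  Ms <- list(M1, M2)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0; cnt <- 0
    for (r in 1:2) for (s in 1:2) {
      if (r == s) next
      acc <- acc + sqrt(sum((Ms[[r]][i, ] - Ms[[s]][j, ])^2)); cnt <- cnt + 1
    }
    expect_equal(unname(rdm2$D[i, j]), acc / cnt, tolerance = 1e-12)
  }
  # identical patterns everywhere (conditions and runs) -> all-zero RDM
  Mc <- matrix(1.5, 3, 4)
  cp3 <- toy_condition_patterns(list(Mc, Mc, Mc))
  expect_true(all(crossrun_rdm(cp3)$D == 0))
  # homogeneity: scaling patterns by 2 doubles every distance
  cp4 <- toy_condition_patterns(list(2 * M1, 2 * M2))
  expect_equal(crossrun_rdm(cp4)$D, 2 * rdm2$D, tolerance = 1e-12)
  # a single run has no cross-run pairs
  expect_error(crossrun_rdm(toy_condition_patterns(list(M1))), "2 runs")
})

test_that("the RDM cell table has 45 unique cells with correct covariates", {
  co <- fixture_cohort()
  rdm <- crossrun_rdm(prepare_condition_patterns(co$patterns[[1]]))
  expect_equal(dim(rdm$D), c(9, 9))
  expect_equal(rdm$D, t(rdm$D))
  cells <- build_rdm_design(rdm)
  expect_equal(nrow(cells), 45)
  # example cell (EV=30/EV_back=50 vs EV=30/EV_back=70)
  cell <- cells[cells$cond_i == "30_50" & cells$cond_j == "30_70", ]
  expect_equal(cell$diag_ev, 0)      # same EV
  expect_equal(cell$vd_ev, 0)
  expect_equal(cell$vd_evback, 20)
  # |30 - 70| = 40
  c2 <- cells[cells$cond_i == "30_30" & cells$cond_j == "70_30", ]
  expect_equal(c2$vd_ev, 40)
  expect_equal(c2$diag_evback, 0)
})

test_that("RDM models recover planted codes and respect null channels", {
  # relevant value code only: EV terms fire, EV_back terms stay quiet
  cells_ev <- sim_rdm_cells(neural_params(n_voxels = 48, a_back = 0, lambda = 0,
                                          s_back = 0), 6, 610, 48)
  tab <- as.data.frame(fit_rdm_models(cells_ev))
  expect_lt(tab$p[tab$model == "+Diagonal_EV"], 0.01)
  # a single replicate: the null channel should show no strong effect (its
  # type-I calibration is checked separately over hundreds of replicates)
  expect_gt(tab$p[tab$model == "+Diagonal_EVback"], 0.005)
  expect_lt(abs(tab$estimate[tab$model == "+Diagonal_EVback"]),
            abs(tab$estimate[tab$model == "+Diagonal_EV"]))
  # background code present: EV_back similarity terms fire
  cells_full <- sim_rdm_cells(neural_params(n_voxels = 48), 6, 620, 48)
  tab2 <- as.data.frame(fit_rdm_models(cells_full))
  expect_lt(tab2$p[tab2$model == "+Diagonal_EVback"], 0.01)
  expect_lt(tab2$p[tab2$model == "+VD_EVback"], 0.01)
  # inverse link: larger dissimilarity for different values = negative estimate
  expect_lt(tab2$estimate[tab2$model == "+Diagonal_EV"], 0)
})

test_that("shuffling condition labels within run destroys the diagonal effects", {
  d <- fixture_design()
  one <- function(perm_seed) {
    cl <- do.call(rbind, lapply(1:4, function(k) {
      bh <- simulate_behavior(d, behavior_params(), 1, 640 + k)
      cb <- make_codebook(48, seed = 640 + k)
      ps <- simulate_patterns(d, bh, cb, neural_params(n_voxels = 48), 640 + k)
      if (!is.na(perm_seed)) {
        set.seed(perm_seed + k)
        ps$runs <- lapply(ps$runs, function(r) {
          i2 <- which(r$labels$dim == "2D")
          sh <- sample(i2)
          r$labels[i2, c("EV", "EV_back")] <- r$labels[sh, c("EV", "EV_back")]
          r
        })
      }
      cells <- build_rdm_design(crossrun_rdm(prepare_condition_patterns(ps)))
      cells$subject <- k
      cells
    }))
    as.data.frame(fit_rdm_models(cl))
  }
  real <- one(NA)
  perm <- one(123)
  expect_lt(real$p[real$model == "+Diagonal_EV"], 0.05)
  expect_gt(abs(real$estimate[1]) / abs(perm$estimate[1]), 3)
})

test_that("increasing the value-code amplitude increases the diagonal-EV effect", {
  eff <- sapply(c(0.5, 1.5, 3), function(a) {
    cells <- sim_rdm_cells(neural_params(n_voxels = 48, a_ev = a, a_back = 0,
                                         lambda = 0, s_back = 0), 4, 660, 48)
    tab <- as.data.frame(fit_rdm_models(cells))
    abs(tab$estimate[tab$model == "+Diagonal_EV"])
  })
  expect_true(all(diff(eff) > 0))
})
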