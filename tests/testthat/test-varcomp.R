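# A hand-built kinship object for degenerate designs: n_pairs MZ twin pairs
# with no parents in the data.
mz_only_kin <- function(n_pairs) {
  n <- 2L * n_pairs
  A <- matrix(0, n, n)
  for (p in seq_len(n_pairs)) {
    ix <- (2 * p - 1):(2 * p)
    A[ix, ix] <- 1
  }
  ids <- sprintf("i%02d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, H = A, id = ids,
                 family = rep(sprintf("f%02d", seq_len(n_pairs)), each = 2)),
            class = "kinship_matrix")
}

test_that("AE estimates agree with a dense grid-search oracle on small probes", {
  ped <- generate_pedigree(15, seed = 1)
  kin <- additive_relationship(ped)
  n <- nrow(ped)
  set.seed(2)
  h2_grid <- seq(0, 0.95, by = 0.025)
  for (p in 1:20) {
    h2_true <- runif(1, 0, 0.6)
    L <- t(chol(h2_true * kin$A + (1 - h2_true) * diag(n) + 1e-9 * diag(n)))
    y <- drop(L %*% rnorm(n))
    names(y) <- kin$id
    fit <- fit_varcomp(y, kin, model = "AE")
    s2_grid <- seq(0.4, 2.5, by = 0.025) * stats::var(y)
    best <- c(-Inf, NA)
    for (h2 in h2_grid) for (s2 in s2_grid) {
      ll <- dense_ae_loglik(y, kin$A, h2 * s2, (1 - h2) * s2)
      if (ll > best[1]) best <- c(ll, h2)
    }
    expect_lt(abs(fit$h2 - best[2]), 0.025 + 1e-9)
    expect_gte(fit$loglik, best[1] - 1e-6)
    # dual-route likelihood agreement at the fitted point
    expect_equal(fit$loglik, dense_ae_loglik(y, kin$A, fit$va, fit$ve),
                 tolerance = 1e-6)
  }
})

test_that("returned estimates beat random feasible points (local-optimum check)", {
  ped <- generate_pedigree(20, seed = 3)
  kin <- additive_relationship(ped)
  n <- nrow(ped)
  set.seed(4)
  for (p in 1:20) {
    y <- rnorm(n, 0, 1)
    names(y) <- kin$id
    fit <- fit_varcomp(y, kin, model = "AE")
    v0 <- stats::var(y)
    for (k in 1:100) {
      va_r <- runif(1, 0, 2 * v0); ve_r <- runif(1, 0.05 * v0, 2 * v0)
      expect_gte(fit$loglik + 1e-8, dense_ae_loglik(y, kin$A, va_r, ve_r))
    }
  }
})

test_that("boundary decisions equal the profile-score oracle probe by probe", {
  ped <- study_pedigree(seed = 5)
  kin <- additive_relationship(ped)
  n <- nrow(ped)
  set.seed(6)
  mismatch <- 0L
  zeros <- 0L
  for (p in 1:200) {
    y <- rnorm(n)
    names(y) <- kin$id
    r <- y - mean(y)
    oracle_zero <- drop(t(r) %*% kin$A %*% r) <= sum(r^2)
    fit <- fit_varcomp(y, kin, model = "AE")
    zeros <- zeros + (fit$h2 < 1e-6)
    if ((fit$h2 < 1e-6) != oracle_zero) mismatch <- mismatch + 1L
  }
  expect_equal(mismatch, 0L)
  expect_gt(zeros, 0L)  # both branches exercised
})

test_that("noise-free MZ pairs drive the heritability to the upper boundary", {
  kin <- mz_only_kin(6)
  set.seed(7)
  y <- rep(rnorm(6), each = 2)
  names(y) <- kin$id
  fit <- fit_varcomp(y, kin, model = "AE")
  expect_gt(fit$h2, 0.999)
})

test_that("AE log-likelihood is invariant to permuting whole families", {
  ped <- generate_pedigree(12, seed = 8)
  kin <- additive_relationship(ped)
  set.seed(9)
  y <- rnorm(nrow(ped))
  names(y) <- kin$id
  f1 <- fit_varcomp(y, kin, model = "AE")
  # reorder individuals with families shuffled as blocks
  fams <- unique(ped$family_id)
  new_order <- unlist(split(seq_len(nrow(ped)), ped$family_id)[sample(fams)])
  ped2 <- ped[new_order, ]
  kin2 <- additive_relationship(ped2)
  f2 <- fit_varcomp(y[kin2$id], kin2, model = "AE")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-8)
})

test_that("AFE recovers the family variance and AE absorbs it upward", {
  ped <- generate_pedigree(200, seed = 10)
  kin <- additive_relationship(ped)
  pm <- make_probe_models(50, va = 0.08, vf = 0.04, ve = 0.13)
  sim <- simulate_methylation(ped, probes = pm, seed = 11)
  res <- normalize_matrix(sim$beta, design = NULL)
  afe <- heritability_screen(res, kin, model = "AFE")
  ae <- heritability_screen(res, kin, model = "AE")
  expect_lt(abs(mean(afe$c2) - 0.16), 0.05)
  expect_lt(abs(mean(afe$h2) - 0.32), 0.05)
  expect_gt(mean(ae$h2), 0.32 + 0.05)        # common environment absorbed
  expect_true(all(afe$h2 + afe$c2 <= 1 + 1e-9))
  expect_true(all(afe$va >= 0 & afe$vf >= 0 & afe$ve >= 0))
  # full-model likelihood dominates its null on every probe
  expect_true(all(afe$loglik >= ae$loglik - 1e-6))
})

test_that("covariate adjustment removes cell-composition inflation", {
  ped <- generate_pedigree(117, seed = 12)
  kin <- additive_relationship(ped)
  # cell proportions partly shared within families, as in real blood
  sheet <- make_sample_sheet(ped, cell_alpha = default_cell_alpha,
                             cell_family_weight = 0.7, seed = 13)
  # 10 probes with a strong cell-type signature on top of h2 = 0.2; 10 without
  pm <- c(
    make_probe_models(10, va = 0.05, vf = 0, ve = 0.2,
                      cell_signature = list(c(granulocytes = 6))),
    make_probe_models(10, va = 0.05, vf = 0, ve = 0.2)
  )
  sim <- simulate_methylation(ped, sheet, probes = pm, seed = 14)
  res <- normalize_matrix(sim$beta, design = NULL)
  cells <- as.matrix(sheet[, blood_cell_types])
  rownames(cells) <- sheet$individual_id
  plain <- heritability_screen(res, kin)
  adj <- heritability_screen(res, kin, covariates = cells[, -1])
  sig <- 1:10; null <- 11:20
  # cell-driven probes drop toward the generative truth
  expect_gt(mean(plain$h2[sig]) - mean(adj$h2[sig]), 0.05)
  expect_lt(abs(mean(adj$h2[sig]) - 0.2), 0.1)
  # probes without signature barely move
  expect_lt(abs(mean(adj$h2[null]) - mean(plain$h2[null])), 0.02)
})

test_that("screen calibration: regression of estimates on truth has slope ~1", {
  ped <- study_pedigree(seed = 15)
  kin <- additive_relationship(ped)
  set.seed(16)
  h2 <- runif(400, 0, 0.4)
  pm <- make_probe_models(400, va = h2 * 0.25, vf = 0, ve = (1 - h2) * 0.25)
  sim <- simulate_methylation(ped, probes = pm, seed = 17)
  res <- normalize_matrix(sim$beta, design = NULL)
  scr <- heritability_screen(res, kin)
  slope <- stats::coef(stats::lm(scr$h2 ~ sim$truth$h2))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("degenerate inputs are rejected with clear messages", {
  ped <- generate_pedigree(3, seed = 18)
  kin <- additive_relationship(ped)
  y <- rnorm(length(kin$id))
  expect_error(fit_varcomp(y[1:5], kin), "ordered")
  y2 <- y; y2[-(1:5)] <- NA
  expect_error(fit_varcomp(y2, kin), "at least 10")
})

test_that("BH step-up matches hand computation and controls the null", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.9), q = 0.05),
                   c(TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  # monotone in p
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2, 0.6)
  m <- bh_fdr(p, 0.05)
  expect_true(all(diff(as.integer(m)) <= 0))
  set.seed(19)
  pnull <- runif(10000)
  expect_lte(mean(bh_fdr(pnull, 0.05)), 0.05)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("zero-fraction bound reproduces its defining arithmetic", {
  expect_equal(zero_fraction_bound(p0 = 0.171)$bound, 65.8)
  expect_equal(zero_fraction_bound(p0 = 0.5)$bound, 0)
  expect_equal(zero_fraction_bound(p0 = 0)$bound, 100)
  expect_equal(zero_fraction_bound(p0 = 0.7)$bound, 0)  # floored
  out <- zero_fraction_bound(c(0, 0, 1e-9, 0.2, 0.5))
  expect_equal(out$p0, 0.6)
  expect_equal(out$bound, 0)  # floored below zero
  expect_error(zero_fraction_bound(c(-0.1, 0.5)), "\\[0,1\\]")
})
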