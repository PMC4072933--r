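# Independent HWE oracle using the choose-based form of the conditional
# heterozygote-count distribution.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nr <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  lp <- vapply(hets, function(h) {
    hr <- (nr - h) / 2
    lchoose(n, hr) + lchoose(n - hr, h) + h * log(2)
  }, 0)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  sum(pr[pr <= pr[obs] * (1 + 1e-7)])
}

test_that("the exact HWE test matches an independent enumeration oracle", {
  cases <- list(c(90, 0, 10), c(50, 21, 29), c(10, 80, 10), c(100, 0, 0),
                c(5, 5, 5), c(300, 150, 50))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10,
                 info = paste(cs, collapse = "/"))
  }
  # extreme heterozygote deficit is far beyond the QC threshold
  expect_lt(hwe_exact_p(90, 0, 10), 1e-6)
  # perfect HWE proportions are not rejected
  expect_gt(hwe_exact_p(81, 18, 1), 0.5)
})

test_that("SNP QC applies strict MAF, HWE and missingness rules", {
  ped <- generate_pedigree(50, seed = 1)
  founders <- ped$individual_id[is.na(ped$father_id)]
  n <- nrow(ped)
  ids <- ped$individual_id
  dos <- matrix(1L, 4, n, dimnames = list(
    c("maf_ok", "maf_low", "hwe_bad", "miss_high"), ids))
  # maf_ok: heterozygote count chosen so MAF equals the threshold exactly
  # (strict "<" keeps it); maf_low: one heterozygote fewer, removed
  k <- max(2L, floor(0.05 * 2 * n))
  maf_min <- k / (2 * n)
  dos["maf_ok", ] <- 0L
  dos["maf_ok", seq_len(k)] <- 1L
  dos["maf_low", ] <- 0L
  dos["maf_low", seq_len(k - 1L)] <- 1L
  # hwe_bad: founders split into homozygote classes only (no hets)
  dos["hwe_bad", ] <- 1L
  dos["hwe_bad", founders] <- rep(c(0L, 2L), length.out = length(founders))
  # miss_high: 11% missing, HWE-plausible genotypes -> removed by missingness
  set.seed(2)
  dos["miss_high", ] <- as.integer(stats::rbinom(n, 2, 0.4))
  dos["miss_high", seq_len(ceiling(0.11 * n))] <- NA_integer_
  geno <- structure(list(dosage = dos,
                         map = data.frame(snp_id = rownames(dos),
                                          chromosome = "1",
                                          position = 1:4 * 1000L,
                                          maf = 0.1,
                                          stringsAsFactors = FALSE)),
                    class = "genotype_matrix")
  out <- snp_qc(geno, ped, maf_min = maf_min)
  expect_identical(rownames(out$geno$dosage), "maf_ok")
  expect_equal(out$tally$removed[out$tally$rule == "maf"], 1L)
  expect_equal(out$tally$removed[out$tally$rule == "hwe"], 1L)
  expect_equal(out$tally$removed[out$tally$rule == "missingness"], 1L)
})

test_that("boundary SNPs at exactly the QC thresholds are retained", {
  ped <- generate_pedigree(25, seed = 3)
  n <- nrow(ped)
  # a SNP at exactly the missingness threshold is retained (strict ">")
  set.seed(4)
  g <- rbinom(n, 2, 0.3)
  g[seq_len(floor(0.1 * n))] <- NA
  dos <- matrix(as.integer(g), 1, n,
                dimnames = list("s1", ped$individual_id))
  geno <- structure(list(dosage = dos,
                         map = data.frame(snp_id = "s1", chromosome = "1",
                                          position = 1L, maf = 0.3,
                                          stringsAsFactors = FALSE)),
                    class = "genotype_matrix")
  out <- snp_qc(geno, ped, max_missing = mean(is.na(g)))
  expect_equal(nrow(out$geno$dosage), 1L)
})

test_that("bonferroni threshold is exact arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_equal(bonferroni_threshold(0.05, 417069) * 417069, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("the scan reduces to OLS when individuals are unrelated", {
  # founders only: A restricted to parents is the identity
  ped <- generate_pedigree(60, seed = 5)
  kin <- additive_relationship(ped)
  founders <- is.na(ped$father_id)
  set.seed(6)
  y <- rep(NA_real_, nrow(ped))
  g <- rbinom(nrow(ped), 2, 0.4)
  y[founders] <- 0.3 * g[founders] + rnorm(sum(founders))
  names(y) <- kin$id
  geno <- structure(list(dosage = matrix(as.integer(g), 1,
                                         dimnames = list("s1", kin$id)),
                         map = data.frame(snp_id = "s1", chromosome = "1",
                                          position = 1L, maf = 0.4,
                                          stringsAsFactors = FALSE)),
                    class = "genotype_matrix")
  scan <- assoc_scan(y, geno, kin)
  ols <- stats::lm(y[founders] ~ g[founders])
  expect_equal(scan$effect, unname(stats::coef(ols)[2]), tolerance = 1e-9)
  # closed-form GLS standard error with the null-model variance
  null_fit <- fit_varcomp(y, kin, model = "AE")
  gf <- g[founders]
  se_closed <- sqrt((null_fit$va + null_fit$ve) /
                      sum((gf - mean(gf))^2))
  expect_equal(scan$se, se_closed, tolerance = 1e-9)
})

test_that("effects are anti-symmetric under allele flipping", {
  ped <- generate_pedigree(40, seed = 7)
  kin <- additive_relationship(ped)
  geno <- simulate_genotypes(ped, 10, seed = 8)
  pm <- make_probe_models(1, va = 0.05, ve = 0.2, mqtl_snp = "snp00003",
                          mqtl_beta = 0.4)
  sim <- simulate_methylation(ped, geno = geno, probes = pm, seed = 9)
  y <- stats::qlogis(sim$beta$values[1, ])  # type II: compression is affine
  flipped <- geno
  flipped$dosage <- 2L - geno$dosage
  s1 <- assoc_scan(y, geno, kin)
  s2 <- assoc_scan(y, flipped, kin)
  expect_equal(s1$effect, -s2$effect, tolerance = 1e-9)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-9)
})

test_that("monomorphic and low-count SNPs are skipped with a flag", {
  ped <- generate_pedigree(20, seed = 10)
  kin <- additive_relationship(ped)
  n <- nrow(ped)
  dos <- rbind(mono = rep(1L, n),
               ok = as.integer(rbinom(n, 2, 0.4)))
  colnames(dos) <- kin$id
  geno <- structure(list(dosage = dos,
                         map = data.frame(snp_id = rownames(dos),
                                          chromosome = "1",
                                          position = c(1L, 2L), maf = 0.4,
                                          stringsAsFactors = FALSE)),
                    class = "genotype_matrix")
  set.seed(11)
  y <- rnorm(n); names(y) <- kin$id
  scan <- assoc_scan(y, geno, kin)
  expect_true(scan$skipped[1])
  expect_true(is.na(scan$p_value[1]))
  expect_false(scan$skipped[2])
})

test_that("family structure inflates naive OLS but not the GLS scan", {
  ped <- generate_pedigree(100, seed = 12)
  kin <- additive_relationship(ped)
  n <- nrow(ped)
  # highly familial phenotype, null SNPs
  pm <- make_probe_models(1, va = 0.2, vf = 0, ve = 0.05, probe_type = "I")
  sim <- simulate_methylation(ped, probes = pm, seed = 13)
  y <- stats::qlogis(sim$beta$values[1, ])
  geno <- simulate_genotypes(ped, 800, maf_range = c(0.1, 0.5), seed = 14)
  scan <- assoc_scan(y, geno, kin)
  gls_t1 <- mean(scan$p_value < 0.05, na.rm = TRUE)
  # naive OLS p-values ignoring relatedness
  yc <- y - mean(y)
  ols_p <- apply(geno$dosage, 1, function(g) {
    r <- suppressWarnings(stats::cor(g, yc))
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  })
  ols_t1 <- mean(ols_p < 0.05)
  expect_gt(ols_t1, 0.08)   # inflation from family structure
  expect_lt(gls_t1, 0.08)   # measured-genotype model stays calibrated
})

test_that("regional profiling recovers bidirectional effects in the window", {
  ped <- generate_pedigree(100, seed = 15)
  kin <- additive_relationship(ped)
  geno <- simulate_genotypes(ped, 20, maf_range = c(0.3, 0.5), seed = 16)
  lead <- geno$map$snp_id[10]
  lead_pos <- geno$map$position[10]
  # 20 driven probes inside the window, alternating sign; 5 null probes
  # inside; 5 probes outside the window entirely
  signs <- rep(c(1, -1), 10)
  pm <- c(
    make_probe_models(20, va = 1e-6, vf = 0, ve = 0.08,
                      mqtl_snp = lead, mqtl_beta = signs * 0.45,
                      position = as.integer(lead_pos + seq(-3e6, 3e6,
                                                           length.out = 20))),
    make_probe_models(5, va = 1e-6, ve = 0.08,
                      position = as.integer(lead_pos + seq(-3.9e6, 3.9e6,
                                                           length.out = 5))),
    make_probe_models(5, va = 1e-6, ve = 0.08,
                      position = as.integer(lead_pos + 5e6 + 1:5 * 1e5))
  )
  sim <- simulate_methylation(ped, geno = geno, probes = pm, seed = 17)
  res <- normalize_matrix(sim$beta, design = NULL)
  out <- region_effects(lead, res, geno, kin, window_bp = 8e6,
                        sig_threshold = bonferroni_threshold(0.05, 417069))
  expect_equal(nrow(out), 25L)  # window excludes the 5 distant probes
  driven <- out[match(sim$truth$probe_id[1:20], out$probe_id), ]
  expect_gte(sum(driven$significant), 18L)
  hit <- driven$significant
  expect_true(all(sign(driven$effect[hit]) == signs[hit]))
  nulls <- out[match(sim$truth$probe_id[21:25], out$probe_id), ]
  expect_lte(sum(nulls$significant), 1L)

  # degenerate window: only probes at the SNP coordinate itself
  out0 <- region_effects(lead, res, geno, kin, window_bp = 0)
  expect_true(all(out0$position == lead_pos))
})
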