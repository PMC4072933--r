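test_that("beta values stay in [0,1] and the truth table is coherent", {
  ped <- generate_pedigree(10, seed = 1)
  pm <- make_probe_models(50, va = c(0, 0.1, 0.3), vf = c(0, 0.05),
                          ve = 0.2, intercept = c(-2, 0, 1),
                          probe_type = c("I", "II"))
  sim <- simulate_methylation(ped, probes = pm, missing_rate = 0.02,
                              detect_fail_rate = 0.01, seed = 2)
  V <- sim$beta$values
  expect_true(all(V >= 0 & V <= 1, na.rm = TRUE))
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(abs(sim$truth$h2 + sim$truth$c2 +
                        (1 - (sim$truth$va + sim$truth$vf) /
                           (sim$truth$va + sim$truth$vf + sim$truth$ve)) - 1)
                  < 1e-12))
  # missing and detection-failure rates near nominal
  expect_lt(abs(mean(is.na(V)) - 0.02), 0.01)
  expect_lt(abs(mean(sim$beta$detp > 1e-3) - 0.01), 0.01)
})

test_that("simulation is deterministic given the seed", {
  ped <- generate_pedigree(5, seed = 3)
  pm <- make_probe_models(10)
  s1 <- simulate_methylation(ped, probes = pm, seed = 9)
  s2 <- simulate_methylation(ped, probes = pm, seed = 9)
  expect_identical(s1, s2)
})

test_that("a pure-noise probe is centred at 0.5 with uncorrelated relatives", {
  ped <- generate_pedigree(60, seed = 4)
  pm <- make_probe_models(400, va = 0, vf = 0, ve = 0.25,
                          probe_type = "I")
  sim <- simulate_methylation(ped, probes = pm, seed = 5)
  expect_lt(abs(mean(sim$beta$values) - 0.5), 0.005)
  pairs <- classify_pairs(ped)
  tab <- correlation_table(sim$beta$values -
                             rowMeans(sim$beta$values), pairs)
  expect_true(all(abs(tab$mean_correlation) < 0.03))
})

test_that("full-heritability probes make MZ co-twins equal up to compression", {
  ped <- generate_pedigree(10, mz_prob = 1, seed = 6)
  pm <- make_probe_models(20, va = 0.25, vf = 0, ve = 1e-12,
                          probe_type = "II", type2_compression = 0.2)
  sim <- simulate_methylation(ped, probes = pm, seed = 7)
  for (lab in unique(stats::na.omit(ped$twin_pair))) {
    tw <- ped$individual_id[!is.na(ped$twin_pair) & ped$twin_pair == lab]
    expect_equal(sim$beta$values[, tw[1]], sim$beta$values[, tw[2]],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # compression keeps type II probes strictly inside [0.1, 0.9] at s = 0.2
  expect_true(all(sim$beta$values > 0.1 - 1e-9 &
                    sim$beta$values < 0.9 + 1e-9))
})

test_that("latent additive values reproduce the covariance Va * A", {
  # type I probes with va = 1, ve = 0 expose the additive component directly
  # on the logit scale; its empirical covariance over probes estimates A
  ped <- generate_pedigree(3, sib_probs = c("1" = 1), seed = 8)
  kin <- additive_relationship(ped)
  pm <- make_probe_models(6000, va = 1, vf = 0, ve = 0, probe_type = "I")
  sim <- simulate_methylation(ped, probes = pm, seed = 9)
  lat <- stats::qlogis(sim$beta$values)
  emp <- stats::cov(lat)
  expect_lt(max(abs(emp - kin$A)), 0.05)
})

test_that("mQTL, covariate and cell-signature effects enter the latent scale", {
  ped <- generate_pedigree(30, seed = 10)
  sheet <- make_sample_sheet(ped, cell_alpha = default_cell_alpha, seed = 11)
  geno <- simulate_genotypes(ped, 5, maf_range = c(0.3, 0.5), seed = 12)
  pm <- list(
    probe_model(va = 1e-16, ve = 1e-16, mqtl_snp = "snp00001",
                mqtl_beta = 0.7, probe_type = "I"),
    probe_model(va = 1e-16, ve = 1e-16, sex_effect = 1, probe_type = "I"),
    probe_model(va = 1e-16, ve = 1e-16, probe_type = "I",
                cell_signature = c(granulocytes = 2))
  )
  sim <- simulate_methylation(ped, sheet, geno, pm, seed = 13)
  lat <- stats::qlogis(sim$beta$values)
  g <- geno$dosage["snp00001", ped$individual_id]
  expect_equal(lat[1, ], 0.7 * g, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(lat[2, ], as.numeric(ped$sex == "female"),
               tolerance = 1e-6, ignore_attr = TRUE)
  gran <- sheet$granulocytes[match(ped$individual_id, sheet$individual_id)]
  expect_equal(lat[3, ], 2 * gran, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("spouse-correlation knob induces parent-parent correlation only", {
  ped <- generate_pedigree(80, seed = 14)
  pm <- make_probe_models(600, va = 0, vf = 0, ve = 0.2, probe_type = "I")
  sim <- simulate_methylation(ped, probes = pm, spouse_var = 0.05, seed = 15)
  pairs <- classify_pairs(ped)
  cent <- sim$beta$values - rowMeans(sim$beta$values)
  tab <- correlation_table(cent, pairs)
  sp <- tab$mean_correlation[tab$class == "spouse"]
  sib <- tab$mean_correlation[tab$class == "sibling"]
  expect_gt(sp, 0.1)            # 0.05 / 0.25 = 0.2 expected
  expect_lt(abs(sib), 0.03)
})

test_that("downstream ML heritability recovers the generative value", {
  # end-to-end parameter recovery: h2 = 0.4 on 200 families
  ped <- generate_pedigree(200, seed = 16)
  kin <- additive_relationship(ped)
  pm <- make_probe_models(500, va = 0.1, vf = 0, ve = 0.15)
  sim <- simulate_methylation(ped, probes = pm, seed = 17)
  res <- normalize_matrix(sim$beta, design = NULL)
  scr <- heritability_screen(res, kin)
  expect_lt(abs(mean(scr$h2) - 0.4), 0.03)
})

test_that("inconsistent covariance requests are rejected", {
  ped <- generate_pedigree(3, seed = 18)
  pm <- list(probe_model(mqtl_snp = "snp00001", mqtl_beta = 1))
  expect_error(simulate_methylation(ped, probes = pm, seed = 1),
               "no genotypes")
  pm2 <- list(probe_model(cell_signature = c(NK = 1)))
  expect_error(simulate_methylation(ped, probes = pm2, seed = 1),
               "cell")
})
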