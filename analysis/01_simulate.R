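#!/usr/bin/env Rscript

# Stage 1: simulate a twin-family methylation cohort with known truth.
#
# Builds the study design: 117 nuclear families (two parents, one MZ or DZ
# twin pair, 0-3 further siblings; ~614 individuals), a randomised array
# layout with family-correlated blood cell proportions, gene-dropped SNP
# genotypes, and a 2,000-probe beta-value panel mixing null probes,
# heritable probes, family-environment probes, cell-composition probes,
# batch-affected probes and cis-mQTL probes. Everything downstream
# (QC, Table-1 correlations, heritability screen, mQTL scan) runs off the
# plain-text outputs written here.

suppressMessages(library(methfam))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240501L

ped <- generate_pedigree(117, seed = seed)
cat(sprintf("cohort: %d individuals in %d families (%d MZ, %d DZ pairs)\n",
            nrow(ped), length(unique(ped$family_id)),
            sum(ped$zygosity == "MZ_twin") / 2,
            sum(ped$zygosity == "DZ_twin") / 2))

sheet <- make_sample_sheet(ped, cell_alpha = default_cell_alpha,
                           cell_family_weight = 0.5, seed = seed + 1L)
geno <- simulate_genotypes(ped, n_snps = 1500, maf_range = c(0.02, 0.5),
                           missing_rate = 0.01, seed = seed + 2L)

# probe panel: generative classes with realistic latent variance (total 0.25
# on the logit scale ~ beta-scale SD 0.12 at a hemimethylated site)
set.seed(seed + 3L)
n_probes <- 2000L
cls <- sample(c("null", "heritable", "family", "cell", "batch", "mqtl"),
              n_probes, replace = TRUE,
              prob = c(0.25, 0.45, 0.10, 0.08, 0.07, 0.05))
h2 <- ifelse(cls == "heritable", runif(n_probes, 0.05, 0.8),
             ifelse(cls == "mqtl", 0.2, 0))
vf <- ifelse(cls == "family", 0.05, 0)
va <- h2 * 0.25
ve <- 0.25 - va - vf
chips <- unique(sheet$chip)
mk_chip_eff <- function() setNames(rnorm(length(chips), 0, 0.15), chips)
probes <- make_probe_models(
  n_probes,
  intercept = rnorm(n_probes, 0, 1.2),
  va = va, vf = vf, ve = ve,
  probe_type = ifelse(runif(n_probes) < 0.72, "II", "I"),
  n_cpg = pmax(0L, rpois(n_probes, 2)),
  n_snp = rbinom(n_probes, 2, ifelse(runif(n_probes) < 0.75, 0, 0.35)),
  chromosome = sample(c(as.character(1:22), "X"), n_probes, TRUE,
                      prob = c(rep(1, 22), 0.6) / 22.6),
  density_class = sample(c("HC", "ICshore", "IC", "LC"), n_probes, TRUE,
                         prob = c(0.3, 0.07, 0.22, 0.41)),
  multimap_flag = runif(n_probes) < 0.01,
  position = as.integer(runif(n_probes, 1e6, 50e6)),
  mqtl_snp = ifelse(cls == "mqtl",
                    sample(geno$map$snp_id, n_probes, TRUE), NA),
  mqtl_beta = ifelse(cls == "mqtl", sample(c(-1, 1), n_probes, TRUE) *
                       runif(n_probes, 0.3, 0.6), 0),
  chip_effects = lapply(seq_len(n_probes), function(i)
    if (cls[i] == "batch") mk_chip_eff() else NULL),
  cell_signature = lapply(seq_len(n_probes), function(i)
    if (cls[i] == "cell")
      setNames(rnorm(2, 0, 3), sample(blood_cell_types, 2)) else NULL)
)
# mQTL probes must sit near their SNP (same chromosome) for the cis
# interpretation
for (i in which(cls == "mqtl")) {
  j <- match(probes[[i]]$mqtl_snp, geno$map$snp_id)
  probes[[i]]$chromosome <- geno$map$chromosome[j]
  probes[[i]]$position <- as.integer(geno$map$position[j] +
                                       round(rnorm(1, 0, 2e5)))
}

sim <- simulate_methylation(ped, sheet, geno, probes,
                            missing_rate = 0.005, detect_fail_rate = 0.003,
                            seed = seed + 4L)

# a separate signature-probe block mixed on the beta scale for the
# reference-based cell deconvolution demonstration
ref <- make_cell_reference(200, seed = 42)
cellsig <- mix_cell_profiles(ref, as.matrix(sheet[, blood_cell_types]),
                             noise_sd = 0.02, seed = seed + 5L)
colnames(cellsig) <- sheet$individual_id

write_pedigree(ped, file.path(out, "pedigree.ped"))
write.csv(sheet, file.path(out, "sample_sheet.csv"), row.names = FALSE)
write_dosage_tsv(geno, file.path(out, "dosages.tsv"))
write_matrix_tsv(sim$beta$values, file.path(out, "beta.tsv"))
write_matrix_tsv(sim$beta$detp, file.path(out, "detection_p.tsv"))
write.table(sim$beta$annotation, file.path(out, "probe_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth <- cbind(sim$truth, class = cls,
               mqtl_snp = vapply(probes, function(p) as.character(p$mqtl_snp), ""),
               mqtl_beta = vapply(probes, `[[`, 0, "mqtl_beta"))
write.table(truth, file.path(out, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_matrix_tsv(cellsig, file.path(out, "cell_signature_beta.tsv"),
                 id_col = "sig_probe")

cat(sprintf("wrote %d probes x %d samples (%.2f%% missing), %d SNPs -> %s\n",
            nrow(sim$beta$values), ncol(sim$beta$values),
            100 * mean(is.na(sim$beta$values)), nrow(geno$dosage), out))
cat(sprintf("mean generative h2: %.3f; probes with h2 > 0: %.1f%%\n",
            mean(truth$h2), 100 * mean(truth$h2 > 0)))
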