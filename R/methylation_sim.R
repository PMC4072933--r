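#' Blood leukocyte cell types used throughout the package
#'
#' Cell types of the reference-based deconvolution: monocytes, B cells,
#' natural killer cells, CD4+ and CD8+ T cells, and granulocytes.
#' @export
blood_cell_types <- c("monocytes", "B_cells", "NK", "CD4_T", "CD8_T",
                      "granulocytes")

#' Describe the generative model of a single methylation probe
#'
#' A probe is generated on a latent logit (log-odds) scale as the sum of an
#' intercept, covariate effects, an optional mQTL fixed effect, an additive
#' genetic value with covariance `va * A`, a nuclear-family common
#' environmental value with variance `vf`, and independent noise with
#' variance `ve`. Beta values are the inverse logit of the latent value;
#' type II probes are additionally compressed linearly toward 0.5.
#'
#' @param intercept Logit-scale intercept (0 = hemimethylated, beta 0.5).
#' @param va,vf,ve Additive genetic, family common-environment and residual
#'   variances on the latent scale. All non-negative, not all zero.
#' @param mqtl_snp Optional SNP id whose dosage has a fixed effect.
#' @param mqtl_beta Log-odds change in methylation per allele.
#' @param sex_effect,age_effect Logit-scale coefficients for the female
#'   indicator and age in years.
#' @param chip_effects,position_effects Optional named vectors of logit-scale
#'   offsets per chip / chip-position level (batch effects).
#' @param cell_signature Optional named vector over [blood_cell_types] of
#'   logit-scale offsets weighted by each sample's cell proportions.
#' @param probe_type `"I"` or `"II"`.
#' @param type2_compression Shrinkage factor `s` in `[0,1)`; type II beta
#'   values become `0.5 + (1 - s) * (beta - 0.5)`.
#' @param chromosome,position,n_cpg,n_snp,density_class,multimap_flag Probe
#'   annotation carried into the generated matrix.
#'
#' @return A list of class `probe_model`.
#' @export
probe_model <- function(intercept = 0, va = 0.05, vf = 0, ve = 0.2,
                        mqtl_snp = NA_character_, mqtl_beta = 0,
                        sex_effect = 0, age_effect = 0,
                        chip_effects = NULL, position_effects = NULL,
                        cell_signature = NULL,
                        probe_type = "II", type2_compression = 0.2,
                        chromosome = "1", position = NA_integer_,
                        n_cpg = 2L, n_snp = 0L, density_class = "IC",
                        multimap_flag = FALSE) {
  if (va < 0 || vf < 0 || ve < 0 || va + vf + ve <= 0)
    stop("variances must be non-negative with positive total")
  if (type2_compression < 0 || type2_compression >= 1)
    stop("'type2_compression' must lie in [0, 1)")
  if (!probe_type %in% c("I", "II")) stop("'probe_type' must be I or II")
  structure(list(
    intercept = intercept, va = va, vf = vf, ve = ve,
    mqtl_snp = mqtl_snp, mqtl_beta = mqtl_beta,
    sex_effect = sex_effect, age_effect = age_effect,
    chip_effects = chip_effects, position_effects = position_effects,
    cell_signature = cell_signature,
    probe_type = probe_type, type2_compression = type2_compression,
    chromosome = chromosome, position = position, n_cpg = n_cpg,
    n_snp = n_snp, density_class = density_class,
    multimap_flag = multimap_flag
  ), class = "probe_model")
}

#' Build a list of probe models with recycled parameters
#'
#' Convenience wrapper around [probe_model()]: scalar or vector arguments
#' are recycled to `n` probes, and probe positions default to an even grid
#' along the chromosome.
#'
#' @param n Number of probes.
#' @param position Probe positions (default even grid on 1..50 Mb).
#' @param ... Arguments of [probe_model()], scalar or length-`n` vectors.
#'   Vector-valued per-probe arguments (`chip_effects`, `cell_signature`,
#'   ...) must be wrapped in a `list()`, one element per probe (recycled).
#' @return List of `n` `probe_model` objects.
#' @export
make_probe_models <- function(n, position = NULL, ...) {
  args <- list(...)
  if (is.null(position))
    position <- as.integer(seq(1e6, 50e6, length.out = n))
  args$position <- position
  lapply(seq_len(n), function(i) {
    one <- lapply(args, function(a) {
      if (is.null(a)) a else a[[((i - 1L) %% length(a)) + 1L]]
    })
    do.call(probe_model, one)
  })
}

#' Generate a sample sheet with chip assignment and cell proportions
#'
#' Samples are randomly placed onto chips of `samples_per_chip` positions,
#' emulating the randomised array layout of a family study (no confounding
#' of chip with family). Optional per-sample blood cell proportions are
#' drawn from a Dirichlet distribution.
#'
#' @param ped Pedigree table.
#' @param samples_per_chip Positions per chip (12 for the 450K BeadChip).
#' @param cell_alpha Optional named Dirichlet concentration vector over
#'   [blood_cell_types]; `NULL` omits cell proportions.
#' @param cell_family_weight Fraction in `[0,1]` of each sample's cell
#'   proportions taken from a family-level Dirichlet draw rather than an
#'   individual one. Blood composition is itself partly heritable, so
#'   members of a family share part of their cell make-up; 0 (default)
#'   makes proportions independent across individuals.
#' @param seed Integer seed.
#' @return `data.frame` with `individual_id`, `chip`, `chip_position` and,
#'   when requested, one column per cell type (rows summing to 1).
#' @export
make_sample_sheet <- function(ped, samples_per_chip = 12L,
                              cell_alpha = NULL, cell_family_weight = 0,
                              seed = 1L) {
  set.seed(seed)
  n <- nrow(ped)
  ord <- sample.int(n)
  chip <- sprintf("chip%03d", (seq_len(n) - 1L) %/% samples_per_chip + 1L)
  pos <- sprintf("R%02d", (seq_len(n) - 1L) %% samples_per_chip + 1L)
  sheet <- data.frame(individual_id = ped$individual_id,
                      chip = chip[order(ord)], chip_position = pos[order(ord)],
                      stringsAsFactors = FALSE)
  if (!is.null(cell_alpha)) {
    if (is.null(names(cell_alpha)) || !all(names(cell_alpha) %in% blood_cell_types))
      stop("'cell_alpha' must be named by blood cell types")
    if (cell_family_weight < 0 || cell_family_weight > 1)
      stop("'cell_family_weight' must lie in [0,1]")
    rdir <- function(m) {
      g <- sapply(cell_alpha, function(a) stats::rgamma(m, shape = a))
      g <- matrix(g, nrow = m)
      g / rowSums(g)
    }
    fam <- factor(ped$family_id, levels = unique(ped$family_id))
    props <- (1 - cell_family_weight) * rdir(n) +
      cell_family_weight * rdir(nlevels(fam))[as.integer(fam), , drop = FALSE]
    sheet[names(cell_alpha)] <- props
  }
  sheet
}

#' Default Dirichlet concentrations for whole-blood cell proportions
#'
#' Mean composition dominated by granulocytes (~60%) with moderate
#' between-sample variability (total concentration 100).
#' @export
default_cell_alpha <- c(monocytes = 7, B_cells = 5, NK = 5, CD4_T = 15,
                        CD8_T = 8, granulocytes = 60)

#' Simulate a beta-value methylation matrix over a pedigree
#'
#' For each probe the latent log-odds of methylation per individual is
#' `intercept + covariate effects + mqtl_beta * dosage + a + f + e`, where
#' `a` is multivariate normal with covariance `va * A` (`A` the additive
#' relationship matrix, MZ entries 1), `f` is shared within each nuclear
#' family with variance `vf`, and `e` is independent with variance `ve`.
#' Beta values are the inverse logit of the latent value; type II probes are
#' compressed toward 0.5 by the probe's compression factor. Entries are set
#' missing completely at random at `missing_rate`; a fraction
#' `detect_fail_rate` of entries is assigned a failing detection p-value
#' (drawn uniform on (1e-3, 1); passing entries uniform on (0, 1e-4)).
#'
#' @param ped Pedigree table.
#' @param sheet Sample sheet from [make_sample_sheet()] (may be `NULL` when
#'   no probe uses covariates or cell signatures).
#' @param geno `genotype_matrix` (may be `NULL` when no probe has an mQTL).
#' @param probes List of [probe_model()] objects.
#' @param missing_rate Fraction of entries set missing at random.
#' @param detect_fail_rate Fraction of entries with failing detection p.
#' @param spouse_var Latent variance shared by the two founders of a family
#'   only (spouse-correlation knob; default 0).
#' @param vf_scope `"family"` shares the common-environment value across the
#'   whole nuclear family (default); `"offspring"` restricts it to children.
#' @param seed Integer seed.
#'
#' @return List with `beta` (a [beta_matrix()]: values, annotation and
#'   detection p), and `truth` (`data.frame` of generative `va`, `vf`, `ve`,
#'   `h2`, `c2` per probe).
#' @export
simulate_methylation <- function(ped, sheet = NULL, geno = NULL, probes,
                                 missing_rate = 0, detect_fail_rate = 0,
                                 spouse_var = 0, vf_scope = c("family", "offspring"),
                                 seed = 1L) {
  vf_scope <- match.arg(vf_scope)
  set.seed(seed)
  n <- nrow(ped)
  P <- length(probes)
  kin <- additive_relationship(ped)
  fam <- factor(ped$family_id, levels = unique(ped$family_id))
  fam_idx <- split(seq_len(n), fam)

  # block square roots of A (eigen-based: A is PSD but singular at MZ pairs)
  Lblocks <- lapply(fam_idx, function(ix) {
    Af <- kin$A[ix, ix, drop = FALSE]
    e <- eigen(Af, symmetric = TRUE)
    if (min(e$values) < -1e-8)
      stop("implied covariance is not positive semi-definite; ",
           "inconsistent pedigree")
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(ix))
  })

  # standardised components, shared across probes up to per-probe scaling
  a_std <- matrix(0, n, P)
  Z <- matrix(stats::rnorm(n * P), n, P)
  for (k in seq_along(fam_idx)) {
    ix <- fam_idx[[k]]
    a_std[ix, ] <- Lblocks[[k]] %*% Z[ix, , drop = FALSE]
  }
  f_draw <- matrix(stats::rnorm(nlevels(fam) * P), nlevels(fam), P)
  f_std <- f_draw[as.integer(fam), , drop = FALSE]
  if (vf_scope == "offspring")
    f_std[is.na(ped$father_id), ] <- 0
  e_std <- matrix(stats::rnorm(n * P), n, P)
  s_std <- matrix(0, n, P)
  if (spouse_var > 0) {
    s_draw <- matrix(stats::rnorm(nlevels(fam) * P), nlevels(fam), P)
    founders <- is.na(ped$father_id)
    s_std[founders, ] <- s_draw[as.integer(fam)[founders], , drop = FALSE]
  }

  female <- as.numeric(ped$sex == "female")
  age <- ped$age
  dos_mean <- NULL
  if (!is.null(geno)) {
    dos <- geno$dosage[, ped$individual_id, drop = FALSE]
    dos_mean <- rowMeans(dos, na.rm = TRUE)
  }
  cellmat <- NULL
  if (!is.null(sheet) && all(blood_cell_types %in% names(sheet)))
    cellmat <- as.matrix(sheet[match(ped$individual_id, sheet$individual_id),
                               blood_cell_types])

  beta <- matrix(NA_real_, P, n)
  for (p in seq_len(P)) {
    pm <- probes[[p]]
    lat <- rep(pm$intercept, n) +
      pm$sex_effect * female + pm$age_effect * age +
      sqrt(pm$va) * a_std[, p] + sqrt(pm$vf) * f_std[, p] +
      sqrt(pm$ve) * e_std[, p] + sqrt(spouse_var) * s_std[, p]
    if (!is.null(pm$chip_effects)) {
      if (is.null(sheet)) stop("probe uses chip effects but no sample sheet given")
      ix <- match(ped$individual_id, sheet$individual_id)
      lat <- lat + pm$chip_effects[sheet$chip[ix]]
    }
    if (!is.null(pm$position_effects)) {
      ix <- match(ped$individual_id, sheet$individual_id)
      lat <- lat + pm$position_effects[sheet$chip_position[ix]]
    }
    if (!is.na(pm$mqtl_snp) && pm$mqtl_beta != 0) {
      if (is.null(geno)) stop("probe references an mQTL but no genotypes given")
      g <- dos[pm$mqtl_snp, ]
      g[is.na(g)] <- dos_mean[pm$mqtl_snp]
      lat <- lat + pm$mqtl_beta * g
    }
    if (!is.null(pm$cell_signature)) {
      if (is.null(cellmat))
        stop("probe has a cell signature but the sheet lacks cell proportions")
      lat <- lat + drop(cellmat[, names(pm$cell_signature), drop = FALSE] %*%
                          pm$cell_signature)
    }
    b <- stats::plogis(lat)
    if (pm$probe_type == "II")
      b <- 0.5 + (1 - pm$type2_compression) * (b - 0.5)
    beta[p, ] <- b
  }

  probe_id <- sprintf("cg%06d", seq_len(P))
  dimnames(beta) <- list(probe_id, ped$individual_id)

  detp <- matrix(stats::runif(P * n, 0, 1e-4), P, n, dimnames = dimnames(beta))
  if (detect_fail_rate > 0) {
    fail <- stats::runif(P * n) < detect_fail_rate
    detp[fail] <- stats::runif(sum(fail), 1e-3, 1)
  }
  if (missing_rate > 0)
    beta[stats::runif(P * n) < missing_rate] <- NA_real_

  annotation <- data.frame(
    probe_id = probe_id,
    chromosome = vapply(probes, `[[`, "", "chromosome"),
    position = vapply(probes, function(x) as.integer(x$position), 0L),
    probe_type = vapply(probes, `[[`, "", "probe_type"),
    n_cpg = vapply(probes, function(x) as.integer(x$n_cpg), 0L),
    n_snp = vapply(probes, function(x) as.integer(x$n_snp), 0L),
    density_class = vapply(probes, `[[`, "", "density_class"),
    multimap_flag = vapply(probes, `[[`, TRUE, "multimap_flag"),
    stringsAsFactors = FALSE
  )
  tot <- vapply(probes, function(x) x$va + x$vf + x$ve, 0)
  truth <- data.frame(
    probe_id = probe_id,
    va = vapply(probes, `[[`, 0, "va"),
    vf = vapply(probes, `[[`, 0, "vf"),
    ve = vapply(probes, `[[`, 0, "ve"),
    h2 = vapply(probes, `[[`, 0, "va") / tot,
    c2 = vapply(probes, `[[`, 0, "vf") / tot,
    stringsAsFactors = FALSE
  )
  list(beta = beta_matrix(beta, annotation, detp), truth = truth)
}
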