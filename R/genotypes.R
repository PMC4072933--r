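#' Gene-drop SNP genotypes through a pedigree
#'
#' Simulates biallelic SNP dosages by gene dropping: founder allele counts
#' are drawn binomially at each SNP's minor allele frequency, each child
#' receives one allele from each parent uniformly at random, and monozygotic
#' co-twins copy the realised gamete pair of their twin. Mendelian
#' transmission therefore holds exactly and MZ pairs are genotypically
#' identical.
#'
#' @param ped Pedigree table from [generate_pedigree()].
#' @param n_snps Number of SNPs (positive integer).
#' @param maf_range Length-2 numeric in (0, 0.5]: per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param chromosome Chromosome label for the SNP map (single string).
#' @param pos_range Length-2 integer range for uniform SNP positions (bp).
#' @param missing_rate Fraction of dosage entries set missing at random.
#' @param seed Integer seed.
#'
#' @return A list of class `genotype_matrix`: `dosage` (SNPs x individuals
#'   integer matrix in `{0,1,2}`, `NA` for missing) and `map` (`data.frame`
#'   with `snp_id`, `chromosome`, `position`, `maf`).
#' @export
simulate_genotypes <- function(ped, n_snps, maf_range = c(0.05, 0.5),
                               chromosome = "1",
                               pos_range = c(1e6L, 50e6L),
                               missing_rate = 0, seed = 1L) {
  if (n_snps < 1) stop("'n_snps' must be positive")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must lie within (0, 0.5]")
  set.seed(seed)

  n <- nrow(ped)
  n_snps <- as.integer(n_snps)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  pos <- sort(as.integer(stats::runif(n_snps, pos_range[1], pos_range[2])))

  ord <- pedigree_order(ped)
  fi <- match(ped$father_id, ped$individual_id)
  mi <- match(ped$mother_id, ped$individual_id)

  # allele matrices: one paternal-origin and one maternal-origin allele per
  # individual, so child transmissions are drawn from true gametes
  pat <- matrix(NA_integer_, n_snps, n)
  mat <- matrix(NA_integer_, n_snps, n)

  mz_partner <- rep(NA_integer_, n)
  mz <- which(ped$zygosity == "MZ_twin")
  for (i in mz) {
    j <- setdiff(which(!is.na(ped$twin_pair) &
                         ped$twin_pair == ped$twin_pair[i]), i)
    mz_partner[i] <- j
  }

  for (i in ord) {
    if (is.na(fi[i])) {
      pat[, i] <- stats::rbinom(n_snps, 1L, maf)
      mat[, i] <- stats::rbinom(n_snps, 1L, maf)
    } else if (!is.na(mz_partner[i]) && !is.na(pat[1L, mz_partner[i]])) {
      pat[, i] <- pat[, mz_partner[i]]
      mat[, i] <- mat[, mz_partner[i]]
    } else {
      pick_f <- stats::runif(n_snps) < 0.5
      pick_m <- stats::runif(n_snps) < 0.5
      pat[, i] <- ifelse(pick_f, pat[, fi[i]], mat[, fi[i]])
      mat[, i] <- ifelse(pick_m, pat[, mi[i]], mat[, mi[i]])
    }
  }

  dosage <- pat + mat
  if (missing_rate > 0)
    dosage[stats::runif(length(dosage)) < missing_rate] <- NA_integer_
  dimnames(dosage) <- list(sprintf("snp%05d", seq_len(n_snps)),
                           ped$individual_id)
  structure(list(
    dosage = dosage,
    map = data.frame(snp_id = rownames(dosage), chromosome = chromosome,
                     position = pos, maf = maf, stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}
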