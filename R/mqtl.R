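#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test of Hardy-Weinberg proportions for a biallelic
#' marker: given the allele counts, the p-value is the total probability of
#' heterozygote counts as or less probable than the one observed.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote; order does not matter for the test).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  n_rare <- 2L * min(n_aa, n_bb) + n_ab
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # log P(het = h | allele counts), up to a common constant
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2L
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  sum(pr[pr <= pr[obs] * (1 + 1e-7)])
}

#' SNP quality control for family association analysis
#'
#' Drops SNPs failing, in order: minor allele frequency strictly below
#' `maf_min` (computed from all non-missing dosages), exact Hardy-Weinberg
#' test below `hwe_alpha` (founders only, avoiding pedigree-induced
#' departures from HWE), and missing rate strictly above `max_missing`.
#'
#' @param geno `genotype_matrix` from [simulate_genotypes()].
#' @param ped Pedigree table (identifies founders for the HWE test).
#' @param maf_min Minimum minor allele frequency (default 0.05; SNPs at
#'   exactly the threshold are retained).
#' @param hwe_alpha HWE exact-test significance threshold (default 1e-6).
#' @param max_missing Maximum missing rate (default 0.10; SNPs at exactly
#'   the threshold are retained).
#' @return List: `geno` (filtered `genotype_matrix`) and `tally`
#'   (`data.frame` of SNPs removed per rule, applied sequentially).
#' @export
snp_qc <- function(geno, ped, maf_min = 0.05, hwe_alpha = 1e-6,
                   max_missing = 0.10) {
  dos <- geno$dosage
  keep <- rep(TRUE, nrow(dos))
  tally <- list()
  drop_rule <- function(keep, bad, rule) {
    bad <- bad & keep
    tally[[length(tally) + 1L]] <<- data.frame(rule = rule, removed = sum(bad))
    keep & !bad
  }

  p <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- drop_rule(keep, maf < maf_min, "maf")

  founders <- ped$individual_id[is.na(ped$father_id)]
  fd <- dos[, intersect(founders, colnames(dos)), drop = FALSE]
  hwe_p <- vapply(seq_len(nrow(fd)), function(i) {
    g <- fd[i, ]
    hwe_exact_p(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, 0)
  keep <- drop_rule(keep, hwe_p < hwe_alpha, "hwe")

  miss <- rowMeans(is.na(dos))
  keep <- drop_rule(keep, miss > max_missing, "missingness")

  out <- geno
  out$dosage <- dos[keep, , drop = FALSE]
  out$map <- geno$map[keep, , drop = FALSE]
  list(geno = out, tally = do.call(rbind, tally))
}

# GLS effect of a single regressor with variance components held fixed:
# rotated weighted least squares on X = [1, g].
gls_snp_effect <- function(ytil, gtil, onetil, w) {
  Xt <- cbind(onetil, gtil)
  Xw <- Xt / w
  xx <- crossprod(Xt, Xw)
  xy <- crossprod(Xw, ytil)
  V <- tryCatch(solve(xx), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  beta <- drop(V %*% xy)
  list(effect = beta[2], se = sqrt(V[2, 2]))
}

#' Family-aware association scan of SNPs against one probe
#'
#' Measured-genotype association on family data: the probe's variance
#' components `(Va, Ve)` are estimated once under the no-SNP AE null, then
#' each SNP's allelic-dosage effect is estimated by generalised least
#' squares with covariance `Va * A + Ve * I` held fixed, with a Wald test
#' against the standard normal. Holding the null components fixed across
#' SNPs keeps the scan linear in the number of SNPs while retaining the
#' family correction that an unrelated-sample scan lacks.
#'
#' @param y Residual row, ordered or named as `kin$id`.
#' @param geno `genotype_matrix`.
#' @param kin `kinship_matrix`.
#' @param probe_id Label copied into the output.
#' @param min_n Minimum individuals with both phenotype and genotype.
#' @return `data.frame`: `snp_id`, `probe_id`, `effect` (per allele, on the
#'   analysis scale), `se`, `p_value`, `n_used`; monomorphic SNPs carry
#'   `NA` effects and are flagged in `skipped`.
#' @export
assoc_scan <- function(y, geno, kin, probe_id = "probe", min_n = 30L) {
  if (!is.null(names(y))) y <- y[kin$id]
  if (length(y) != length(kin$id)) stop("'y' must be ordered as kin$id")
  idx <- !is.na(y)
  if (sum(idx) < min_n)
    stop("need at least ", min_n, " individuals with phenotype")
  null_fit <- fit_varcomp(y, kin, model = "AE")
  va <- null_fit$va; ve <- null_fit$ve

  dos <- geno$dosage[, kin$id, drop = FALSE]
  cache <- new.env(parent = emptyenv())
  get_struct <- function(sub) {
    key <- paste(which(sub), collapse = ",")
    st <- cache[[key]]
    if (is.null(st)) {
      st <- ae_structure(kin, sub)
      st$w <- va * st$d + ve
      st$onetil <- drop(st$Ut %*% rep(1, sum(sub)))
      cache[[key]] <- st
    }
    st
  }

  n_snp <- nrow(dos)
  eff <- se <- pv <- rep(NA_real_, n_snp)
  nu <- integer(n_snp)
  skip <- logical(n_snp)
  for (i in seq_len(n_snp)) {
    g <- dos[i, ]
    sub <- idx & !is.na(g)
    nu[i] <- sum(sub)
    if (nu[i] < min_n || stats::var(g[sub]) == 0) {
      skip[i] <- TRUE
      next
    }
    st <- get_struct(sub)
    ytil <- drop(st$Ut %*% y[sub])
    gtil <- drop(st$Ut %*% g[sub])
    fit <- gls_snp_effect(ytil, gtil, st$onetil, st$w)
    if (is.null(fit)) { skip[i] <- TRUE; next }
    eff[i] <- fit$effect
    se[i] <- fit$se
    pv[i] <- 2 * stats::pnorm(-abs(fit$effect / fit$se))
  }
  data.frame(snp_id = rownames(dos), probe_id = probe_id, effect = eff,
             se = se, p_value = pv, n_used = nu, skipped = skip,
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (positive).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (n_tests < 1) stop("'n_tests' must be positive")
  alpha / n_tests
}

#' Regional effect profile of a lead SNP on surrounding probes
#'
#' Tests a single lead SNP for association with every probe whose target
#' CpG lies within `window_bp / 2` of the SNP on the same chromosome (the
#' full window spans `window_bp`). Each probe is analysed with
#' [assoc_scan()]'s measured-genotype model; effects are reported signed,
#' since regional mQTL typically act in both directions, and probes passing
#' the Bonferroni threshold are flagged.
#'
#' @param lead_snp SNP id present in `geno`.
#' @param resid `residual_matrix` (its annotation provides probe positions).
#' @param geno `genotype_matrix`.
#' @param kin `kinship_matrix`.
#' @param window_bp Full window span centred on the SNP (default 8 Mb).
#' @param sig_threshold P-value cutoff for the `significant` flag; defaults
#'   to `bonferroni_threshold(0.05, nrow(resid$values))`.
#' @return `data.frame`: `probe_id`, `position`, `distance_bp`, `effect`,
#'   `se`, `p_value`, `n_used`, `significant`. Empty (with a message) when
#'   no probe falls in the window.
#' @export
region_effects <- function(lead_snp, resid, geno, kin, window_bp = 8e6,
                           sig_threshold = NULL) {
  stopifnot(inherits(resid, "residual_matrix"))
  map <- geno$map
  hit <- match(lead_snp, map$snp_id)
  if (is.na(hit)) stop("lead SNP not found in genotype map")
  if (is.null(sig_threshold))
    sig_threshold <- bonferroni_threshold(0.05, nrow(resid$values))

  ann <- resid$annotation
  sel <- which(ann$chromosome == map$chromosome[hit] &
                 abs(ann$position - map$position[hit]) <= window_bp / 2)
  if (!length(sel)) {
    message("no probes within ", window_bp, " bp of ", lead_snp)
    return(data.frame(probe_id = character(), position = integer(),
                      distance_bp = integer(), effect = numeric(),
                      se = numeric(), p_value = numeric(),
                      n_used = integer(), significant = logical()))
  }
  sub <- geno
  sub$dosage <- geno$dosage[hit, , drop = FALSE]
  sub$map <- map[hit, , drop = FALSE]

  rows <- lapply(sel, function(p) {
    a <- assoc_scan(resid$values[p, ], sub, kin,
                    probe_id = ann$probe_id[p])
    data.frame(probe_id = ann$probe_id[p], position = ann$position[p],
               distance_bp = ann$position[p] - map$position[hit],
               effect = a$effect, se = a$se, p_value = a$p_value,
               n_used = a$n_used,
               significant = !is.na(a$p_value) & a$p_value < sig_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
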