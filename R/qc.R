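#' Construct a beta-value matrix with probe annotation
#'
#' Container for a probes x samples methylation matrix: beta values in
#' `[0,1]` (missing allowed), per-probe annotation, and an optional matching
#' detection p-value matrix.
#'
#' @param values Numeric matrix, probes x samples, entries in `[0,1]` or `NA`.
#' @param annotation `data.frame` with one row per probe: `probe_id`,
#'   `chromosome`, `position`, `probe_type`, `n_cpg`, `n_snp`,
#'   `density_class`, `multimap_flag`.
#' @param detp Optional detection p-value matrix, same shape as `values`.
#' @return List of class `beta_matrix`.
#' @export
beta_matrix <- function(values, annotation, detp = NULL) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  need <- c("probe_id", "chromosome", "position", "probe_type", "n_cpg",
            "n_snp", "density_class", "multimap_flag")
  if (!all(need %in% names(annotation)))
    stop("annotation is missing columns: ",
         paste(setdiff(need, names(annotation)), collapse = ", "))
  if (nrow(annotation) != nrow(values))
    stop("annotation must have one row per probe")
  if (!is.null(detp) && !identical(dim(detp), dim(values)))
    stop("'detp' must match the dimensions of 'values'")
  structure(list(values = values, annotation = annotation, detp = detp),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples;",
      sum(is.na(x$values)), "missing entries;",
      if (is.null(x$detp)) "no" else "with", "detection p\n")
  invisible(x)
}

#' Binomial threshold for per-probe missingness or detection failures
#'
#' Returns the smallest integer `k` such that the probability of more than
#' `k` affected samples under `Binomial(n_samples, avg_rate)` falls below a
#' Bonferroni-corrected significance level `alpha / n_probes`. Probes with
#' more than `k` affected samples deviate significantly from random
#' missingness (or excess poor binding) and are removed.
#'
#' @param avg_rate Pooled mean rate over all probes and samples, in (0, 1).
#' @param n_samples Number of samples.
#' @param n_probes Number of probes (Bonferroni denominator).
#' @param alpha Significance level before correction.
#' @return Integer cutoff `k`; a probe is flagged when its count exceeds `k`.
#' @export
missingness_threshold <- function(avg_rate, n_samples, n_probes, alpha = 0.05) {
  if (!is.finite(avg_rate) || avg_rate <= 0 || avg_rate >= 1)
    stop("'avg_rate' must lie strictly between 0 and 1")
  if (n_samples < 1 || n_probes < 1 || alpha <= 0 || alpha > 1)
    stop("invalid 'n_samples', 'n_probes' or 'alpha'")
  k <- 0:n_samples
  tail <- stats::pbinom(k, n_samples, avg_rate, lower.tail = FALSE)
  hit <- which(tail < alpha / n_probes)
  if (!length(hit)) return(as.integer(n_samples))
  as.integer(k[hit[1]])
}

#' Apply probe-level quality-control filters
#'
#' Removes, in order: probes on the sex chromosomes, probes annotated as
#' mapping to multiple chromosomes, probes covering zero CpG sites, probes
#' with more missing samples than `cutoff_missing`, probes with more samples
#' at detection p above `detect_p` than `cutoff_detect`, and (optionally)
#' probes containing annotated SNPs. The filter is idempotent.
#'
#' @param bm A [beta_matrix()].
#' @param cutoff_missing Integer; probes with missing count strictly greater
#'   are removed (`NULL` skips the rule).
#' @param cutoff_detect Integer; probes with more samples than this at
#'   detection p > `detect_p` are removed (`NULL` or absent detection
#'   matrix skips the rule).
#' @param detect_p Detection p-value considered a failure (default 0.001).
#' @param exclude_snp_probes If `TRUE`, additionally keep only probes with
#'   `n_snp == 0` (used to guard heritability estimates against SNPs
#'   disrupting probe binding).
#' @return List: `beta` (filtered [beta_matrix()]) and `tally`
#'   (`data.frame` of probes removed per rule, applied sequentially).
#' @export
filter_probes <- function(bm, cutoff_missing = NULL, cutoff_detect = NULL,
                          detect_p = 0.001, exclude_snp_probes = FALSE) {
  stopifnot(inherits(bm, "beta_matrix"))
  ann <- bm$annotation
  keep <- rep(TRUE, nrow(ann))
  tally <- list()
  drop_rule <- function(keep, bad, rule) {
    bad <- bad & keep
    tally[[length(tally) + 1L]] <<- data.frame(rule = rule,
                                               removed = sum(bad))
    keep & !bad
  }

  chr <- toupper(sub("^chr", "", ann$chromosome, ignore.case = TRUE))
  keep <- drop_rule(keep, chr %in% c("X", "Y"), "sex_chromosome")
  keep <- drop_rule(keep, ann$multimap_flag, "multi_mapping")
  keep <- drop_rule(keep, ann$n_cpg == 0, "zero_cpg")
  if (!is.null(cutoff_missing)) {
    nmiss <- rowSums(is.na(bm$values))
    keep <- drop_rule(keep, nmiss > cutoff_missing, "missingness")
  }
  if (!is.null(cutoff_detect) && !is.null(bm$detp)) {
    nfail <- rowSums(bm$detp > detect_p, na.rm = TRUE)
    keep <- drop_rule(keep, nfail > cutoff_detect, "detection_p")
  }
  if (exclude_snp_probes)
    keep <- drop_rule(keep, ann$n_snp > 0, "snp_in_probe")

  out <- beta_matrix(bm$values[keep, , drop = FALSE],
                     ann[keep, , drop = FALSE],
                     if (is.null(bm$detp)) NULL else bm$detp[keep, , drop = FALSE])
  list(beta = out, tally = do.call(rbind, tally))
}
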