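#' Enumerate and classify relative pairs from a pedigree
#'
#' Produces every within-family pair classified as MZ twin, DZ twin,
#' sibling (including twin-to-non-twin-sibling pairs), parent-offspring
#' (with the parent's sex recorded so mother- and father-offspring rows can
#' be split out) or spouse (the two parents of shared children). When
#' `include_unrelated = TRUE` all cross-family pairs are appended as
#' unrelated. Each unordered pair is emitted exactly once.
#'
#' @param ped Pedigree table.
#' @param include_unrelated Append all cross-family pairs (quadratic in the
#'   cohort size; 187,331 pairs for a 614-individual cohort).
#' @return `data.frame` with `id_a`, `id_b`, `class`, `expected_share`
#'   (coefficient on h-squared: 1, 0.5 or 0) and `parent_sex` (`NA` except
#'   for parent-offspring pairs).
#' @export
classify_pairs <- function(ped, include_unrelated = FALSE) {
  validate_pedigree(ped)
  rows <- list()
  add <- function(a, b, class, share, psex = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id_a = a, id_b = b, class = class, expected_share = share,
      parent_sex = psex, stringsAsFactors = FALSE)
  }
  for (fam in unique(ped$family_id)) {
    fp <- ped[ped$family_id == fam, ]
    parents <- fp$individual_id[is.na(fp$father_id)]
    children <- fp[!is.na(fp$father_id), ]
    if (length(parents) == 2L) {
      kids_of <- function(p) children$individual_id[
        children$father_id == p | children$mother_id == p]
      if (length(intersect(kids_of(parents[1]), kids_of(parents[2]))) > 0)
        add(parents[1], parents[2], "spouse", 0)
    }
    for (p in parents) {
      psex <- fp$sex[fp$individual_id == p]
      kids <- children$individual_id[children$father_id == p |
                                       children$mother_id == p]
      for (k in kids) add(p, k, "parent_offspring", 0.5, psex)
    }
    nk <- nrow(children)
    if (nk >= 2L) {
      for (i in seq_len(nk - 1L)) for (j in (i + 1L):nk) {
        a <- children[i, ]; b <- children[j, ]
        if (!is.na(a$twin_pair) && !is.na(b$twin_pair) &&
            a$twin_pair == b$twin_pair) {
          if (a$zygosity == "MZ_twin") add(a$individual_id, b$individual_id, "MZ", 1)
          else add(a$individual_id, b$individual_id, "DZ", 0.5)
        } else {
          add(a$individual_id, b$individual_id, "sibling", 0.5)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (include_unrelated) {
    fam <- ped$family_id
    id <- ped$individual_id
    n <- length(id)
    ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    jj <- sequence((n - 1L):1L) + ii
    cross <- fam[ii] != fam[jj]
    out <- rbind(out, data.frame(
      id_a = id[ii[cross]], id_b = id[jj[cross]], class = "unrelated",
      expected_share = 0, parent_sex = NA_character_,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Subsample a pair table to disjoint pairs
#'
#' Greedily keeps, within each relationship class, only pairs whose members
#' have not appeared in an earlier retained pair of that class, so the
#' retained pairs are independent draws from distinct individuals.
#' All-pairs enumeration reuses individuals (one parent pairs with each of
#' its children, every unrelated pair shares members with many others),
#' which biases the average intraclass correlation slightly downward; on
#' disjoint pairs that non-independence bias vanishes.
#'
#' @param pairs Pair table from [classify_pairs()].
#' @return The subset of `pairs` with member-disjoint rows per class.
#' @export
disjoint_pairs <- function(pairs) {
  keep <- logical(nrow(pairs))
  for (cls in unique(pairs$class)) {
    ix <- which(pairs$class == cls)
    used <- character(0)
    for (i in ix) {
      if (!(pairs$id_a[i] %in% used) && !(pairs$id_b[i] %in% used)) {
        keep[i] <- TRUE
        used <- c(used, pairs$id_a[i], pairs$id_b[i])
      }
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Intraclass correlation of paired values by one-way ANOVA
#'
#' Treats each pair as a group of two and computes
#' `(MS_B - MS_W) / (MS_B + MS_W)` where `MS_B` and `MS_W` are the between-
#' and within-pair mean squares of the one-way random-effects ANOVA. Pairs
#' with a missing member are dropped. The statistic is order-invariant
#' within pairs, so no double entry is needed.
#'
#' @param a,b Numeric vectors: the two members of each pair.
#' @return ICC in `[-1, 1]`; 0 with a warning when all values are identical
#'   (both mean squares vanish).
#' @export
icc <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs")
  m <- (a + b) / 2
  g <- mean(m)
  msb <- 2 * sum((m - g)^2) / (n - 1)
  msw <- sum((a - b)^2) / (2 * n)
  if (msb + msw == 0) {
    warning("all values identical; ICC undefined, returning 0")
    return(0)
  }
  (msb - msw) / (msb + msw)
}

#' Per-relationship-class average correlations across probes
#'
#' For every relationship class, computes the ANOVA intraclass correlation
#' of each probe's residuals over the class's pairs, then averages across
#' probes (unweighted) — the per-class "average correlation across all
#' probes" summary of a family methylation study. Parent-offspring pairs
#' are additionally split into mother- and father-offspring rows.
#'
#' @param resid A `residual_matrix` from [normalize_matrix()], or a plain
#'   probes x samples matrix with sample ids as column names.
#' @param pairs Pair table from [classify_pairs()].
#' @return `data.frame` with `class`, `n_pairs`, `mean_correlation`, `se`
#'   (Monte-Carlo standard error of the mean over probes), `n_probes`
#'   (probes contributing) and `expected` (`"h2"`, `"h2/2"` or `"0"`),
#'   ordered MZ, DZ, sibling, parent-offspring, mother-offspring,
#'   father-offspring, spouse, unrelated.
#' @export
correlation_table <- function(resid, pairs) {
  V <- if (inherits(resid, "residual_matrix")) resid$values else resid
  if (is.null(colnames(V))) stop("residual matrix must have sample ids as colnames")
  if (!all(c(pairs$id_a, pairs$id_b) %in% colnames(V)))
    stop("pair table references samples absent from the matrix")

  split_defs <- list(
    MZ = quote(pairs$class == "MZ"),
    DZ = quote(pairs$class == "DZ"),
    sibling = quote(pairs$class == "sibling"),
    parent_offspring = quote(pairs$class == "parent_offspring"),
    mother_offspring = quote(pairs$class == "parent_offspring" &
                               pairs$parent_sex == "female"),
    father_offspring = quote(pairs$class == "parent_offspring" &
                               pairs$parent_sex == "male"),
    spouse = quote(pairs$class == "spouse"),
    unrelated = quote(pairs$class == "unrelated")
  )
  expected <- c(MZ = "h2", DZ = "h2/2", sibling = "h2/2",
                parent_offspring = "h2/2", mother_offspring = "h2/2",
                father_offspring = "h2/2", spouse = "0", unrelated = "0")

  out <- list()
  for (cls in names(split_defs)) {
    sel <- eval(split_defs[[cls]])
    if (!any(sel)) next
    ia <- match(pairs$id_a[sel], colnames(V))
    ib <- match(pairs$id_b[sel], colnames(V))
    vals <- rep(NA_real_, nrow(V))
    for (p in seq_len(nrow(V))) {
      x <- V[p, ia]; y <- V[p, ib]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= 2L)
        vals[p] <- icc(x[ok], y[ok])
    }
    used <- sum(!is.na(vals))
    out[[cls]] <- data.frame(class = cls, n_pairs = sum(sel),
                             mean_correlation = mean(vals, na.rm = TRUE),
                             se = stats::sd(vals, na.rm = TRUE) / sqrt(used),
                             n_probes = used,
                             expected = expected[[cls]],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
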