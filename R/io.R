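#' Write a probes x samples matrix as TSV
#'
#' Probe ids in the first column, sample ids as header — the plain-text
#' interchange format used by the analysis scripts for beta, detection-p
#' and residual matrices.
#'
#' @param m Matrix with row and column names.
#' @param path Output file path.
#' @param id_col Name of the id column (default `"probe_id"`).
#' @return Invisibly `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probes x samples TSV matrix written by [write_matrix_tsv()]
#'
#' @param path Input file path.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write genotype dosages as TSV (SNP map columns then per-sample dosages)
#'
#' @param geno `genotype_matrix`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(geno$map, geno$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
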