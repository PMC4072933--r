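#' Synthetic blood cell-type methylation reference
#'
#' Builds a reference panel of mean beta profiles for the six leukocyte
#' types over a set of signature probes. Profiles are drawn once from a
#' fixed seed so the panel is reproducible; each probe is made discriminative
#' by giving each cell type an independent Beta-distributed mean. The panel
#' is synthetic: it emulates the role of a sorted-cell reference data set,
#' not any published panel.
#'
#' @param n_probes Number of signature probes (default 200).
#' @param seed Integer seed.
#' @return Matrix `n_probes` x 6 in `[0,1]`, columns [blood_cell_types],
#'   rows named `sig0001...`.
#' @export
make_cell_reference <- function(n_probes = 200L, seed = 42L) {
  set.seed(seed)
  ref <- matrix(stats::rbeta(n_probes * length(blood_cell_types), 0.8, 0.8),
                n_probes, length(blood_cell_types),
                dimnames = list(sprintf("sig%04d", seq_len(n_probes)),
                                blood_cell_types))
  ref
}

#' Estimate cell-type proportions by constrained least squares
#'
#' Per sample, finds the non-negative, sum-to-one mixture of reference
#' profiles closest (least squares) to the sample's beta values at the
#' signature probes — the standard reference-based deconvolution of whole
#' blood into monocytes, B cells, NK, CD4+ and CD8+ T cells and
#' granulocytes. The constrained optimum is found exactly by solving the
#' equality-constrained problem on every support (subset of cell types
#' allowed to be non-zero) and keeping the feasible solution with the
#' smallest residual.
#'
#' @param beta Matrix of beta values, signature probes x samples (rows
#'   matched to `ref` by name when both are named).
#' @param ref Reference matrix, signature probes x cell types.
#' @return List: `proportions` (samples x cell types, rows on the simplex)
#'   and `residual_norm` (per-sample Euclidean residual).
#' @export
estimate_cell_proportions <- function(beta, ref) {
  if (is.vector(beta)) beta <- matrix(beta, ncol = 1L)
  if (!is.null(rownames(beta)) && !is.null(rownames(ref))) {
    common <- intersect(rownames(beta), rownames(ref))
    if (length(common) < ncol(ref))
      stop("fewer shared signature probes than cell types")
    beta <- beta[common, , drop = FALSE]
    ref <- ref[common, , drop = FALSE]
  }
  if (nrow(ref) < ncol(ref))
    stop("need at least as many signature probes as cell types")
  if (qr(ref)$rank < ncol(ref))
    stop("reference matrix is rank deficient")

  K <- ncol(ref)
  supports <- lapply(seq_len(2^K - 1L),
                     function(m) which(bitwAnd(m, 2^(seq_len(K) - 1L)) > 0))
  n <- ncol(beta)
  W <- matrix(0, n, K, dimnames = list(colnames(beta), colnames(ref)))
  rn <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    b <- beta[, s]
    ok <- !is.na(b)
    best <- Inf; best_w <- NULL
    for (sup in supports) {
      R <- ref[ok, sup, drop = FALSE]
      k <- length(sup)
      # KKT system for min ||R w - b||^2 s.t. sum(w) = 1
      M <- rbind(cbind(2 * crossprod(R), rep(1, k)), c(rep(1, k), 0))
      rhs <- c(2 * crossprod(R, b[ok]), 1)
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      w <- sol[seq_len(k)]
      if (any(w < -1e-10)) next
      r2 <- sum((R %*% w - b[ok])^2)
      if (r2 < best - 1e-12) { best <- r2; best_w <- replace(numeric(K), sup, w) }
    }
    W[s, ] <- pmax(best_w, 0)
    W[s, ] <- W[s, ] / sum(W[s, ])
    rn[s] <- sqrt(best)
  }
  list(proportions = W, residual_norm = rn)
}

#' Mix reference profiles into synthetic sample beta values
#'
#' Convenience generator for deconvolution tests and demonstrations:
#' `ref %*% t(props)` plus optional Gaussian noise, clipped to `[0,1]`.
#'
#' @param ref Reference matrix (probes x cell types).
#' @param props Samples x cell types proportion matrix.
#' @param noise_sd Standard deviation of added measurement noise.
#' @param seed Integer seed.
#' @return Matrix of beta values, signature probes x samples.
#' @export
mix_cell_profiles <- function(ref, props, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  stopifnot(ncol(ref) == ncol(props))
  B <- ref %*% t(props)
  if (noise_sd > 0)
    B <- B + matrix(stats::rnorm(length(B), 0, noise_sd), nrow(B))
  pmin(pmax(B, 0), 1)
}
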