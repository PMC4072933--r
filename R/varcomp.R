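#' @title Per-probe variance-component machinery
#' @description Internal helpers exploit the block-diagonal structure of the
#'   relationship matrices over families: the multivariate-normal likelihood
#'   factors over families, and for the additive-plus-residual (AE) model a
#'   per-family eigendecomposition of A turns every likelihood evaluation
#'   into O(n) vector arithmetic.
#' @name varcomp-internal
#' @keywords internal
NULL

# Eigen structure of A restricted to the individuals in `idx` (a logical or
# integer index into kin$id), block-diagonal over families. Returns the
# (dense) transposed eigenvector matrix Ut, eigenvalues d, family factor.
ae_structure <- function(kin, idx) {
  ids <- seq_along(kin$id)[idx]
  m <- length(ids)
  fam <- kin$family[ids]
  Ut <- matrix(0, m, m)
  d <- numeric(m)
  for (f in unique(fam)) {
    loc <- which(fam == f)
    e <- eigen(kin$A[ids[loc], ids[loc], drop = FALSE], symmetric = TRUE)
    Ut[loc, loc] <- t(e$vectors)
    d[loc] <- pmax(e$values, 0)
  }
  list(Ut = Ut, d = d, ids = ids, fam = fam)
}

# Profiled AE negative log-likelihood in the rotated basis at variance
# ratio lambda = va/ve: weights w = lambda*d + 1, mean profiled by GLS and
# ve profiled analytically. Returns the components needed to reconstruct
# the fit. (Up to the 2*pi constant handled by the caller.)
ae_profile <- function(lam, ytil, Xtil, d) {
  m <- length(ytil)
  w <- lam * d + 1
  Xw <- Xtil / w
  xx <- crossprod(Xtil, Xw)
  xy <- crossprod(Xw, ytil)
  beta <- tryCatch(solve(xx, xy), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = 1e10))
  r <- drop(ytil - Xtil %*% beta)
  ve <- mean(r^2 / w)
  if (ve <= 0) return(list(nll = 1e10))
  list(nll = 0.5 * (sum(log(w)) + m * log(ve) + m), ve = ve, r = r, w = w)
}

# Exact maximum of the AE likelihood over va, ve >= 0. The boundary va = 0
# is decided by the sign of the profile score there (envelope theorem: at
# lambda = 0 the derivative is 0.5 * (sum(d * r0^2) / ve0 - sum(d)) with r0
# the OLS residuals); an interior optimum is located by golden-section
# search on log(lambda) and compared against the boundary.
fit_ae_rotated <- function(ytil, Xtil, d) {
  m <- length(ytil)
  p0 <- ae_profile(0, ytil, Xtil, d)
  interior_score <- sum(d * p0$r^2) / p0$ve - sum(d)
  best <- list(lam = 0, prof = p0)
  if (interior_score > 0) {
    o <- stats::optimize(function(t) ae_profile(exp(t), ytil, Xtil, d)$nll,
                         interval = c(log(1e-8), log(1e8)), tol = 1e-9)
    pI <- ae_profile(exp(o$minimum), ytil, Xtil, d)
    if (pI$nll < p0$nll) best <- list(lam = exp(o$minimum), prof = pI)
  }
  list(va = best$lam * best$prof$ve, ve = best$prof$ve,
       nll = best$prof$nll, converged = TRUE)
}

# Group the families of the individuals in `ids` by identical (A, H) block
# structure, so each likelihood evaluation factors one covariance per
# distinct family composition and batches the solves across families.
afe_blocks <- function(kin, ids, fam) {
  fams <- unique(fam)
  keys <- character(length(fams))
  blocks <- vector("list", length(fams))
  for (k in seq_along(fams)) {
    loc <- which(fam == fams[k])
    A <- kin$A[ids[loc], ids[loc], drop = FALSE]
    H <- kin$H[ids[loc], ids[loc], drop = FALSE]
    blocks[[k]] <- list(loc = loc, A = A, H = H)
    keys[k] <- paste(length(loc), paste(round(A * 2^16), collapse = ","),
                     paste(H, collapse = ","))
  }
  lapply(split(seq_along(fams), keys), function(g) {
    b <- blocks[[g[1]]]
    lm_ <- vapply(g, function(k) blocks[[k]]$loc, integer(nrow(b$A)))
    if (!is.matrix(lm_)) lm_ <- matrix(lm_, nrow = nrow(b$A))
    list(A = b$A, H = b$H, I = diag(nrow(b$A)), loc_mat = lm_,
         n_fam = length(g))
  })
}

# Profiled AFE negative log-likelihood at variance ratios
# (la, lf) = (va, vf) / ve: one Cholesky per distinct family pattern, mean
# and ve profiled. Returns the profiled ve as an attribute for the caller.
nll_afe_profiled <- function(par, y, X, blocks) {
  la <- par[1]; lf <- par[2]
  m <- length(y)
  p <- ncol(X)
  intercept_only <- p == 1L
  xx <- matrix(0, p, p); xy <- numeric(p); yy <- 0; logdet <- 0
  for (b in blocks) {
    S <- la * b$A + lf * b$H + b$I  # PD for la, lf >= 0
    C <- chol(S)
    lm_ <- b$loc_mat
    logdet <- logdet + 2 * b$n_fam * sum(log(diag(C)))
    Z <- backsolve(C, matrix(y[lm_], nrow = nrow(lm_)), transpose = TRUE)
    yy <- yy + sum(Z^2)
    if (intercept_only) {
      zx <- backsolve(C, rep(1, nrow(lm_)), transpose = TRUE)
      xx <- xx + b$n_fam * sum(zx^2)
      xy <- xy + sum(zx * rowSums(Z))
    } else {
      Xb <- matrix(X[as.vector(lm_), , drop = FALSE], nrow = nrow(lm_))
      Zx <- backsolve(C, Xb, transpose = TRUE)
      nf <- b$n_fam
      for (f in seq_len(nf)) {
        zf <- Zx[, f + (seq_len(p) - 1L) * nf, drop = FALSE]
        xx <- xx + crossprod(zf)
        xy <- xy + crossprod(zf, Z[, f])
      }
    }
  }
  beta <- tryCatch(solve(xx, xy), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  quad <- yy - 2 * sum(beta * xy) + drop(t(beta) %*% xx %*% beta)
  ve <- quad / m
  if (ve <= 0) return(1e10)
  structure(0.5 * (logdet + m * log(ve) + m), ve = ve)
}


#' Maximum-likelihood variance components for one probe
#'
#' Maximises the multivariate-normal log-likelihood of a residual row with
#' covariance `Va * A + Vf * H + Ve * I` (terms depending on `model`) and
#' mean `X beta` (intercept plus optional covariates, profiled by
#' generalised least squares), subject to `Va, Vf, Ve >= 0`. For the AE
#' model the residual variance is profiled out and the likelihood maximised
#' over the single variance ratio `Va/Ve`; the zero boundary is decided
#' exactly by the sign of the profile score at `Va = 0`, so boundary
#' estimates are exact zeros. The AFE model is maximised over both variance
#' ratios by bound-constrained quasi-Newton from three starting points
#' (equal split, residual-heavy, genetic-heavy). The p-value is a
#' likelihood-ratio test of the
#' model's focal component (`Va` for AE against E; `Vf` for AFE against AE)
#' referred to an equal mixture of a point mass at zero and chi-squared with
#' one degree of freedom, the null distribution of a variance tested on the
#' boundary of its parameter space.
#'
#' @param y Numeric response vector ordered as `kin$id` (`NA` allowed).
#' @param kin `kinship_matrix` from [additive_relationship()].
#' @param model `"AE"` (additive + residual), `"AFE"` (additive + family
#'   common environment + residual) or `"E"` (residual only).
#' @param covariates Optional numeric matrix of fixed-effect covariates
#'   (e.g. cell proportions), rows ordered or named as `kin$id`.
#' @param struct Precomputed [ae_structure()] for the probe's missingness
#'   pattern (internal use by [heritability_screen()]).
#' @return List of class `varcomp_fit`: `va`, `vf`, `ve`, `h2`, `c2`,
#'   `loglik`, `loglik_null`, `lrt`, `p_value`, `n_used`, `converged`,
#'   `model`.
#' @export
fit_varcomp <- function(y, kin, model = c("AE", "AFE", "E"),
                        covariates = NULL, struct = NULL) {
  model <- match.arg(model)
  n <- length(kin$id)
  if (length(y) != n) stop("'y' must be ordered as kin$id")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates)))
      covariates <- covariates[kin$id, , drop = FALSE]
    idx <- !is.na(y) & stats::complete.cases(covariates)
  } else idx <- !is.na(y)
  m <- sum(idx)
  if (m < 10L) stop("need at least 10 non-missing individuals")
  X <- cbind(`(Intercept)` = rep(1, m),
             if (!is.null(covariates)) covariates[idx, , drop = FALSE])
  npar <- switch(model, E = 1L, AE = 2L, AFE = 3L)
  if (m <= ncol(X) + npar)
    stop("fewer individuals than parameters")

  # standardise so optimiser tolerances are scale-free
  s <- stats::sd(y[idx])
  if (s == 0) s <- 1
  ys <- y[idx] / s
  lconst <- -0.5 * m * log(2 * pi) - m * log(s)

  fit_e <- function() {
    b <- stats::lm.fit(X, ys)
    ve <- mean(b$residuals^2)
    ll <- lconst - 0.5 * (m * log(ve) + m)
    list(va = 0, vf = 0, ve = ve * s^2, loglik = ll, converged = TRUE)
  }

  e0 <- fit_e()
  if (model == "E") {
    out <- e0
    out <- c(out, list(h2 = 0, c2 = 0, loglik_null = NA_real_,
                       lrt = NA_real_, p_value = NA_real_,
                       n_used = m, model = model))
    class(out) <- "varcomp_fit"
    return(out)
  }

  if (model == "AE") {
    if (is.null(struct)) struct <- ae_structure(kin, idx)
    ytil <- drop(struct$Ut %*% ys)
    Xtil <- struct$Ut %*% X
    o <- fit_ae_rotated(ytil, Xtil, struct$d)
    ll <- lconst - o$nll
    va <- o$va * s^2; vf <- 0; ve <- o$ve * s^2
    conv <- o$converged
    ll_null <- e0$loglik
  } else {
    ids <- seq_len(n)[idx]
    fam <- kin$family[ids]
    blocks <- afe_blocks(kin, ids, fam)
    # AE fit doubles as the LRT null and an informed starting point
    if (is.null(struct)) struct <- ae_structure(kin, idx)
    ae <- fit_ae_rotated(drop(struct$Ut %*% ys), struct$Ut %*% X, struct$d)
    ratio0 <- ae$va / ae$ve
    inits <- list(c(ratio0, max(0.05, ratio0 / 4)), c(0.02, 0.02),
                  c(max(0.5, 2 * ratio0), 0.5))
    best <- NULL
    conv <- FALSE
    for (init in inits) {
      o <- tryCatch(
        stats::optim(init, function(p) as.numeric(nll_afe_profiled(p, ys, X, blocks)),
                     method = "L-BFGS-B",
                     lower = c(0, 0), upper = c(1e6, 1e6),
                     control = list(factr = 1e6, maxit = 200)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-10) best <- o
      if (o$convergence == 0) conv <- TRUE
    }
    if (is.null(best)) stop("variance-component optimisation failed")
    ll <- lconst - best$value
    la <- best$par[1]; lf <- best$par[2]
    ve_prof <- attr(nll_afe_profiled(best$par, ys, X, blocks), "ve")
    va <- la * ve_prof * s^2; vf <- lf * ve_prof * s^2; ve <- ve_prof * s^2
    # null for the family component: the AE fit on the same data
    ll_null <- lconst - ae$nll
  }

  lrt <- max(0, 2 * (ll - ll_null))
  p <- if (lrt <= 1e-10) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  tot <- va + vf + ve
  out <- list(va = va, vf = vf, ve = ve,
              h2 = if (tot > 0) va / tot else 0,
              c2 = if (tot > 0) vf / tot else 0,
              loglik = ll, loglik_null = ll_null, lrt = lrt, p_value = p,
              n_used = m, converged = conv, model = model)
  class(out) <- "varcomp_fit"
  out
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("varcomp_fit [%s]: va=%.4g vf=%.4g ve=%.4g  h2=%.3f c2=%.3f  logLik=%.2f  p=%.3g  (n=%d%s)\n",
              x$model, x$va, x$vf, x$ve, x$h2, x$c2, x$loglik,
              x$p_value, x$n_used,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Genome-wide per-probe variance-component screen
#'
#' Maps [fit_varcomp()] over every probe of a residual matrix, subsetting
#' the relationship matrices to each probe's non-missing individuals. The
#' AE eigen structure is cached per missingness pattern, so a screen over a
#' complete matrix costs one decomposition in total.
#'
#' @param resid `residual_matrix` from [normalize_matrix()] or plain matrix
#'   with sample ids as column names (ordered or matched to `kin$id`).
#' @param kin `kinship_matrix`.
#' @param model `"AE"` or `"AFE"`.
#' @param covariates Optional covariate matrix (see [fit_varcomp()]).
#' @return `data.frame`, one row per probe: `probe_id`, `n_used`, `va`,
#'   `vf`, `ve`, `h2`, `c2`, `loglik`, `p_value`, `converged`.
#' @export
heritability_screen <- function(resid, kin, model = c("AE", "AFE"),
                                covariates = NULL) {
  model <- match.arg(model)
  V <- if (inherits(resid, "residual_matrix")) resid$values else resid
  if (!is.null(colnames(V))) {
    if (!all(kin$id %in% colnames(V)))
      stop("residual matrix lacks samples present in the pedigree")
    V <- V[, kin$id, drop = FALSE]
  } else if (ncol(V) != length(kin$id))
    stop("residual matrix columns must match pedigree individuals")

  probe_id <- rownames(V)
  if (is.null(probe_id)) probe_id <- sprintf("probe%05d", seq_len(nrow(V)))
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(V))
  for (p in seq_len(nrow(V))) {
    y <- V[p, ]
    struct <- NULL
    if (model == "AE") {
      key <- paste(which(!is.na(y)), collapse = ",")
      struct <- cache[[key]]
      if (is.null(struct)) {
        struct <- ae_structure(kin, !is.na(y))
        cache[[key]] <- struct
      }
    }
    f <- tryCatch(fit_varcomp(y, kin, model = model, covariates = covariates,
                              struct = struct),
                  error = function(e) NULL)
    rows[[p]] <- if (is.null(f)) {
      data.frame(probe_id = probe_id[p], n_used = sum(!is.na(y)),
                 va = NA_real_, vf = NA_real_, ve = NA_real_, h2 = NA_real_,
                 c2 = NA_real_, loglik = NA_real_, p_value = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(probe_id = probe_id[p], n_used = f$n_used, va = f$va,
                 vf = f$vf, ve = f$ve, h2 = f$h2, c2 = f$c2,
                 loglik = f$loglik, p_value = f$p_value,
                 converged = f$converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg significance mask
#'
#' Standard step-up false-discovery-rate procedure at level `q`: a p-value
#' is significant when its BH-adjusted value is at most `q`. The mask is
#' monotone in the p-values.
#'
#' @param p Numeric vector of p-values in `[0,1]` (`NA` passed through as
#'   not significant).
#' @param q FDR level (default 0.05).
#' @return Logical vector, `TRUE` where significant.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  adj <- stats::p.adjust(p, method = "BH")
  !is.na(adj) & adj <= q
}

#' Lower bound on the fraction of probes with a genetic component
#'
#' With maximum-likelihood variance estimation the additive variance is
#' constrained to be non-negative, so under a true null half of the
#' estimates land exactly on the zero boundary. An observed boundary-zero
#' fraction `p0` therefore implies that at most `2 * p0` of probes can be
#' true nulls, giving the lower bound `100 - 2 * p0 * 100` percent of probes
#' with a genetic component.
#'
#' @param h2_estimates Numeric vector of heritability estimates in `[0,1]`;
#'   estimates below `tol` count as boundary zeros.
#' @param p0 Alternatively, the boundary-zero fraction itself (overrides
#'   `h2_estimates`).
#' @param tol Zero-detection threshold (boundary convergence does not land
#'   at machine zero reliably).
#' @return List: `p0` (fraction of zero estimates) and `bound` (percentage,
#'   floored at 0).
#' @export
zero_fraction_bound <- function(h2_estimates = NULL, p0 = NULL, tol = 1e-6) {
  if (is.null(p0)) {
    if (is.null(h2_estimates)) stop("supply 'h2_estimates' or 'p0'")
    if (any(h2_estimates < 0 | h2_estimates > 1, na.rm = TRUE))
      stop("heritability estimates must lie in [0,1]")
    p0 <- mean(h2_estimates < tol, na.rm = TRUE)
  }
  list(p0 = p0, bound = max(0, 100 - 2 * p0 * 100))
}
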