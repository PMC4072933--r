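#' Design matrix for per-probe normalisation
#'
#' Builds the covariate design used by [normalize_probe()]: chip, position
#' on the chip, sex, age, age squared, and the sex-by-age and
#' sex-by-age-squared interactions. Factor levels present in the sheet but
#' unused in a given fit are dropped inside the fit.
#'
#' @param sheet Sample sheet with `chip`, `chip_position`, plus `sex` and
#'   `age` columns (taken from the pedigree when absent).
#' @param ped Optional pedigree supplying `sex` and `age`.
#' @return Numeric model matrix with one row per sample.
#' @export
normalization_design <- function(sheet, ped = NULL) {
  if (!is.null(ped)) {
    ix <- match(sheet$individual_id, ped$individual_id)
    sheet$sex <- ped$sex[ix]
    sheet$age <- ped$age[ix]
  }
  need <- c("chip", "chip_position", "sex", "age")
  if (!all(need %in% names(sheet)))
    stop("sample sheet is missing: ", paste(setdiff(need, names(sheet)),
                                            collapse = ", "))
  df <- data.frame(chip = factor(sheet$chip),
                   chip_position = factor(sheet$chip_position),
                   sex = factor(sheet$sex), age = sheet$age)
  X <- stats::model.matrix(~ chip + chip_position + sex + age + I(age^2) +
                             sex:age + sex:I(age^2), df)
  rownames(X) <- sheet$individual_id
  X
}

#' Normalise one probe against technical and demographic covariates
#'
#' Fits the probe's beta values on the covariate design through a
#' generalised linear model with a logistic link (quasi-binomial, so
#' fractional responses are handled without integer trials) and returns the
#' response-scale residuals (observed minus fitted beta). If the GLM fails
#' to converge or separates, the fit falls back to a linear model on
#' logit-transformed values (clipped to `[1e-6, 1 - 1e-6]`), whose residuals
#' are link-scale; the fallback is flagged.
#'
#' @param y Numeric vector of beta values in `[0,1]` (`NA` allowed).
#' @param X Design matrix from [normalization_design()] (with intercept).
#' @param residual_scale `"response"` (default: observed minus fitted beta)
#'   or `"link"` (logit of the clipped observation minus the linear
#'   predictor, in log-odds units).
#' @return List: `residuals` (same length as `y`, `NA` where `y` is
#'   missing), `coefficients` (link-scale), `method` (`"glm"` or
#'   `"linear_fallback"`).
#' @export
normalize_probe <- function(y, X, residual_scale = c("response", "link")) {
  residual_scale <- match.arg(residual_scale)
  res <- rep(NA_real_, length(y))
  obs <- which(!is.na(y))
  if (length(obs) < 2L) stop("need at least 2 non-missing values")
  yo <- y[obs]
  if (stats::var(yo) == 0)  # constant probe: intercept fits exactly
    return(list(residuals = replace(res, obs, 0),
                coefficients = c(`(Intercept)` = stats::qlogis(
                  min(max(yo[1], 1e-12), 1 - 1e-12))),
                method = "glm"))
  Xo <- X[obs, , drop = FALSE]
  Xo <- Xo[, c(1L, which(apply(Xo[, -1L, drop = FALSE], 2L,
                               function(v) stats::var(v) > 0)) + 1L),
           drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo, yo,
                                    family = stats::quasibinomial("logit"))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && all(is.finite(fit$fitted.values))) {
    res[obs] <- if (residual_scale == "response") {
      yo - fit$fitted.values
    } else {
      stats::qlogis(pmin(pmax(yo, 1e-6), 1 - 1e-6)) - fit$linear.predictors
    }
    return(list(residuals = res, coefficients = fit$coefficients,
                method = "glm"))
  }
  warning("logistic GLM did not converge; falling back to linear model on ",
          "logit values")
  z <- stats::qlogis(pmin(pmax(yo, 1e-6), 1 - 1e-6))
  lf <- stats::lm.fit(Xo, z)
  res[obs] <- z - lf$fitted.values
  list(residuals = res, coefficients = lf$coefficients,
       method = "linear_fallback")
}

#' Normalise a full beta matrix to a residual matrix
#'
#' Applies [normalize_probe()] to every probe and then [mask_outliers()] to
#' every residual row. Residuals from the canonical-link GLM sum to zero per
#' probe by the score equations, so rows are centred by construction.
#'
#' @param bm A [beta_matrix()].
#' @param design Design matrix from [normalization_design()], or `NULL` for
#'   intercept-only normalisation (plain per-probe centring on the response
#'   scale).
#' @param mask_k Interquartile-range multiple for outlier masking; `NULL`
#'   skips masking.
#' @param residual_scale Passed to [normalize_probe()].
#' @return List of class `residual_matrix`: `values` (probes x samples),
#'   `annotation`, `n_fallback` (probes that used the linear fallback),
#'   `n_masked` (entries removed as outliers).
#' @export
normalize_matrix <- function(bm, design = NULL, mask_k = 5,
                             residual_scale = c("response", "link")) {
  residual_scale <- match.arg(residual_scale)
  stopifnot(inherits(bm, "beta_matrix"))
  V <- bm$values
  if (is.null(design))
    design <- matrix(1, ncol(V), 1L,
                     dimnames = list(colnames(V), "(Intercept)"))
  if (nrow(design) != ncol(V))
    stop("design rows must match samples")
  if (!is.null(colnames(V)) && !is.null(rownames(design)))
    design <- design[colnames(V), , drop = FALSE]
  R <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
  n_fallback <- 0L
  for (p in seq_len(nrow(V))) {
    np <- normalize_probe(V[p, ], design, residual_scale)
    if (np$method != "glm") n_fallback <- n_fallback + 1L
    R[p, ] <- np$residuals
  }
  n_masked <- 0L
  if (!is.null(mask_k)) {
    for (p in seq_len(nrow(R))) {
      m <- mask_outliers(R[p, ], k = mask_k)
      n_masked <- n_masked + sum(is.na(m)) - sum(is.na(R[p, ]))
      # re-centre after masking so the residual-mean invariant holds
      R[p, ] <- m - mean(m, na.rm = TRUE)
    }
  }
  structure(list(values = R, annotation = bm$annotation,
                 n_fallback = n_fallback, n_masked = n_masked),
            class = "residual_matrix")
}

#' Mask residuals far outside the interquartile range
#'
#' Entries strictly greater than `Q3 + k * IQR` or strictly less than
#' `Q1 - k * IQR` are set missing. Quartiles (linear-interpolation type 7)
#' are computed once on the non-missing values before masking; the pass is
#' not iterated. With zero IQR any value differing from the common quartile
#' is masked (the strict inequality still governs exact ties).
#'
#' @param x Numeric vector (residuals), `NA` allowed.
#' @param k IQR multiple (default 5).
#' @return `x` with outlying entries replaced by `NA`.
#' @export
mask_outliers <- function(x, k = 5) {
  obs <- !is.na(x)
  if (sum(obs) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(x[obs], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- obs & (x > q[2] + k * iqr | x < q[1] - k * iqr)
  x[out] <- NA_real_
  x
}
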