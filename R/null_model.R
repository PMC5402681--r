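# Covariate-only null model, standardized compositions and score vectors:
# the shared substrate of every association test in the package.

#' Convert counts to per-sample proportions
#'
#' @param otu an [otu_table()] or numeric count matrix (samples x OTUs).
#' @return Numeric matrix of row-proportions; each row sums to 1.
#' @export
to_composition <- function(otu) {
  m <- unclass(as.matrix(otu))
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop2("zero-total sample(s): ",
          paste(utils::head(rownames(m)[totals <= 0], 5L), collapse = ", "))
  }
  m / totals
}

#' Column-standardize a proportion matrix
#'
#' Each OTU column is centered at its mean and divided by its sample
#' standard deviation (the n-1 divisor).  Zero-variance columns are set to
#' all zeros and flagged in the `"degenerate"` attribute so that they
#' contribute nothing to any score statistic instead of producing NaN.
#'
#' @param P proportion matrix, samples x OTUs.
#' @return Z-scored matrix with a logical `"degenerate"` attribute per column.
#' @export
standardize_composition <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 2L) stop2("standardization needs at least 2 samples")
  zscore_cols(P)
}

#' Fit the covariate-only null model
#'
#' Continuous traits: ordinary least squares of `y` on an intercept plus the
#' covariates; the dispersion `phi` is the residual variance
#' RSS / (n - q - 1).  Binary traits: logistic maximum likelihood; fitted
#' probabilities are the null means and `phi = 1`.  The fit involves the
#' microbiome in no way, so a single fit is shared by every taxon tested on
#' the same samples.
#'
#' @param design a [study_design()].
#' @return A `null_fit` list: `mu0`, `residuals`, `phi`, `trait`, `n`, `q`.
#' @export
fit_null <- function(design) {
  stopifnot(inherits(design, "study_design"))
  y <- design$y
  n <- length(y)
  X <- design$X
  q <- ncol(X)
  df <- if (q) data.frame(y = y, X) else data.frame(y = y)
  if (q) {
    M <- cbind(1, X)
    r <- qr(M)
    if (r$rank < ncol(M)) {
      bad <- colnames(X)[setdiff(seq_len(ncol(M)), r$pivot[seq_len(r$rank)]) - 1L]
      stop2("rank-deficient covariates (collinear): ",
            paste(bad, collapse = ", "))
    }
  }
  if (design$trait == "continuous") {
    fit <- lm(y ~ ., data = df)
    mu0 <- as.numeric(fitted(fit))
    res <- y - mu0
    phi <- sum(res^2) / (n - q - 1L)
    if (!is.finite(phi) || phi <= 0) stop2("degenerate null fit: zero residual variance")
  } else {
    fit <- suppressWarnings(glm(y ~ ., family = stats::binomial(), data = df))
    if (!fit$converged) {
      stop2("logistic null model failed to converge; consider fewer covariates")
    }
    mu0 <- as.numeric(fitted(fit))
    if (any(mu0 < 1e-10 | mu0 > 1 - 1e-10)) {
      stop2("logistic separation detected; consider fewer covariates")
    }
    res <- y - mu0
    phi <- 1
  }
  # orthonormal basis of the (intercept, covariates) column space; the
  # permutation engine re-projects permuted residuals onto its orthogonal
  # complement (Freedman-Lane style) so they satisfy the same score
  # constraints as the observed residuals
  Q <- qr.Q(qr(cbind(1, X)))
  structure(list(mu0 = mu0, residuals = res, phi = phi,
                 trait = design$trait, n = n, q = q, proj = Q),
            class = "null_fit")
}

#' Per-OTU score vector
#'
#' `U_j = sum_i (y_i - mu0_i) * Z_ij`: the covariance between null-model
#' residuals and each standardized OTU column.  Its sign is the per-OTU
#' effect direction.
#'
#' @param fit a [fit_null()] result.
#' @param Z standardized composition matrix (samples x OTUs).
#' @return Numeric vector of length `ncol(Z)`.
#' @export
score_vector <- function(fit, Z) {
  stopifnot(inherits(fit, "null_fit"))
  Z <- as.matrix(Z)
  if (nrow(Z) != fit$n) stop2("Z rows must match the fitted sample count")
  drop(crossprod(Z, fit$residuals))
}

#' Effect-direction label for score components
#'
#' @param u numeric vector of score components.
#' @return `"+"` where `u >= 0`, `"-"` otherwise.
#' @export
effect_sign <- function(u) ifelse(u >= 0, "+", "-")
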