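# Association test statistics and their permutation p-values: SPU(gamma),
# aSPU, per-kernel MiRKAT, Optimal MiRKAT, OMiAT, the aggregate-based
# comparator, and the single-OTU score test.

#' Default SPU exponent grid
#'
#' Positive integers 1..8 plus the `Inf` sentinel (maximum absolute score
#' component).  Small exponents favor many/rare signals, large exponents
#' few/abundant signals.
#' @export
GAMMA_GRID <- c(1:8, Inf)

#' Sum of powered score components
#'
#' Finite `gamma`: `T = sum_j U_j^gamma`.  `gamma = Inf`: `T = max_j |U_j|`.
#'
#' @param U score vector from [score_vector()].
#' @param gamma exponent (positive integer or `Inf`).
#' @return Scalar statistic.
#' @export
spu_statistic <- function(U, gamma) {
  if (length(U) == 0L) stop2("empty score vector")
  if (is.infinite(gamma)) max(abs(U)) else sum(U^gamma)
}

# Oriented (larger = more extreme) SPU statistics for a matrix of score
# vectors (rows).  Every SPU statistic is compared by absolute value; for
# even gamma the statistic is already non-negative so this is a no-op.
spu_stats_oriented <- function(Umat, grid) {
  B <- nrow(Umat)
  out <- matrix(0, B, length(grid))
  finite <- grid[is.finite(grid)]
  if (length(finite)) {
    # powers built by repeated elementwise multiplication (integer grid)
    cur <- NULL
    for (g in seq_len(max(finite))) {
      cur <- if (g == 1L) Umat else cur * Umat
      hit <- which(grid == g)
      if (length(hit)) out[, hit] <- abs(rowSums(cur))
    }
  }
  inf_at <- which(is.infinite(grid))
  if (length(inf_at)) {
    absU <- abs(Umat)
    out[, inf_at] <- absU[cbind(seq_len(B), max.col(absU,
                                                    ties.method = "first"))]
  }
  colnames(out) <- paste0("spu_", ifelse(is.infinite(grid), "inf", grid))
  out
}

# Observed + permuted oriented statistics for the full candidate pool.
# Zstd NULL drops the SPU block; kernels NULL/empty drops the MiRKAT block.
candidate_pool <- function(fit, Rm, Zstd = NULL, kernels = NULL,
                           grid = GAMMA_GRID) {
  obs <- numeric(0)
  perm <- NULL
  if (!is.null(Zstd)) {
    Zstd <- as.matrix(Zstd)
    U_obs <- drop(crossprod(Zstd, fit$residuals))
    U_perm <- Rm %*% Zstd
    obs_spu <- drop(spu_stats_oriented(matrix(U_obs, 1L), grid))
    perm_spu <- spu_stats_oriented(U_perm, grid)
    obs <- c(obs, stats::setNames(obs_spu, colnames(perm_spu)))
    perm <- perm_spu
  }
  if (length(kernels)) {
    r <- fit$residuals
    qobs <- vapply(kernels, function(K) {
      M <- attr(K, "factor")
      if (is.null(M)) drop(crossprod(r, K %*% r)) / (2 * fit$phi)
      else sum(drop(crossprod(M, r))^2) / (2 * fit$phi)
    }, numeric(1))
    qperm <- vapply(kernels, function(K) {
      M <- attr(K, "factor")
      if (is.null(M)) rowSums((Rm %*% K) * Rm) / (2 * fit$phi)
      else rowSums((Rm %*% M)^2) / (2 * fit$phi)
    }, numeric(nrow(Rm)))
    labels <- paste0("mirkat_", names(kernels))
    names(qobs) <- labels
    colnames(qperm) <- labels
    obs <- c(obs, qobs)
    perm <- if (is.null(perm)) qperm else cbind(perm, qperm)
  }
  if (!length(obs)) stop2("candidate pool is empty")
  list(obs = obs, perm = perm)
}

test_result <- function(method, statistic, p, B, p_each = NULL, flags = NULL) {
  structure(list(method = method, statistic = statistic, p = p, B = B,
                 p_each = p_each, flags = flags),
            class = "micam_test")
}

#' @export
print.micam_test <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (B = %d)\n", x$method, x$p, x$B))
  invisible(x)
}

#' Adaptive SPU test
#'
#' Computes the SPU p-value for every exponent on the grid and combines
#' them by the minimum p-value; the null distribution of the minimum is
#' taken from the same permutation set by the leave-one-out rank
#' construction (no nested permutations).
#'
#' @param fit a [fit_null()] result.
#' @param Zstd standardized composition matrix (samples x OTUs).
#' @param perms a [make_permutations()] set.
#' @param grid SPU exponent grid.
#' @return A `micam_test` with the combined `p` and per-exponent `p_each`.
#' @export
aspu_test <- function(fit, Zstd, perms, grid = GAMMA_GRID) {
  Rm <- perm_residuals(fit, perms)
  pool <- candidate_pool(fit, Rm, Zstd = Zstd, grid = grid)
  cmb <- minp_combine(pool$obs, pool$perm)
  test_result("aSPU", cmb$minp_obs, cmb$p, perms$B,
              p_each = stats::setNames(cmb$p_each, names(pool$obs)))
}

#' Single-kernel MiRKAT test
#'
#' One-sided permutation p-value for the variance-component score statistic
#' `Q = r' K r / (2 phi)`.
#'
#' @inheritParams aspu_test
#' @param K kernel matrix from [distance_to_kernel()].
#' @return A `micam_test`.
#' @export
mirkat_test <- function(fit, K, perms) {
  Rm <- perm_residuals(fit, perms)
  Q <- mirkat_statistic(fit, K)
  Qperm <- rowSums((Rm %*% K) * Rm) / (2 * fit$phi)
  test_result("MiRKAT", Q, perm_pvalue(Q, Qperm), perms$B)
}

#' Optimal MiRKAT test
#'
#' Min-P combination over a candidate kernel set, using the leave-one-out
#' construction on the shared permutation set.
#'
#' @inheritParams aspu_test
#' @param kernels named list of kernel matrices (see [kernel_candidates()]).
#' @return A `micam_test` with per-kernel `p_each`.
#' @export
optimal_mirkat_test <- function(fit, kernels, perms) {
  Rm <- perm_residuals(fit, perms)
  pool <- candidate_pool(fit, Rm, kernels = kernels)
  cmb <- minp_combine(pool$obs, pool$perm)
  test_result("Optimal MiRKAT", cmb$minp_obs, cmb$p, perms$B,
              p_each = stats::setNames(cmb$p_each, names(pool$obs)))
}

#' OMiAT: optimal microbiome-based association test
#'
#' Pools all SPU candidates (exponent grid) and all MiRKAT candidates
#' (kernel set) and takes the minimum per-candidate p-value as the test
#' statistic; its null distribution comes from the single shared
#' permutation set.  When the kernel set carries the
#' `"unifrac_degenerate"` flag the pool is SPU plus the Bray-Curtis kernel
#' alone.
#'
#' @inheritParams optimal_mirkat_test
#' @param grid SPU exponent grid.
#' @return A `micam_test` with all per-candidate `p_each`.
#' @export
omiat_test <- function(fit, Zstd, kernels, perms, grid = GAMMA_GRID) {
  Rm <- perm_residuals(fit, perms)
  pool <- candidate_pool(fit, Rm, Zstd = Zstd, kernels = kernels, grid = grid)
  cmb <- minp_combine(pool$obs, pool$perm)
  test_result("OMiAT", cmb$minp_obs, cmb$p, perms$B,
              p_each = stats::setNames(cmb$p_each, names(pool$obs)),
              flags = list(unifrac_degenerate =
                             isTRUE(attr(kernels, "unifrac_degenerate"))))
}

#' Aggregate-based comparator test
#'
#' Sums the standardized composition per sample into one predictor
#' `a_i = sum_j Z_ij` and tests `U = sum_i r_i a_i` two-sided by absolute
#' value.  Opposite-direction OTU effects cancel in the aggregate, the
#' known weakness of this conventional approach.
#'
#' @inheritParams aspu_test
#' @return A `micam_test`.
#' @export
aggregate_test <- function(fit, Zstd, perms) {
  Zstd <- as.matrix(Zstd)
  a <- rowSums(Zstd)
  U <- sum(fit$residuals * a)
  Rm <- perm_residuals(fit, perms)
  Uperm <- drop(Rm %*% a)
  test_result("aggregate", U, perm_pvalue(U, Uperm, two_sided_by_abs = TRUE),
              perms$B)
}

#' Score test for a taxon containing a single OTU
#'
#' Two-sided permutation p-value on `U = sum_i r_i z_i` for one
#' standardized OTU column.  A zero-variance column gives `p = 1` with a
#' flag instead of an error.
#'
#' @inheritParams aspu_test
#' @param z one standardized OTU column.
#' @return A `micam_test`.
#' @export
single_otu_test <- function(fit, z, perms) {
  z <- as.numeric(z)
  if (all(z == 0)) {
    return(test_result("single-OTU", 0, 1, perms$B,
                       flags = list(zero_variance = TRUE)))
  }
  U <- sum(fit$residuals * z)
  Rm <- perm_residuals(fit, perms)
  Uperm <- drop(Rm %*% z)
  test_result("single-OTU", U, perm_pvalue(U, Uperm, two_sided_by_abs = TRUE),
              perms$B)
}

#' Run the full family of group tests with one shared permutation set
#'
#' Computes OMiAT, aSPU, Optimal MiRKAT and the aggregate test for one
#' microbial group from a single candidate-statistic evaluation, so all
#' four share every permuted residual vector.  This is the engine behind
#' both the simulation experiments and the rank scan.
#'
#' @inheritParams omiat_test
#' @return Named list of `micam_test` objects
#'   (`omiat`, `aspu`, `optimal_mirkat`, `aggregate`).
#' @export
group_association <- function(fit, Zstd, kernels, perms, grid = GAMMA_GRID) {
  Zstd <- as.matrix(Zstd)
  Rm <- perm_residuals(fit, perms)
  pool <- candidate_pool(fit, Rm, Zstd = Zstd, kernels = kernels, grid = grid)
  n_spu <- length(grid)
  idx_spu <- seq_len(n_spu)
  idx_k <- setdiff(seq_along(pool$obs), idx_spu)
  omiat <- minp_combine(pool$obs, pool$perm)
  aspu <- minp_combine(pool$obs[idx_spu], pool$perm[, idx_spu, drop = FALSE])
  omk <- if (length(idx_k)) {
    minp_combine(pool$obs[idx_k], pool$perm[, idx_k, drop = FALSE])
  } else NULL
  a <- rowSums(Zstd)
  U_agg <- sum(fit$residuals * a)
  p_agg <- perm_pvalue(U_agg, drop(Rm %*% a), two_sided_by_abs = TRUE)
  list(
    omiat = test_result("OMiAT", omiat$minp_obs, omiat$p, perms$B,
                        p_each = stats::setNames(omiat$p_each,
                                                 names(pool$obs))),
    aspu = test_result("aSPU", aspu$minp_obs, aspu$p, perms$B),
    optimal_mirkat = if (!is.null(omk)) {
      test_result("Optimal MiRKAT", omk$minp_obs, omk$p, perms$B)
    },
    aggregate = test_result("aggregate", U_agg, p_agg, perms$B)
  )
}
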