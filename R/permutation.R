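# Seeded permutation sets and permutation p-value machinery.  One
# permutation set is shared by every statistic for every taxon in a scan:
# that sharing is what makes the min-P combinations and the rank-wide scans
# both valid and computationally tractable.

#' Generate a reproducible set of sample permutations
#'
#' @param n number of samples.
#' @param B number of permutations (>= 1).
#' @param seed integer seed; identical `(n, B, seed)` give identical sets.
#' @return A `perm_set` list: `n`, `B`, `seed`, and `idx`, a `B x n` integer
#'   matrix whose rows are permutations of `1:n`.
#' @export
make_permutations <- function(n, B, seed = 1L) {
  stopifnot(n >= 2L, B >= 1L)
  idx <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  })
  structure(list(n = as.integer(n), B = as.integer(B),
                 seed = as.integer(seed), idx = idx),
            class = "perm_set")
}

# B x n matrix of residuals re-indexed by each stored permutation, then
# re-projected off the covariate space and rescaled to the observed
# residual norm.  The observed residuals satisfy the null-model score
# equations (orthogonality to intercept and covariates); each permuted
# copy is made to satisfy them too, which keeps the permutation null
# calibrated when covariates are correlated with the microbiome.  The
# projection shrinks a permuted vector's norm (it removes its
# covariate-space component), so each row is rescaled back to ||r||;
# observed and permuted vectors then differ only in direction within the
# covariate-orthogonal subspace.
perm_residuals <- function(fit, perms) {
  stopifnot(inherits(fit, "null_fit"), inherits(perms, "perm_set"))
  if (perms$n != fit$n) stop2("permutation set built for a different n")
  Rm <- matrix(fit$residuals[perms$idx], perms$B, perms$n)
  if (!is.null(fit$proj) && ncol(fit$proj) > 1L) {
    Rm <- Rm - (Rm %*% fit$proj) %*% t(fit$proj)
    target <- sqrt(sum(fit$residuals^2))
    norms <- sqrt(rowSums(Rm^2))
    norms[norms < .Machine$double.eps] <- 1
    Rm <- Rm * (target / norms)
  }
  Rm
}

#' Permutation p-value with the add-one convention
#'
#' `p = (1 + #{b : s_b >= s_obs}) / (B + 1)`; with
#' `two_sided_by_abs = TRUE` both sides are compared on the absolute value.
#' Ties count as exceedances, and the estimator never returns 0.
#'
#' @param observed observed statistic.
#' @param permuted vector of permuted statistics.
#' @param two_sided_by_abs compare `|s|` instead of `s`.
#' @return p-value in `(0, 1]`, never below `1/(B+1)`.
#' @export
perm_pvalue <- function(observed, permuted, two_sided_by_abs = FALSE) {
  if (two_sided_by_abs) {
    observed <- abs(observed)
    permuted <- abs(permuted)
  }
  (1 + sum(permuted >= observed)) / (length(permuted) + 1)
}

# Leave-one-out permutation p-values for a vector of oriented statistics
# (larger = more extreme): p_b = #{b' : t_{b'} >= t_b} / B, self included,
# which equals (1 + #{b' != b : t_{b'} >= t_b}) / B.
loo_pvalues <- function(t) rank(-t, ties.method = "max") / length(t)

# Min-P combination over a candidate pool under the shared permutation set.
# obs_t: oriented observed statistics (length C); perm_t: B x C oriented
# permuted statistics.  Returns per-candidate p-values, the observed min-p,
# and the combined p-value.
minp_combine <- function(obs_t, perm_t) {
  B <- nrow(perm_t)
  C <- ncol(perm_t)
  p_each <- (1 + colSums(perm_t >= rep(obs_t, each = B))) / (B + 1)
  minp_obs <- min(p_each)
  minp_b <- loo_pvalues(perm_t[, 1L])
  for (c in seq_len(C)[-1L]) {
    minp_b <- pmin(minp_b, loo_pvalues(perm_t[, c]))
  }
  p <- (1 + sum(minp_b <= minp_obs)) / (B + 1)
  list(p = p, p_each = p_each, minp_obs = minp_obs)
}
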