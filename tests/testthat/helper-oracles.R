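# Brute-force oracles and small fixture builders shared across the suite.
# The oracles deliberately avoid the package's traversal/vectorized code
# paths: every quantity is recomputed from explicit per-edge leaf sets or
# per-pair loops.

# leaf label set descending from the child node of edge e
edge_leaf_set <- function(tree, e) {
  node <- tree$edge[e, 2L]
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# branch profiles by explicit leaf-set sums (no traversal reuse)
oracle_profiles <- function(P, tree) {
  E <- nrow(tree$edge)
  out <- matrix(0, nrow(P), E)
  for (e in seq_len(E)) {
    tips <- intersect(edge_leaf_set(tree, e), colnames(P))
    if (length(tips)) out[, e] <- rowSums(P[, tips, drop = FALSE])
  }
  list(P = out, lengths = tree$edge.length)
}

# per-pair, per-edge UniFrac sums
oracle_unifrac <- function(P, tree, type = c("unweighted", "weighted",
                                             "generalized"), alpha = 0.5) {
  type <- match.arg(type)
  pr <- oracle_profiles(P, tree)
  n <- nrow(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- den <- 0
      for (e in seq_along(pr$lengths)) {
        pi <- pr$P[i, e]; pj <- pr$P[j, e]; be <- pr$lengths[e]
        if (type == "unweighted") {
          num <- num + be * abs((pi > 0) - (pj > 0))
          den <- den + be * ((pi > 0) || (pj > 0))
        } else if (type == "weighted") {
          num <- num + be * abs(pi - pj)
          den <- den + be * (pi + pj)
        } else if (pi + pj > 0) {
          num <- num + be * (pi + pj)^alpha * abs(pi - pj) / (pi + pj)
          den <- den + be * (pi + pj)^alpha
        }
      }
      D[i, j] <- if (den > 0) num / den else 0
    }
  }
  D
}

# explicit double-centering oracle for the kernel formula
oracle_kernel <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% (D * D) %*% J
}

# small random proportion matrix whose columns match tree tips; sparse so
# presence/absence varies across samples (as real OTU tables do)
random_composition <- function(n, tree, seed, sparsity = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(rgamma(n * length(tree$tip.label), 1), n)
    m[m < quantile(m, sparsity)] <- 0
    # keep every row non-empty
    empty <- rowSums(m) == 0
    m[empty, 1] <- 1
    colnames(m) <- tree$tip.label
    rownames(m) <- paste0("s", seq_len(n))
    m / rowSums(m)
  })
}

make_design <- function(n, trait = "continuous", q = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- if (q > 0) matrix(rnorm(n * q), n, dimnames = list(NULL,
                                            paste0("x", seq_len(q)))) else NULL
    y <- if (trait == "continuous") rnorm(n) else rbinom(n, 1, 0.5)
    if (trait == "binary" && length(unique(y)) < 2) y[1] <- 1 - y[1]
    study_design(y, X, trait = trait, sample_ids = paste0("s", seq_len(n)))
  })
}
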