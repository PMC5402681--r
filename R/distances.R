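# Candidate distance measures (Bray-Curtis + the UniFrac family), their
# conversion to centered kernels, and the kernel-machine score statistic.

#' Bray-Curtis dissimilarity matrix
#'
#' `D_ij = sum_k |P_ik - P_jk| / sum_k (P_ik + P_jk)`, computed with
#' [vegan::vegdist()].  On row-normalized proportions the denominator is 2,
#' so D lies in `[0, 1]`.
#'
#' @param P proportion matrix, samples x OTUs.
#' @return Symmetric distance matrix with a `"measure"` attribute.
#' @export
bray_curtis <- function(P) {
  D <- suppressWarnings(as.matrix(vegan::vegdist(P, method = "bray")))
  # a pair of all-zero rows (possible inside a taxon subgroup) is 0/0:
  # define the dissimilarity of two empty profiles as 0
  if (anyNA(D)) D[is.na(D)] <- 0
  attr(D, "measure") <- "bray_curtis"
  D
}

#' Precompute the traversal order of a tree
#'
#' Internal index reused across replicates so that branch-profile
#' accumulation does not re-sort edges every call.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return A list with postorder edges, edge lengths and tip labels.
#' @keywords internal
tree_index <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, lengths = tree$edge.length,
       tips = tree$tip.label, n_tip = length(tree$tip.label),
       n_node = tree$Nnode)
}

#' Per-edge aggregated descendant proportions
#'
#' For every edge of the tree, accumulates (one postorder pass) the total
#' proportion of OTUs descending from that edge, per sample.  These branch
#' profiles are the shared substrate of every UniFrac variant.
#'
#' @param P proportion matrix, samples x OTUs (columns named by OTU id).
#' @param tree an `ape::phylo` tree whose tips cover `colnames(P)`, or a
#'   [tree_index()].
#' @return A `branch_profile` list: `P` (samples x edges), `lengths`.
#' @export
branch_profiles <- function(P, tree) {
  ti <- if (inherits(tree, "phylo")) tree_index(tree) else tree
  P <- as.matrix(P)
  missing_tips <- setdiff(colnames(P), ti$tips)
  if (length(missing_tips)) {
    stop2("OTU column(s) not on the tree: ",
          paste(utils::head(missing_tips, 5L), collapse = ", "))
  }
  n <- nrow(P)
  n_vert <- ti$n_tip + ti$n_node
  V <- matrix(0, n, n_vert)
  idx <- match(ti$tips, colnames(P))
  present <- !is.na(idx)
  V[, seq_len(ti$n_tip)[present]] <- P[, idx[present], drop = FALSE]
  edge <- ti$edge
  # postorder accumulation: children are visited before their parents
  for (e in seq_len(nrow(edge))) {
    V[, edge[e, 1L]] <- V[, edge[e, 1L]] + V[, edge[e, 2L]]
  }
  structure(list(P = V[, edge[, 2L], drop = FALSE], lengths = ti$lengths,
                 n_tip = ti$n_tip),
            class = "branch_profile")
}

# Shared pairwise scan over branch profiles computing every requested
# UniFrac variant in one pass over the pair x edge grid (compiled kernel;
# this is the innermost loop of every simulation replicate).
unifrac_family <- function(prof, alphas = c(0, 0.25, 0.5, 0.75),
                           unweighted = TRUE, weighted = TRUE) {
  B <- prof$P
  res <- .unifrac_pairs_cpp(t(B), prof$lengths, as.numeric(alphas),
                            unweighted, weighted)
  labels <- c(if (unweighted) "u_unifrac", if (weighted) "w_unifrac",
              if (length(alphas)) sprintf("g_unifrac_%g", alphas))
  degenerate <- isTRUE(attr(res, "degenerate"))
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (m in seq_along(labels)) {
    D <- res[[m]]
    dimnames(D) <- list(rownames(B), rownames(B))
    attr(D, "measure") <- labels[m]
    attr(D, "degenerate") <- degenerate || all(D == 0)
    out[[m]] <- D
  }
  if (degenerate) {
    warning("UniFrac denominator zero for at least one sample pair; ",
            "distance set to 0 and matrix flagged degenerate", call. = FALSE)
  }
  out
}

#' Unweighted UniFrac distances
#'
#' Presence/absence-weighted fraction of unshared branch length:
#' `D_ij = sum_e b_e |1(p_ei>0) - 1(p_ej>0)| / sum_e b_e 1(p_ei>0 or p_ej>0)`.
#'
#' @param prof a [branch_profiles()] result.
#' @return Symmetric distance matrix in `[0, 1]`.
#' @export
unweighted_unifrac <- function(prof) {
  unifrac_family(prof, alphas = numeric(0), weighted = FALSE)$u_unifrac
}

#' Normalized weighted UniFrac distances
#'
#' `D_ij = sum_e b_e |p_ei - p_ej| / sum_e b_e (p_ei + p_ej)`; the
#' normalization bounds the distance in `[0, 1]`, which keeps all candidate
#' measures on one scale inside the min-P combination.
#'
#' @inheritParams unweighted_unifrac
#' @return Symmetric distance matrix in `[0, 1]`.
#' @export
weighted_unifrac <- function(prof) {
  unifrac_family(prof, alphas = numeric(0), unweighted = FALSE)$w_unifrac
}

#' Generalized UniFrac distances
#'
#' `D_ij = sum_e b_e (p_ei+p_ej)^alpha |p_ei-p_ej|/(p_ei+p_ej) /
#'         sum_e b_e (p_ei+p_ej)^alpha`, edges with `p_ei + p_ej = 0`
#' skipped.  `alpha = 1` recovers the normalized weighted UniFrac; smaller
#' `alpha` down-weights abundant lineages.
#'
#' @inheritParams unweighted_unifrac
#' @param alpha abundance-weighting exponent in `[0, 1]`.
#' @return Symmetric distance matrix in `[0, 1]`.
#' @export
generalized_unifrac <- function(prof, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  unifrac_family(prof, alphas = alpha, unweighted = FALSE,
                 weighted = FALSE)[[sprintf("g_unifrac_%g", alpha)]]
}

#' Convert a distance matrix to a centered kernel
#'
#' `K = -1/2 (I - 11'/n) D^2 (I - 11'/n)` with `D^2` the element-wise
#' square.  When `repair = TRUE` (default) negative eigenvalues are clipped
#' to zero and the kernel reconstructed, the established practice for
#' non-Euclidean measures such as Bray-Curtis; the repair is recorded in the
#' `"repaired"` attribute.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param repair clip negative eigenvalues to keep the kernel PSD.
#' @return Symmetric kernel matrix.
#' @export
distance_to_kernel <- function(D, repair = TRUE) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop2("distance matrix not symmetric")
  D2 <- D * D
  rm_ <- rowMeans(D2)
  K <- -0.5 * (D2 - outer(rm_, rep(1, ncol(D2))) -
               outer(rep(1, nrow(D2)), colMeans(D2)) + mean(D2))
  K <- (K + t(K)) / 2
  repaired <- FALSE
  if (repair) {
    e <- eigen(K, symmetric = TRUE)
    tol <- 1e-12 * max(1, abs(e$values[1L]))
    if (any(e$values < -tol)) {
      v <- pmax(e$values, 0)
      K <- e$vectors %*% (v * t(e$vectors))
      K <- (K + t(K)) / 2
      repaired <- TRUE
    }
    # low-rank factor K = M M' reused by the permutation engine, which
    # evaluates r' K r as ||M' r||^2 at reduced cost
    pos <- e$values > tol
    attr(K, "factor") <- e$vectors[, pos, drop = FALSE] *
      rep(sqrt(e$values[pos]), each = nrow(K))
  }
  attr(K, "measure") <- attr(D, "measure")
  attr(K, "repaired") <- repaired
  K
}

#' Export a distance matrix as a square TSV
#'
#' Writes the matrix with a sample-id header row and first column, for
#' external inspection.
#'
#' @param D distance matrix with sample dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Kernel-machine variance-component score statistic
#'
#' `Q = r' K r / (2 phi)` with `r` the null-model residuals and `phi` the
#' null dispersion.  Large `Q` is evidence of association.
#'
#' @param fit a [fit_null()] result.
#' @param K kernel matrix from [distance_to_kernel()].
#' @return Scalar statistic.
#' @export
mirkat_statistic <- function(fit, K) {
  stopifnot(inherits(fit, "null_fit"))
  r <- fit$residuals
  drop(crossprod(r, K %*% r)) / (2 * fit$phi)
}

#' Build the candidate kernel set for a microbial group
#'
#' The seven candidate measures are Bray-Curtis, unweighted UniFrac,
#' normalized weighted UniFrac and generalized UniFrac with
#' `alpha` in `{0, 0.25, 0.5, 0.75}`.  When any UniFrac measure is
#' degenerate (a zero denominator for some pair, or an all-zero matrix,
#' i.e. no phylogenetic disparity between any two samples), the UniFrac
#' kernels are dropped and only the Bray-Curtis kernel is returned, with
#' the `"unifrac_degenerate"` attribute set.
#'
#' @param P proportion matrix for the group (samples x member OTUs).
#' @param tree pruned tree over the member OTUs (`phylo` or [tree_index()]),
#'   or `NULL` to use the Bray-Curtis kernel alone.
#' @param alphas generalized UniFrac exponents.
#' @return Named list of kernel matrices; attribute `"unifrac_degenerate"`.
#' @export
kernel_candidates <- function(P, tree = NULL, alphas = c(0, 0.25, 0.5, 0.75)) {
  dists <- list(bray_curtis = bray_curtis(P))
  degenerate <- is.null(tree)
  if (!is.null(tree)) {
    prof <- branch_profiles(P, tree)
    ufs <- suppressWarnings(unifrac_family(prof, alphas = alphas))
    if (any(vapply(ufs, function(d) isTRUE(attr(d, "degenerate")), TRUE))) {
      degenerate <- TRUE
    } else {
      dists <- c(dists, ufs)
    }
  }
  kernels <- lapply(dists, distance_to_kernel)
  attr(kernels, "unifrac_degenerate") <- degenerate
  kernels
}
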