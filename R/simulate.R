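# Synthetic microbiome generator (Dirichlet-multinomial counts over a random
# phylogeny) and the type-I-error / power experiments that validate the
# association tests.

#' Dirichlet-multinomial parameters
#'
#' @param pi proportion means (non-negative, summing to 1).
#' @param theta overdispersion in `[0, 1)`; 0 degenerates to the
#'   multinomial.  The Dirichlet concentration vector is
#'   `pi * (1 - theta) / theta`.
#' @return A `dm_params` list.
#' @export
dm_params <- function(pi, theta) {
  pi <- as.numeric(pi)
  stopifnot(all(pi >= 0), theta >= 0, theta < 1)
  s <- sum(pi)
  if (abs(s - 1) > 1e-8) stop2("proportion means must sum to 1")
  structure(list(pi = pi / s, theta = theta), class = "dm_params")
}

#' Default synthetic community parameters
#'
#' A skewed, power-law-like mean composition (`pi_j` proportional to
#' `j^-decay`) over `p` taxa with moderate overdispersion, emulating the
#' highly imbalanced abundance profile of an infant gut community after
#' abundance filtering.
#'
#' @param p number of OTUs (default 71).
#' @param theta overdispersion (default 0.02).
#' @param decay power-law exponent of the ranked mean proportions.
#' @return A [dm_params()] object.
#' @export
default_dm_params <- function(p = 71L, theta = 0.02, decay = 1.2) {
  w <- seq_len(p)^(-decay)
  dm_params(w / sum(w), theta)
}

#' Random rooted binary tree over p leaves
#'
#' @param p number of leaves (>= 2).
#' @param seed integer seed.
#' @return An `ape::phylo` tree with tips `otu1..otup` and positive branch
#'   lengths.
#' @export
synth_tree <- function(p, seed = 1L) {
  stopifnot(p >= 2L)
  with_seed(seed, ape::rtree(p, tip.label = paste0("otu", seq_len(p))))
}

#' Method-of-moments Dirichlet-multinomial estimation
#'
#' Pooled-count estimate of the proportion means and the Weir-Mosimann
#' weighted moment estimator of the overdispersion.
#'
#' @param otu an [otu_table()] or count matrix (samples x OTUs).
#' @return A [dm_params()] object (theta truncated to `[0, 1)`).
#' @export
estimate_dm_params <- function(otu) {
  m <- unclass(as.matrix(otu))
  n <- nrow(m)
  if (n < 2L) stop2("need at least 2 samples to estimate dispersion")
  N <- rowSums(m)
  Sn <- sum(N)
  pi_hat <- colSums(m) / Sn
  P <- m / N
  dev <- sweep(P, 2L, pi_hat, "-")
  MSP <- sum(N * rowSums(dev^2)) / (n - 1)
  MSG <- sum(N * rowSums(P * (1 - P))) / (Sn - n)
  nc <- (Sn - sum(N^2) / Sn) / (n - 1)
  theta <- (MSP - MSG) / (MSP + (nc - 1) * MSG)
  theta <- min(max(theta, 0), 1 - 1e-8)
  dm_params(pi_hat, theta)
}

#' Sample library sizes from a negative binomial
#'
#' Defaults to mean 300 and size 10; zero draws are redrawn so every
#' sample has at least one read.
#'
#' @param n number of samples.
#' @param mean,size negative binomial parameters.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return Integer vector of totals, all `>= 1`.
#' @export
sample_library_sizes <- function(n, mean = 300, size = 10, seed = NULL) {
  stopifnot(mean > 0, size > 0)
  with_seed(seed, {
    totals <- rnbinom(n, mu = mean, size = size)
    while (any(totals == 0L)) {
      k <- totals == 0L
      totals[k] <- rnbinom(sum(k), mu = mean, size = size)
    }
    totals
  })
}

#' Sample an OTU table from the Dirichlet-multinomial
#'
#' Per sample, a composition is drawn from the Dirichlet with
#' concentration `pi (1 - theta) / theta` (or taken as `pi` exactly when
#' `theta = 0`), then counts from the multinomial with the sample's total.
#'
#' @param n number of samples.
#' @param params a [dm_params()] object.
#' @param totals per-sample totals (e.g. [sample_library_sizes()]).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return An [otu_table()] (`n` x `length(pi)`).
#' @export
sample_dm <- function(n, params, totals, seed = NULL) {
  stopifnot(inherits(params, "dm_params"), length(totals) == n)
  p <- length(params$pi)
  with_seed(seed, {
    counts <- matrix(0, n, p)
    if (params$theta == 0) {
      for (i in seq_len(n)) {
        counts[i, ] <- rmultinom(1L, totals[i], params$pi)
      }
    } else {
      conc <- params$pi * (1 - params$theta) / params$theta
      for (i in seq_len(n)) {
        g <- rgamma(p, shape = conc)
        s <- sum(g)
        prop <- if (s > 0) g / s else params$pi
        counts[i, ] <- rmultinom(1L, totals[i], prop)
      }
    }
    otu_table(counts, sample_ids = paste0("s", seq_len(n)),
              otu_ids = paste0("otu", seq_len(p)))
  })
}

#' PAM clustering of tree leaves by cophenetic distance
#'
#' @param tree an `ape::phylo` tree.
#' @param k number of clusters (default 5).
#' @return Integer cluster assignment named by tip label.
#' @export
pam_clusters <- function(tree, k = 5L) {
  stopifnot(k >= 1L, k <= length(tree$tip.label))
  if (k == 1L) {
    return(stats::setNames(rep(1L, length(tree$tip.label)), tree$tip.label))
  }
  if (k == length(tree$tip.label)) {
    return(stats::setNames(seq_len(k), tree$tip.label))
  }
  d <- ape::cophenetic.phylo(tree)
  cluster::pam(stats::as.dist(d), k, diss = TRUE, cluster.only = TRUE)
}

#' Select the associated OTU index set for a simulation scenario
#'
#' `top10` / `bottom10`: the `round(0.1 p)` (at least 1) OTUs with the
#' highest / lowest mean proportion.  `random10`: a seeded random 10%.
#' `pam_cluster`: all members of one cluster drawn uniformly at random, so
#' that over replicates every cluster is exercised.
#'
#' @param selector one of `"top10"`, `"random10"`, `"bottom10"`,
#'   `"pam_cluster"`.
#' @param otu an [otu_table()] (used for abundance ranking).
#' @param clusters cluster assignment from [pam_clusters()] (required for
#'   `"pam_cluster"`).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param frac fraction of OTUs deemed associated (default 0.1).
#' @return Integer vector of associated OTU column indices.
#' @export
select_associated <- function(selector = c("top10", "random10", "bottom10",
                                           "pam_cluster"),
                              otu, clusters = NULL, seed = NULL, frac = 0.1) {
  selector <- match.arg(selector)
  p <- ncol(otu)
  m <- max(1L, round(frac * p))
  mp <- colMeans(to_composition(otu))
  with_seed(seed, switch(selector,
    top10 = order(mp, decreasing = TRUE)[seq_len(m)],
    bottom10 = order(mp)[seq_len(m)],
    random10 = sample.int(p, m),
    pam_cluster = {
      if (is.null(clusters)) stop2("pam_cluster scenario needs cluster labels")
      cl <- sample(unique(clusters), 1L)
      which(clusters[colnames(otu)] == cl)
    }))
}

#' Assemble a simulation scenario (associated set and coefficients)
#'
#' Coefficients are drawn `Uniform(0, c)` in same-direction mode and
#' `Uniform(-c, c)` in mixed mode; `"balanced"` re-projects mixed draws so
#' the planted signal is exactly uncorrelated with the aggregate predictor
#' (the cancellation diagnostic); `c = 0` gives the null scenario while
#' still fixing an associated set for the correlated-covariate mode.
#'
#' @inheritParams select_associated
#' @param effect_size the scale `c` (0, 1, 2, or 3 in the experiments).
#' @param direction `"same"`, `"mixed"`, or `"balanced"`.
#' @return A `scenario` list: `lambda` (indices), `beta` (same length),
#'   `selector`, `direction`, `effect_size`.
#' @export
draw_scenario <- function(selector, otu, effect_size,
                          direction = c("same", "mixed", "balanced"),
                          clusters = NULL, seed = NULL) {
  direction <- match.arg(direction)
  lambda <- select_associated(selector, otu, clusters, seed = seed)
  m <- unclass(as.matrix(otu))
  beta <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    make_beta(direction, effect_size, lambda, zscore_cols(m),
                              rowSums(zscore_cols(m / rowSums(m)))))
  structure(list(lambda = lambda, beta = beta, selector = selector,
                 direction = direction, effect_size = effect_size),
            class = "scenario")
}

#' Simulate an outcome and covariates for a count table
#'
#' Linear predictor `0.5 scale(X1 + X2) + sum_{j in Lambda} beta_j
#' scale(Z_ij)`, with `X1 ~ Bernoulli(0.5)` independent of the OTUs and
#' `X2` either independent `N(0, 1)` or correlated with the associated
#' OTUs (`X2 = sum_{j in Lambda} scale(Z_ij) + N(0, 1)`).  Continuous
#' traits add `N(0, 1)` noise; binary traits are Bernoulli draws through
#' the inverse logit.  `scale` uses the sample (n-1) standard deviation.
#'
#' @param otu an [otu_table()] of simulated counts.
#' @param scenario a [draw_scenario()] result.
#' @param trait `"continuous"` or `"binary"`.
#' @param x2_mode `"independent"` or `"correlated"`.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A [study_design()] with covariates `X1`, `X2`.
#' @export
simulate_outcome <- function(otu, scenario, trait = c("continuous", "binary"),
                             x2_mode = c("independent", "correlated"),
                             seed = NULL) {
  trait <- match.arg(trait)
  x2_mode <- match.arg(x2_mode)
  m <- unclass(as.matrix(otu))
  n <- nrow(m)
  Zs <- zscore_cols(m)
  with_seed(seed, {
    x1 <- rbinom(n, 1L, 0.5)
    x2 <- if (x2_mode == "correlated") {
      rowSums(Zs[, scenario$lambda, drop = FALSE]) + rnorm(n)
    } else {
      rnorm(n)
    }
    xs <- x1 + x2
    s <- sd(xs)
    xs <- if (s > 0) (xs - mean(xs)) / s else rep(0, n)
    eta <- 0.5 * xs +
      drop(Zs[, scenario$lambda, drop = FALSE] %*% scenario$beta)
    y <- if (trait == "continuous") {
      eta + rnorm(n)
    } else {
      rbinom(n, 1L, stats::plogis(eta))
    }
    if (trait == "binary" && length(unique(y)) < 2L) {
      y[sample.int(n, 1L)] <- 1 - y[1L] # guard: keep both classes present
    }
    study_design(y, data.frame(X1 = x1, X2 = x2), trait = trait,
                 sample_ids = rownames(m))
  })
}

draw_beta <- function(direction, effect_size, m) {
  if (effect_size == 0) return(rep(0, m))
  switch(direction,
    same = runif(m, 0, effect_size),
    mixed = ,
    balanced = runif(m, -effect_size, effect_size),
    stop2("unknown effect direction: ", direction))
}

# Project mixed-direction coefficients so the planted signal
# sum_{j in lambda} beta_j scale(Z_ij) is exactly uncorrelated with the
# aggregate test's predictor a_i = sum_j z-scored proportions: after
# balancing, positive and negative effects cancel in the aggregate and
# only its cancellation failure mode remains.
balance_beta <- function(beta, Zsig, a) {
  cvec <- drop(crossprod(Zsig, a))
  denom <- sum(cvec^2)
  if (denom > 0) beta - (sum(beta * cvec) / denom) * cvec else beta
}

# Zcnt: z-scored counts (the outcome model's scale(Z)); agg: the aggregate
# predictor of the test (row sums of the standardized composition)
make_beta <- function(direction, effect_size, lambda, Zcnt, agg) {
  beta <- draw_beta(direction, effect_size, length(lambda))
  if (direction == "balanced") {
    balance_beta(beta, Zcnt[, lambda, drop = FALSE], agg)
  } else {
    beta
  }
}

# Shared core of the simulation experiments.  `cells` is a data frame with
# columns trait, x2_mode, direction, effect_size: every cell for one
# scenario selector is evaluated on the same replicate draws (counts,
# kernels and permutation indices are built once per replicate and shared;
# a common-random-numbers design that also sharpens across-cell power
# comparisons).
run_sim_cells <- function(reps, n_perm, seed, selector, cells, n = 100L,
                          params = default_dm_params(),
                          tree = synth_tree(length(params$pi), seed = 7L),
                          lib_mean = 300, lib_size = 10, alpha = 0.05,
                          grid = GAMMA_GRID) {
  ti <- tree_index(tree)
  clusters <- if (selector == "pam_cluster") pam_clusters(tree, 5L) else NULL
  methods <- c("omiat", "aspu", "optimal_mirkat", "aggregate")
  rej <- array(0L, dim = c(nrow(cells), length(methods)),
               dimnames = list(NULL, methods))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      totals <- sample_library_sizes(n, lib_mean, lib_size)
      counts <- sample_dm(n, params, totals)
      lambda <- select_associated(selector, counts, clusters)
      P <- to_composition(counts)
      Zstd <- standardize_composition(P)
      Zcnt <- zscore_cols(unclass(counts)) # the scale(Z) of the outcome model
      agg <- rowSums(Zstd)
      kernels <- kernel_candidates(P, ti)
      pseed <- sample.int(.Machine$integer.max - 1L, 1L)
      perms <- make_permutations(n, n_perm, pseed)
      for (ci in seq_len(nrow(cells))) {
        scen <- structure(
          list(lambda = lambda,
               beta = make_beta(cells$direction[ci], cells$effect_size[ci],
                                lambda, Zcnt, agg),
               selector = selector, direction = cells$direction[ci],
               effect_size = cells$effect_size[ci]),
          class = "scenario")
        design <- simulate_outcome(counts, scen, cells$trait[ci],
                                   cells$x2_mode[ci])
        fit <- fit_null(design)
        res <- group_association(fit, Zstd, kernels, perms, grid)
        for (m in methods) {
          if (!is.null(res[[m]]) && res[[m]]$p <= alpha) {
            rej[ci, m] <- rej[ci, m] + 1L
          }
        }
      }
    }
  })
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    data.frame(trait = cells$trait[ci], x2_mode = cells$x2_mode[ci],
               method = methods, selector = selector,
               direction = cells$direction[ci],
               effect_size = cells$effect_size[ci],
               rate = as.numeric(rej[ci, ]) / reps, reps = reps,
               stringsAsFactors = FALSE)
  }))
  out$mc_se <- sqrt(out$rate * (1 - out$rate) / out$reps)
  out
}

#' Type-I-error experiment
#'
#' Simulates the null (`beta = 0`) for every combination of trait type and
#' covariate mode and reports the rejection rate at `alpha` for OMiAT,
#' aSPU, Optimal MiRKAT and the aggregate test, with Monte-Carlo standard
#' errors.  All four methods are evaluated on the same replicates under
#' one shared permutation set.
#'
#' @param reps replicates per cell.
#' @param n_perm permutations per test.
#' @param seed master seed.
#' @param traits,x2_modes cells to run.
#' @param ... further arguments to the simulation core (`n`, `params`,
#'   `tree`, `alpha`, ...).
#' @return Data frame of rejection rates (one row per cell x method).
#' @export
run_type1_experiment <- function(reps = 2000L, n_perm = 1000L, seed = 1L,
                                 traits = c("continuous", "binary"),
                                 x2_modes = c("independent", "correlated"),
                                 ...) {
  cells <- expand.grid(trait = traits, x2_mode = x2_modes,
                       stringsAsFactors = FALSE)
  cells$direction <- "same"
  cells$effect_size <- 0
  run_sim_cells(reps, n_perm, seed, selector = "random10", cells = cells, ...)
}

#' Power experiment
#'
#' Rejection rates for each method over a grid of association scenarios,
#' effect scales and effect-direction modes.
#'
#' @param reps replicates per cell.
#' @param n_perm permutations per test.
#' @param seed master seed.
#' @param selectors scenario selectors (see [select_associated()]).
#' @param effect_sizes effect scales `c`.
#' @param directions `"same"`, `"mixed"`, or both.
#' @param trait,x2_mode the (single) trait type and covariate mode to run.
#' @param ... further arguments to the simulation core.
#' @return Data frame of rejection rates per cell x method.
#' @export
run_power_experiment <- function(reps = 500L, n_perm = 1000L, seed = 1L,
                                 selectors = c("top10", "random10",
                                               "bottom10", "pam_cluster"),
                                 effect_sizes = c(1, 2, 3),
                                 directions = c("same", "mixed"),
                                 trait = "binary",
                                 x2_mode = "independent", ...) {
  out <- lapply(seq_along(selectors), function(i) {
    cells <- expand.grid(trait = trait, x2_mode = x2_mode,
                         direction = directions,
                         effect_size = effect_sizes,
                         stringsAsFactors = FALSE)
    run_sim_cells(reps, n_perm,
                  seed = seed + i, # distinct stream per scenario selector
                  selector = selectors[i], cells = cells, ...)
  })
  do.call(rbind, out)
}

#' Synthetic taxonomy nested along phylogenetic clusters
#'
#' Builds Greengenes-style lineages in which each PAM cluster of the tree
#' is one phylum (classes and orders follow the phylum), families and
#' genera subdivide each cluster by cophenetic proximity, and species are
#' mostly one per OTU with occasional multi-OTU species.  The layout gives
#' a planted phylogenetic signal a clean taxonomic footprint.
#'
#' @param tree an `ape::phylo` tree.
#' @param clusters cluster assignment from [pam_clusters()].
#' @return Taxonomy matrix as from [read_taxonomy()].
#' @export
synth_taxonomy <- function(tree, clusters = pam_clusters(tree, 5L)) {
  tips <- tree$tip.label
  cl <- clusters[tips]
  tax <- matrix(NA_character_, length(tips), 7L,
                dimnames = list(tips, TAXONOMIC_RANKS))
  tax[, "kingdom"] <- "Bacteria"
  tax[, "phylum"] <- paste0("Phylum", cl)
  tax[, "class"] <- paste0("Class", cl)
  tax[, "order"] <- paste0("Order", cl)
  d <- ape::cophenetic.phylo(tree)
  for (c_id in unique(cl)) {
    members <- tips[cl == c_id]
    sub <- if (length(members) >= 4L) {
      cluster::pam(stats::as.dist(d[members, members]), 2L, diss = TRUE,
                   cluster.only = TRUE)
    } else {
      stats::setNames(rep(1L, length(members)), members)
    }
    tax[members, "family"] <- paste0("Family", c_id, letters[sub])
    for (f_id in unique(sub)) {
      fm <- members[sub == f_id]
      gsub_ <- if (length(fm) >= 4L) {
        cluster::pam(stats::as.dist(d[fm, fm, drop = FALSE]), 2L,
                     diss = TRUE, cluster.only = TRUE)
      } else {
        stats::setNames(rep(1L, length(fm)), fm)
      }
      tax[fm, "genus"] <- paste0("Genus", c_id, letters[f_id], gsub_)
    }
  }
  # species: one per OTU, except the first two members of any genus with
  # >= 3 members share one (multi-OTU species are tested as groups)
  tax[, "species"] <- paste0("sp_", tips)
  for (g_id in unique(tax[, "genus"])) {
    gm <- tips[tax[, "genus"] == g_id]
    if (length(gm) >= 3L) {
      tax[gm[1:2], "species"] <- paste0("sp_shared_", g_id)
    }
  }
  tax
}

#' Build a complete synthetic dataset for a rank scan
#'
#' Draws a tree, Dirichlet-multinomial counts, a cluster-aligned taxonomy,
#' a scenario, and an outcome, and returns the harmonized dataset together
#' with the generating truth.
#'
#' @param n samples; `p` OTUs.
#' @param p number of OTUs.
#' @param selector,effect_size,direction scenario specification.
#' @param trait,x2_mode outcome specification.
#' @param params Dirichlet-multinomial parameters.
#' @param seed master seed.
#' @return List: `dataset` (a `micam_dataset`), `scenario`, `clusters`,
#'   `tree`.
#' @export
synth_dataset <- function(n = 100L, p = 71L, selector = "pam_cluster",
                          effect_size = 2, direction = "same",
                          trait = "continuous", x2_mode = "independent",
                          params = default_dm_params(p), seed = 1L) {
  tree <- synth_tree(p, seed = seed)
  clusters <- pam_clusters(tree, 5L)
  tax <- synth_taxonomy(tree, clusters)
  with_seed(seed + 1L, {
    totals <- sample_library_sizes(n)
    counts <- sample_dm(n, params, totals)
    scen <- draw_scenario(selector, counts, effect_size, direction,
                          clusters = clusters)
    design <- simulate_outcome(counts, scen, trait, x2_mode)
    ds <- harmonize(counts, tree, tax, design)
    list(dataset = ds, scenario = scen, clusters = clusters, tree = tree)
  })
}
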