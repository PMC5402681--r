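test_that("Bray-Curtis matches the hand formula and its bounds", {
  P <- rbind(s1 = c(0.75, 0.25), s2 = c(1 / 3, 2 / 3))
  D <- bray_curtis(P)
  expect_equal(D[1, 2], (abs(0.75 - 1 / 3) + abs(0.25 - 2 / 3)) / 2,
               tolerance = 1e-12)
  expect_equal(D[1, 2], 0.4166667, tolerance = 1e-6)

  # identical rows -> 0; disjoint supports -> 1
  P2 <- rbind(a = c(0.5, 0.5, 0, 0), b = c(0.5, 0.5, 0, 0),
              c = c(0, 0, 0.3, 0.7))
  D2 <- bray_curtis(P2)
  expect_equal(D2["a", "b"], 0)
  expect_equal(D2["a", "c"], 1)
  expect_true(all(D2 >= 0 & D2 <= 1))
  expect_equal(unname(diag(D2)), rep(0, 3))
})

test_that("branch profiles equal explicit per-edge leaf-set sums", {
  tr <- synth_tree(10, seed = 21)
  trp <- ape::reorder.phylo(tr, "postorder")
  P <- random_composition(6, tr, seed = 3)
  prof <- branch_profiles(P, tr)
  oracle <- oracle_profiles(P, trp)
  expect_equal(unname(prof$P), unname(oracle$P), tolerance = 1e-12)
  expect_equal(prof$lengths, oracle$lengths)

  # star-like check: the edge above each leaf carries that leaf's proportion
  leaf_edges <- match(seq_len(10), trp$edge[, 2])
  expect_equal(unname(prof$P[, leaf_edges]),
               unname(P[, trp$tip.label]), tolerance = 1e-12)
  # profiles at the root-adjacent edges sum the full composition
  expect_true(all(prof$P >= 0 & prof$P <= 1 + 1e-12))
})

test_that("UniFrac family equals the brute-force per-edge oracle", {
  for (seed in c(2, 13)) {
    tr <- synth_tree(12, seed = seed)
    P <- random_composition(5, tr, seed = seed + 100)
    # sprinkle zeros so presence/absence differs across samples
    P[P < quantile(P, 0.3)] <- 0
    P <- P / rowSums(P)
    prof <- branch_profiles(P, tr)
    expect_equal(unname(unweighted_unifrac(prof)),
                 oracle_unifrac(P, tr, "unweighted"), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(weighted_unifrac(prof)),
                 oracle_unifrac(P, tr, "weighted"), tolerance = 1e-12,
                 ignore_attr = TRUE)
    for (a in c(0, 0.25, 0.5, 0.75)) {
      expect_equal(unname(generalized_unifrac(prof, a)),
                   oracle_unifrac(P, tr, "generalized", alpha = a),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("UniFrac boundary cases and closed-form identities hold", {
  # 2-leaf tree, lengths (1, 2); A has only L1, B has both
  tr <- ape::read.tree(text = "(L1:1,L2:2);")
  P <- rbind(A = c(L1 = 1, L2 = 0), B = c(L1 = 0.5, L2 = 0.5))
  prof <- branch_profiles(P, tr)
  expect_equal(unweighted_unifrac(prof)[1, 2], 2 / 3, tolerance = 1e-12)

  # disjoint supports on a unit star: both unweighted and weighted are 1
  tr2 <- ape::read.tree(text = "(L1:1,L2:1);")
  P2 <- rbind(A = c(L1 = 1, L2 = 0), B = c(L1 = 0, L2 = 1))
  prof2 <- branch_profiles(P2, tr2)
  expect_equal(unweighted_unifrac(prof2)[1, 2], 1)
  expect_equal(weighted_unifrac(prof2)[1, 2], 1)

  # alpha = 1 generalized equals normalized weighted, machine precision
  tr3 <- synth_tree(9, seed = 5)
  P3 <- random_composition(7, tr3, seed = 6)
  prof3 <- branch_profiles(P3, tr3)
  expect_equal(unname(generalized_unifrac(prof3, 1)),
               unname(weighted_unifrac(prof3)),
               tolerance = 1e-14, ignore_attr = TRUE)

  # identical profiles -> all-zero distances (and degeneracy flagged)
  P4 <- P3[c(1, 1), ]
  rownames(P4) <- c("a", "b")
  prof4 <- branch_profiles(P4, tr3)
  D4 <- weighted_unifrac(prof4)
  expect_equal(D4[1, 2], 0)
  expect_true(attr(D4, "degenerate"))

  # distances in [0,1] and symmetric on random fixtures
  D <- generalized_unifrac(prof3, 0.5)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("pruned-subtree UniFrac equals full-tree UniFrac on zeroed OTUs", {
  # kept tips span the root, so pruning only compresses all-absent chains
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,((C:0.5,D:2):1,E:1):0.5);")
  keep <- c("A", "D", "E")
  P <- random_composition(6, tr, seed = 8)
  P[, c("B", "C")] <- 0
  P <- P / rowSums(P)
  sub <- prune_tree(tr, keep)
  prof_full <- branch_profiles(P, tr)
  prof_sub <- branch_profiles(P[, keep], sub)
  expect_equal(unname(weighted_unifrac(prof_full)),
               unname(weighted_unifrac(prof_sub)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(unweighted_unifrac(prof_full)),
               unname(unweighted_unifrac(prof_sub)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(generalized_unifrac(prof_full, 0.5)),
               unname(generalized_unifrac(prof_sub, 0.5)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("kernel conversion reproduces -1/2 J D^2 J and repairs PSD", {
  D <- matrix(c(0, 2, 2, 0), 2)
  K <- distance_to_kernel(D)
  expect_equal(unname(K), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_false(attr(K, "repaired"))

  expect_equal(distance_to_kernel(matrix(0, 3, 3)),
               matrix(0, 3, 3), ignore_attr = TRUE)

  withr::local_seed(17)
  n <- 8
  D2 <- as.matrix(dist(matrix(runif(n * 3), n)))^0.7 # non-Euclidean-ish
  K0 <- distance_to_kernel(D2, repair = FALSE)
  expect_equal(unname(K0), unname(oracle_kernel(D2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(K0)), rep(0, n), tolerance = 1e-10)

  Kr <- distance_to_kernel(D2)
  ev <- eigen(Kr, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # the factor form reproduces the repaired kernel
  M <- attr(Kr, "factor")
  expect_equal(unname(M %*% t(M)), unname(Kr), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("distance matrices export to square TSV losslessly", {
  tr <- synth_tree(5, seed = 2)
  P <- random_composition(4, tr, seed = 3)
  D <- bray_curtis(P)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, f)
  back <- read.delim(f, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), unclass(D), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the MiRKAT statistic matches its quadratic form", {
  K <- matrix(c(1, -1, -1, 1), 2)
  d <- study_design(c(6, 4), trait = "continuous") # residuals (1, -1)
  f <- fit_null(d)
  f$phi <- 1
  expect_equal(mirkat_statistic(f, K), 2) # r'Kr = 4, over 2*phi

  f0 <- f
  f0$residuals <- c(0, 0)
  expect_equal(mirkat_statistic(f0, K), 0)

  # Q >= 0 for any residuals after PSD repair
  withr::local_seed(23)
  tr <- synth_tree(8, seed = 2)
  P <- random_composition(10, tr, seed = 3)
  Kb <- distance_to_kernel(bray_curtis(P))
  for (i in 1:5) {
    fr <- f
    fr$n <- 10
    fr$residuals <- rnorm(10)
    expect_gte(mirkat_statistic(fr, Kb), -1e-10)
  }
})

test_that("degenerate phylogeny triggers the Bray-Curtis-only fallback", {
  # two tips at zero distance: no phylogenetic disparity is possible
  tr <- ape::read.tree(text = "(L1:0,L2:0);")
  P <- rbind(s1 = c(L1 = 0.2, L2 = 0.8), s2 = c(L1 = 0.7, L2 = 0.3),
             s3 = c(L1 = 0.5, L2 = 0.5))
  ks <- suppressWarnings(kernel_candidates(P, tr))
  expect_true(attr(ks, "unifrac_degenerate"))
  expect_identical(names(ks), "bray_curtis")

  tr2 <- synth_tree(4, seed = 4)
  P2 <- random_composition(5, tr2, seed = 5)
  ks2 <- kernel_candidates(P2, tr2)
  expect_false(attr(ks2, "unifrac_degenerate"))
  expect_length(ks2, 7)
  expect_setequal(names(ks2),
                  c("bray_curtis", "u_unifrac", "w_unifrac", "g_unifrac_0",
                    "g_unifrac_0.25", "g_unifrac_0.5", "g_unifrac_0.75"))
})
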