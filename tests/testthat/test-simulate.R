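test_that("synthetic trees are seeded, rooted, binary and sized", {
  tr <- synth_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  tr2 <- synth_tree(17, seed = 5)
  expect_equal(ape::Ntip(tr2), 17)
  expect_true(ape::is.rooted(tr2))
  expect_true(all(tr2$edge.length > 0))
  expect_identical(ape::write.tree(synth_tree(17, seed = 5)),
                   ape::write.tree(tr2))
})

test_that("library sizes follow the negative binomial moments", {
  tot <- sample_library_sizes(50000, mean = 300, size = 10, seed = 3)
  expect_true(all(tot >= 1))
  expect_equal(mean(tot), 300, tolerance = 0.02)
  # Var = mu + mu^2/size = 9300
  expect_equal(var(tot), 9300, tolerance = 0.08)
})

test_that("Dirichlet-multinomial draws match their closed-form moments", {
  pars <- dm_params(c(0.5, 0.3, 0.2), theta = 0.1)
  totals <- rep(200L, 4000)
  otu <- sample_dm(4000, pars, totals, seed = 9)
  expect_true(all(rowSums(otu) == 200))
  props <- colMeans(unclass(otu)) / 200
  expect_equal(unname(props), pars$pi, tolerance = 0.03)

  # overdispersion: count variance exceeds the multinomial variance
  v_mult <- 200 * pars$pi * (1 - pars$pi)
  v_obs <- apply(unclass(otu), 2, var)
  expect_true(all(v_obs > 1.5 * v_mult))

  # theta -> 0 limit: variance collapses to the multinomial
  otu0 <- sample_dm(4000, dm_params(pars$pi, 0), totals, seed = 10)
  v0 <- apply(unclass(otu0), 2, var)
  expect_equal(unname(v0 / v_mult), rep(1, 3), tolerance = 0.1)
})

test_that("moment estimation recovers known DM parameters", {
  pars <- default_dm_params(12, theta = 0.05)
  totals <- sample_library_sizes(500, seed = 2)
  otu <- sample_dm(500, pars, totals, seed = 4)
  est <- estimate_dm_params(otu)
  expect_equal(sum(est$pi), 1, tolerance = 1e-12)
  expect_equal(est$pi, pars$pi, tolerance = 0.05)
  expect_equal(est$theta, 0.05, tolerance = 0.02)

  # identical compositions at large depth: no overdispersion
  flat <- otu_table(matrix(rep(c(600L, 300L, 100L), each = 10), 10))
  expect_lt(estimate_dm_params(flat)$theta, 1e-6)
  expect_error(estimate_dm_params(otu_table(matrix(1:3, 1))), "2 samples")
})

test_that("PAM clustering on cophenetic distances behaves sensibly", {
  tr <- synth_tree(12, seed = 6)
  expect_equal(unname(pam_clusters(tr, 1)), rep(1L, 12))
  expect_length(unique(pam_clusters(tr, 12)), 12)

  cl <- pam_clusters(tr, 4)
  expect_length(cl, 12)
  d <- ape::cophenetic.phylo(tr)
  # within-cluster medoid cost beats 100 random partitions
  cost <- function(assign) {
    sum(vapply(unique(assign), function(k) {
      idx <- names(assign)[assign == k]
      min(colSums(d[idx, idx, drop = FALSE]))
    }, numeric(1)))
  }
  pam_cost <- cost(cl)
  withr::with_seed(8, {
    rand_costs <- replicate(100, {
      cost(stats::setNames(sample(rep_len(1:4, 12)), rownames(d)))
    })
  })
  expect_true(all(pam_cost <= rand_costs))
})

test_that("associated-set selection honors each scenario rule", {
  pars <- default_dm_params(40)
  totals <- sample_library_sizes(60, seed = 1)
  otu <- sample_dm(60, pars, totals, seed = 2)
  mp <- colMeans(to_composition(otu))

  top <- select_associated("top10", otu)
  expect_length(top, 4) # round(0.1 * 40)
  expect_setequal(top, order(mp, decreasing = TRUE)[1:4])
  bottom <- select_associated("bottom10", otu)
  expect_setequal(bottom, order(mp)[1:4])
  expect_length(intersect(top, bottom), 0)

  expect_identical(select_associated("random10", otu, seed = 3),
                   select_associated("random10", otu, seed = 3))

  tr <- synth_tree(40, seed = 3)
  cl <- pam_clusters(tr, 5)
  picks <- vapply(1:200, function(s) {
    idx <- select_associated("pam_cluster", otu, cl, seed = s)
    unique(cl[colnames(otu)[idx]])
  }, integer(1))
  freq <- table(picks) / 200
  expect_length(freq, 5)
  expect_true(all(abs(freq - 0.2) < 0.12)) # each cluster ~1/5 of the time
})

test_that("balanced coefficients cancel exactly in the aggregate", {
  pars <- default_dm_params(30)
  otu <- sample_dm(50, pars, sample_library_sizes(50, seed = 21), seed = 22)
  scen <- draw_scenario("top10", otu, 2, "balanced", seed = 23)
  m <- unclass(as.matrix(otu))
  signal <- drop(micam:::zscore_cols(m)[, scen$lambda] %*% scen$beta)
  agg <- rowSums(standardize_composition(to_composition(otu)))
  expect_equal(sum(signal * agg), 0, tolerance = 1e-8)
  expect_gt(sum(abs(scen$beta)), 0)
  expect_true(all(micam:::draw_beta("same", 2, 5) >= 0))
  expect_true(all(abs(micam:::draw_beta("mixed", 3, 50)) <= 3))
})

test_that("simulated outcomes follow the generating model", {
  pars <- default_dm_params(20)
  otu <- sample_dm(80, pars, sample_library_sizes(80, seed = 4), seed = 5)
  scen0 <- draw_scenario("random10", otu, 0, "same", seed = 6)
  expect_true(all(scen0$beta == 0))

  d0 <- simulate_outcome(otu, scen0, "continuous", "independent", seed = 7)
  expect_equal(length(d0$y), 80)
  expect_equal(colnames(d0$X), c("X1", "X2"))
  expect_true(all(d0$X[, "X1"] %in% 0:1))

  db <- simulate_outcome(otu, scen0, "binary", "correlated", seed = 8)
  expect_true(all(db$y %in% 0:1))

  # Var(Y) grows with the effect scale in same-direction mode
  vars <- vapply(c(0, 1, 3), function(cc) {
    scen <- draw_scenario("top10", otu, cc, "same", seed = 11)
    mean(vapply(1:30, function(r) {
      var(simulate_outcome(otu, scen, "continuous", "independent",
                           seed = 100 + r)$y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))

  # correlated X2 really is correlated with the associated OTUs
  scen <- draw_scenario("top10", otu, 1, "same", seed = 12)
  dx <- simulate_outcome(otu, scen, "continuous", "correlated", seed = 13)
  agg <- rowSums(scale(unclass(otu))[, scen$lambda])
  expect_gt(cor(dx$X[, "X2"], agg), 0.5)
})

test_that("experiment tables are deterministic with identical seeds", {
  r1 <- run_type1_experiment(reps = 3, n_perm = 59, seed = 42,
                             traits = "continuous",
                             x2_modes = "independent")
  r2 <- run_type1_experiment(reps = 3, n_perm = 59, seed = 42,
                             traits = "continuous",
                             x2_modes = "independent")
  expect_identical(r1, r2)
  expect_setequal(r1$method, c("omiat", "aspu", "optimal_mirkat",
                               "aggregate"))
  expect_true(all(r1$rate >= 0 & r1$rate <= 1))
  expect_equal(r1$mc_se, sqrt(r1$rate * (1 - r1$rate) / 3))

  p1 <- run_power_experiment(reps = 2, n_perm = 59, seed = 4,
                             selectors = "top10", effect_sizes = 2,
                             directions = "same")
  expect_equal(nrow(p1), 4) # one row per method
})
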