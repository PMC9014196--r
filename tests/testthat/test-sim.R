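# Monte Carlo simulator: determinism, structural constraints, and agreement
# with the exact layers on small runs.

test_that("simulation is reproducible given the seed and respects divergence", {
  S <- two_pop_tree(D = 10, eta_x = 0.5)
  b1 <- simulate_gene_trees(S, c(X = 2, Y = 2), R = 500, seed = 101)
  b2 <- simulate_gene_trees(S, c(X = 2, Y = 2), R = 500, seed = 101)
  expect_identical(b1$pair_times, b2$pair_times)
  expect_identical(b1$parent, b2$parent)
  b3 <- simulate_gene_trees(S, c(X = 2, Y = 2), R = 500, seed = 102)
  expect_false(identical(b1$pair_times, b3$pair_times))
  # cross-population coalescence cannot predate the divergence
  expect_gte(min(b1$pair_times[, "X_1:Y_1"]), 10)
  # within-population times are unconstrained and sometimes recent
  expect_lt(min(b1$pair_times[, "X_1:X_2"]), 10)
})

test_that("panmictic mean coalescence time matches the exponential within MC error", {
  S <- panmictic_tree(two_eta = 2)
  b <- simulate_gene_trees(S, c(X = 2), R = 50000, seed = 7)
  x <- b$pair_times[, 1L]
  expect_lt(abs(z_mean(x, 2)), 4)
  expect_lt(abs(z_var(x, 4)), 4)
})

test_that("simulator errors on invalid sampling requests", {
  S <- two_pop_tree(10, 1)
  expect_error(simulate_gene_trees(S, c(Z = 2), 10, 1),
               class = "msccov_error_pop")
  expect_error(simulate_gene_trees(S, c(X = 1), 10, 1),
               class = "msccov_error_config")
})

test_that("shared branch length on explicit trees follows the indicator definition", {
  # balanced tree ((a,b),(c,d)): tips 1..4, cherries (1,2) at t=1, (3,4) at
  # t=2, root at t=5
  tree_bal <- list(parent = c(5L, 5L, 6L, 6L, 7L, 7L, NA),
                   times = c(0, 0, 0, 0, 1, 2, 5))
  expect_equal(shared_branch_on_tree(tree_bal, c(1, 2), c(3, 4)), 0)
  expect_equal(shared_branch_on_tree(tree_bal, c(1, 2), c(1, 2)),
               2 * 1)                       # identical pairs: 2 * t_A
  # crossing tree ((a,c),(b,d)) with pairs {a,b},{c,d}:
  # cherries (1,3) at t_u=1 and (2,4) at t_v=2, root t_r=5
  tree_cross <- list(parent = c(5L, 6L, 5L, 6L, 7L, 7L, NA),
                     times = c(0, 0, 0, 0, 1, 2, 5))
  expect_equal(shared_branch_on_tree(tree_cross, c(1, 2), c(3, 4)),
               (5 - 1) + (5 - 2))
  expect_error(shared_branch_on_tree(tree_bal, c(1, 9), c(3, 4)),
               class = "msccov_error_pop")
})

test_that("empirical shared branch lengths match the exact engine", {
  S <- panmictic_tree()
  b <- simulate_gene_trees(S, c(X = 4), R = 20000, seed = 13)
  sb <- vapply(seq_len(b$R), function(r)
    shared_branch_on_tree(b, c("X_1", "X_2"), c("X_3", "X_4"), rep = r),
    numeric(1))
  expect_lt(abs(z_mean(sb, oracle_shared_4lin())), 4)
  sb3 <- vapply(seq_len(b$R), function(r)
    shared_branch_on_tree(b, c("X_1", "X_2"), c("X_1", "X_3"), rep = r),
    numeric(1))
  expect_lt(abs(z_mean(sb3, oracle_shared_3lin())), 4)
})

test_that("mutation overlay is marginally Poisson(2 mu t) with shared-branch covariance", {
  S <- panmictic_tree()
  b <- simulate_gene_trees(S, c(X = 2, Y = 2), R = 50000, seed = 23)
  b0 <- overlay_mutations(b, 0, seed = 1)
  expect_true(all(b0$k == 0L))
  mu <- 1
  b <- overlay_mutations(b, mu, seed = 24)
  k12 <- b$k[, "X_1:X_2"]; k34 <- b$k[, "Y_1:Y_2"]
  expect_lt(abs(z_mean(k12, 2 * mu * 1)), 4)
  expect_lt(abs(z_cov(k12, k34, 14 / 9)), 4)
  # law of total variance: Var(k) = 2 mu E(t) + 4 mu^2 Var(t)
  expect_lt(abs(z_var(k12, 2 * mu + 4 * mu^2)), 4)
})

test_that("empirical d statistics are exact averages and exchangeable", {
  # nX = nY = 2 with known pairwise counts
  k <- matrix(0L, 4, 4)
  k[1, 2] <- 2L                      # within X
  k[3, 4] <- 4L                      # within Y
  k[1, 3] <- 3L; k[1, 4] <- 4L; k[2, 3] <- 5L; k[2, 4] <- 6L
  k <- k + t(k)
  d <- empirical_d_stats(k, 2, 2)
  expect_equal(d$dX, 2)
  expect_equal(d$dY, 4)
  expect_equal(d$dXY, 4.5)
  expect_equal(d$dnet, 1.5)
  # permuting labels within a population leaves the statistics unchanged
  perm <- c(2, 1, 4, 3)
  expect_equal(empirical_d_stats(k[perm, perm], 2, 2), d)
  # constant differences give zero net divergence
  kc <- matrix(7L, 4, 4); diag(kc) <- 0L
  expect_equal(empirical_d_stats(kc, 2, 2)$dnet, 0)
})

test_that("per-locus F_ST excludes dXY = 0 loci and reports the ratio of averages", {
  S <- scaled_two_pop(1)
  b <- simulate_gene_trees(S, c(X = 2, Y = 2), R = 400, seed = 3)
  b <- overlay_mutations(b, 0.05, seed = 4)      # low rate: some dXY = 0
  ef <- empirical_fst(b, 2, 2)
  expect_gt(ef$n_excluded, 0)
  expect_equal(sum(!is.na(ef$fstg)) + ef$n_excluded, b$R)
  expect_equal(ef$mean, mean(ef$fstg, na.rm = TRUE))
  d <- empirical_d_stats(b$k, 2, 2)
  expect_equal(ef$ratio_of_averages,
               (mean(d$dXY) - (mean(d$dX) + mean(d$dY)) / 2) / mean(d$dXY))
  # single locus arithmetic
  k <- matrix(0L, 4, 4)
  k[1, 2] <- 2L; k[3, 4] <- 4L
  k[1, 3] <- k[1, 4] <- k[2, 3] <- k[2, 4] <- 4.5
  k <- k + t(k)
  d1 <- empirical_d_stats(k, 2, 2)
  expect_equal(d1$dnet / d1$dXY, 1 / 3)
})

test_that("per-locus estimator mean matches the Taylor expectation in the high-rate regime", {
  S <- scaled_two_pop(20)
  mu <- 10 / 2                       # 2 mu eta = 10, D' = 20
  b <- simulate_gene_trees(S, c(X = 5, Y = 5), R = 1500, seed = 61)
  b <- overlay_mutations(b, mu, seed = 62)
  ef <- empirical_fst(b, 5, 5)
  expect_equal(ef$n_excluded, 0L)
  ex <- e_fstg_approx(diff_stat_moments(S, mu, 5, 5))
  expect_lt(abs(ef$mean - ex) / ef$se, 4)
})

test_that("the ratio of averages sidesteps the single-locus bias", {
  S <- scaled_two_pop(1)
  mu <- 1 / 2                        # 2 mu eta = 1, D' = 1
  b <- simulate_gene_trees(S, c(X = 10, Y = 10), R = 1500, seed = 71)
  b <- overlay_mutations(b, mu, seed = 72)
  ef <- empirical_fst(b, 10, 10)
  f <- fst_true(S, "X", "Y")
  expect_lt(abs(ef$ratio_of_averages - f), abs(ef$mean - f))
})

test_that("within-population pair times are exchangeable in distribution", {
  S <- scaled_two_pop(1, size_ratio = 2)
  b <- simulate_gene_trees(S, c(X = 3, Y = 3), R = 50000, seed = 29)
  ks <- suppressWarnings(
    stats::ks.test(b$pair_times[, "X_1:X_2"], b$pair_times[, "X_1:X_3"]))
  expect_gt(ks$p.value, 0.001)
})

test_that("gene trees export as valid newick with generation branch lengths", {
  S <- two_pop_tree(10, 1)
  b <- simulate_gene_trees(S, c(X = 2, Y = 2), R = 3, seed = 5)
  nwk <- batch_newick(b)
  expect_length(nwk, 3L)
  phy <- ape::read.tree(text = nwk[1L])
  expect_equal(sort(phy$tip.label), sort(b$labels))
  d <- ape::node.depth.edgelength(phy)
  root_time <- max(b$times[1L, ])
  expect_equal(max(d[seq_len(4)]), root_time, tolerance = 1e-6)
})
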