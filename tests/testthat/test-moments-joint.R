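# The exact joint-moment engine against independently derived constants,
# closed forms, and structural invariants.

test_that("panmictic joint moments match the staged-exponential oracles", {
  S <- panmictic_tree()
  cfg3 <- sample_config(c(a = "X", b = "X", c = "X"),
                        pairA = c("a", "b"), pairB = c("a", "c"))
  j3 <- joint_pair_moment(S, cfg3)
  expect_equal(j3$product_moment, oracle_prod_3lin(), tolerance = 1e-10)
  expect_equal(j3$covariance, oracle_prod_3lin() - 1, tolerance = 1e-10)
  expect_equal(j3$shared_branch_mean, oracle_shared_3lin(), tolerance = 1e-10)

  cfg4 <- sample_config(c(a = "X", b = "X", c = "X", d = "X"),
                        pairA = c("a", "b"), pairB = c("c", "d"))
  j4 <- joint_pair_moment(S, cfg4)
  expect_equal(j4$product_moment, oracle_prod_4lin(), tolerance = 1e-10)
  expect_equal(j4$covariance, oracle_prod_4lin() - 1, tolerance = 1e-10)
  expect_equal(j4$shared_branch_mean, oracle_shared_4lin(), tolerance = 1e-10)
  # the classic constants in (2 eta)^2 units
  expect_equal(j3$covariance, 1 / 3, tolerance = 1e-10)
  expect_equal(j4$covariance, 2 / 9, tolerance = 1e-10)
})

test_that("panmictic case probabilities match the enumeration oracle", {
  S <- panmictic_tree()
  cfg4 <- sample_config(c(a = "X", b = "X", c = "X", d = "X"),
                        pairA = c("a", "b"), pairB = c("c", "d"))
  pc <- case_probabilities(S, cfg4)
  expect_equal(pc, oracle_cases_4lin(), tolerance = 1e-12)
  expect_equal(sum(pc), 1, tolerance = 1e-12)
  expect_equal(unname(pc["C1"]), 1 / 6, tolerance = 1e-12)
  expect_equal(unname(pc["C3"]), 2 / 9, tolerance = 1e-12)
})

test_that("identical pairs reduce to the pair's second moment and full sharing", {
  set.seed(31)
  for (i in 1:4) {
    S <- random_species_tree(sample(2:4, 1L))
    pops <- sample(S$tips, 2L, replace = TRUE)
    cfg <- sample_config(c(u = pops[1L], v = pops[2L]),
                         pairA = c("u", "v"), pairB = c("u", "v"))
    j <- joint_pair_moment(S, cfg)
    pm <- pair_time_moments(S, pops[1L], pops[2L])
    expect_equal(j$product_moment, pm$second_moment,
                 tolerance = 1e-10)
    expect_equal(j$covariance, pm$variance, tolerance = 1e-10)
    expect_equal(j$shared_branch_mean, 2 * pm$mean, tolerance = 1e-10)
    expect_equal(unname(j$cases["C3"]), 1, tolerance = 1e-12)
  }
})

test_that("deep divergence decouples within-population pairs", {
  S <- two_pop_tree(D = 50, eta_x = 0.5)   # D = 50 in 2*eta units
  cfg <- sample_config(c(a = "X", b = "X", u = "Y", v = "Y"),
                       pairA = c("a", "b"), pairB = c("u", "v"))
  j <- joint_pair_moment(S, cfg)
  expect_lt(abs(j$covariance), 1e-6)
  expect_lt(j$shared_branch_mean, 1e-6)
})

test_that("covariances satisfy Cauchy-Schwarz and relabelling invariance on random scenarios", {
  set.seed(1203)
  for (i in 1:6) {
    S <- random_species_tree(sample(2:4, 1L))
    tips <- S$tips
    pops <- sample(tips, 4L, replace = TRUE)
    cfg <- sample_config(stats::setNames(pops, c("a", "b", "u", "v")),
                         pairA = c("a", "b"), pairB = c("u", "v"))
    j <- joint_pair_moment(S, cfg)
    expect_lte(abs(j$covariance),
               sqrt(j$var_A * j$var_B) * (1 + 1e-9) + 1e-12)
    expect_equal(sum(j$cases), 1, tolerance = 1e-10)
    expect_true(all(j$cases >= -1e-12))
    expect_gte(j$shared_branch_mean, -1e-12)
    expect_lte(j$shared_branch_mean,
               2 * min(j$mean_A, j$mean_B) * (1 + 1e-9))
    # swapping the order within each pair must not change anything
    cfg2 <- sample_config(stats::setNames(pops, c("a", "b", "u", "v")),
                          pairA = c("b", "a"), pairB = c("v", "u"))
    j2 <- joint_pair_moment(S, cfg2)
    expect_equal(j2$product_moment, j$product_moment, tolerance = 1e-12)
    expect_equal(j2$shared_branch_mean, j$shared_branch_mean,
                 tolerance = 1e-12)
  }
})

test_that("results are invariant under relabelling lineages within a population", {
  S <- scaled_two_pop(Dprime = 1.5, size_ratio = 2)
  cfg1 <- sample_config(c(i1 = "X", i2 = "X", j1 = "Y", j2 = "Y"),
                        pairA = c("i1", "j1"), pairB = c("i2", "j2"))
  cfg2 <- sample_config(c(i1 = "X", i2 = "X", j1 = "Y", j2 = "Y"),
                        pairA = c("i2", "j2"), pairB = c("i1", "j1"))
  j1 <- joint_pair_moment(S, cfg1)
  j2 <- joint_pair_moment(S, cfg2)
  expect_equal(j1$product_moment, j2$product_moment, tolerance = 1e-12)
  expect_equal(j1$shared_branch_mean, j2$shared_branch_mean,
               tolerance = 1e-12)
  # exchangeable-within-population pair choices give identical covariances
  cfg3 <- sample_config(c(i1 = "X", i3 = "X", j1 = "Y", j3 = "Y"),
                        pairA = c("i1", "j1"), pairB = c("i3", "j3"))
  expect_equal(joint_pair_moment(S, cfg3)$covariance, j1$covariance,
               tolerance = 1e-12)
})

test_that("three-lineage configurations arise from the four-lineage machinery by substitution", {
  S <- scaled_two_pop(Dprime = 0.8, size_ratio = 2)
  cfg <- sample_config(c(i = "X", ip = "X", j = "Y"),
                       pairA = c("i", "ip"), pairB = c("i", "j"))
  j <- joint_pair_moment(S, cfg)
  expect_equal(j$covariance,
               j$product_moment - j$mean_A * j$mean_B, tolerance = 1e-12)
  # only C1, C3, C5 are possible with two coalescent events
  expect_equal(unname(j$cases["C2"] + j$cases["C4"] + j$cases["C6"]), 0,
               tolerance = 1e-12)
  expect_equal(sum(j$cases), 1, tolerance = 1e-10)
})

test_that("within-pair moments are divergence-independent while cross pairs track D + 2 eta", {
  eta <- 0.5
  base <- pair_time_moments(two_pop_tree(2, eta), "X", "X")
  for (D in c(5, 20, 60)) {
    S <- two_pop_tree(D, eta)
    cross <- pair_time_moments(S, "X", "Y")
    expect_equal(cross$mean, D + 2 * eta, tolerance = 1e-12)
    within <- pair_time_moments(S, "X", "X")
    expect_equal(within$mean, base$mean, tolerance = 1e-12)
    expect_equal(within$variance, base$variance, tolerance = 1e-12)
  }
})
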