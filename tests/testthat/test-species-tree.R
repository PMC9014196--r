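test_that("two-tip construction yields three branches with unbounded root epoch", {
  S <- species_tree("(X:1000,Y:1000)XY;",
                    sizes = list(X = 500, Y = 500, XY = 500))
  expect_s3_class(S, "species_tree")
  expect_equal(nrow(S$branches), 3L)
  ep_root <- S$epochs[["XY"]]
  expect_true(is.infinite(ep_root$end[nrow(ep_root)]))
  expect_equal(divergence_time(S, "X", "Y"), 1000)
  expect_equal(divergence_time(S, "X", "X"), 0)
})

test_that("validation errors are distinct named conditions", {
  expect_error(species_tree("(X:1,Y:1,Z:1)R;", list(X = 1, Y = 1, Z = 1, R = 1)),
               class = "msccov_error_topology")
  expect_error(species_tree("(X:1,Y:2)XY;", list(X = 1, Y = 1, XY = 1)),
               class = "msccov_error_times")
  expect_error(species_tree("(X:1,Y:1)XY;", list(Y = 1, XY = 1)),
               class = "msccov_error_sizes")
  expect_error(species_tree("(X:1,Y:1)XY;",
                            list(X = cbind(0, -5), Y = 1, XY = 1)),
               class = "msccov_error_sizes")
  expect_error(species_tree("(X:1,Y:1)XY;",
                            list(X = cbind(0.5, 1), Y = 1, XY = 1)),
               class = "msccov_error_epochs")
  expect_error(divergence_time(two_pop_tree(1, 1), "X", "Z"),
               class = "msccov_error_pop")
  expect_error(marginal_profile(two_pop_tree(1, 1), character(0)),
               class = "msccov_error_pop")
})

test_that("divergence times follow the nested four-species topology", {
  S <- species_tree("(((A:1,B:1)AB:1,C:2)ABC:1,D:3)R;",
                    sizes = list(A = 1, B = 1, C = 1, D = 1,
                                 AB = 1, ABC = 1, R = 1))
  expect_equal(divergence_time(S, "A", "B"), 1)
  expect_equal(divergence_time(S, "A", "C"), 2)
  expect_equal(divergence_time(S, "B", "D"), 3)
  expect_equal(divergence_time(S, "A", "D"), S$branches["R", "start"])
})

test_that("marginal profiles tile the half-line and merge equal sizes", {
  S <- species_tree("(X:1000,Y:1000)XY;",
                    sizes = list(X = 500, Y = 700, XY = 500))
  pXY <- marginal_profile(S, c("X", "Y"))
  expect_equal(nrow(pXY), 1L)
  expect_equal(pXY$start, 1000)
  expect_true(is.infinite(pXY$end))
  # X and XY have equal size: merged into one interval from 0
  pX <- marginal_profile(S, "X")
  expect_equal(nrow(pX), 1L)
  expect_equal(pX$start, 0)
  # Y has its own size then the ancestral size
  pY <- marginal_profile(S, "Y")
  expect_equal(pY$size, c(700, 500))
  expect_equal(pY$start, c(0, 1000))
})

test_that("parse -> serialize -> parse is the identity on canonical form", {
  set.seed(421)
  for (i in 1:5) {
    S <- random_species_tree(sample(2:5, 1L))
    S2 <- parse_species_tree(serialize_species_tree(S))
    expect_equal(S2$branches, S$branches)
    expect_equal(S2$epochs, S$epochs)
    expect_identical(serialize_species_tree(S2), serialize_species_tree(S))
  }
})

test_that("zero-length epochs are dropped and equal neighbours merged", {
  S <- species_tree("(X:10,Y:10)XY;",
                    sizes = list(X = rbind(c(0, 5), c(4, 5), c(4, 7)),
                                 Y = 5, XY = 5))
  expect_equal(S$epochs[["X"]]$size, c(5, 7))
  expect_equal(S$epochs[["X"]]$start, c(0, 4))
})

test_that("profiles tile and divergence times are ultrametric on random trees", {
  set.seed(77)
  for (i in 1:8) {
    S <- random_species_tree(sample(2:5, 1L))
    tips <- S$tips
    for (p in tips) {
      pr <- marginal_profile(S, p)
      expect_equal(pr$start[1L], 0)
      expect_true(is.infinite(pr$end[nrow(pr)]))
      if (nrow(pr) > 1L) {
        expect_equal(pr$start[-1L], pr$end[-nrow(pr)])
        expect_true(all(diff(pr$start) > 0))
      }
    }
    if (length(tips) >= 3L) {
      tri <- sample(tips, 3L)
      dAB <- divergence_time(S, tri[1L], tri[2L])
      dBC <- divergence_time(S, tri[2L], tri[3L])
      dAC <- divergence_time(S, tri[1L], tri[3L])
      expect_lte(dAC, max(dAB, dBC) + 1e-9)
      expect_equal(dAB, divergence_time(S, tri[2L], tri[1L]))
    }
  }
})

test_that("scaled 2N_ref time units convert at parse time", {
  Sg <- species_tree("(X:2000,Y:2000)XY;",
                     sizes = list(X = 1000, Y = 2000, XY = 1000))
  Ss <- species_tree("(X:1,Y:1)XY;",
                     sizes = list(X = 1, Y = 2, XY = 1),
                     time_units = "2N_ref", N_ref = 1000)
  expect_equal(Ss$branches, Sg$branches)
  expect_equal(Ss$epochs, Sg$epochs)
})
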