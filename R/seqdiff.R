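# Moments of pairwise sequence differences under infinite sites.
#
# Conditional on a gene tree, the number of differences between two
# sequences is Poisson with mean 2*mu*t (mu per sequence per generation, so
# 2*mu*t mutations accumulate along the two branches of total length 2t).
# The k-layer moments follow from the laws of total variance/covariance:
#   Var(k)          = 2 mu E(t) + 4 mu^2 Var(t)
#   Cov(k_A, k_B)   = mu E(t_cap) + 4 mu^2 Cov(t_A, t_B)
# The averaged statistics dX, dY, dXY and the net divergence
# d = dXY - (dX + dY)/2 are assembled by bilinear expansion over the
# exchangeable classes of lineage pairs, which reproduces the classical
# sample-size coefficients and is automatically correct at n = 2 and n = 3.

#' Expected number of pairwise differences
#'
#' @param mu Mutation rate per sequence per generation.
#' @param pair A [pair_time_moments()].
#' @return `2 * mu * E(t)`.
#' @export
k_mean <- function(mu, pair) {
  stopifnot(mu >= 0)
  2 * mu * pair$mean
}

#' Variance and second moment of pairwise differences
#'
#' Applies the law of total variance to the Poisson mutation layer:
#' `Var(k) = 2 mu E(t) + 4 mu^2 Var(t)`, and
#' `E(k^2) = Var(k) + (2 mu E(t))^2 = 2 mu E(t) + 4 mu^2 E(t^2)`.
#'
#' @inheritParams k_mean
#' @return List with `variance` and `second_moment`.
#' @export
k_second_moments <- function(mu, pair) {
  stopifnot(mu >= 0)
  v <- 2 * mu * pair$mean + 4 * mu^2 * pair$variance
  list(variance = v, second_moment = v + (2 * mu * pair$mean)^2)
}

#' Covariance of two pairwise-difference counts
#'
#' `Cov(k_A, k_B) = mu * E(t_cap) + 4 mu^2 * Cov(t_A, t_B)`: conditional on
#' the gene tree the covariance is the mutation rate times the shared branch
#' length, and the unconditional law of total covariance adds the
#' coalescence-time covariance term.
#'
#' @param mu Mutation rate per sequence per generation.
#' @param shared_mean Expected shared branch length `E(t_cap)` (generations).
#' @param time_cov Covariance of the two coalescence times (generations^2).
#' @return Covariance of the two difference counts.
#' @export
k_cov <- function(mu, shared_mean, time_cov) {
  stopifnot(mu >= 0, shared_mean >= -1e-12)
  mu * shared_mean + 4 * mu^2 * time_cov
}

# k-layer covariance for one joint configuration.
k_cov_from_joint <- function(mu, jt) {
  k_cov(mu, jt$shared_branch_mean, jt$covariance)
}

#' Moments of the averaged difference statistics dX, dY, dXY and d
#'
#' Computes the exact means, variances and covariances of the average
#' pairwise differences within population X (`dX`, over `nX` sequences),
#' within Y (`dY`), between the populations (`dXY`), and of the net
#' divergence `d = dXY - (dX + dY)/2`, by combining the coalescence-time
#' moment engine over every required pair-of-pairs configuration (pairs
#' sharing 0, 1 or 2 lineages, within and across populations) with the
#' Poisson mutation layer.
#'
#' @param S A [species_tree()].
#' @param mu Mutation rate per sequence per generation.
#' @param nX,nY Sample sizes (sequences) from populations X and Y; the
#'   variance of `dX` requires `nX >= 2` (likewise `dY`).
#' @param popX,popY Tip population names (defaults `"X"`, `"Y"`).
#' @return An object of class `diff_stat_moments`: means `mean_dX`,
#'   `mean_dY`, `mean_dXY`, `mean_dnet`; variances `var_dX`, `var_dY`,
#'   `var_dXY`, `var_dnet`; covariances `cov_dX_dY`, `cov_dXY_dX`,
#'   `cov_dXY_dY`; plus the inputs.
#' @export
diff_stat_moments <- function(S, mu, nX, nY, popX = "X", popY = "Y") {
  stopifnot(mu >= 0)
  if (nX < 2L || nY < 2L)
    mcc_stop("within-population variances require nX >= 2 and nY >= 2",
             "msccov_error_config")
  check_tip(S, popX); check_tip(S, popY)

  jt <- function(pops, pairA, pairB)
    joint_pair_moment(S, sample_config(pops, pairA, pairB))

  pXX <- pair_time_moments(S, popX, popX)
  pYY <- pair_time_moments(S, popY, popY)
  pXY <- pair_time_moments(S, popX, popY)
  kXX <- k_second_moments(mu, pXX)
  kYY <- k_second_moments(mu, pYY)
  kXY <- k_second_moments(mu, pXY)

  # within-population variance: pairs sharing 1 and 0 lineages
  within_var <- function(pop, n, pm, kv) {
    c1 <- if (n >= 3L)
      k_cov_from_joint(mu, jt(stats::setNames(rep(pop, 3L), c("a", "b", "c")),
                              c("a", "b"), c("a", "c")))
    else 0
    c0 <- if (n >= 4L)
      k_cov_from_joint(mu, jt(stats::setNames(rep(pop, 4L), c("a", "b", "c", "d")),
                              c("a", "b"), c("c", "d")))
    else 0
    (2 / (n * (n - 1))) *
      (kv$variance + 2 * (n - 2) * c1 + (n - 2) * (n - 3) / 2 * c0)
  }
  var_dX <- within_var(popX, nX, pXX, kXX)
  var_dY <- within_var(popY, nY, pYY, kYY)

  # cross-population variance: shared X lineage, shared Y lineage, disjoint
  cXs <- k_cov_from_joint(mu, jt(c(a = popX, u = popY, v = popY),
                                 c("a", "u"), c("a", "v")))
  cYs <- k_cov_from_joint(mu, jt(c(a = popX, b = popX, u = popY),
                                 c("a", "u"), c("b", "u")))
  c00 <- k_cov_from_joint(mu, jt(c(a = popX, b = popX, u = popY, v = popY),
                                 c("a", "u"), c("b", "v")))
  var_dXY <- (1 / (nX * nY)) *
    (kXY$variance + (nY - 1) * cXs + (nX - 1) * cYs +
       (nX - 1) * (nY - 1) * c00)

  # Cov(dX, dY): one pair inside each population
  cov_dX_dY <- k_cov_from_joint(mu, jt(c(a = popX, b = popX, u = popY, v = popY),
                                       c("a", "b"), c("u", "v")))

  # Cov(dXY, dX): cross pair sharing / not sharing the X lineage
  cov_cross <- function(popW, nW, popO) {
    csh <- k_cov_from_joint(mu, jt(c(a = popW, b = popW, u = popO),
                                   c("a", "b"), c("a", "u")))
    cns <- if (nW >= 3L)
      k_cov_from_joint(mu, jt(c(a = popW, b = popW, cc = popW, u = popO),
                              c("a", "b"), c("cc", "u")))
    else 0
    (2 / nW) * csh + ((nW - 2) / nW) * cns
  }
  cov_dXY_dX <- cov_cross(popX, nX, popY)
  cov_dXY_dY <- cov_cross(popY, nY, popX)

  var_dnet <- var_dXY + 0.25 * (var_dX + var_dY) + 0.5 * cov_dX_dY -
    cov_dXY_dX - cov_dXY_dY

  mean_dX <- k_mean(mu, pXX)
  mean_dY <- k_mean(mu, pYY)
  mean_dXY <- k_mean(mu, pXY)

  structure(list(mean_dX = mean_dX, mean_dY = mean_dY, mean_dXY = mean_dXY,
                 mean_dnet = mean_dXY - (mean_dX + mean_dY) / 2,
                 var_dX = var_dX, var_dY = var_dY, var_dXY = var_dXY,
                 var_dnet = var_dnet,
                 cov_dX_dY = cov_dX_dY, cov_dXY_dX = cov_dXY_dX,
                 cov_dXY_dY = cov_dXY_dY,
                 mu = mu, nX = nX, nY = nY, popX = popX, popY = popY),
            class = "diff_stat_moments")
}

#' @export
print.diff_stat_moments <- function(x, ...) {
  cat(sprintf("diff-stat moments (mu = %g, nX = %d, nY = %d):\n",
              x$mu, x$nX, x$nY))
  cat(sprintf("  means:  dX %.6g  dY %.6g  dXY %.6g  dnet %.6g\n",
              x$mean_dX, x$mean_dY, x$mean_dXY, x$mean_dnet))
  cat(sprintf("  vars:   dX %.6g  dY %.6g  dXY %.6g  dnet %.6g\n",
              x$var_dX, x$var_dY, x$var_dXY, x$var_dnet))
  cat(sprintf("  covs:   (dX,dY) %.6g  (dXY,dX) %.6g  (dXY,dY) %.6g\n",
              x$cov_dX_dY, x$cov_dXY_dX, x$cov_dXY_dY))
  invisible(x)
}
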