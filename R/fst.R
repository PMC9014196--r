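# F_ST from coalescence times, and Taylor approximations for its
# sequence-based estimator.
#
# The coalescent F_ST of two populations is
#   F_ST = 1 - (E(t_within_X) + E(t_within_Y)) / (2 E(t_between)),
# a pure function of mean coalescence times (no mu, no sample sizes).  Its
# single-locus plug-in estimator F_ST^G = (dXY - (dX+dY)/2)/dXY is a ratio
# of correlated averages; its expectation, bias and variance are
# approximated by second-/first-order Taylor (delta-method) expansions in
# the exact moments of dX, dY, dXY.

#' Coalescent F_ST of two populations
#'
#' `1 - (E(t_XX) + E(t_YY)) / (2 E(t_XY))` from exact mean coalescence
#' times; independent of the mutation rate and of sample sizes.
#'
#' @param S A [species_tree()].
#' @param X,Y Distinct tip population names.
#' @return F_ST (dimensionless).
#' @export
fst_true <- function(S, X, Y) {
  check_tip(S, X); check_tip(S, Y)
  if (X == Y) mcc_stop("X and Y must differ", "msccov_error_pop")
  tw <- pair_time_moments(S, X, X)$mean + pair_time_moments(S, Y, Y)$mean
  tb <- pair_time_moments(S, X, Y)$mean
  1 - tw / (2 * tb)
}

fst_from_means <- function(stats) {
  1 - (stats$mean_dX + stats$mean_dY) / (2 * stats$mean_dXY)
}

check_dxy <- function(stats) {
  if (!inherits(stats, "diff_stat_moments"))
    mcc_stop("stats must be a diff_stat_moments object", "msccov_error_config")
  if (stats$mean_dXY <= 0)
    mcc_stop("E(dXY) = 0 (mu = 0?): F_ST^G statistics are undefined",
             "msccov_error_undefined")
}

#' Approximate expectation of the sequence-based F_ST estimator
#'
#' Second-order Taylor expansion of
#' `E(F_ST^G) = 1 - (1/2) E((dX + dY)/dXY)` around the means, using the
#' exact variances/covariances of the averaged difference statistics.
#' Reduces to [fst_true()] when all variance and covariance terms vanish.
#'
#' @param stats A [diff_stat_moments()].
#' @return Approximate `E(F_ST^G)` (dimensionless).
#' @export
e_fstg_approx <- function(stats) {
  check_dxy(stats)
  EA <- stats$mean_dX + stats$mean_dY
  EB <- stats$mean_dXY
  ratio <- EA / EB + EA * stats$var_dXY / EB^3 -
    (stats$cov_dXY_dX + stats$cov_dXY_dY) / EB^2
  1 - ratio / 2
}

#' Approximate bias of the sequence-based F_ST estimator
#'
#' The second-order bias expression
#' `E(F_ST^G) - F_ST ~ (1/(2 E(dXY)^2)) * (Cov(dX,dXY) + Cov(dY,dXY)
#'   - (E(dX)+E(dY))/E(dXY) * Var(dXY))`; algebraically identical to
#' `e_fstg_approx(stats) - fst_true`.
#'
#' @inheritParams e_fstg_approx
#' @return Approximate bias (typically negative).
#' @export
fstg_bias <- function(stats) {
  check_dxy(stats)
  EA <- stats$mean_dX + stats$mean_dY
  EB <- stats$mean_dXY
  (stats$cov_dXY_dX + stats$cov_dXY_dY - EA / EB * stats$var_dXY) / (2 * EB^2)
}

#' First-order approximation to the variance of the F_ST estimator
#'
#' Delta-method variance of `(1/2) (dX + dY)/dXY`.  The first-order
#' approximation is known to be poor for recent divergence times; the result
#' carries a `low_trust` attribute set to `TRUE` as a standing caveat.
#'
#' @inheritParams e_fstg_approx
#' @return Approximate `Var(F_ST^G)` with attribute `low_trust = TRUE`.
#' @export
var_fstg_approx <- function(stats) {
  check_dxy(stats)
  EA <- stats$mean_dX + stats$mean_dY
  EB <- stats$mean_dXY
  varA <- stats$var_dX + stats$var_dY + 2 * stats$cov_dX_dY
  covAB <- stats$cov_dXY_dX + stats$cov_dXY_dY
  v <- 0.25 * (varA / EB^2 + EA^2 * stats$var_dXY / EB^4 -
                 2 * EA * covAB / EB^3)
  structure(v, low_trust = TRUE)
}

#' Island-model gene-flow transform of F_ST
#'
#' `<Nm>_F = (1/F_ST - 1)/2`.
#'
#' @param fst A value in (0, 1).
#' @return The transform value.
#' @export
nm_transform <- function(fst) {
  if (any(fst <= 0 | fst >= 1))
    mcc_stop("nm_transform requires 0 < fst < 1", "msccov_error_undefined")
  (1 / fst - 1) / 2
}

#' Approximate expectation of the gene-flow transform under F_ST^G
#'
#' Second-order Taylor expansion of
#' `E(<Nm>_F) = (1/4) E((dX + dY) / (dXY - (dX + dY)/2))` using the exact
#' moments of the difference statistics (the denominator is the net
#' divergence d).
#'
#' @inheritParams e_fstg_approx
#' @return Approximate `E(<Nm>_F)`.
#' @export
e_nm_approx <- function(stats) {
  check_dxy(stats)
  EA <- stats$mean_dX + stats$mean_dY
  EB <- stats$mean_dnet
  if (EB <= 0)
    mcc_stop("E(dnet) <= 0 (F_ST = 0 regime): <Nm>_F is undefined",
             "msccov_error_undefined")
  varA <- stats$var_dX + stats$var_dY + 2 * stats$cov_dX_dY
  covAB <- stats$cov_dXY_dX + stats$cov_dXY_dY - varA / 2
  varB <- stats$var_dnet
  0.25 * (EA / EB + EA * varB / EB^3 - covAB / EB^2)
}

#' Approximate expectations of two F_ST linearizations
#'
#' For divergence-time linearization, two transforms of the estimator are in
#' common use: `-log(1 - F_ST^G)` and `F_ST^G / (1 - F_ST^G)`.  The first is
#' approximated to first order as `-log(1 - E(F_ST^G))`; the second via
#' `E(F_ST^G/(1-F_ST^G)) = 2 E(dXY/(dX+dY)) - 1` with a second-order Taylor
#' expansion of the ratio.
#'
#' @inheritParams e_fstg_approx
#' @return List with `log_linear` and `ratio_linear`.
#' @export
linearized_expectations <- function(stats) {
  check_dxy(stats)
  ef <- e_fstg_approx(stats)
  if (ef >= 1)
    mcc_stop("approximate E(F_ST^G) >= 1", "msccov_error_undefined")
  EA <- stats$mean_dX + stats$mean_dY
  EB <- stats$mean_dXY
  varA <- stats$var_dX + stats$var_dY + 2 * stats$cov_dX_dY
  covAB <- stats$cov_dXY_dX + stats$cov_dXY_dY
  e_ratio <- EB / EA - covAB / EA^2 + EB * varA / EA^3
  list(log_linear = -log1p(-ef), ratio_linear = 2 * e_ratio - 1)
}

#' Full F_ST report for a two-population scenario
#'
#' Assembles the exact coalescent F_ST, the Taylor approximations to the
#' expectation, bias and (low-trust) variance of the sequence-based
#' estimator, the gene-flow transform at the true and estimated F_ST, and
#' the two linearization expectations, for one species tree, mutation rate
#' and sample layout.
#'
#' @inheritParams diff_stat_moments
#' @return An object of class `fst_report` with fields `fst_true`, `e_fstg`,
#'   `bias`, `var_fstg` (attribute `low_trust`), `nm_true`, `e_nm`,
#'   `nm_percent_over` (percent overestimation of the transform),
#'   `log_linear`, `ratio_linear`, and the underlying `stats`.
#' @export
fst_report <- function(S, mu, nX, nY, popX = "X", popY = "Y") {
  stats <- diff_stat_moments(S, mu, nX, nY, popX, popY)
  ft <- fst_true(S, popX, popY)
  ef <- e_fstg_approx(stats)
  nm_true <- if (ft > 0 && ft < 1) nm_transform(ft) else NA_real_
  e_nm <- tryCatch(e_nm_approx(stats), msccov_error = function(e) NA_real_)
  lins <- linearized_expectations(stats)
  structure(list(fst_true = ft, e_fstg = ef, bias = ef - ft,
                 var_fstg = var_fstg_approx(stats),
                 nm_true = nm_true, e_nm = e_nm,
                 nm_percent_over = if (is.na(nm_true) || is.na(e_nm)) NA_real_
                                   else 100 * (e_nm - nm_true) / nm_true,
                 log_linear = lins$log_linear,
                 ratio_linear = lins$ratio_linear,
                 stats = stats),
            class = "fst_report")
}

#' @export
print.fst_report <- function(x, ...) {
  cat(sprintf("F_ST report (mu = %g, nX = %d, nY = %d):\n",
              x$stats$mu, x$stats$nX, x$stats$nY))
  cat(sprintf("  F_ST (true)        %.6g\n", x$fst_true))
  cat(sprintf("  E(F_ST^G) approx   %.6g   bias %.6g\n", x$e_fstg, x$bias))
  cat(sprintf("  Var(F_ST^G) approx %.6g   (first order; low trust at small D)\n",
              as.numeric(x$var_fstg)))
  if (!is.na(x$nm_true))
    cat(sprintf("  <Nm>_F true %.6g   E approx %.6g   (+%.3g%%)\n",
                x$nm_true, x$e_nm, x$nm_percent_over))
  cat(sprintf("  linearizations: -log(1-F) %.6g   F/(1-F) %.6g\n",
              x$log_linear, x$ratio_linear))
  invisible(x)
}

#' Bottleneck scenario trees
#'
#' Two-population trees with equal baseline diploid size `eta0` and
#' divergence `Dprime` in units of `2*eta0` generations, with a 10-fold
#' bottleneck placed per scenario: `"none"`; `"recent"` -- in X, starting at
#' time 0; `"postsplit"` -- in X, ending at the divergence; `"ancestral"` --
#' in the ancestral population, starting at the divergence.  Bottlenecks in
#' X last `min(1, Dprime) * 2 * eta0` generations (they must fit on the X
#' branch, so for `Dprime <= 1` the recent and post-split scenarios
#' coincide); the ancestral bottleneck lasts `2 * eta0` generations.
#'
#' @param Dprime Divergence time in units of `2*eta0` generations.
#' @param scenario One of `"none"`, `"recent"`, `"postsplit"`, `"ancestral"`.
#' @param eta0 Baseline diploid size.
#' @param factor Bottleneck severity (size divisor), default 10.
#' @return A `species_tree`.
#' @export
bottleneck_tree <- function(Dprime,
                            scenario = c("none", "recent", "postsplit",
                                         "ancestral"),
                            eta0 = 1e4, factor = 10) {
  scenario <- match.arg(scenario)
  D <- Dprime * 2 * eta0
  lenX <- min(1, Dprime) * 2 * eta0
  bn <- switch(scenario,
    none = NULL,
    recent = list(branch = "X", start = 0, duration = lenX, factor = factor),
    postsplit = list(branch = "X", start = D - lenX, duration = lenX,
                     factor = factor),
    ancestral = list(branch = "XY", start = 0, duration = 2 * eta0,
                     factor = factor))
  two_pop_tree(D, eta_x = eta0, bottleneck = bn)
}
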