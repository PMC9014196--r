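# Exact first and second moments of a single pairwise coalescence time.
#
# With the marginal size profile (tau_k, tau_{k+1}, eta_k) of the pair's
# shared ancestral path, the coalescence density within interval k is
# (1/2eta_k) exp(-(t - tau_k)/(2eta_k)) weighted by the probability P22 that
# the pair failed to coalesce in all earlier intervals.  The per-interval
# integrals of t and t^2 against that density have scalar closed forms; the
# final, unbounded interval uses their limits.  expm1() forms avoid
# cancellation when an interval is short relative to 2eta.

#' Probability that a pair of lineages fails to coalesce over a time span
#'
#' The "two-in, two-out" survival probability across the part of a marginal
#' profile between `from_time` and `to_time`: the product over intersected
#' intervals of `exp(-duration/(2*eta))`.
#'
#' @param profile A [marginal_profile()].
#' @param from_time,to_time Times in generations, `from_time <= to_time`.
#' @return A probability in (0, 1].
#' @export
survival_prob <- function(profile, from_time, to_time) {
  stopifnot(inherits(profile, "marginal_profile"))
  if (from_time > to_time)
    mcc_stop("from_time must not exceed to_time", "msccov_error_times")
  lo <- pmax(profile$start, from_time)
  hi <- pmin(profile$end, to_time)
  dur <- pmax(hi - lo, 0)
  exp(-sum(dur / (2 * profile$size)))
}

# Per-interval closed forms.  x = duration/(2 eta); for the unbounded final
# interval the exp terms vanish.
pair_interval_m1 <- function(tau, dur, eta) {
  if (is.infinite(dur)) return(tau + 2 * eta)
  x <- dur / (2 * eta)
  -(tau + 2 * eta) * expm1(-x) - dur * exp(-x)
}

pair_interval_m2 <- function(tau, dur, eta) {
  a <- tau^2 + 4 * tau * eta + 8 * eta^2
  if (is.infinite(dur)) return(a)
  x <- dur / (2 * eta)
  -a * expm1(-x) - dur * (2 * tau + dur + 4 * eta) * exp(-x)
}

#' Exact moments of the pairwise coalescence time for two populations
#'
#' Computes E(t), E(t^2) and Var(t) for the coalescence time of one lineage
#' from `popA` and one from `popB` (which may be the same population) by
#' closed-form integration over the marginal size profile -- a weighted sum
#' over coalescence intervals with survival weights.
#'
#' @param S A [species_tree()].
#' @param popA,popB Tip population names.
#' @return An object of class `pair_time_moments`: list with `mean`,
#'   `second_moment`, `variance` (generations, generations^2) and the
#'   divergence time `divergence`.
#' @export
pair_time_moments <- function(S, popA, popB) {
  prof <- marginal_profile(S, unique(c(popA, popB)))
  V <- nrow(prof)
  m1 <- 0; m2 <- 0; p22 <- 1
  for (k in seq_len(V)) {
    tau <- prof$start[k]
    dur <- prof$end[k] - tau
    eta <- prof$size[k]
    m1 <- m1 + p22 * pair_interval_m1(tau, dur, eta)
    m2 <- m2 + p22 * pair_interval_m2(tau, dur, eta)
    if (is.finite(dur)) p22 <- p22 * exp(-dur / (2 * eta))
  }
  structure(list(mean = m1, second_moment = m2,
                 variance = m2 - m1^2,
                 divergence = prof$start[1L]),
            class = "pair_time_moments")
}

#' @export
print.pair_time_moments <- function(x, ...) {
  cat(sprintf("pair coalescence time: mean %.6g  var %.6g  (E t^2 = %.6g)\n",
              x$mean, x$variance, x$second_moment))
  invisible(x)
}
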