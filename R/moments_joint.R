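# Joint moments of two pairwise coalescence times under the MSC.
#
# The engine tracks the labelled ancestral-lineage configuration of the 2-4
# sampled lineages through the species tree: the state is the set partition
# of the sampled lineages into ancestral lineages, and within every time
# segment on which all population sizes are constant (segments are delimited
# by species divergence times and epoch boundaries) the process is a
# continuous-time Markov chain whose merge rates are 1/(2*eta) for each pair
# of ancestral lineages currently residing in the same population.  Lineages
# in different populations cannot coalesce ("no gene flow"), which is the
# constraint that every coalescence is at least as old as the corresponding
# species divergence.
#
# All quantities are exact:
#  * E(t_A * t_B) = int int P(both pairs still uncoalesced ...) uses mean
#    residual absorption times propagated backwards through the segments and
#    forward sub-probability vectors, with every within-segment integral
#    evaluated as a Van Loan block matrix exponential and the unbounded root
#    epoch via phase-type inverses (-Q^{-1});
#  * E(t_cap), the expected shared branch length, integrates the expected
#    number of ancestral lineages subtending exactly one member of each pair;
#  * case probabilities C1..C6 come from an augmented chain recording at
#    which coalescent event each pair's MRCA occurred.

#' Sampling configuration for a pair of pairwise coalescence times
#'
#' @param pops Named character vector: names are lineage labels, values the
#'   tip populations they are sampled from.  2 to 4 lineages.
#' @param pairA,pairB Character vectors of two distinct lineage labels each;
#'   the two (possibly overlapping or identical) pairs whose coalescence
#'   times are studied.
#' @return An object of class `sample_config`.
#' @examples
#' cfg <- sample_config(c(i1 = "X", i2 = "X", j1 = "Y"),
#'                      pairA = c("i1", "i2"), pairB = c("i1", "j1"))
#' @export
sample_config <- function(pops, pairA, pairB) {
  labs <- names(pops)
  if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs)))
    mcc_stop("pops must be a named vector with unique lineage labels",
             "msccov_error_config")
  for (p in c(pairA, pairB)) {
    if (!p %in% labs)
      mcc_stop(sprintf("pair member '%s' is not a declared lineage", p),
               "msccov_error_config")
  }
  if (length(pairA) != 2L || length(pairB) != 2L ||
      pairA[1L] == pairA[2L] || pairB[1L] == pairB[2L])
    mcc_stop("each pair must consist of two distinct lineage labels",
             "msccov_error_config")
  used <- unique(c(pairA, pairB))
  if (!setequal(used, labs))
    mcc_stop("every declared lineage must appear in pairA or pairB",
             "msccov_error_config")
  if (length(labs) < 2L || length(labs) > 4L)
    mcc_stop("a sample configuration has 2, 3 or 4 lineages",
             "msccov_error_config")
  structure(list(pops = pops, pairA = pairA, pairB = pairB),
            class = "sample_config")
}

expm_d <- function(M) {
  if (nrow(M) == 1L) return(matrix(exp(M[1L, 1L]), 1L, 1L))
  as.matrix(Matrix::expm(Matrix::Matrix(M)))
}

# Van Loan integral int_0^L exp(A1 u) B exp(A2 (L - u)) du.
vanloan2 <- function(A1, B, A2, L) {
  n1 <- nrow(A1); n2 <- nrow(A2)
  H <- rbind(cbind(A1, B), cbind(matrix(0, n2, n1), A2))
  expm_d(H * L)[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
}

# Van Loan integral int_0^L exp(A1 u) B1 [ int_0^{L-u} exp(A2 v) b2 dv ] du
# (b2 a column vector); returns a column vector.
vanloan3 <- function(A1, B1, A2, b2, L) {
  n1 <- nrow(A1); n2 <- nrow(A2)
  H <- rbind(cbind(A1, B1, matrix(0, n1, 1L)),
             cbind(matrix(0, n2, n1), A2, matrix(b2, ncol = 1L)),
             matrix(0, 1L, n1 + n2 + 1L))
  expm_d(H * L)[seq_len(n1), n1 + n2 + 1L, drop = FALSE]
}

# int_0^L exp(Q u) du %*% v  for a column vector v.
int_expm_vec <- function(Q, v, L) {
  vanloan2(Q, diag(nrow(Q)), matrix(0, nrow(Q), nrow(Q)), L) %*% v
}

# Build the segmented partition chain for a species tree and configuration.
msc_chain <- function(S, cfg) {
  stopifnot(inherits(S, "species_tree"), inherits(cfg, "sample_config"))
  for (p in cfg$pops) check_tip(S, p)
  labs <- names(cfg$pops)
  n <- length(labs)
  iA <- match(cfg$pairA, labs)
  iB <- match(cfg$pairB, labs)
  ps <- partition_space(n)

  br <- S$branches
  ep <- do.call(rbind, S$epochs)
  bounds <- sort(unique(c(0, br$start, br$end[is.finite(br$end)],
                          ep$start, ep$end[is.finite(ep$end)])))
  bounds <- bounds[bounds >= 0]
  M <- length(bounds)
  seg_start <- bounds
  seg_end <- c(bounds[-1L], Inf)
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  M <- length(seg_start)

  # Host population and size of each block of each partition, per segment.
  # A block can only exist once all its members' populations share an
  # ancestor; before that its host is NA (the state is unreachable there).
  lin_pops <- unname(cfg$pops)
  Q <- vector("list", M)
  for (m in seq_len(M)) {
    tmid <- if (is.finite(seg_end[m])) (seg_start[m] + seg_end[m]) / 2
            else seg_start[m] + 1
    host <- vector("list", ps$P)
    eta <- vector("list", ps$P)
    for (s in seq_len(ps$P)) {
      bl <- ps$blocks[[s]]
      h <- character(length(bl)); e <- numeric(length(bl))
      for (b in seq_along(bl)) {
        pops_b <- unique(lin_pops[bl[[b]]])
        anc <- mrca_branch(S, pops_b)
        if (tmid < br[anc, "start"]) {
          h[b] <- NA_character_; e[b] <- NA_real_
        } else {
          h[b] <- branch_at_time(S, anc, tmid)
          e[b] <- epoch_size_at(S, h[b], tmid)
        }
      }
      host[[s]] <- h; eta[[s]] <- e
    }
    Qm <- matrix(0, ps$P, ps$P)
    for (s in seq_len(ps$P)) {
      mg <- ps$merges[[s]]
      if (nrow(mg) == 0L) next
      for (r in seq_len(nrow(mg))) {
        h1 <- host[[s]][mg[r, 1L]]; h2 <- host[[s]][mg[r, 2L]]
        if (is.na(h1) || is.na(h2) || h1 != h2) next
        rate <- 1 / (2 * eta[[s]][mg[r, 1L]])
        Qm[s, mg[r, 3L]] <- Qm[s, mg[r, 3L]] + rate
        Qm[s, s] <- Qm[s, s] - rate
      }
    }
    Q[[m]] <- Qm
  }

  Am <- vapply(seq_len(ps$P), function(s) pair_merged(ps, s, iA), logical(1))
  Bm <- vapply(seq_len(ps$P), function(s) pair_merged(ps, s, iB), logical(1))
  init <- ps$index[[rgs_key(seq_len(n))]]

  list(ps = ps, n = n, iA = iA, iB = iB, Am = Am, Bm = Bm, init = init,
       Q = Q, M = M, seg_start = seg_start, seg_end = seg_end,
       seg_len = seg_end - seg_start)
}

# E(t_A * t_B): forward sub-probability over both-unmerged states combined
# with backward mean-residual-time vectors for each pair.
joint_product_moment <- function(ch) {
  UAB <- which(!ch$Am & !ch$Bm)
  UA <- which(!ch$Am)
  UB <- which(!ch$Bm)
  RA <- matrix(0, length(UAB), length(UA))
  RA[cbind(seq_along(UAB), match(UAB, UA))] <- 1
  RB <- matrix(0, length(UAB), length(UB))
  RB[cbind(seq_along(UAB), match(UAB, UB))] <- 1

  QAB <- lapply(ch$Q, function(q) q[UAB, UAB, drop = FALSE])
  QA <- lapply(ch$Q, function(q) q[UA, UA, drop = FALSE])
  QB <- lapply(ch$Q, function(q) q[UB, UB, drop = FALSE])

  M <- ch$M
  onesA <- rep(1, length(UA)); onesB <- rep(1, length(UB))
  # backward pass: mean residual time to each pair's coalescence
  mA <- vector("list", M); mB <- vector("list", M)
  mA[[M]] <- solve(-QA[[M]], onesA)
  mB[[M]] <- solve(-QB[[M]], onesB)
  if (M > 1L) {
    for (r in (M - 1L):1L) {
      L <- ch$seg_len[r]
      mA[[r]] <- int_expm_vec(QA[[r]], onesA, L) +
        expm_d(QA[[r]] * L) %*% mA[[r + 1L]]
      mB[[r]] <- int_expm_vec(QB[[r]], onesB, L) +
        expm_d(QB[[r]] * L) %*% mB[[r + 1L]]
    }
  }
  # forward pass
  p <- matrix(0, 1L, length(UAB))
  p[1L, match(ch$init, UAB)] <- 1
  acc <- 0
  if (M > 1L) {
    for (r in seq_len(M - 1L)) {
      L <- ch$seg_len[r]
      vB <- vanloan3(QAB[[r]], RB, QB[[r]], onesB, L) +
        vanloan2(QAB[[r]], RB, QB[[r]], L) %*% mB[[r + 1L]]
      vA <- vanloan3(QAB[[r]], RA, QA[[r]], onesA, L) +
        vanloan2(QAB[[r]], RA, QA[[r]], L) %*% mA[[r + 1L]]
      acc <- acc + as.numeric(p %*% (vA + vB))
      p <- p %*% expm_d(QAB[[r]] * L)
    }
  }
  vB <- solve(-QAB[[M]], RB %*% mB[[M]])
  vA <- solve(-QAB[[M]], RA %*% mA[[M]])
  acc + as.numeric(p %*% (vA + vB))
}

# E(t_cap): integral over time of the expected number of ancestral lineages
# subtending exactly one member of pairA and exactly one member of pairB.
joint_shared_branch <- function(ch) {
  ps <- ch$ps
  nvec <- vapply(seq_len(ps$P), function(s) {
    sum(vapply(ps$blocks[[s]], function(b) {
      length(intersect(b, ch$iA)) == 1L && length(intersect(b, ch$iB)) == 1L
    }, logical(1)))
  }, numeric(1))
  p <- matrix(0, 1L, ps$P); p[1L, ch$init] <- 1
  acc <- 0
  M <- ch$M
  if (M > 1L) {
    for (r in seq_len(M - 1L)) {
      L <- ch$seg_len[r]
      acc <- acc + as.numeric(p %*% int_expm_vec(ch$Q[[r]], nvec, L))
      p <- p %*% expm_d(ch$Q[[r]] * L)
    }
  }
  trans <- which(ps$n_blocks >= 2L)
  QTT <- ch$Q[[M]][trans, trans, drop = FALSE]
  acc + as.numeric(p[, trans, drop = FALSE] %*% solve(-QTT, nvec[trans]))
}

# Probabilities of the six orderings of the two pairs' MRCA events.
joint_case_probs <- function(ch) {
  ps <- ch$ps; n <- ch$n
  Am <- ch$Am; Bm <- ch$Bm
  nb <- ps$n_blocks
  # augmented states
  st <- list()
  add <- function(cls, part, e) {
    st[[length(st) + 1L]] <<- list(cls = cls, part = part, e = e)
  }
  for (s in seq_len(ps$P)) {
    if (!Am[s] && !Bm[s]) add("N", s, 0L)
    else if (Am[s] && !Bm[s]) for (e in seq_len(n - nb[s])) add("A", s, e)
    else if (!Am[s] && Bm[s]) for (e in seq_len(n - nb[s])) add("B", s, e)
  }
  KT <- length(st)
  key <- vapply(st, function(x) paste(x$cls, x$part, x$e), character(1))
  idx <- structure(seq_len(KT), names = key)
  K <- KT + 6L  # C1..C6 appended
  cases <- paste0("C", 1:6)
  class_of <- function(first, eFirst, eSecond) {
    if (first == "A") { if (eFirst == 1L) "C1" else "C2" }
    else {
      if (eFirst == 1L) { if (eSecond == eFirst + 1L) "C5" else "C6" }
      else "C4"
    }
  }
  Qa <- vector("list", ch$M)
  for (m in seq_len(ch$M)) {
    Qm <- ch$Q[[m]]
    A <- matrix(0, K, K)
    for (k in seq_len(KT)) {
      s <- st[[k]]$part
      # off-diagonal rates of the partition generator, target by target
      for (t in which(Qm[s, ] > 0)) {
        rate <- Qm[s, t]
        dest <- if (st[[k]]$cls == "N") {
          if (!Am[t] && !Bm[t]) idx[[paste("N", t, 0L)]]
          else if (Am[t] && !Bm[t]) idx[[paste("A", t, n - nb[t])]]
          else if (!Am[t] && Bm[t]) idx[[paste("B", t, n - nb[t])]]
          else KT + 3L                               # simultaneous -> C3
        } else if (st[[k]]$cls == "A") {
          if (!Bm[t]) idx[[paste("A", t, st[[k]]$e)]]
          else KT + match(class_of("A", st[[k]]$e, n - nb[t]), cases)
        } else {
          if (!Am[t]) idx[[paste("B", t, st[[k]]$e)]]
          else KT + match(class_of("B", st[[k]]$e, n - nb[t]), cases)
        }
        A[k, dest] <- A[k, dest] + rate
        A[k, k] <- A[k, k] - rate
      }
    }
    Qa[[m]] <- A
  }
  p <- matrix(0, 1L, K)
  p[1L, idx[[paste("N", ch$init, 0L)]]] <- 1
  if (ch$M > 1L) {
    for (r in seq_len(ch$M - 1L)) {
      p <- p %*% expm_d(Qa[[r]] * ch$seg_len[r])
    }
  }
  Tix <- seq_len(KT); Cix <- KT + 1:6
  QTT <- Qa[[ch$M]][Tix, Tix, drop = FALSE]
  QTC <- Qa[[ch$M]][Tix, Cix, drop = FALSE]
  pc <- as.numeric(p[, Cix]) +
    as.numeric(p[, Tix, drop = FALSE] %*% solve(-QTT, QTC))
  stats::setNames(pc, cases)
}

#' Exact joint moment and covariance of two pairwise coalescence times
#'
#' For two (possibly overlapping or identical) pairs of sampled lineages on
#' a species tree, computes the exact product moment `E(t_A * t_B)`, the
#' covariance, the probabilities of the six coalescent-event orderings
#' C1..C6, and the expected shared branch length `E(t_cap)` -- the expected
#' total length of gene-tree edges lying on both pairs' connecting paths.
#'
#' @param S A [species_tree()].
#' @param cfg A [sample_config()].
#' @return An object of class `joint_time_result`: list with
#'   `product_moment`, `covariance` (generations^2), `cases` (named C1..C6
#'   probabilities), `shared_branch_mean` (generations), and the marginal
#'   `mean_A`, `mean_B`, `var_A`, `var_B`.
#' @export
joint_pair_moment <- function(S, cfg) {
  ch <- msc_chain(S, cfg)
  pmA <- pair_time_moments(S, cfg$pops[[cfg$pairA[1L]]],
                           cfg$pops[[cfg$pairA[2L]]])
  pmB <- pair_time_moments(S, cfg$pops[[cfg$pairB[1L]]],
                           cfg$pops[[cfg$pairB[2L]]])
  prod <- joint_product_moment(ch)
  shared <- joint_shared_branch(ch)
  cases <- joint_case_probs(ch)
  structure(list(product_moment = prod,
                 covariance = prod - pmA$mean * pmB$mean,
                 cases = cases,
                 shared_branch_mean = shared,
                 mean_A = pmA$mean, mean_B = pmB$mean,
                 var_A = pmA$variance, var_B = pmB$variance),
            class = "joint_time_result")
}

#' @export
print.joint_time_result <- function(x, ...) {
  cat(sprintf("joint coalescence-time result:\n  E(tA tB) = %.6g   Cov = %.6g   E(t_cap) = %.6g\n",
              x$product_moment, x$covariance, x$shared_branch_mean))
  cat("  case probabilities:",
      paste(sprintf("%s=%.4g", names(x$cases), x$cases), collapse = " "), "\n")
  invisible(x)
}

#' Probabilities of the six coalescent-event orderings
#'
#' @inheritParams joint_pair_moment
#' @return Named numeric vector `C1..C6` summing to 1: C1 -- pair A's MRCA is
#'   the first coalescent event; C2 -- second with pair B's third; C3 -- both
#'   MRCAs at the same (final) event; C4 -- pair B's second, pair A's third;
#'   C5 -- pair B's first, pair A's second; C6 -- pair B's first, pair A's
#'   third.
#' @export
case_probabilities <- function(S, cfg) {
  joint_case_probs(msc_chain(S, cfg))
}

#' Expected shared branch length of two pairs of lineages
#'
#' `E(t_cap)`: the expected total length of gene-tree branches that lie on
#' both the path connecting pair A and the path connecting pair B, i.e. the
#' time integral of the number of ancestral lineages subtending exactly one
#' member of each pair.  For identical pairs this is `2 * E(t_A)`.
#'
#' @inheritParams joint_pair_moment
#' @return Expected shared branch length in generations.
#' @export
expected_shared_branch <- function(S, cfg) {
  joint_shared_branch(msc_chain(S, cfg))
}
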