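# Monte Carlo oracle: gene trees under the MSC, infinite-sites mutation
# overlay, and empirical difference / F_ST statistics.

# Flatten a species tree into the segment structure the C++ core consumes.
flatten_species_tree <- function(S) {
  br <- S$branches
  nbr <- nrow(br)
  ep <- do.call(rbind, S$epochs)
  bounds <- sort(unique(c(0, br$start, br$end[is.finite(br$end)],
                          ep$start, ep$end[is.finite(ep$end)])))
  bounds <- bounds[bounds >= 0]
  nseg <- length(bounds)
  eta <- matrix(-1, nbr, nseg)
  for (i in seq_len(nbr)) {
    epi <- S$epochs[[br$name[i]]]
    if (nrow(epi) == 0L) next
    for (m in seq_len(nseg)) {
      tmid <- if (m < nseg) (bounds[m] + bounds[m + 1L]) / 2 else bounds[m] + 1
      k <- which(epi$start <= tmid & tmid < epi$end)
      if (length(k) == 1L) eta[i, m] <- epi$size[k]
    }
  }
  list(parent = match(br$parent, br$name) - 1L,
       seg_start = bounds, eta = eta, names = br$name)
}

#' Simulate labelled gene trees under the multi-species coalescent
#'
#' Draws `R` independent gene trees for the given per-population sample
#' counts: within each branch epoch, waiting times between coalescences of
#' the `m` resident lineages are exponential with rate `choose(m,2)/(2*eta)`,
#' truncated at epoch and divergence boundaries; surviving lineages enter
#' the parent population, and the root population runs to completion.
#' Fully reproducible given `seed`.
#'
#' @param S A [species_tree()].
#' @param samples Named integer vector: sequences sampled per tip population
#'   (e.g. `c(X = 3, Y = 3)`).
#' @param R Number of replicate gene trees.
#' @param seed Integer seed.
#' @return An object of class `gene_tree_batch`: `parent` and `times` are
#'   `R x (2n-1)` matrices encoding each gene tree (nodes `1..n` are tips in
#'   the order of `labels`, `parent` is 1-based with `NA` at the root);
#'   `pair_times` is `R x choose(n,2)` with columns following
#'   `utils::combn(n, 2)` over `labels`.
#' @export
simulate_gene_trees <- function(S, samples, R, seed) {
  stopifnot(inherits(S, "species_tree"), R >= 1)
  if (is.null(names(samples)) || any(samples < 0) || sum(samples) < 2)
    mcc_stop("samples must be a named vector with at least two sequences",
             "msccov_error_config")
  for (p in names(samples)) check_tip(S, p)
  if (all(samples == 0))
    mcc_stop("at least one population must be sampled", "msccov_error_config")
  fl <- flatten_species_tree(S)
  pops <- rep(names(samples), samples)
  labels <- unlist(lapply(names(samples), function(p)
    paste0(p, "_", seq_len(samples[[p]]))), use.names = FALSE)
  lin_branch <- match(pops, fl$names) - 1L
  set.seed(seed)
  res <- sim_msc_cpp(lin_branch, fl$parent, fl$seg_start, fl$eta, as.integer(R))
  n <- length(labels)
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  pair_names <- apply(utils::combn(n, 2L), 2L,
                      function(ij) paste(labels[ij], collapse = ":"))
  colnames(res$pair_times) <- pair_names
  structure(list(parent = parent, times = res$times,
                 pair_times = res$pair_times,
                 labels = labels, pops = pops, n = n, R = R, seed = seed,
                 k = NULL, mu = NULL),
            class = "gene_tree_batch")
}

#' @export
print.gene_tree_batch <- function(x, ...) {
  cat(sprintf("gene_tree_batch: %d replicates, %d lineages (%s)%s\n",
              x$R, x$n, paste(unique(x$pops), collapse = ", "),
              if (!is.null(x$k)) sprintf("; mutations overlaid (mu = %g)", x$mu)
              else ""))
  invisible(x)
}

# Logical (2n-1) x n matrix: does gene-tree node v subtend tip i?
node_tip_matrix <- function(parent_row, n) {
  nnode <- length(parent_row)
  M <- matrix(FALSE, nnode, n)
  M[cbind(seq_len(n), seq_len(n))] <- TRUE
  # nodes are created in time order, so a simple ascending pass suffices
  for (v in seq_len(nnode)) {
    p <- parent_row[v]
    if (!is.na(p)) M[p, ] <- M[p, ] | M[v, ]
  }
  M
}

#' Overlay infinite-sites mutations on a batch of gene trees
#'
#' Draws Poisson(`mu` x branch length) mutation counts per gene-tree branch
#' and accumulates pairwise difference counts `k[i,j]` as path sums, so that
#' marginally `k[i,j] | t[i,j] ~ Poisson(2 * mu * t[i,j])` while preserving
#' the shared-branch correlation structure across pairs.
#'
#' @param batch A [simulate_gene_trees()] result.
#' @param mu Mutation rate per sequence per generation.
#' @param seed Integer seed for the mutation layer.
#' @return The batch with elements `k` (`R x choose(n,2)` integer matrix of
#'   pairwise differences) and `mu` filled in.
#' @export
overlay_mutations <- function(batch, mu, seed) {
  stopifnot(inherits(batch, "gene_tree_batch"), mu >= 0)
  set.seed(seed)
  n <- batch$n; R <- batch$R
  nnode <- 2L * n - 1L
  # branch length above each non-root node
  plen <- matrix(0, R, nnode)
  for (v in seq_len(nnode)) {
    p <- batch$parent[, v]
    ok <- !is.na(p)
    plen[ok, v] <- batch$times[cbind(which(ok), p[ok])] -
      batch$times[ok, v]
  }
  muts <- matrix(stats::rpois(R * nnode, mu * plen), R, nnode)
  cmb <- utils::combn(n, 2L)
  k <- matrix(0L, R, ncol(cmb))
  for (r in seq_len(R)) {
    M <- node_tip_matrix(batch$parent[r, ], n)
    w <- muts[r, ]
    a <- colSums(w * M)                     # mutations on edges subtending tip i
    cross <- crossprod(M, w * M)            # joint subtending counts
    K <- outer(a, a, "+") - 2 * cross
    k[r, ] <- as.integer(K[cbind(cmb[1L, ], cmb[2L, ])])
  }
  colnames(k) <- colnames(batch$pair_times)
  batch$k <- k
  batch$mu <- mu
  batch
}

#' Shared branch length between two pairs on one gene tree
#'
#' Sums, over tree edges, edge length times the indicator that the edge's
#' descendant tip set contains exactly one member of `pairA` and exactly one
#' member of `pairB`.
#'
#' @param tree A list with `parent` (1-based, `NA` at root) and `times`
#'   vectors for one gene tree, or a `gene_tree_batch` with `rep` selecting
#'   the replicate.
#' @param pairA,pairB Tip labels (length 2 each) or tip indices.
#' @param rep Replicate index when `tree` is a batch.
#' @return Shared branch length in generations.
#' @export
shared_branch_on_tree <- function(tree, pairA, pairB, rep = 1L) {
  if (inherits(tree, "gene_tree_batch")) {
    labels <- tree$labels
    tree <- list(parent = tree$parent[rep, ], times = tree$times[rep, ])
  } else labels <- NULL
  n <- (length(tree$parent) + 1L) / 2L
  ix <- function(p) {
    if (is.character(p)) {
      if (is.null(labels)) mcc_stop("tip labels unavailable", "msccov_error_config")
      i <- match(p, labels)
    } else i <- as.integer(p)
    if (anyNA(i) || any(i < 1L | i > n))
      mcc_stop("unknown tip label", "msccov_error_pop")
    i
  }
  iA <- ix(pairA); iB <- ix(pairB)
  M <- node_tip_matrix(tree$parent, n)
  tot <- 0
  for (v in seq_along(tree$parent)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    if (sum(M[v, iA]) == 1L && sum(M[v, iB]) == 1L)
      tot <- tot + tree$times[p] - tree$times[v]
  }
  tot
}

#' Empirical average pairwise-difference statistics for one or many loci
#'
#' Computes `dX`, `dY`, `dXY` and the net divergence `dnet` from a pairwise
#' difference matrix (or a batch's rows of pairwise counts).
#'
#' @param k Either a symmetric per-locus difference matrix over the
#'   `nX + nY` sequences (X first), or an `R x choose(n,2)` matrix of
#'   pairwise counts in `utils::combn` column order (as stored in a batch).
#' @param nX,nY Sample sizes; `dX` requires `nX >= 2` (likewise `dY`).
#' @return A data frame with columns `dX`, `dY`, `dXY`, `dnet` (one row per
#'   locus).
#' @export
empirical_d_stats <- function(k, nX, nY) {
  n <- nX + nY
  if (is.matrix(k) && nrow(k) == n && ncol(k) == n) {
    k <- matrix(k[cbind(utils::combn(n, 2L)[1L, ], utils::combn(n, 2L)[2L, ])],
                nrow = 1L)
  }
  if (ncol(k) != n * (n - 1L) / 2L)
    mcc_stop("k has the wrong number of pair columns for nX + nY sequences",
             "msccov_error_config")
  if (nX < 2L || nY < 2L)
    mcc_stop("dX and dY require nX >= 2 and nY >= 2", "msccov_error_config")
  cmb <- utils::combn(n, 2L)
  inX <- cmb <= nX
  wX <- which(inX[1L, ] & inX[2L, ])
  wY <- which(!inX[1L, ] & !inX[2L, ])
  wXY <- which(xor(inX[1L, ], inX[2L, ]))
  dX <- rowMeans(k[, wX, drop = FALSE])
  dY <- rowMeans(k[, wY, drop = FALSE])
  dXY <- rowMeans(k[, wXY, drop = FALSE])
  data.frame(dX = dX, dY = dY, dXY = dXY, dnet = dXY - (dX + dY) / 2)
}

#' Empirical per-locus F_ST estimates from a mutated batch
#'
#' Computes the single-locus estimator `F_ST^G = dnet/dXY` for every locus,
#' its mean and standard error over loci with `dXY > 0` (loci with
#' `dXY == 0` are excluded and counted), and the multi-locus
#' ratio-of-averages estimate `(mean dXY - (mean dX + mean dY)/2)/mean dXY`
#' over all loci.
#'
#' @param batch A batch with mutations overlaid ([overlay_mutations()]).
#' @param nX,nY Sample sizes per population (X sequences first in the batch
#'   layout).
#' @return List with `fstg` (per-locus values, `NA` where `dXY = 0`),
#'   `mean`, `se`, `n_excluded`, and `ratio_of_averages`.
#' @export
empirical_fst <- function(batch, nX, nY) {
  stopifnot(inherits(batch, "gene_tree_batch"))
  if (is.null(batch$k))
    mcc_stop("overlay mutations before computing empirical F_ST",
             "msccov_error_config")
  d <- empirical_d_stats(batch$k, nX, nY)
  ok <- d$dXY > 0
  if (!any(ok))
    mcc_stop("all loci have dXY = 0; F_ST^G undefined everywhere",
             "msccov_error_undefined")
  fstg <- ifelse(ok, d$dnet / d$dXY, NA_real_)
  v <- fstg[ok]
  list(fstg = fstg,
       mean = mean(v),
       se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
       n_excluded = sum(!ok),
       ratio_of_averages =
         (mean(d$dXY) - (mean(d$dX) + mean(d$dY)) / 2) / mean(d$dXY))
}

#' Export simulated gene trees in newick format
#'
#' @param batch A [simulate_gene_trees()] result.
#' @param reps Replicate indices to export.
#' @return Character vector of newick strings with branch lengths in
#'   generations.
#' @export
batch_newick <- function(batch, reps = seq_len(min(batch$R, 10L))) {
  vapply(reps, function(r) {
    parent <- batch$parent[r, ]
    tms <- batch$times[r, ]
    n <- batch$n
    lab <- c(batch$labels, paste0("n", seq_len(n - 1L)))
    build <- function(v) {
      kids <- which(parent == v)
      if (length(kids) == 0L) return(lab[v])
      sub <- vapply(kids, function(u)
        sprintf("%s:%.8g", build(u), tms[v] - tms[u]), character(1))
      sprintf("(%s)", paste(sub, collapse = ","))
    }
    paste0(build(which(is.na(parent))), ";")
  }, character(1))
}
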