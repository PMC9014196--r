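# Species trees with piecewise-constant demography.
#
# A species tree is a rooted, strictly bifurcating tree whose tips sit at
# time 0, with time measured in generations and increasing into the past.
# Every node (tip or internal, including the root) names the branch that
# connects it to its parent; the root branch extends to +Inf.  Each branch
# carries an ordered list of epochs (start, end, size): half-open intervals
# [start, end) with constant diploid population size eta, tiling the branch
# exactly.  A pair of lineages in a population of size eta coalesces at rate
# 1/(2*eta) per generation.

mcc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "msccov_error", "error")))
}

#' Construct a species tree with piecewise-constant population sizes
#'
#' @param newick Newick string for the topology.  All tips and internal nodes
#'   (including the root) must carry unique names; branch lengths are
#'   durations in generations (or in units of `2 * N_ref` generations when
#'   `time_units = "2N_ref"`).  Tips must be contemporaneous (ultrametric
#'   tree); they are placed at time 0, with time increasing into the past.
#' @param sizes Named list mapping each branch name to its population size
#'   history: either a single positive number (one epoch spanning the whole
#'   branch) or a two-column matrix / data frame with columns `offset` and
#'   `size`, where offsets are measured from the branch's start (its child
#'   node, i.e. the more recent end) and the first offset must be 0.  The
#'   root branch's final epoch extends to +Inf.  Branches of zero length
#'   (possible when a divergence time is 0) need no entry.
#' @param time_units Either `"generations"` (default) or `"2N_ref"`.  In the
#'   latter case branch lengths and epoch offsets are multiplied by
#'   `2 * N_ref` and sizes by `N_ref` at parse time, so that the tree can be
#'   written in the conventional scaled units (divergence `D' = D/(2*eta)`,
#'   sizes as multiples of a reference size).
#' @param N_ref Reference diploid size, required iff `time_units = "2N_ref"`.
#' @return An object of class `species_tree`.
#' @examples
#' S <- species_tree("(X:1000,Y:1000)XY;",
#'                   sizes = list(X = 500, Y = 500, XY = 500))
#' divergence_time(S, "X", "Y")
#' @export
species_tree <- function(newick, sizes, time_units = c("generations", "2N_ref"),
                         N_ref = NULL) {
  time_units <- match.arg(time_units)
  if (time_units == "2N_ref") {
    if (is.null(N_ref) || !is.numeric(N_ref) || N_ref <= 0)
      mcc_stop("N_ref must be a positive number when time_units = '2N_ref'",
               "msccov_error_config")
    tscale <- 2 * N_ref
    escale <- N_ref
  } else {
    tscale <- 1
    escale <- 1
  }

  phy <- tryCatch(ape::read.tree(text = newick),
                  error = function(e) NULL)
  if (is.null(phy))
    mcc_stop("could not parse newick topology", "msccov_error_topology")
  ntip <- length(phy$tip.label)
  if (ntip < 2L)
    mcc_stop("species tree needs at least two tips", "msccov_error_topology")
  # strictly bifurcating: every internal node has exactly two children
  kids <- tabulate(phy$edge[, 1L], nbins = ntip + phy$Nnode)
  if (any(kids[(ntip + 1L):(ntip + phy$Nnode)] != 2L))
    mcc_stop("species tree must be strictly bifurcating (no polytomies)",
             "msccov_error_topology")
  if (is.null(phy$edge.length))
    mcc_stop("newick must carry branch lengths (durations)",
             "msccov_error_times")
  if (any(phy$edge.length < 0))
    mcc_stop("negative branch lengths are not allowed", "msccov_error_times")
  if (is.null(phy$node.label) || any(!nzchar(phy$node.label)))
    mcc_stop("all internal nodes (including the root) must be named",
             "msccov_error_topology")
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels))
    mcc_stop("tip and internal node names must be unique",
             "msccov_error_topology")

  phy$edge.length <- phy$edge.length * tscale
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  depth <- numeric(nnode)    # distance from root, root-first traversal
  parent <- rep(NA_integer_, nnode)
  ord <- rev(ape::postorder(phy))
  for (e in ord) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    depth[b] <- depth[a] + phy$edge.length[e]
    parent[b] <- a
  }
  td <- depth[seq_len(ntip)]
  span <- max(td)
  tol <- 1e-8 * max(span, 1)
  if (max(td) - min(td) > tol)
    mcc_stop("tips are not contemporaneous (tree is not ultrametric)",
             "msccov_error_times")
  tm <- span - depth            # node time, tips at ~0
  tm[seq_len(ntip)] <- 0
  tm[abs(tm) < tol] <- 0

  br_name <- labels
  br_parent <- ifelse(is.na(parent), NA_character_, labels[parent])
  br_start <- tm
  br_end <- ifelse(is.na(parent), Inf, tm[parent])
  if (any(br_end < br_start - tol))
    mcc_stop("node times must not decrease towards the root",
             "msccov_error_times")
  branches <- data.frame(name = br_name, parent = br_parent,
                         start = br_start, end = br_end,
                         is_tip = seq_len(nnode) <= ntip,
                         stringsAsFactors = FALSE)
  rownames(branches) <- branches$name

  if (!is.list(sizes))
    mcc_stop("sizes must be a named list keyed by branch name",
             "msccov_error_sizes")
  epochs <- stats::setNames(vector("list", nnode), br_name)
  for (i in seq_len(nnode)) {
    nm <- br_name[i]
    dur <- br_end[i] - br_start[i]
    if (dur <= 0) {                     # zero-length branch: no epochs
      epochs[[nm]] <- data.frame(start = numeric(0), end = numeric(0),
                                 size = numeric(0))
      next
    }
    sz <- sizes[[nm]]
    if (is.null(sz))
      mcc_stop(sprintf("missing population size for branch '%s'", nm),
               "msccov_error_sizes")
    if (is.numeric(sz) && is.null(dim(sz)) && length(sz) == 1L)
      sz <- cbind(offset = 0, size = sz)
    sz <- as.matrix(sz)
    if (ncol(sz) != 2L)
      mcc_stop(sprintf("size table for branch '%s' must have two columns (offset, size)", nm),
               "msccov_error_sizes")
    off <- sz[, 1L] * tscale
    eta <- sz[, 2L] * escale
    o <- order(off)
    off <- off[o]; eta <- eta[o]
    if (any(!is.finite(eta)) || any(eta <= 0))
      mcc_stop(sprintf("population sizes on branch '%s' must be positive", nm),
               "msccov_error_sizes")
    if (any(off < 0))
      mcc_stop(sprintf("negative epoch offset on branch '%s'", nm),
               "msccov_error_epochs")
    if (abs(off[1L]) > tol)
      mcc_stop(sprintf("epochs on branch '%s' leave a gap: first offset must be 0", nm),
               "msccov_error_epochs")
    off[1L] <- 0
    if (is.finite(dur) && any(off >= dur - tol & off > 0))
      mcc_stop(sprintf("epoch offset beyond the end of branch '%s'", nm),
               "msccov_error_epochs")
    st <- br_start[i] + off
    en <- c(st[-1L], br_end[i])
    keep <- en > st               # drop zero-length epochs
    st <- st[keep]; en <- en[keep]; eta <- eta[keep]
    # merge adjacent equal-size epochs (canonical form)
    if (length(st) > 1L) {
      j <- 1L
      for (k in 2L:length(st)) {
        if (eta[k] == eta[j]) {
          en[j] <- en[k]; st[k] <- NA
        } else j <- k
      }
      keep <- !is.na(st)
      st <- st[keep]; en <- en[keep]; eta <- eta[keep]
    }
    epochs[[nm]] <- data.frame(start = unname(st), end = unname(en),
                               size = unname(eta))
  }

  S <- structure(list(branches = branches, epochs = epochs,
                      tips = phy$tip.label,
                      newick = ape::write.tree(phy)),
                 class = "species_tree")
  S
}

#' Parse a species-tree configuration
#'
#' Reads the JSON configuration format
#' `{"newick": ..., "sizes": {branch: [[offset, size], ...]},
#'   "time_units": "generations"|"2N_ref", "N_ref": ...}`
#' and returns a validated [species_tree()].
#'
#' @param config Path to a JSON file, a JSON string, or an already-parsed
#'   list with elements `newick`, `sizes` and optionally `time_units`,
#'   `N_ref`.
#' @return A `species_tree`.
#' @export
parse_species_tree <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config) || is.null(config$newick) || is.null(config$sizes))
    mcc_stop("config must provide 'newick' and 'sizes'", "msccov_error_config")
  sizes <- lapply(config$sizes, function(x) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, unlist))
    x <- as.matrix(x)
    if (ncol(x) == 1L) x <- t(x)
    x
  })
  species_tree(config$newick, sizes,
               time_units = if (is.null(config$time_units)) "generations"
                            else config$time_units,
               N_ref = config$N_ref)
}

#' Serialize a species tree to its canonical JSON configuration
#'
#' Writes times in generations; epoch offsets are relative to each branch's
#' start.  `parse_species_tree(serialize_species_tree(S))` reproduces `S`
#' exactly (canonical form: zero-length epochs dropped, equal-size neighbours
#' merged).
#'
#' @param S A `species_tree`.
#' @param path Optional file path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
serialize_species_tree <- function(S, path = NULL) {
  stopifnot(inherits(S, "species_tree"))
  sizes <- lapply(S$epochs, function(ep) {
    if (nrow(ep) == 0L) return(NULL)
    cbind(ep$start - ep$start[1L] + 0, ep$size)
  })
  sizes <- Filter(Negate(is.null), sizes)
  # offsets must be relative to branch start, not first epoch start
  for (nm in names(sizes)) {
    b0 <- S$branches[nm, "start"]
    sizes[[nm]][, 1L] <- S$epochs[[nm]]$start - b0
  }
  txt <- jsonlite::toJSON(list(newick = S$newick, sizes = sizes,
                               time_units = "generations"),
                          auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$tips), "tips:",
      paste(x$tips, collapse = ", "), "\n")
  cat("  newick:", x$newick, "\n")
  nb <- x$branches
  for (nm in rownames(nb)) {
    ep <- x$epochs[[nm]]
    cat(sprintf("  branch %-8s [%g, %g): %s\n", nm, nb[nm, "start"],
                nb[nm, "end"],
                if (nrow(ep)) paste(sprintf("eta=%g on [%g,%g)", ep$size,
                                            ep$start, ep$end),
                                    collapse = "; ")
                else "(zero length)"))
  }
  invisible(x)
}

check_tip <- function(S, pop) {
  if (!pop %in% S$tips)
    mcc_stop(sprintf("unknown population '%s'", pop), "msccov_error_pop")
}

# Chain of branch names from `name` up to the root (inclusive).
ancestor_path <- function(S, name) {
  out <- character(0)
  cur <- name
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- S$branches[cur, "parent"]
  }
  out
}

# Lowest branch ancestral to all populations in `pops`.
mrca_branch <- function(S, pops) {
  paths <- lapply(unique(pops), function(p) ancestor_path(S, p))
  common <- Reduce(intersect, paths)
  common[1L]   # paths are root-terminated, intersect preserves first path's order
}

#' Species divergence time of two tip populations
#'
#' Returns the time (generations) of the most recent population ancestral to
#' both `A` and `B`; 0 when `A == B` (lineages from the same population can
#' coalesce immediately).
#'
#' @param S A `species_tree`.
#' @param A,B Tip population names.
#' @return Time in generations.
#' @export
divergence_time <- function(S, A, B) {
  check_tip(S, A); check_tip(S, B)
  if (A == B) return(0)
  S$branches[mrca_branch(S, c(A, B)), "start"]
}

#' Marginal population-size profile along an ancestral path
#'
#' For a single population, the piecewise-constant size history along its
#' ancestral path from time 0 to +Inf; for several populations, the history
#' of their shared ancestral path starting at the joint divergence time.
#' Adjacent intervals of equal size are merged.
#'
#' @param S A `species_tree`.
#' @param pops Character vector of tip population names (non-empty).
#' @return A data frame of class `marginal_profile` with columns `start`,
#'   `end`, `size`; intervals tile `[t0, Inf)`.
#' @export
marginal_profile <- function(S, pops) {
  if (length(pops) == 0L)
    mcc_stop("pops must be non-empty", "msccov_error_pop")
  for (p in pops) check_tip(S, p)
  start_branch <- if (length(unique(pops)) == 1L) pops[1L]
                  else mrca_branch(S, pops)
  path <- ancestor_path(S, start_branch)
  ivs <- do.call(rbind, lapply(path, function(nm) S$epochs[[nm]]))
  # zero-length branches contribute no rows; intervals are already ordered
  stopifnot(nrow(ivs) >= 1L, is.infinite(ivs$end[nrow(ivs)]))
  # merge adjacent equal sizes
  if (nrow(ivs) > 1L) {
    j <- 1L
    for (k in 2L:nrow(ivs)) {
      if (ivs$size[k] == ivs$size[j]) {
        ivs$end[j] <- ivs$end[k]; ivs$start[k] <- NA
      } else j <- k
    }
    ivs <- ivs[!is.na(ivs$start), , drop = FALSE]
  }
  rownames(ivs) <- NULL
  structure(ivs, class = c("marginal_profile", "data.frame"))
}

# Active branch (by name) holding a lineage whose home branch is `name`,
# at time t (half-open epochs: at t == branch end the lineage is in the
# parent).
branch_at_time <- function(S, name, t) {
  cur <- name
  while (!is.na(S$branches[cur, "parent"]) && t >= S$branches[cur, "end"]) {
    cur <- S$branches[cur, "parent"]
  }
  if (t < S$branches[cur, "start"]) return(NA_character_)
  cur
}

# Diploid size on branch `name` at time t.
epoch_size_at <- function(S, name, t) {
  ep <- S$epochs[[name]]
  i <- which(ep$start <= t & t < ep$end)
  if (length(i) != 1L)
    mcc_stop(sprintf("time %g not covered by an epoch on branch '%s'", t, name),
             "msccov_error_epochs")
  ep$size[i]
}

#' Two-population species tree
#'
#' Convenience constructor for the tree `(X, Y)XY` with divergence time `D`
#' generations and constant sizes, optionally with one bottleneck epoch
#' inserted on a named branch.
#'
#' @param D Divergence time in generations (may be 0).
#' @param eta_x,eta_y,eta_anc Diploid sizes of X, Y and the ancestral
#'   population.
#' @param bottleneck Optional list with elements `branch` (`"X"`, `"Y"` or
#'   `"XY"`), `start` (offset from the branch start, generations), `duration`
#'   (generations) and `factor` (size divisor, default 10).
#' @return A `species_tree` with tips `X` and `Y`.
#' @export
two_pop_tree <- function(D, eta_x, eta_y = eta_x, eta_anc = eta_x,
                         bottleneck = NULL) {
  nwk <- sprintf("(X:%.17g,Y:%.17g)XY;", D, D)
  sizes <- list(X = eta_x, Y = eta_y, XY = eta_anc)
  if (!is.null(bottleneck)) {
    br <- bottleneck$branch
    fac <- if (is.null(bottleneck$factor)) 10 else bottleneck$factor
    base <- sizes[[br]]
    s0 <- bottleneck$start
    s1 <- s0 + bottleneck$duration
    dur <- if (br == "XY") Inf else D
    if (s0 < 0 || (is.finite(dur) && s1 > dur + 1e-9))
      mcc_stop("bottleneck does not fit on the branch", "msccov_error_epochs")
    off <- c(0, s0, s1)
    eta <- c(base, base / fac, base)
    if (s0 == 0) { off <- off[-1L]; eta <- eta[-1L] }
    if (is.finite(dur) && abs(s1 - dur) < 1e-9) { off <- off[-length(off)]; eta <- eta[-length(eta)] }
    sizes[[br]] <- cbind(off, eta)
  }
  species_tree(nwk, sizes)
}

#' Random species tree fixture generator
#'
#' Draws a small random ultrametric species tree (coalescent-shaped topology)
#' with 1--3 epochs per branch, for property-style tests.  Uses the current
#' RNG state; call `set.seed()` for reproducibility.
#'
#' @param n_tips Number of tip populations (2--5).
#' @param mean_height Expected scale of node times, in generations.
#' @param size_range Range from which diploid sizes are drawn uniformly.
#' @param max_epochs Maximum epochs per branch.
#' @return A `species_tree`.
#' @export
random_species_tree <- function(n_tips = sample(2:5, 1L), mean_height = 1000,
                                size_range = c(100, 2000), max_epochs = 3L) {
  phy <- ape::rcoal(n_tips, tip.label = paste0("P", seq_len(n_tips)))
  phy$edge.length <- phy$edge.length * mean_height /
    max(ape::node.depth.edgelength(phy))
  phy$node.label <- paste0("N", seq_len(phy$Nnode))
  nwk <- ape::write.tree(phy)
  Stmp <- species_tree(nwk, sizes = stats::setNames(
    as.list(rep(size_range[1L], n_tips + phy$Nnode)),
    c(phy$tip.label, phy$node.label)))
  sizes <- list()
  for (nm in rownames(Stmp$branches)) {
    dur <- Stmp$branches[nm, "end"] - Stmp$branches[nm, "start"]
    if (dur <= 0) next
    k <- sample.int(max_epochs, 1L)
    ref <- if (is.finite(dur)) dur else mean_height
    off <- sort(c(0, stats::runif(k - 1L, 0, 0.9 * ref)))
    eta <- stats::runif(k, size_range[1L], size_range[2L])
    sizes[[nm]] <- cbind(off, eta)
  }
  species_tree(nwk, sizes)
}
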