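# Set-partition state space for the joint-moment engine.
#
# States of the ancestral process for n <= 4 sampled lineages are the set
# partitions of {1..n} (Bell numbers 2, 5, 15): each block is one ancestral
# lineage, identified by the set of sampled lineages it subtends.  Partitions
# are stored as canonical restricted-growth strings (RGS).

# Enumerate all set partitions of n elements as canonical RGS vectors.
rgs_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxb) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxb + 1L)) rec(c(prefix, b), max(maxb, b))
  }
  rec(integer(0), 0L)
  out
}

# Canonicalize a block-assignment vector to RGS form (blocks numbered by
# first appearance).
rgs_canon <- function(a) match(a, unique(a))

rgs_key <- function(a) paste(a, collapse = "")

# Build the full partition space for n lineages:
#   assign  : P x n matrix of block assignments (canonical RGS)
#   n_blocks: blocks per partition
#   blocks  : list of lists of integer member vectors
#   merges  : per partition, a matrix with columns (b1, b2, target) listing
#             every unordered pair of blocks and the partition reached by
#             merging them
partition_space <- function(n) {
  stopifnot(n >= 1, n <= 8)
  parts <- rgs_partitions(n)
  P <- length(parts)
  assign <- do.call(rbind, parts)
  keys <- apply(assign, 1L, rgs_key)
  index <- structure(seq_len(P), names = keys)
  n_blocks <- apply(assign, 1L, max)
  blocks <- lapply(seq_len(P), function(s) {
    a <- assign[s, ]
    lapply(seq_len(n_blocks[s]), function(b) which(a == b))
  })
  merges <- lapply(seq_len(P), function(s) {
    a <- assign[s, ]
    nb <- n_blocks[s]
    if (nb < 2L) {
      return(matrix(integer(0), ncol = 3L,
                    dimnames = list(NULL, c("b1", "b2", "target"))))
    }
    cmb <- utils::combn(nb, 2L)
    tg <- apply(cmb, 2L, function(pq) {
      a2 <- a
      a2[a2 == pq[2L]] <- pq[1L]
      index[[rgs_key(rgs_canon(a2))]]
    })
    cbind(b1 = cmb[1L, ], b2 = cmb[2L, ], target = tg)
  })
  list(n = n, P = P, assign = assign, n_blocks = n_blocks,
       blocks = blocks, merges = merges, index = index)
}

# Has the given (unordered) lineage pair coalesced in partition s?
pair_merged <- function(ps, s, pair) {
  ps$assign[s, pair[1L]] == ps$assign[s, pair[2L]]
}
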