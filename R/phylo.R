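# Distance-based trees for the two coordinate systems: the beta1-beta8
# segment alignment and the 55-column CSR fingerprint alignment. Trees are
# neighbor-joining on p-distances with nonparametric bootstrap (column
# resampling) supports; alignments can be exported (PHYLIP/FASTA) for
# external maximum-likelihood programs.

msa_to_int <- function(msa) {
  m <- as.matrix(msa)
  x <- matrix(match(m, AA20, nomatch = 0L), nrow = nrow(m))
  rownames(x) <- msa$row_ids
  x
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i,j)` = mismatches / number of columns where both rows hold residues
#' (pairwise deletion; gaps and `X` are not residues). With
#' `gap_handling = "complete"`, columns containing any gap are dropped for
#' all pairs first. Pairs with zero comparable columns get distance 1 with a
#' warning.
#'
#' @param msa A `gh13_msa` with at least 2 rows.
#' @param gap_handling `"pairwise"` (default) or `"complete"` deletion.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance <- function(msa, gap_handling = c("pairwise", "complete")) {
  gap_handling <- match.arg(gap_handling)
  if (length(msa$row_ids) < 2) stop("need at least 2 rows")
  x <- msa_to_int(msa)
  if (gap_handling == "complete") {
    keep <- colSums(x == 0L) == 0L
    x <- x[, keep, drop = FALSE]
  }
  d <- .pdist_core(x)
  if (attr(d, "zero_comparable_pairs") > 0) {
    warning("some pairs share no comparable columns; their distance is 1")
  }
  dimnames(d) <- list(msa$row_ids, msa$row_ids)
  attr(d, "zero_comparable_pairs") <- NULL
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q-criterion, via `ape::nj`); negative branch
#' lengths are clamped to zero afterwards. Deterministic for a given matrix.
#'
#' @param d Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement `n_replicates` times;
#' the support of each internal edge of the point-estimate tree is the
#' number of replicate trees containing its bipartition, stored as integer
#' node labels. Fully deterministic given `(msa, n_replicates, seed)`.
#'
#' @param msa A `gh13_msa` (>= 3 rows).
#' @param n_replicates Number of bootstrap replicates (default 500).
#' @param seed Integer seed for the resampling.
#' @param gap_handling Passed to [p_distance()].
#' @return An `ape::phylo` tree with `node.label` holding supports in
#'   `[0, n_replicates]`.
#' @export
bootstrap_tree <- function(msa, n_replicates = 500L, seed = 1L,
                           gap_handling = "pairwise") {
  if (n_replicates < 1) stop("need at least 1 replicate")
  point <- neighbor_joining(p_distance(msa, gap_handling))
  x <- msa_to_int(msa)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(x), ncol(x), replace = TRUE)
      xb <- x[, cols, drop = FALSE]
      db <- suppressWarnings(.pdist_core(xb))
      dimnames(db) <- list(rownames(x), rownames(x))
      neighbor_joining(db)
    })
  })
  supports <- ape::prop.clades(point, reps, rooted = FALSE)
  supports[is.na(supports)] <- 0L
  point$node.label <- as.character(as.integer(supports))
  attr(point, "n_replicates") <- as.integer(n_replicates)
  point
}

# canonical string for one bipartition (side not containing the reference
# leaf, sorted), so splits compare independently of orientation
split_strings <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- vapply(parts, function(idx) {
    side <- sort(labs[idx])
    if (ref %in% side) side <- sort(setdiff(tips, side))
    paste(side, collapse = "|")
  }, "")
  sizes <- vapply(strsplit(out, "|", fixed = TRUE), length, integer(1))
  unique(out[sizes >= 2 & sizes <= length(tips) - 2])  # non-trivial only
}

#' Build the segment tree and the CSR-fingerprint tree
#'
#' Computes a bootstrap NJ tree from the beta1-beta8 segment alignment and
#' another from the 55-column fingerprint alignment of the same taxa, plus
#' a comparison of their internal splits.
#'
#' @param segment_msa Trimmed `gh13_msa` (see [trim_beta_segment()]).
#' @param fingerprints [extract_fingerprints()] result for the same taxa.
#' @param n_replicates,seed,gap_handling Passed to [bootstrap_tree()].
#' @return List with `segment_tree`, `csr_tree` (both `ape::phylo` with
#'   supports) and `splits`: list with `shared`, `segment_only`, `csr_only`
#'   (counts of non-trivial bipartitions).
#' @export
build_both_trees <- function(segment_msa, fingerprints, n_replicates = 500L,
                             seed = 1L, gap_handling = "pairwise") {
  fp_msa <- fingerprints_to_msa(fingerprints)
  if (!setequal(segment_msa$row_ids, fp_msa$row_ids)) {
    stop("segment alignment and fingerprints cover different taxa")
  }
  seg <- bootstrap_tree(segment_msa, n_replicates, seed, gap_handling)
  csr <- bootstrap_tree(fp_msa, n_replicates, seed, gap_handling)
  s1 <- split_strings(seg)
  s2 <- split_strings(csr)
  list(segment_tree = seg, csr_tree = csr,
       splits = list(shared = length(intersect(s1, s2)),
                     segment_only = length(setdiff(s1, s2)),
                     csr_only = length(setdiff(s2, s1))))
}
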