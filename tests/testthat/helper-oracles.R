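# Independent oracles used across tests.

# Brute-force global-alignment score: plain recursion over every alignment,
# tracking the previous move so affine gap runs cost open + (k-1) * extend.
# Exponential, for short sequences only; deliberately shares no code with
# the package's dynamic-programming aligner.
oracle_align_score <- function(a, b, S, open, ext) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc)) {
      best <- max(best, S[ac[i], bc[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= length(ac)) {
      best <- max(best, -(if (last == 1L) ext else open) + rec(i + 1L, j, 1L))
    }
    if (j <= length(bc)) {
      best <- max(best, -(if (last == 2L) ext else open) + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# all strings of length 1..maxlen over an alphabet
all_strings <- function(alphabet, maxlen) {
  out <- character(0)
  cur <- ""
  for (len in seq_len(maxlen)) {
    cur <- as.vector(outer(if (len == 1) "" else cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

# a small substitution matrix over a 3-letter alphabet, with dimnames
toy_matrix <- function() {
  m <- matrix(c(4, -1, -2,
                -1, 5, -3,
                -2, -3, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "C", "D"), c("A", "C", "D")))
  m
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.1, 1))
  list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
}

# does `tree` contain the same unrooted topology as `ref`?
same_topology <- function(tree, ref) {
  ape::dist.topo(ape::unroot(tree), ape::unroot(ref)) == 0
}

# support of the bipartition separating `group` from the rest (0 if absent)
split_support <- function(tree, group) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  tips <- tree$tip.label
  for (k in seq_along(parts)) {
    clade <- labs[parts[[k]]]
    if (setequal(clade, group) || setequal(clade, setdiff(tips, group))) {
      lab <- tree$node.label[k]
      if (!is.null(lab) && nzchar(lab)) return(as.integer(lab))
      return(NA_integer_)
    }
  }
  0L
}

small_family <- function(n = 8, eps = 0.05, seed = 42, subfamily = "GH13_24",
                         ...) {
  generate_family(synthetic_config(n_sequences = n, subfamily = subfamily,
                                   substitution_rate = eps, seed = seed, ...))
}
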