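SCORING_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                      "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                      "PAM250")

#' Alignment parameters
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (`"BLOSUM62"` by default) or a numeric matrix with residue letters as
#'   dimnames.
#' @param gap_open Penalty for the first column of a gap run (positive).
#' @param gap_extend Penalty for each further column (positive,
#'   `<= gap_open`). A gap of length k costs `gap_open + (k-1)*gap_extend`;
#'   terminal gaps are penalized like internal ones.
#' @return Object of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

get_submatrix <- function(params) {
  m <- params$matrix
  if (is.character(m)) {
    if (!m %in% SCORING_MATRICES) {
      stop("unknown substitution matrix '", m, "'; available: ",
           paste(SCORING_MATRICES, collapse = ", "))
    }
    e <- new.env()
    utils::data(list = m, package = "Biostrings", envir = e)
    m <- get(m, envir = e)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("substitution matrix needs residue letters as dimnames")
  }
  storage.mode(m) <- "double"
  m
}

path_to_strings <- function(path, a_chars, b_chars) {
  n <- length(path)
  ai <- 0L; bi <- 0L
  a_out <- character(n); b_out <- character(n)
  for (k in seq_len(n)) {
    mv <- path[k]
    if (mv == 0L) {
      ai <- ai + 1L; bi <- bi + 1L
      a_out[k] <- a_chars[ai]; b_out[k] <- b_chars[bi]
    } else if (mv == 1L) {
      ai <- ai + 1L
      a_out[k] <- a_chars[ai]; b_out[k] <- "-"
    } else {
      bi <- bi + 1L
      a_out[k] <- "-"; b_out[k] <- b_chars[bi]
    }
  }
  list(a = paste(a_out, collapse = ""), b = paste(b_out, collapse = ""))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment maximizing the substitution-matrix score
#' under the gap-cost convention of [align_params()]. Traceback ties are
#' broken deterministically: match/mismatch over a gap in the first sequence
#' over a gap in the second.
#'
#' @param a,b Residue strings (non-empty).
#' @param params An [align_params()].
#' @return List with `a`, `b` (gapped aligned strings) and `score`.
#' @examples
#' pairwise_align("MKLV", "MKIV")$score
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  S <- get_submatrix(params)
  a_chars <- strsplit(toupper(a), "")[[1]]
  b_chars <- strsplit(toupper(b), "")[[1]]
  ai <- match(a_chars, rownames(S))
  bi <- match(b_chars, colnames(S))
  if (anyNA(ai) || anyNA(bi)) {
    stop("residue letter not covered by the substitution matrix")
  }
  CS <- S[ai, bi, drop = FALSE]
  res <- .gotoh_core(CS, params$gap_open, params$gap_extend)
  out <- path_to_strings(res$path, a_chars, b_chars)
  list(a = out$a, b = out$b, score = res$score)
}

# fraction of matching letters over columns where both rows hold residues
identity_from_alignment <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  both <- ac != "-" & bc != "-"
  n_cols <- sum(both)
  matches <- sum(ac[both] == bc[both])
  list(identity = if (n_cols) matches / n_cols else 0,
       aligned_columns = n_cols)
}

profile_of_rows <- function(rows, alphabet) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  P <- matrix(0, nrow = length(alphabet), ncol = L)
  for (k in seq_along(alphabet)) {
    P[k, ] <- colSums(m == alphabet[k])
  }
  P / length(rows)
}

merge_msas <- function(rows1, rows2, path) {
  gap1 <- path == 2L  # columns where group 1 gets a gap
  gap2 <- path == 1L
  expand <- function(rows, gapmask) {
    vapply(rows, function(r) {
      chars <- character(length(gapmask))
      chars[gapmask] <- "-"
      chars[!gapmask] <- strsplit(r, "")[[1]]
      paste(chars, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  list(rows1 = expand(rows1, gap1), rows2 = expand(rows2, gap2))
}

#' Progressive multiple sequence alignment
#'
#' Self-contained progressive aligner: a UPGMA guide tree is built on
#' pairwise-identity distances (1 - identity from global pairwise
#' alignments), then sub-alignments are merged bottom-up by profile-profile
#' Gotoh alignment (column score = frequency-weighted substitution score,
#' gap columns contributing zero). Row order follows the input order.
#'
#' @param records A `gh13_records` data.frame (or any data.frame with
#'   `accession` and `residues` columns).
#' @param params An [align_params()].
#' @return A `gh13_msa`.
#' @export
progressive_msa <- function(records, params = align_params()) {
  n <- nrow(records)
  if (n == 0) stop("no records to align")
  if (n == 1) return(gh13_msa(records$accession, records$residues))
  S <- get_submatrix(params)
  seqs <- records$residues
  if (n == 2) {
    al <- pairwise_align(seqs[1], seqs[2], params)
    return(gh13_msa(records$accession, c(al$a, al$b)))
  }
  # guide tree from identity distances
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      al <- pairwise_align(seqs[i], seqs[j], params)
      d[i, j] <- d[j, i] <- 1 - identity_from_alignment(al$a, al$b)$identity
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  alphabet <- rownames(S)
  clusters <- lapply(seq_len(n), function(i) {
    list(ids = i, rows = seqs[i])
  })
  merged <- vector("list", nrow(hc$merge))
  getc <- function(k) if (k < 0) clusters[[-k]] else merged[[k]]
  for (step in seq_len(nrow(hc$merge))) {
    c1 <- getc(hc$merge[step, 1])
    c2 <- getc(hc$merge[step, 2])
    P1 <- profile_of_rows(c1$rows, alphabet)
    P2 <- profile_of_rows(c2$rows, alphabet)
    CS <- crossprod(P1, S %*% P2)
    res <- .gotoh_core(CS, params$gap_open, params$gap_extend)
    ex <- merge_msas(c1$rows, c2$rows, res$path)
    merged[[step]] <- list(ids = c(c1$ids, c2$ids),
                           rows = c(ex$rows1, ex$rows2))
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- order(final$ids)
  gh13_msa(records$accession[final$ids[ord]], final$rows[ord])
}
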