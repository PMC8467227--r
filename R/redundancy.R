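#' Pairwise sequence identity from a global alignment
#'
#' Identity is the number of identical letters divided by the number of
#' alignment columns in which both rows hold residues (gap-containing
#' columns are excluded from the denominator).
#'
#' @param a,b Residue strings, or single-row `gh13_records`.
#' @param params An [align_params()].
#' @return List with `identity` (fraction in 0..1) and `aligned_columns`.
#' @examples
#' pairwise_identity("MKLV", "MKIV")$identity  # 0.75
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  if (is.data.frame(a)) a <- a$residues[1]
  if (is.data.frame(b)) b <- b$residues[1]
  al <- pairwise_align(a, b, params)
  identity_from_alignment(al$a, al$b)
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Records are visited longest-first (ties broken by accession); a record is
#' kept if its identity to every already-kept representative is at or below
#' the threshold, otherwise it joins the cluster of the first representative
#' it exceeds the threshold against. With the default threshold 0.90 no two
#' retained sequences share more than 90% identity.
#'
#' @param records A `gh13_records` data.frame.
#' @param threshold Identity threshold in (0, 1]; strictly greater than the
#'   threshold triggers removal.
#' @param params An [align_params()].
#' @return List with `kept` (a `gh13_records` subset, input order preserved)
#'   and `clusters` (named list: representative accession -> character
#'   vector of member accessions, representative first).
#' @export
dedupe <- function(records, threshold = 0.90, params = align_params()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (nrow(records) == 0) {
    return(list(kept = records, clusters = list()))
  }
  ord <- order(-nchar(records$residues), records$accession)
  reps <- integer(0)  # row indices of representatives
  clusters <- list()
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      idt <- pairwise_identity(records$residues[i], records$residues[r],
                               params)$identity
      if (idt > threshold) {
        acc_r <- records$accession[r]
        clusters[[acc_r]] <- c(clusters[[acc_r]], records$accession[i])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      clusters[[records$accession[i]]] <- records$accession[i]
    }
  }
  keep_rows <- sort(reps)
  kept <- records[keep_rows, , drop = FALSE]
  class(kept) <- class(records)
  list(kept = kept, clusters = clusters)
}

#' Write a dedupe cluster report as tab-separated text
#' @param clusters The `clusters` element of a [dedupe()] result.
#' @param path Output path.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- do.call(rbind, lapply(names(clusters), function(rep) {
    data.frame(representative = rep, member = clusters[[rep]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(representative = character(0), member = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
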