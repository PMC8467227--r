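# Sequence-logo statistics over CSR fingerprints: per-column residue counts,
# Shannon information content in bits against the 20-letter background, and
# consensus letters. The rendering of stacked-letter graphics is out of
# scope; the numeric profile table is the unit of analysis.

#' Per-column residue counts, information content and consensus
#'
#' Counts are over the 20 standard amino acids; gaps and `X` are excluded
#' from counts and from the non-gap total. Information content per column is
#' `log2(20) - H` with `H` the Shannon entropy of the observed letter
#' frequencies; the optional small-sample correction subtracts
#' `e_n = 19 / (2 ln(2) n)`. All-gap columns carry zero counts, IC 0, an
#' `all_gap` flag and consensus `-`.
#'
#' @param fingerprints Data.frame with `accession` and `fingerprint` columns
#'   (see [extract_fingerprints()]), or a character vector of equal-length
#'   strings.
#' @param small_sample_correction Apply the small-sample IC correction.
#' @return Object of class `logo_profile`: list with `counts` (20 x width
#'   matrix), `total` (non-gap totals per column), `ic` (bits per column),
#'   `consensus` (string), `all_gap` (logical per column) and `n` (number of
#'   fingerprints).
#' @export
column_frequencies <- function(fingerprints, small_sample_correction = FALSE) {
  fps <- if (is.data.frame(fingerprints)) fingerprints$fingerprint else fingerprints
  if (length(fps) == 0) stop("no fingerprints supplied")
  if (length(unique(nchar(fps))) != 1) stop("fingerprints differ in length")
  m <- do.call(rbind, strsplit(fps, ""))
  width <- ncol(m)
  counts <- matrix(0L, nrow = length(AA20), ncol = width,
                   dimnames = list(AA20, NULL))
  for (k in seq_along(AA20)) counts[k, ] <- colSums(m == AA20[k])
  total <- colSums(counts)
  ic <- ic_from_counts(counts, total, small_sample_correction)
  consensus <- vapply(seq_len(width), function(j) {
    if (total[j] == 0) "-" else AA20[which.max(counts[, j])]
  }, "")
  structure(list(counts = counts, total = total, ic = ic,
                 consensus = paste(consensus, collapse = ""),
                 all_gap = total == 0, n = length(fps)),
            class = "logo_profile")
}

#' Information content of a logo profile, in bits per column
#'
#' `IC = log2(20) - H`, `H = -sum(p log2 p)` over the letters observed in
#' the column. With `small_sample_correction` the estimator
#' `e_n = 19 / (2 ln(2) n)` is subtracted. All-gap columns report 0 (they
#' are flagged in the profile's `all_gap` field). Negative corrected values
#' are clamped to 0.
#'
#' @param profile A `logo_profile` from [column_frequencies()].
#' @param small_sample_correction Apply the small-sample correction.
#' @return Numeric vector of bits, one per column.
#' @export
information_content <- function(profile, small_sample_correction = FALSE) {
  stopifnot(inherits(profile, "logo_profile"))
  ic_from_counts(profile$counts, profile$total, small_sample_correction)
}

ic_from_counts <- function(counts, total, small_sample_correction = FALSE) {
  width <- ncol(counts)
  ic <- numeric(width)
  for (j in seq_len(width)) {
    n <- total[j]
    if (n == 0) { ic[j] <- 0; next }
    p <- counts[, j][counts[, j] > 0] / n
    h <- -sum(p * log2(p))
    v <- log2(length(AA20)) - h
    if (small_sample_correction) v <- v - 19 / (2 * log(2) * n)
    ic[j] <- max(v, 0)
  }
  ic
}

#' @export
print.logo_profile <- function(x, ...) {
  cat("logo_profile over", x$n, "fingerprints,", length(x$total), "columns\n")
  cat("consensus:", x$consensus, "\n")
  cat("mean IC:", round(mean(x$ic), 3), "bits\n")
  invisible(x)
}

#' Pooled and per-subfamily logo profiles
#'
#' One profile over all fingerprints plus one per subfamily present in the
#' input (seven profiles when all six subfamilies occur).
#'
#' @param fingerprints Data.frame with `accession` and `fingerprint`.
#' @param subfamily Character vector of subfamily labels, one per row.
#' @param small_sample_correction Passed to [column_frequencies()].
#' @return Named list of `logo_profile`s; the pooled profile is named
#'   `"all"`, the rest after their subfamily.
#' @export
subfamily_logos <- function(fingerprints, subfamily,
                            small_sample_correction = FALSE) {
  stopifnot(length(subfamily) == nrow(fingerprints))
  out <- list(all = column_frequencies(fingerprints, small_sample_correction))
  for (sf in unique(subfamily)) {
    out[[sf]] <- column_frequencies(fingerprints[subfamily == sf, , drop = FALSE],
                                    small_sample_correction)
  }
  out
}

#' Write a logo profile as a tab-separated matrix
#'
#' One row per fingerprint column: the 20 residue counts, the non-gap
#' total, the information content in bits and the consensus letter.
#' @param profile A `logo_profile`.
#' @param path Output path.
#' @export
write_logo_profile <- function(profile, path) {
  df <- data.frame(column = seq_along(profile$total),
                   t(profile$counts),
                   total = profile$total,
                   ic_bits = round(profile$ic, 6),
                   consensus = strsplit(profile$consensus, "")[[1]],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
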