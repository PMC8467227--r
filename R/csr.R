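#' Anchor the CSR coordinate system onto an alignment
#'
#' Maps a reference annotation (ungapped CSR start and catalytic-triad
#' positions of one alignment row) into MSA column space by counting
#' non-gap characters along the reference row. The reference row must show
#' the catalytic Asp/Glu/Asp at its annotated triad positions and must be
#' gap-free inside every CSR (CSRs are ungapped blocks by definition).
#'
#' @param msa A `gh13_msa` containing the reference row.
#' @param reference A [reference_annotation()].
#' @param strict If `TRUE` (default), a gap column inside any CSR span of
#'   the reference row is an error; if `FALSE`, the (non-contiguous)
#'   reference-residue columns are used as-is.
#' @return Object of class `anchor_set`: list with `csr_cols` (named list of
#'   MSA column vectors, one per CSR, in layout order), `triad_cols`,
#'   `beta1_col` (first column of CSR-VIII) and `beta8_col` (last column of
#'   CSR-VII).
#' @export
locate_anchors <- function(msa, reference, strict = TRUE) {
  stopifnot(inherits(msa, "gh13_msa"), inherits(reference, "reference_annotation"))
  lay <- reference$layout
  if (!reference$accession %in% msa$row_ids) {
    stop("reference row '", reference$accession, "' not found in alignment")
  }
  chars <- strsplit(msa$rows[[reference$accession]], "")[[1]]
  res_cols <- which(chars != "-")
  widths <- csr_span_widths(lay)
  ends <- reference$csr_starts + widths - 1L
  if (max(ends) > length(res_cols)) {
    stop("reference annotation extends beyond the reference sequence")
  }
  # triad verification: D (nucleophile), E (proton donor), D (stabilizer)
  triad_cols <- res_cols[reference$triad]
  expected <- c(nucleophile = "D", proton_donor = "E", stabilizer = "D")
  got <- chars[triad_cols]
  if (!all(got == expected)) {
    bad <- names(expected)[got != expected]
    stop("catalytic triad mismatch in reference row: expected D/E/D, found ",
         paste(got, collapse = "/"), " (", paste(bad, collapse = ", "), ")")
  }
  csr_cols <- vector("list", length(lay$order))
  names(csr_cols) <- lay$order
  for (k in seq_along(lay$order)) {
    nm <- lay$order[k]
    cols <- res_cols[seq(reference$csr_starts[[nm]], ends[[nm]])]
    if (strict && (cols[length(cols)] - cols[1] + 1L) != widths[[nm]]) {
      stop("reference row has a gap inside ", nm,
           " (CSRs must be ungapped blocks)")
    }
    csr_cols[[nm]] <- cols
  }
  structure(list(csr_cols = csr_cols,
                 triad_cols = stats::setNames(triad_cols, names(reference$triad)),
                 beta1_col = csr_cols[[1]][1],
                 beta8_col = csr_cols[[length(csr_cols)]][widths[length(widths)]],
                 layout = lay,
                 reference = reference$accession),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set on reference", x$reference, "\n")
  for (nm in names(x$csr_cols)) {
    cols <- x$csr_cols[[nm]]
    cat(sprintf("  %-9s columns %d-%d\n", nm, cols[1], cols[length(cols)]))
  }
  cat("triad columns:", paste(x$triad_cols, collapse = "/"), "\n")
  invisible(x)
}

#' Trim an alignment to the beta1-beta8 segment
#'
#' Removes all columns before the first column of CSR-VIII (start of strand
#' beta1) and after the last column of CSR-VII (end of strand beta8).
#'
#' @param msa A `gh13_msa`.
#' @param anchors An [locate_anchors()] result from the same alignment.
#' @return A trimmed `gh13_msa`; row set unchanged.
#' @export
trim_beta_segment <- function(msa, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (anchors$beta8_col > msa$width) stop("anchors do not fit this alignment")
  rows <- substr(unname(msa$rows), anchors$beta1_col, anchors$beta8_col)
  gh13_msa(msa$row_ids, rows)
}

#' Extract the 55-column CSR fingerprint of every aligned sequence
#'
#' For each row, the residues at the reference-residue columns of the eight
#' CSRs are concatenated in layout order; a row gapped at any of those
#' columns carries `-` there. Every fingerprint has exactly the layout
#' width (55 by default).
#'
#' @param msa A `gh13_msa`.
#' @param anchors An [locate_anchors()] result from the same alignment.
#' @return Data.frame with columns `accession`, `fingerprint` and one
#'   per-CSR substring column (named after the CSRs).
#' @export
extract_fingerprints <- function(msa, anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  lay <- anchors$layout
  widths <- csr_span_widths(lay)
  for (nm in names(anchors$csr_cols)) {
    if (length(anchors$csr_cols[[nm]]) < widths[[nm]]) {
      stop("MSA span narrower than the layout span for ", nm)
    }
  }
  all_cols <- unlist(anchors$csr_cols, use.names = FALSE)
  if (max(all_cols) > msa$width) stop("anchors do not fit this alignment")
  m <- as.matrix(msa)
  fp_chars <- m[, all_cols, drop = FALSE]
  fp <- apply(fp_chars, 1, paste, collapse = "")
  out <- data.frame(accession = msa$row_ids, fingerprint = unname(fp),
                    stringsAsFactors = FALSE)
  offset <- 0L
  for (nm in names(anchors$csr_cols)) {
    w <- widths[[nm]]
    out[[nm]] <- substr(out$fingerprint, offset + 1L, offset + w)
    offset <- offset + w
  }
  out
}

#' View fingerprints as a 55-column alignment
#' @param fingerprints Result of [extract_fingerprints()] (or any data.frame
#'   with `accession` and `fingerprint` columns).
#' @return A `gh13_msa` of the fingerprint strings.
#' @export
fingerprints_to_msa <- function(fingerprints) {
  gh13_msa(fingerprints$accession, fingerprints$fingerprint)
}

#' Heuristic de-novo anchor inference (no reference annotation)
#'
#' A conservation-based fallback for alignments lacking an annotated
#' reference row. The catalytic-triad columns are found as the D/E/D column
#' triple maximizing joint occupancy-weighted conservation under
#' layout-compatible ordering; CSR-II/III/IV column spans then follow from
#' the fixed landmark offsets (assuming ungapped CSR blocks), and each
#' remaining CSR span is placed at the conservation-maximizing window within
#' its order constraints. This is a heuristic: prefer a curated
#' [reference_annotation()] whenever one is available.
#'
#' @param msa A `gh13_msa`.
#' @param layout A [csr_layout()].
#' @return An `anchor_set`.
#' @export
infer_anchors <- function(msa, layout = csr_layout()) {
  m <- as.matrix(msa)
  n <- nrow(m)
  occ <- colSums(m != "-") / n
  score_letter <- function(letter) colSums(m == letter) / n
  dfrac <- score_letter("D"); efrac <- score_letter("E")
  rfrac <- score_letter("R"); nfrac <- score_letter("N")
  # candidate triad columns: strongly conserved D / E / D with CSR-compatible
  # spacing, disambiguated by the family's other near-invariant landmarks:
  # Arg two columns before the nucleophile (26 vs 28), Asn two before the
  # stabilizer (44 vs 46) and the conserved Asp closing CSR-III (40 vs 37)
  candD <- which(dfrac * occ > 0.5)
  candE <- which(efrac * occ > 0.5)
  nc <- ncol(m)
  best <- NULL; best_score <- -Inf
  for (c2 in candE) {
    c1s <- candD[candD <= c2 - 9L & candD > 2L]
    c3s <- candD[candD >= c2 + 9L & candD > 2L & candD <= nc]
    if (!length(c1s) || !length(c3s) || c2 + 3L > nc) next
    for (c1 in c1s) for (c3 in c3s) {
      sc <- dfrac[c1] + efrac[c2] + dfrac[c3] +
        rfrac[c1 - 2L] + nfrac[c3 - 2L] + dfrac[c2 + 3L]
      if (sc > best_score) { best_score <- sc; best <- c(c1, c2, c3) }
    }
  }
  if (is.null(best)) stop("no conserved D/E/D column triple found")
  # conservation score per column: occupancy-weighted top-letter frequency
  cons <- vapply(seq_len(ncol(m)), function(j) {
    cnt <- table(m[m[, j] != "-", j])
    if (!length(cnt)) return(0)
    max(cnt) / n
  }, numeric(1))
  spans <- vector("list", length(layout$order))
  names(spans) <- layout$order
  widths <- csr_span_widths(layout)
  off <- function(col, csr) col - layout$spans[[csr]][1] + 1L
  spans[["CSR-II"]] <- best[1] - off(layout$triad[["nucleophile"]], "CSR-II") +
    seq_len(widths[["CSR-II"]])
  spans[["CSR-III"]] <- best[2] - off(layout$triad[["proton_donor"]], "CSR-III") +
    seq_len(widths[["CSR-III"]])
  spans[["CSR-IV"]] <- best[3] - off(layout$triad[["stabilizer"]], "CSR-IV") +
    seq_len(widths[["CSR-IV"]])
  place <- function(lo, hi, w) {
    starts <- seq(lo, hi - w + 1L)
    sc <- vapply(starts, function(s) sum(cons[s:(s + w - 1L)]), numeric(1))
    starts[which.max(sc)] + seq_len(w) - 1L
  }
  # remaining CSRs in order VIII < VI < I < V < II and IV < VII
  lim <- spans[["CSR-II"]][1] - 1L
  pos <- 1L
  for (nm in c("CSR-VIII", "CSR-VI", "CSR-I", "CSR-V")) {
    later <- switch(nm,
      "CSR-VIII" = sum(widths[c("CSR-VI", "CSR-I", "CSR-V")]),
      "CSR-VI" = sum(widths[c("CSR-I", "CSR-V")]),
      "CSR-I" = widths[["CSR-V"]],
      "CSR-V" = 0L)
    spans[[nm]] <- place(pos, lim - later, widths[[nm]])
    pos <- spans[[nm]][widths[[nm]]] + 1L
  }
  spans[["CSR-VII"]] <- place(spans[["CSR-IV"]][widths[["CSR-IV"]]] + 1L,
                              ncol(m), widths[["CSR-VII"]])
  structure(list(csr_cols = spans,
                 triad_cols = stats::setNames(best, names(layout$triad)),
                 beta1_col = spans[[1]][1],
                 beta8_col = spans[[length(spans)]][widths[length(widths)]],
                 layout = layout,
                 reference = NA_character_),
            class = "anchor_set")
}

#' Write a fingerprint table as tab-separated text
#' @param fingerprints Result of [extract_fingerprints()].
#' @param path Output path.
#' @export
write_fingerprints <- function(fingerprints, path) {
  utils::write.table(fingerprints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
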