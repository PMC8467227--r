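# Chloride-binding classification. Animal and animal-like alpha-amylases are
# allosterically activated by a chloride anion coordinated by two arginines
# and one asparagine (the second arginine sometimes replaced by an equally
# positive lysine). On the 55-column fingerprint those sites are columns 26
# (Arg, CSR-II), 44 (Asn, CSR-IV) and 50 (Arg/Lys, CSR-VII).

#' Classify chloride-binding capability from a fingerprint
#'
#' A record is called capable iff column 26 is R, column 44 is N and column
#' 50 is R or K. `X` and gaps never satisfy a site; each unsatisfied site is
#' listed in `missing_sites`.
#'
#' @param fingerprint A 55-character fingerprint string, or a data.frame
#'   with `accession` and `fingerprint` columns (one verdict per row).
#' @param accession Accession label when `fingerprint` is a plain string.
#' @param layout A [csr_layout()] supplying the site columns.
#' @return Data.frame with one row per record: `accession`, `pos26`,
#'   `pos44`, `pos50`, `capable`, `variant` (`"arg"`, `"lys"` or `"none"`)
#'   and `missing_sites` (comma-joined site names, empty when capable).
#' @examples
#' classify_chloride("QYAGVTIVWLPPDAVINHMLDFAGFRIDASKHEWGSEVIDFVDNHDGQNKVMSSY")
#' @export
classify_chloride <- function(fingerprint, accession = "query",
                              layout = csr_layout()) {
  if (is.data.frame(fingerprint)) {
    out <- do.call(rbind, lapply(seq_len(nrow(fingerprint)), function(i) {
      classify_chloride(fingerprint$fingerprint[i],
                        fingerprint$accession[i], layout)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (nchar(fingerprint) != layout$width) {
    stop("fingerprint must have exactly ", layout$width, " characters (got ",
         nchar(fingerprint), ")")
  }
  chars <- strsplit(toupper(fingerprint), "")[[1]]
  p26 <- chars[layout$chloride[["arg1"]]]
  p44 <- chars[layout$chloride[["asn"]]]
  p50 <- chars[layout$chloride[["arg2"]]]
  miss <- character(0)
  if (p26 != "R") miss <- c(miss, "arg26")
  if (p44 != "N") miss <- c(miss, "asn44")
  if (!p50 %in% c("R", "K")) miss <- c(miss, "arglys50")
  capable <- length(miss) == 0
  variant <- if (!capable) "none" else if (p50 == "K") "lys" else "arg"
  data.frame(accession = accession, pos26 = p26, pos44 = p44, pos50 = p50,
             capable = capable, variant = variant,
             missing_sites = paste(miss, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Per-subfamily summary of chloride verdicts
#'
#' @param verdicts Data.frame from [classify_chloride()].
#' @param subfamily Character vector of subfamily labels, one per verdict
#'   row (a single label is recycled).
#' @return Data.frame with one row per subfamily: `n`, `capable`,
#'   `lys_variant`, and counts of records missing each site
#'   (`missing_arg26`, `missing_asn44`, `missing_arglys50`).
#' @export
summarize_chloride <- function(verdicts, subfamily = "unknown") {
  if (nrow(verdicts) == 0) {
    return(data.frame(subfamily = character(0), n = integer(0),
                      capable = integer(0), lys_variant = integer(0),
                      missing_arg26 = integer(0), missing_asn44 = integer(0),
                      missing_arglys50 = integer(0)))
  }
  subfamily <- rep_len(subfamily, nrow(verdicts))
  groups <- unique(subfamily)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- verdicts[subfamily == g, , drop = FALSE]
    data.frame(
      subfamily = g,
      n = nrow(v),
      capable = sum(v$capable),
      lys_variant = sum(v$variant == "lys"),
      missing_arg26 = sum(grepl("arg26", v$missing_sites)),
      missing_asn44 = sum(grepl("asn44", v$missing_sites)),
      missing_arglys50 = sum(grepl("arglys50", v$missing_sites)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
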