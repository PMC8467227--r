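#' @useDynLib gh13csr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_RESIDUES <- c(AA20, "X")

#' Construct a table of protein sequence records
#'
#' The package's working container for unaligned sequences is a plain
#' data.frame with class `gh13_records` and columns `accession`, `organism`,
#' `subfamily`, `taxon_domain`, `note` and `residues`.
#'
#' @param accession Character vector of database accessions (non-empty).
#' @param residues Character vector of amino-acid sequences (20 IUPAC letters
#'   plus X; no gaps; non-empty).
#' @param organism Organism binomials (spaces, not underscores).
#' @param subfamily One of `GH13_1, GH13_5, GH13_15, GH13_24, GH13_32,
#'   GH13_42` or `"unknown"`.
#' @param taxon_domain `"Procarya"`, `"Eucarya"` or `"unknown"`.
#' @param note Free-text note (e.g. a tissue qualifier such as "saliva").
#' @return A `gh13_records` data.frame.
#' @export
gh13_records <- function(accession, residues, organism = "",
                         subfamily = "unknown", taxon_domain = "unknown",
                         note = "") {
  n <- length(accession)
  accession <- as.character(accession)
  residues <- toupper(as.character(residues))
  df <- data.frame(
    accession = accession,
    organism = rep_len(as.character(organism), n),
    subfamily = rep_len(as.character(subfamily), n),
    taxon_domain = rep_len(as.character(taxon_domain), n),
    note = rep_len(as.character(note), n),
    residues = residues,
    stringsAsFactors = FALSE
  )
  validate_records(df)
  class(df) <- c("gh13_records", "data.frame")
  df
}

validate_records <- function(df) {
  if (any(!nzchar(df$accession))) stop("empty accession")
  if (any(!nzchar(df$residues))) stop("empty residues")
  bad_sub <- setdiff(unique(df$subfamily), c(GH13_SUBFAMILIES, "unknown"))
  if (length(bad_sub)) stop("unknown subfamily label: ", paste(bad_sub, collapse = ", "))
  bad_dom <- setdiff(unique(df$taxon_domain), c("Procarya", "Eucarya", "unknown"))
  if (length(bad_dom)) stop("unknown taxon domain: ", paste(bad_dom, collapse = ", "))
  ok <- grepl(paste0("^[", paste(VALID_RESIDUES, collapse = ""), "]+$"), df$residues)
  if (any(!ok)) {
    stop("non-amino-acid characters in record(s): ",
         paste(df$accession[!ok], collapse = ", "))
  }
  invisible(df)
}

#' Parse a record identifier of the form ACCESSION_Genus_species
#'
#' The first underscore-delimited token is the accession; the remainder, with
#' underscores turned into spaces, is the organism. A trailing parenthetical
#' (e.g. a tissue such as `"(saliva)"`) is split off into a free-text note.
#'
#' @param id Character vector of raw identifiers.
#' @return Data.frame with columns `accession`, `organism`, `note`.
#' @examples
#' parse_record_id("AAA85446_Paenibacillus_polymyxa")
#' @export
parse_record_id <- function(id) {
  id <- trimws(as.character(id))
  note <- ifelse(grepl("\\(([^)]*)\\)\\s*$", id),
                 sub("^.*\\(([^)]*)\\)\\s*$", "\\1", id), "")
  core <- trimws(sub("\\s*\\([^)]*\\)\\s*$", "", id))
  acc <- sub("_.*$", "", core)
  org <- ifelse(grepl("_", core),
                gsub("_", " ", sub("^[^_]*_", "", core)), "")
  data.frame(accession = acc, organism = trimws(org), note = note,
             stringsAsFactors = FALSE)
}

#' Compose a record identifier from accession, organism and note
#' @param accession,organism,note Character vectors (recycled).
#' @return Character vector of ids, inverse of [parse_record_id()].
#' @export
compose_record_id <- function(accession, organism = "", note = "") {
  org <- gsub(" ", "_", organism)
  id <- ifelse(nzchar(org), paste0(accession, "_", org), accession)
  ifelse(nzchar(note), paste0(id, " (", note, ")"), id)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed with [parse_record_id()]; residues are upper-cased and
#' a terminal `*` stop character is stripped.
#'
#' @param path Path to a FASTA file.
#' @param subfamily,taxon_domain Labels applied to every record (the FASTA
#'   header carries no subfamily information).
#' @return A `gh13_records` data.frame.
#' @export
read_fasta <- function(path, subfamily = "unknown", taxon_domain = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  meta <- parse_record_id(names(set))
  gh13_records(meta$accession, seqs, organism = meta$organism,
               subfamily = subfamily, taxon_domain = taxon_domain,
               note = meta$note)
}

#' Write records to a FASTA file
#' @param records A `gh13_records` data.frame.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  ids <- compose_record_id(records$accession, records$organism, records$note)
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- records$residues[i]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    lines <- c(lines, paste0(">", ids[i]), chunks)
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' A `gh13_msa` is a list of equal-length gapped rows (gap character `-`)
#' with unique row ids and 1-based column coordinates.
#'
#' @param row_ids Character vector of unique accessions/ids.
#' @param rows Character vector of gapped strings, same length as `row_ids`.
#' @return An object of class `gh13_msa` with elements `row_ids`, `rows`
#'   (named by `row_ids`) and `width`.
#' @export
gh13_msa <- function(row_ids, rows) {
  row_ids <- as.character(row_ids)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)  # normalize '.' gap dialect
  if (length(row_ids) != length(rows)) stop("row_ids and rows differ in length")
  if (anyDuplicated(row_ids)) stop("duplicated row ids in alignment")
  w <- nchar(rows)
  if (length(unique(w)) > 1) {
    bad <- row_ids[w != w[1]][1]
    stop("ragged alignment: row '", bad, "' has different width")
  }
  names(rows) <- row_ids
  structure(list(row_ids = row_ids, rows = rows, width = unname(w[1])),
            class = "gh13_msa")
}

#' @export
print.gh13_msa <- function(x, ...) {
  cat("gh13_msa:", length(x$row_ids), "rows x", x$width, "columns\n")
  show <- utils::head(x$row_ids, 5)
  for (id in show) {
    s <- x$rows[[id]]
    cat(sprintf("  %-20s %s%s\n", id, substr(s, 1, 50),
                if (x$width > 50) "..." else ""))
  }
  if (length(x$row_ids) > 5) cat("  ...\n")
  invisible(x)
}

#' Character matrix view of an alignment
#' @param x A `gh13_msa`.
#' @param ... Unused.
#' @return Character matrix, rows named by row ids.
#' @export
as.matrix.gh13_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), ""))
  rownames(m) <- x$row_ids
  m
}

#' Remove gaps from one alignment row
#' @param msa A `gh13_msa`.
#' @param id Row id.
#' @return Ungapped residue string.
#' @export
msa_degap <- function(msa, id) {
  gsub("-", "", msa$rows[[id]], fixed = TRUE)
}

#' Read a multiple sequence alignment
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned_fasta"` or `"clustal"`. The Clustal reader accepts
#'   the common dialect drift across tools: any (or no) header line, optional
#'   trailing residue counts, and conservation lines.
#' @return A `gh13_msa`.
#' @export
read_msa <- function(path, dialect = c("aligned_fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "aligned_fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0) stop("no records in alignment file: ", path)
    meta <- parse_record_id(names(set))
    return(gh13_msa(meta$accession, as.character(set)))
  }
  read_clustal(path)
}

# Clustal block format: optional "CLUSTAL ..." header, then blocks of
# "<name> <whitespace> <gapped segment> [count]" lines separated by blanks;
# conservation lines (only * : . and spaces) are skipped.
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  segs <- list()
  order_seen <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln) || grepl("^[*:. ]+$", ln)) next  # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) == 0) next
    nm <- m[2]
    seg <- m[3]
    if (!nm %in% order_seen) order_seen <- c(order_seen, nm)
    segs[[nm]] <- paste0(if (is.null(segs[[nm]])) "" else segs[[nm]], seg)
  }
  if (length(order_seen) == 0) stop("no records in Clustal file: ", path)
  rows <- unlist(segs[order_seen], use.names = FALSE)
  meta <- parse_record_id(order_seen)
  w <- nchar(rows)
  if (length(unique(w)) > 1) {
    bad <- order_seen[w != w[1]][1]
    stop("ragged alignment: row '", bad, "' has different width")
  }
  gh13_msa(meta$accession, rows)
}

#' Write an alignment as aligned FASTA
#' @param msa A `gh13_msa`.
#' @param path Output path.
#' @export
write_msa <- function(msa, path) {
  lines <- as.vector(rbind(paste0(">", msa$row_ids), unname(msa$rows)))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write an alignment in interleaved PHYLIP format
#'
#' Provided so that alignments can be handed to external maximum-likelihood
#' programs.
#' @param msa A `gh13_msa`.
#' @param path Output path.
#' @export
write_phylip <- function(msa, path) {
  n <- length(msa$row_ids)
  lines <- sprintf("%d %d", n, msa$width)
  nm <- sprintf("%-10s", substr(msa$row_ids, 1, 10))
  block <- 60L
  starts <- seq(1L, msa$width, block)
  for (k in seq_along(starts)) {
    from <- starts[k]; to <- min(from + block - 1L, msa$width)
    seg <- substr(unname(msa$rows), from, to)
    pre <- if (k == 1) nm else strrep(" ", 10)
    lines <- c(lines, paste0(pre, " ", seg), "")
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are kept; integer bootstrap supports stored as node labels
#' are written as internal-node labels.
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
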