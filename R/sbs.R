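# Surface-binding-site (SBS) correspondence mapping. Templates are solved
# structures with experimentally identified SBSs; their residue positions are
# carried through an alignment row onto every other sequence, and the
# conservation of the corresponding (ideally aromatic, F/W/Y) positions is
# tallied per subfamily.

AROMATIC <- c("F", "W", "Y")

#' Map the residues of an SBS template onto alignment columns
#'
#' Each template residue position is counted along the non-gap characters of
#' the template's own alignment row under the chosen numbering (mature =
#' signal peptide removed; precursor = full translated product) and the
#' row's letter at the mapped column is verified against the template.
#'
#' @param template An [get_template()] result (or a synthetic template from
#'   [synthetic_sbs_template()]).
#' @param msa A `gh13_msa` containing the template row.
#' @param template_row Accession of the row carrying the template sequence.
#' @param numbering `"mature"` or `"precursor"` — must match how the row's
#'   sequence was deposited.
#' @return Object of class `sbs_mapping`: data.frame with `site`, `letter`,
#'   `position`, `column`; attributes `pdb_code`, `template_row`,
#'   `numbering`.
#' @export
map_template_columns <- function(template, msa, template_row,
                                 numbering = c("mature", "precursor")) {
  numbering <- match.arg(numbering)
  stopifnot(inherits(template, "sbs_template"), inherits(msa, "gh13_msa"))
  if (!template_row %in% msa$row_ids) {
    stop("template row '", template_row, "' not found in alignment")
  }
  chars <- strsplit(msa$rows[[template_row]], "")[[1]]
  res_cols <- which(chars != "-")
  res <- template$residues
  pos <- if (numbering == "mature") res$mature_pos else res$precursor_pos
  if (any(pos > length(res_cols))) {
    stop("template residue position exceeds the ungapped length of row '",
         template_row, "'")
  }
  cols <- res_cols[pos]
  found <- chars[cols]
  bad <- which(found != res$letter)
  if (length(bad)) {
    b <- bad[1]
    stop("template residue mismatch: expected ", res$letter[b],
         res$mature_pos[b], " (", numbering, " numbering, column ", cols[b],
         "), found ", found[b])
  }
  out <- data.frame(site = res$site, letter = res$letter, position = pos,
                    column = cols, stringsAsFactors = FALSE)
  attr(out, "pdb_code") <- template$pdb_code
  attr(out, "template_row") <- template_row
  attr(out, "numbering") <- numbering
  class(out) <- c("sbs_mapping", "data.frame")
  out
}

#' Read the observed residues at mapped SBS columns for every sequence
#'
#' @param mapping An [map_template_columns()] result.
#' @param msa The same `gh13_msa` the mapping was computed on.
#' @return Data.frame with one row per (sequence, template residue):
#'   `accession`, `pdb_code`, `site`, `template` (letter + mature-style
#'   position), `observed` (residue letter or `-`), `aromatic` (observed in
#'   F/W/Y).
#' @export
sbs_correspondences <- function(mapping, msa) {
  stopifnot(inherits(mapping, "sbs_mapping"), inherits(msa, "gh13_msa"))
  if (max(mapping$column) > msa$width) stop("mapping does not fit this alignment")
  m <- as.matrix(msa)
  out <- do.call(rbind, lapply(seq_len(nrow(mapping)), function(k) {
    obs <- m[, mapping$column[k]]
    data.frame(accession = msa$row_ids,
               pdb_code = attr(mapping, "pdb_code"),
               site = mapping$site[k],
               template = paste0(mapping$letter[k], mapping$position[k]),
               observed = unname(obs),
               aromatic = unname(obs %in% AROMATIC),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Conservation summary per template residue
#'
#' @param correspondences Data.frame from [sbs_correspondences()] or
#'   [read_sbs_grid()].
#' @return Data.frame with one row per (pdb_code, site, template): `n`
#'   records, `aromatic_count`, `aromatic_fraction` and a list-column
#'   `letters` of named observed-letter counts.
#' @export
conservation_summary <- function(correspondences) {
  key <- paste(correspondences$pdb_code, correspondences$site,
               correspondences$template, sep = "\r")
  keys <- unique(key)
  out <- do.call(rbind, lapply(keys, function(k) {
    cc <- correspondences[key == k, , drop = FALSE]
    data.frame(pdb_code = cc$pdb_code[1], site = cc$site[1],
               template = cc$template[1], n = nrow(cc),
               aromatic_count = sum(cc$aromatic),
               aromatic_fraction = mean(cc$aromatic),
               stringsAsFactors = FALSE)
  }))
  out$letters <- lapply(keys, function(k) {
    table(correspondences$observed[key == k])
  })
  rownames(out) <- NULL
  out
}

#' Read a transcribed SBS residue grid
#'
#' The packaged grids transcribe, for each record of a subfamily, the
#' residues observed at the alignment positions corresponding to a
#' template's SBS residues. Format: tab-separated, first column `record_id`,
#' remaining columns named `PDB_SITE_LETTERPOS` (e.g. `3BLP_SBS-I_W284`,
#' mature numbering).
#'
#' @param path Path to the grid file (see
#'   `system.file("extdata", "tables", package = "gh13csr")`).
#' @return Correspondence data.frame as from [sbs_correspondences()].
#' @export
read_sbs_grid <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- setdiff(names(df), "record_id")
  meta <- parse_record_id(df$record_id)
  out <- do.call(rbind, lapply(cols, function(cn) {
    parts <- strsplit(cn, "_")[[1]]
    if (length(parts) != 3) stop("malformed grid column name: ", cn)
    data.frame(accession = meta$accession,
               pdb_code = parts[1],
               site = parts[2],
               template = parts[3],
               observed = toupper(df[[cn]]),
               aromatic = toupper(df[[cn]]) %in% AROMATIC,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Path to a packaged SBS residue grid
#' @param name Grid file name, one of `"gh13_1_sbs_grid.tsv"`,
#'   `"gh13_5_sbs_grid.tsv"`, `"gh13_24_sbs_grid.tsv"`.
#' @return File path.
#' @export
sbs_grid_path <- function(name) {
  p <- system.file("extdata", "tables", name, package = "gh13csr")
  if (!nzchar(p)) stop("no packaged grid named '", name, "'")
  p
}

#' Build an SBS template from a synthetic family's planted truth
#'
#' Uses the planted SBS residues of one record (default the first) as a
#' template, so that the SBS machinery can be exercised on synthetic data.
#' Positions are taken from the truth table; precursor numbering counts the
#' signal peptide, mature numbering does not. The template is labelled
#' `SYNT` and marked synthetic.
#'
#' @param fam A `synthetic_family` with `sbs_plant` entries.
#' @param which Record index to use as the template row.
#' @return An `sbs_template`.
#' @export
synthetic_sbs_template <- function(fam, which = 1L) {
  sb <- fam$truth$sbs[[which]]
  if (nrow(sb) == 0) stop("family was generated without planted SBS residues")
  sig <- fam$config$signal_peptide
  sites <- lapply(seq_len(nrow(sb)), function(k) {
    list(site = paste0("SBS-", as.character(utils::as.roman(k))),
         residues = list(list(letter = sb$letter[k],
                              mature = sb$position[k] - sig,
                              precursor = sb$position[k])))
  })
  tpl <- sbs_template("SYNT", fam$config$subfamily,
                      "synthetic family template", sites,
                      check_aromatic = FALSE)
  tpl$synthetic <- TRUE
  tpl
}

#' Write correspondence and summary tables as tab-separated text
#' @param correspondences Data.frame from [sbs_correspondences()].
#' @param path Output path.
#' @export
write_sbs_table <- function(correspondences, path) {
  utils::write.table(correspondences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
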