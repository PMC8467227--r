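registry_path <- function(file) {
  p <- system.file("extdata", "registry", file, package = "gh13csr")
  if (!nzchar(p)) stop("registry file not installed: ", file)
  p
}

#' Load the study-set manifest
#'
#' Per-subfamily sequence counts of the 268-sequence GH13 alpha-amylase
#' study set, split into prokaryotic ("Procarya") and eukaryotic ("Eucarya")
#' origin.
#'
#' @return Data.frame with columns `subfamily`, `procarya`, `eucarya`,
#'   `total`, one row per subfamily.
#' @examples
#' m <- load_manifest()
#' sum(m$total)  # 268
#' @export
load_manifest <- function() {
  raw <- yaml::read_yaml(registry_path("manifest.yaml"))
  df <- data.frame(
    subfamily = names(raw),
    procarya = vapply(raw, function(x) as.integer(x$procarya), integer(1)),
    eucarya = vapply(raw, function(x) as.integer(x$eucarya), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(df$procarya < 0 | df$eucarya < 0)) stop("negative manifest count")
  if (!setequal(df$subfamily, GH13_SUBFAMILIES)) {
    stop("manifest subfamilies do not match the expected six")
  }
  df$total <- df$procarya + df$eucarya
  df
}

load_templates <- function() {
  raw <- yaml::read_yaml(registry_path("sbs_templates.yaml"))$templates
  tpl <- list()
  for (t in raw) {
    obj <- sbs_template(t$pdb_code, t$subfamily, t$source_organism, t$sites)
    tpl[[t$pdb_code]] <- obj
    for (a in t$aliases %||% character(0)) tpl[[a]] <- obj
  }
  tpl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sbs_template <- function(pdb_code, subfamily, source_organism, sites,
                         check_aromatic = TRUE) {
  res <- do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(s$residues, function(r) {
      data.frame(site = s$site, letter = toupper(r$letter),
                 mature_pos = as.integer(r$mature),
                 precursor_pos = as.integer(r$precursor),
                 variant_precursor = as.integer(r$variant_precursor %||% NA),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (nrow(res) == 0) stop("template without sites: ", pdb_code)
  if (check_aromatic && !all(res$letter %in% c("F", "W", "Y"))) {
    stop("non-aromatic residue in packaged template ", pdb_code)
  }
  if (any(res$mature_pos > res$precursor_pos)) {
    stop("mature position exceeds precursor position in ", pdb_code)
  }
  structure(
    list(pdb_code = pdb_code, subfamily = subfamily,
         source_organism = source_organism, residues = res),
    class = "sbs_template"
  )
}

#' @export
print.sbs_template <- function(x, ...) {
  cat("SBS template", x$pdb_code, "-", x$source_organism,
      paste0("(", x$subfamily, ")"), "\n")
  print(x$residues, row.names = FALSE)
  invisible(x)
}

#' Retrieve a packaged surface-binding-site template
#'
#' Templates describe the aromatic residues (F/W/Y) forming each
#' experimentally determined SBS of a solved alpha-amylase structure, in both
#' mature (signal peptide removed) and precursor numbering.
#'
#' @param pdb_code 4-character PDB code. Registered codes: `2GUY` (alias
#'   `2GVY`), `2GJP`, `6TOZ`, `3BC9`, `3BLP`.
#' @return An `sbs_template`: list with `pdb_code`, `subfamily`,
#'   `source_organism` and a `residues` data.frame (`site`, `letter`,
#'   `mature_pos`, `precursor_pos`, `variant_precursor`).
#' @examples
#' get_template("3BLP")$residues
#' @export
get_template <- function(pdb_code) {
  tpl <- load_templates()
  if (!pdb_code %in% names(tpl)) {
    stop("unknown template '", pdb_code, "'; registered codes: ",
         paste(sort(unique(names(tpl))), collapse = ", "))
  }
  tpl[[pdb_code]]
}

#' List registered template codes
#' @return Character vector of PDB codes (including aliases).
#' @export
list_templates <- function() sort(unique(names(load_templates())))

#' Reference chloride-triad numbering in the P. haloplanktis alpha-amylase
#'
#' Documentation record: the chloride-coordinating triad of the GH13_32
#' alpha-amylase from *Pseudoalteromonas haloplanktis* sits at residues
#' Arg196, Asn286 and Lys324, the residues corresponding to fingerprint
#' columns 26, 44 and 50.
#' @return Named integer vector `c(arg1 = 196, asn = 286, lys = 324)`.
#' @export
phaloplanktis_triad <- function() c(arg1 = 196L, asn = 286L, lys = 324L)

#' Construct a reference CSR annotation
#'
#' A reference annotation pins the eight CSRs onto one concrete (ungapped)
#' sequence: the 1-based position of the first residue of each CSR plus the
#' positions of the catalytic triad. It is the anchor used by
#' [locate_anchors()] to transfer the fingerprint coordinate system onto an
#' alignment.
#'
#' @param accession Accession of the annotated sequence.
#' @param csr_starts Named integer vector: for each CSR name of the layout,
#'   the ungapped position of its first residue.
#' @param triad Named integer vector `c(nucleophile=, proton_donor=,
#'   stabilizer=)` of ungapped positions.
#' @param layout A [csr_layout()].
#' @return Object of class `reference_annotation`.
#' @export
reference_annotation <- function(accession, csr_starts, triad,
                                 layout = csr_layout()) {
  csr_starts <- csr_starts[layout$order]
  if (any(is.na(csr_starts))) stop("csr_starts must name every CSR of the layout")
  if (is.unsorted(csr_starts, strictly = TRUE)) {
    stop("CSR starts must increase along the sequence in layout order")
  }
  widths <- csr_span_widths(layout)
  ends <- csr_starts + widths - 1L
  if (any(csr_starts[-1] <= ends[-length(ends)])) stop("overlapping CSRs in reference")
  # triad positions must fall inside CSR-II, CSR-III, CSR-IV respectively
  inside <- function(p, csr) p >= csr_starts[[csr]] && p <= ends[[csr]]
  if (!inside(triad[["nucleophile"]], "CSR-II") ||
      !inside(triad[["proton_donor"]], "CSR-III") ||
      !inside(triad[["stabilizer"]], "CSR-IV")) {
    stop("triad positions must fall inside CSR-II, CSR-III and CSR-IV")
  }
  structure(list(accession = accession,
                 csr_starts = csr_starts,
                 triad = triad,
                 layout = layout),
            class = "reference_annotation")
}

#' Write / read a reference annotation as a small YAML file
#' @param ref A `reference_annotation`.
#' @param path File path.
#' @export
write_reference <- function(ref, path) {
  yaml::write_yaml(list(accession = ref$accession,
                        csr_starts = as.list(ref$csr_starts),
                        triad = as.list(ref$triad)), path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  raw <- yaml::read_yaml(path)
  reference_annotation(raw$accession,
                       unlist(raw$csr_starts),
                       unlist(raw$triad))
}
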