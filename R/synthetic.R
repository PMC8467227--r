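# Synthetic GH13-like families with planted truth.
#
# A synthetic record is assembled as
#   [signal peptide] nterm CSR-VIII L1 CSR-VI L2 CSR-I L3 CSR-V L4 CSR-II
#   L5 CSR-III L6 CSR-IV L7 CSR-VII cterm
# where CSR blocks are copied from a per-subfamily consensus motif and the
# seven inter-CSR linkers (plus terminal flanks) take a per-subfamily
# consensus prefix of random length, point-substituted at a configurable
# rate. Catalytic-triad, chloride-site and planted-SBS positions are never
# mutated, so the generated truth table is exact by construction.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default per-subfamily CSR consensus motifs
#'
#' Each subfamily's eight motif strings match the [csr_layout()] span widths
#' and carry the family landmarks: Asp/Glu/Asp of the catalytic triad at
#' fingerprint columns 28/37/46 and the broadly conserved Arg at 26. The
#' asparagine at 44 is present in all subfamilies except GH13_42, whose
#' motif instead shows the subfamily's distinctive serine there (along with
#' Thr11, Tyr41, the MTA start and the YYG tail at columns 53-55). Column 50
#' carries Arg in the chloride-dependent animal subfamilies (GH13_15,
#' GH13_24) and a non-Arg/Lys residue elsewhere.
#'
#' @param subfamily One of the six GH13 subfamily labels.
#' @return Named list of eight motif strings in layout order.
#' @export
default_csr_motifs <- function(subfamily) {
  m <- switch(subfamily,
    GH13_1 = list("ATP", "GLTHVELPG", "DVVANH", "AGLRI",
                  "GLRIDTVKH", "WVSEEVLD", "FIENHD", "GTPSIYYGD"),
    GH13_5 = list("VNG", "GITALWLPP", "DVVINH", "SGLRL",
                  "GFRIDAAKH", "FQNEEVID", "WVNNHD", "GWTEGVTEN"),
    GH13_15 = list("IHL", "GVAGVQVSP", "DAVINH", "AGVRI",
                   "GFRIDAAKH", "YLNQEVID", "FVDNHD", "GSNRLMSSF"),
    GH13_24 = list("QYA", "GVTIVWLPP", "DAVINH", "MLDFA",
                   "GFRIDASKH", "EWGSEVID", "FVDNHD", "GQNRVMSSY"),
    GH13_32 = list("VDL", "GINFIWISP", "DIVLNH", "TDWRA",
                   "GFRIDAAKH", "FLGKEWVD", "MLGNHD", "GSAQHLGAF"),
    GH13_42 = list("MTA", "GVNTLWITP", "DLVVNH", "GDLQA",
                   "GHRIDVAHG", "ALGREWLD", "YWASHD", "GSGQLVYYG"),
    stop("no default motifs for subfamily '", subfamily, "'")
  )
  names(m) <- csr_layout()$order
  m
}

LINKER_PATTERNS <- c(
  GH13_1 = "ASGTPLVKDQENIGHW", GH13_5 = "TSLNGVDAKEQPIRFH",
  GH13_15 = "VNGAETSLKDQIPHRW", GH13_24 = "GQTSVANLEKDPIHRF",
  GH13_32 = "LSTAGNVEKDQPIFHR", GH13_42 = "NTGSLAVEKDQPIHRF"
)

# deterministic consensus content for linker j (0 = N flank, 8 = C flank)
consensus_linker <- function(pattern, j, len) {
  if (len == 0L) return("")
  chars <- strsplit(pattern, "")[[1]]
  k <- j %% length(chars)
  rot <- if (k == 0) chars else c(chars[-seq_len(k)], chars[seq_len(k)])
  paste(rep_len(rot, len), collapse = "")
}

#' Configuration for a synthetic family
#'
#' @param n_sequences Number of records to generate.
#' @param subfamily GH13 subfamily label; selects default motifs and linker
#'   consensus content.
#' @param csr_motifs Named list of eight motif strings (layout span widths);
#'   defaults to [default_csr_motifs()].
#' @param linker_ranges List of seven `c(min, max)` length ranges for the
#'   inter-CSR linkers, in sequence order.
#' @param nterm_range,cterm_range `c(min, max)` length ranges for the flanks
#'   before CSR-VIII and after CSR-VII (outside the beta1-beta8 segment).
#' @param substitution_rate Per-position probability that a linker/flank
#'   position (and, when `protect_csr = FALSE`, a non-landmark CSR position)
#'   is replaced by a uniformly random different residue.
#' @param protect_csr If `TRUE` (default) CSR columns are copied verbatim
#'   from the motif.
#' @param chloride_triad `"none"`, `"RNR"`, `"RNK"` or `"custom"`; `NULL`
#'   picks the subfamily default (`"RNR"` for GH13_15/GH13_24, `"none"`
#'   otherwise). `"none"` forces a non-Arg/Lys residue (Gln) at fingerprint
#'   column 50; `"RNR"`/`"RNK"` plant Arg26/Asn44 and Arg or Lys at 50.
#' @param custom_triad Length-3 character vector of letters for columns
#'   26/44/50 when `chloride_triad = "custom"`.
#' @param sbs_plant List of plant specifications, each a list with `linker`
#'   (1-7), `offset` (1-based within the linker; must not exceed the
#'   linker's minimum length), `letter` and optional `fraction` (default 1)
#'   of records receiving the planted residue.
#' @param signal_peptide Length of a fixed N-terminal signal peptide
#'   (0 = none); used to exercise mature vs precursor numbering.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param accession_prefix Prefix for generated accessions (`SYN` gives
#'   `SYN0001`, ...); set distinct prefixes when combining families.
#' @param layout A [csr_layout()].
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sequences = 60L,
                             subfamily = "GH13_24",
                             csr_motifs = default_csr_motifs(subfamily),
                             linker_ranges = list(
                               c(8L, 14L), c(15L, 25L), c(20L, 30L),
                               c(10L, 18L), c(12L, 20L), c(25L, 35L),
                               c(15L, 25L)
                             ),
                             nterm_range = c(5L, 12L),
                             cterm_range = c(5L, 12L),
                             substitution_rate = 0.10,
                             protect_csr = TRUE,
                             chloride_triad = NULL,
                             custom_triad = NULL,
                             sbs_plant = list(),
                             signal_peptide = 0L,
                             seed = 1L,
                             accession_prefix = "SYN",
                             layout = csr_layout()) {
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must lie in [0, 1]")
  }
  widths <- csr_span_widths(layout)
  got <- vapply(csr_motifs[layout$order], nchar, integer(1))
  if (any(is.na(got)) || any(got != widths)) {
    stop("csr_motifs lengths must match layout span widths (",
         paste(widths, collapse = "/"), ")")
  }
  if (length(linker_ranges) != length(layout$order) - 1L) {
    stop("need one linker range per inter-CSR gap (",
         length(layout$order) - 1L, ")")
  }
  for (r in c(linker_ranges, list(nterm_range, cterm_range))) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) stop("invalid length range")
  }
  if (is.null(chloride_triad)) {
    chloride_triad <- if (subfamily %in% c("GH13_15", "GH13_24")) "RNR" else "none"
  }
  chloride_triad <- match.arg(chloride_triad, c("none", "RNR", "RNK", "custom"))
  if (chloride_triad == "custom" &&
      (is.null(custom_triad) || length(custom_triad) != 3)) {
    stop("custom chloride triad requires 3 letters")
  }
  for (p in sbs_plant) {
    if (!all(c("linker", "offset", "letter") %in% names(p))) {
      stop("sbs_plant entries need linker, offset, letter")
    }
    if (p$linker < 1 || p$linker > length(linker_ranges)) {
      stop("sbs_plant linker index out of range")
    }
    if (p$offset < 1 || p$offset > linker_ranges[[p$linker]][1]) {
      stop("sbs_plant offset exceeds the linker's minimum length")
    }
  }
  structure(
    list(n_sequences = as.integer(n_sequences), subfamily = subfamily,
         csr_motifs = csr_motifs[layout$order], linker_ranges = linker_ranges,
         nterm_range = nterm_range, cterm_range = cterm_range,
         substitution_rate = substitution_rate, protect_csr = protect_csr,
         chloride_triad = chloride_triad, custom_triad = custom_triad,
         sbs_plant = sbs_plant, signal_peptide = as.integer(signal_peptide),
         seed = as.integer(seed), accession_prefix = accession_prefix,
         layout = layout),
    class = "synthetic_config"
  )
}

# motifs after applying the chloride-triad setting; also returns the
# protected offsets (within each CSR) that are never mutated
resolve_motifs <- function(config) {
  lay <- config$layout
  motifs <- config$csr_motifs
  set_col <- function(motifs, col, letter) {
    for (nm in lay$order) {
      s <- lay$spans[[nm]]
      if (col >= s[1] && col <= s[2]) {
        substr(motifs[[nm]], col - s[1] + 1L, col - s[1] + 1L) <- letter
      }
    }
    motifs
  }
  cl <- lay$chloride
  if (config$chloride_triad == "RNR") {
    motifs <- set_col(motifs, cl[["arg1"]], "R")
    motifs <- set_col(motifs, cl[["asn"]], "N")
    motifs <- set_col(motifs, cl[["arg2"]], "R")
  } else if (config$chloride_triad == "RNK") {
    motifs <- set_col(motifs, cl[["arg1"]], "R")
    motifs <- set_col(motifs, cl[["asn"]], "N")
    motifs <- set_col(motifs, cl[["arg2"]], "K")
  } else if (config$chloride_triad == "custom") {
    motifs <- set_col(motifs, cl[["arg1"]], config$custom_triad[1])
    motifs <- set_col(motifs, cl[["asn"]], config$custom_triad[2])
    motifs <- set_col(motifs, cl[["arg2"]], config$custom_triad[3])
  } else {
    cur <- substr(motifs[["CSR-VII"]],
                  cl[["arg2"]] - lay$spans[["CSR-VII"]][1] + 1L,
                  cl[["arg2"]] - lay$spans[["CSR-VII"]][1] + 1L)
    if (cur %in% c("R", "K")) motifs <- set_col(motifs, cl[["arg2"]], "Q")
  }
  motifs
}

mutate_positions <- function(chars, rate, protect = integer(0)) {
  if (rate <= 0 || length(chars) == 0) {
    return(list(chars = chars, n = 0L))
  }
  hit <- stats::runif(length(chars)) < rate
  hit[protect] <- FALSE
  idx <- which(hit)
  for (i in idx) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  list(chars = chars, n = length(idx))
}

#' Generate a synthetic alpha-amylase-like family with planted truth
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_family` with elements
#'   \describe{
#'     \item{records}{a `gh13_records` data.frame,}
#'     \item{truth}{a data.frame with one row per record: `accession`,
#'       `fingerprint` (the planted 55-mer), `chloride_capable`,
#'       `n_substitutions`, `n_mutable` (number of positions eligible for
#'       substitution) and list-columns `csr_starts`, `triad` (1-based
#'       ungapped positions in the stored residues, signal peptide included)
#'       and `sbs` (per plant specification: `linker`, `offset`, `position`,
#'       `letter`, `planted`),}
#'     \item{config}{the configuration.}
#'   }
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lay <- config$layout
  motifs <- resolve_motifs(config)
  pattern <- LINKER_PATTERNS[[config$subfamily]] %||% LINKER_PATTERNS[["GH13_1"]]
  eps <- config$substitution_rate
  n_csr <- length(lay$order)
  # protected offsets per CSR (triad + chloride landmark columns)
  protected <- lapply(lay$order, function(nm) {
    s <- lay$spans[[nm]]
    land <- c(lay$triad, lay$chloride)
    as.integer(land[land >= s[1] & land <= s[2]] - s[1] + 1L)
  })
  names(protected) <- lay$order
  signal <- if (config$signal_peptide > 0) {
    paste0("M", consensus_linker("ALSTVAGLCA", 0L, config$signal_peptide - 1L))
  } else ""

  with_seed(config$seed, {
    recs <- vector("list", config$n_sequences)
    truths <- vector("list", config$n_sequences)
    for (i in seq_len(config$n_sequences)) {
      acc <- sprintf("%s%04d", config$accession_prefix, i)
      draw_len <- function(r) {
        as.integer(r[1]) + sample.int(r[2] - r[1] + 1, 1L) - 1L
      }
      nt <- draw_len(config$nterm_range)
      ct <- draw_len(config$cterm_range)
      lens <- vapply(config$linker_ranges, draw_len, integer(1))
      # decide plants for this record
      plant_here <- vapply(config$sbs_plant, function(p) {
        stats::runif(1) < (p$fraction %||% 1)
      }, logical(1))
      # build linker/flank contents
      linker_chars <- vector("list", n_csr + 1L)  # nterm, L1..L7, cterm
      all_lens <- c(nt, lens, ct)
      n_sub <- 0L; n_mut <- 0L
      for (j in seq_along(all_lens)) {
        cons <- strsplit(consensus_linker(pattern, j - 1L, all_lens[j]), "")[[1]]
        prot <- integer(0)
        if (j >= 2 && j <= n_csr) {  # inter-CSR linker index j-1
          for (k in seq_along(config$sbs_plant)) {
            p <- config$sbs_plant[[k]]
            if (p$linker == j - 1L && plant_here[k]) prot <- c(prot, p$offset)
          }
        }
        mu <- mutate_positions(cons, eps, prot)
        chars <- mu$chars
        n_sub <- n_sub + mu$n
        n_mut <- n_mut + length(cons) - length(prot)
        if (j >= 2 && j <= n_csr) {
          for (k in seq_along(config$sbs_plant)) {
            p <- config$sbs_plant[[k]]
            if (p$linker == j - 1L && plant_here[k]) chars[p$offset] <- p$letter
          }
        }
        linker_chars[[j]] <- chars
      }
      # CSR blocks
      csr_chars <- vector("list", n_csr)
      for (c_i in seq_len(n_csr)) {
        chars <- strsplit(motifs[[c_i]], "")[[1]]
        if (!config$protect_csr) {
          mu <- mutate_positions(chars, eps, protected[[c_i]])
          chars <- mu$chars
          n_sub <- n_sub + mu$n
          n_mut <- n_mut + length(chars) - length(protected[[c_i]])
        }
        csr_chars[[c_i]] <- chars
      }
      # assemble and record coordinates
      parts <- list(strsplit(signal, "")[[1]], linker_chars[[1]])
      csr_starts <- integer(n_csr)
      pos <- length(parts[[1]]) + length(parts[[2]])
      for (c_i in seq_len(n_csr)) {
        csr_starts[c_i] <- pos + 1L
        parts <- c(parts, list(csr_chars[[c_i]]))
        pos <- pos + length(csr_chars[[c_i]])
        parts <- c(parts, list(linker_chars[[c_i + 1L]]))
        pos <- pos + length(linker_chars[[c_i + 1L]])
      }
      names(csr_starts) <- lay$order
      residues <- paste(unlist(parts), collapse = "")
      fp <- paste(vapply(csr_chars, paste, "", collapse = ""), collapse = "")
      fp_chars <- strsplit(fp, "")[[1]]
      triad <- vapply(lay$triad, function(col) {
        nm <- lay$order[vapply(lay$order, function(o) {
          s <- lay$spans[[o]]; col >= s[1] && col <= s[2]
        }, logical(1))][1]
        csr_starts[[nm]] + col - lay$spans[[nm]][1]
      }, integer(1))
      capable <- fp_chars[lay$chloride[["arg1"]]] == "R" &&
        fp_chars[lay$chloride[["asn"]]] == "N" &&
        fp_chars[lay$chloride[["arg2"]]] %in% c("R", "K")
      sbs_truth <- if (length(config$sbs_plant)) {
        do.call(rbind, lapply(seq_along(config$sbs_plant), function(k) {
          p <- config$sbs_plant[[k]]
          lk_start <- csr_starts[[p$linker]] +
            nchar(motifs[[p$linker]])  # linker p$linker follows CSR block p$linker
          posn <- lk_start + p$offset - 1L
          data.frame(linker = p$linker, offset = p$offset, position = posn,
                     letter = linker_chars[[p$linker + 1L]][p$offset],
                     planted = plant_here[k], stringsAsFactors = FALSE)
        }))
      } else {
        data.frame(linker = integer(0), offset = integer(0),
                   position = integer(0), letter = character(0),
                   planted = logical(0))
      }
      recs[[i]] <- data.frame(
        accession = acc,
        organism = sprintf("Synthetica specimen %d", i),
        residues = residues, stringsAsFactors = FALSE
      )
      truths[[i]] <- list(accession = acc, fingerprint = fp,
                          chloride_capable = capable,
                          n_substitutions = n_sub, n_mutable = n_mut,
                          csr_starts = csr_starts, triad = triad,
                          sbs = sbs_truth, lengths = all_lens)
    }
    rdf <- do.call(rbind, recs)
    records <- gh13_records(rdf$accession, rdf$residues,
                            organism = rdf$organism,
                            subfamily = config$subfamily,
                            taxon_domain = "unknown")
    truth <- data.frame(
      accession = vapply(truths, `[[`, "", "accession"),
      fingerprint = vapply(truths, `[[`, "", "fingerprint"),
      chloride_capable = vapply(truths, `[[`, TRUE, "chloride_capable"),
      n_substitutions = vapply(truths, `[[`, 0L, "n_substitutions"),
      n_mutable = vapply(truths, `[[`, 0L, "n_mutable"),
      stringsAsFactors = FALSE
    )
    truth$csr_starts <- I(lapply(truths, `[[`, "csr_starts"))
    truth$triad <- I(lapply(truths, `[[`, "triad"))
    truth$sbs <- I(lapply(truths, `[[`, "sbs"))
    truth$block_lengths <- I(lapply(truths, `[[`, "lengths"))
    structure(list(records = records, truth = truth, config = config),
              class = "synthetic_family")
  })
}

#' Exact alignment of a synthetic family
#'
#' Builds the oracle alignment by padding every variable-length block
#' (flanks and inter-CSR linkers) to its family-wide maximum with trailing
#' gaps, so that CSR columns line up exactly across records.
#'
#' @param fam A `synthetic_family` from [generate_family()].
#' @return A `gh13_msa` with attribute `anchor_truth`: list with `csr_cols`
#'   (named list of MSA column vectors per CSR) and `triad_cols`.
#' @export
generate_truth_msa <- function(fam) {
  stopifnot(inherits(fam, "synthetic_family"))
  config <- fam$config
  lay <- config$layout
  n_csr <- length(lay$order)
  widths <- csr_span_widths(lay)
  lens <- do.call(rbind, fam$truth$block_lengths)  # nterm, L1..L7, cterm
  if (nrow(lens) != nrow(fam$records)) stop("records/truth mismatch")
  maxlen <- apply(lens, 2, max)
  rows <- character(nrow(fam$records))
  for (i in seq_len(nrow(fam$records))) {
    res <- fam$records$residues[i]
    pos <- 1L + config$signal_peptide
    out <- substr(res, 1, config$signal_peptide)
    for (b in seq_len(n_csr + 1L)) {  # block b then (for b<=n_csr) CSR b
      L <- lens[i, b]
      out <- paste0(out, substr(res, pos, pos + L - 1L),
                    strrep("-", maxlen[b] - L))
      pos <- pos + L
      if (b <= n_csr) {
        out <- paste0(out, substr(res, pos, pos + widths[b] - 1L))
        pos <- pos + widths[b]
      }
    }
    rows[i] <- out
  }
  msa <- gh13_msa(fam$records$accession, rows)
  # planted CSR column spans
  csr_cols <- vector("list", n_csr)
  col <- config$signal_peptide
  for (b in seq_len(n_csr)) {
    col <- col + maxlen[b]
    csr_cols[[b]] <- seq(col + 1L, col + widths[b])
    col <- col + widths[b]
  }
  names(csr_cols) <- lay$order
  triad_cols <- vapply(lay$triad, function(fpcol) {
    nm <- lay$order[vapply(lay$order, function(o) {
      s <- lay$spans[[o]]; fpcol >= s[1] && fpcol <= s[2]
    }, logical(1))][1]
    csr_cols[[nm]][fpcol - lay$spans[[nm]][1] + 1L]
  }, integer(1))
  attr(msa, "anchor_truth") <- list(csr_cols = csr_cols, triad_cols = triad_cols)
  msa
}

#' Reference annotation for a synthetic family
#'
#' Uses the planted coordinates of one record (by default the first) as the
#' reference annotation consumed by [locate_anchors()].
#' @param fam A `synthetic_family`.
#' @param which Row index of the record to annotate.
#' @return A [reference_annotation()].
#' @export
synthetic_reference <- function(fam, which = 1L) {
  tr <- fam$truth[which, ]
  reference_annotation(tr$accession,
                       tr$csr_starts[[1]],
                       tr$triad[[1]],
                       layout = fam$config$layout)
}

#' Write a synthetic family to disk (FASTA + tab-separated truth table)
#' @param fam A `synthetic_family`.
#' @param fasta,truth_tsv Output paths.
#' @export
write_family <- function(fam, fasta, truth_tsv) {
  write_fasta(fam$records, fasta)
  flat <- fam$truth[, c("accession", "fingerprint", "chloride_capable",
                        "n_substitutions", "n_mutable")]
  utils::write.table(flat, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta)
}
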