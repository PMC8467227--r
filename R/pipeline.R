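#' Subset alignment rows
#' @param msa A `gh13_msa`.
#' @param ids Row ids to keep (output keeps `msa` order).
#' @return A `gh13_msa`.
#' @export
msa_subset <- function(msa, ids) {
  keep <- msa$row_ids[msa$row_ids %in% ids]
  gh13_msa(keep, unname(msa$rows[keep]))
}

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()] describing the family to simulate
#'   (ignored when `fasta` is given). Its seed is overridden by `seed` so a
#'   single integer controls the whole run.
#' @param fasta Optional path to an input FASTA file (real data).
#' @param reference Optional path to a reference-annotation YAML (see
#'   [write_reference()]); required for FASTA input.
#' @param out_dir Output directory (created if missing).
#' @param dedupe_threshold Identity threshold for redundancy reduction.
#' @param align An [align_params()].
#' @param bootstrap_n Bootstrap replicates for both trees.
#' @param seed Integer seed controlling simulation and bootstrap.
#' @param use_truth_msa For synthetic input: use the exact truth alignment
#'   instead of the progressive aligner.
#' @param sbs_template,sbs_row,sbs_numbering For FASTA input: PDB code of a
#'   registered template, the accession of its row, and its numbering mode.
#'   For synthetic input the template is built from the planted truth.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(
                              sbs_plant = list(
                                list(linker = 6L, offset = 8L, letter = "W"),
                                list(linker = 7L, offset = 5L, letter = "Y")
                              )
                            ),
                            fasta = NULL, reference = NULL,
                            out_dir = tempfile("gh13csr_run_"),
                            dedupe_threshold = 0.90,
                            align = align_params(),
                            bootstrap_n = 100L,
                            seed = 1L,
                            use_truth_msa = FALSE,
                            sbs_template = NULL, sbs_row = NULL,
                            sbs_numbering = "mature") {
  structure(list(synthetic = synthetic, fasta = fasta, reference = reference,
                 out_dir = out_dir, dedupe_threshold = dedupe_threshold,
                 align = align, bootstrap_n = as.integer(bootstrap_n),
                 seed = as.integer(seed), use_truth_msa = use_truth_msa,
                 sbs_template = sbs_template, sbs_row = sbs_row,
                 sbs_numbering = sbs_numbering),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) sequences, reduce redundancy, align, anchor and
#' extract CSR fingerprints, compute logo profiles, classify chloride
#' capability, map SBS correspondences and build the two bootstrap NJ
#' trees. All outputs are plain text and byte-identical across reruns with
#' the same configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and `files`
#'   (named vector of the paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  fam <- stage("simulate", {
    if (is.null(config$fasta)) {
      sc <- config$synthetic
      sc$seed <- config$seed
      generate_family(sc)
    } else NULL
  })
  records <- stage("simulate", {
    if (is.null(fam)) read_fasta(config$fasta) else fam$records
  })

  ded <- stage("dedupe", dedupe(records, config$dedupe_threshold, config$align))
  write_cluster_report(ded$clusters, out("dedupe_report.tsv"))
  kept <- ded$kept

  msa <- stage("align", {
    if (!is.null(fam) && config$use_truth_msa) {
      msa_subset(generate_truth_msa(fam), kept$accession)
    } else {
      progressive_msa(kept, config$align)
    }
  })
  write_msa(msa, out("alignment.fasta"))
  write_phylip(msa, out("alignment.phy"))

  anchors <- stage("csr", {
    ref <- if (!is.null(fam)) {
      synthetic_reference(fam, match(kept$accession[1], fam$truth$accession))
    } else if (!is.null(config$reference)) {
      read_reference(config$reference)
    } else {
      stop("reference annotation required for anchoring")
    }
    locate_anchors(msa, ref)
  })
  fingerprints <- stage("csr", extract_fingerprints(msa, anchors))
  write_fingerprints(fingerprints, out("fingerprints.tsv"))
  segment <- stage("csr", trim_beta_segment(msa, anchors))

  logos <- stage("logo", subfamily_logos(fingerprints, kept$subfamily))
  write_logo_profile(logos$all, out("logo_profile_pooled.tsv"))

  verdicts <- stage("chloride", classify_chloride(fingerprints))
  utils::write.table(verdicts, out("chloride_verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sbs <- stage("sbs", {
    if (!is.null(fam)) {
      if (length(config$synthetic$sbs_plant) == 0) {
        NULL
      } else {
        ridx <- match(kept$accession[1], fam$truth$accession)
        tpl <- synthetic_sbs_template(fam, ridx)
        mp <- map_template_columns(tpl, msa, kept$accession[1], "precursor")
        sbs_correspondences(mp, msa)
      }
    } else if (!is.null(config$sbs_template)) {
      tpl <- get_template(config$sbs_template)
      mp <- map_template_columns(tpl, msa, config$sbs_row,
                                 config$sbs_numbering)
      sbs_correspondences(mp, msa)
    } else NULL
  })
  if (!is.null(sbs)) write_sbs_table(sbs, out("sbs_correspondences.tsv"))

  trees <- stage("tree", build_both_trees(segment, fingerprints,
                                          n_replicates = config$bootstrap_n,
                                          seed = config$seed))
  write_newick(trees$segment_tree, out("segment_tree.nwk"))
  write_newick(trees$csr_tree, out("csr_tree.nwk"))

  manifest <- list(
    package = "gh13csr",
    version = as.character(utils::packageVersion("gh13csr")),
    seed = config$seed,
    parameters = list(
      dedupe_threshold = config$dedupe_threshold,
      gap_open = config$align$gap_open,
      gap_extend = config$align$gap_extend,
      matrix = if (is.character(config$align$matrix)) config$align$matrix else "custom",
      bootstrap_n = config$bootstrap_n,
      use_truth_msa = config$use_truth_msa,
      input = if (is.null(config$fasta)) "synthetic" else config$fasta
    ),
    n_input = nrow(records),
    n_kept = nrow(kept),
    splits = trees$splits
  )
  yaml::write_yaml(manifest, out("run_manifest.yaml"))

  files <- c("dedupe_report.tsv", "alignment.fasta", "alignment.phy",
             "fingerprints.tsv", "logo_profile_pooled.tsv",
             "chloride_verdicts.tsv",
             if (!is.null(sbs)) "sbs_correspondences.tsv",
             "segment_tree.nwk", "csr_tree.nwk", "run_manifest.yaml")
  invisible(list(records = records, dedupe = ded, msa = msa,
                 anchors = anchors, fingerprints = fingerprints,
                 segment = segment, logos = logos, verdicts = verdicts,
                 sbs = sbs, trees = trees, truth = if (!is.null(fam)) fam$truth,
                 files = stats::setNames(file.path(config$out_dir, files), files)))
}
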