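test_that("the default layout partitions exactly 55 columns with landmarks", {
  lay <- csr_layout()
  expect_equal(lay$width, 55)
  widths <- csr_span_widths(lay)
  expect_equal(sum(widths), 55)
  # spans cover 1..55 without overlap
  covered <- unlist(lapply(lay$spans, function(s) seq(s[1], s[2])),
                    use.names = FALSE)
  expect_equal(sort(covered), 1:55)
  expect_equal(unname(lay$triad), c(28L, 37L, 46L))
  expect_equal(unname(lay$chloride), c(26L, 44L, 50L))
  # sequence order of the eight regions
  expect_equal(lay$order, c("CSR-VIII", "CSR-VI", "CSR-I", "CSR-V",
                            "CSR-II", "CSR-III", "CSR-IV", "CSR-VII"))
})

test_that("anchors on a gap-free alignment map columns to positions", {
  fam <- generate_family(synthetic_config(
    n_sequences = 3,
    linker_ranges = lapply(c(10, 18, 22, 12, 15, 28, 20), function(x) c(x, x)),
    nterm_range = c(6, 6), cterm_range = c(6, 6), seed = 4
  ))
  msa <- generate_truth_msa(fam)   # degenerate ranges: gap-free
  an <- locate_anchors(msa, synthetic_reference(fam))
  starts <- fam$truth$csr_starts[[1]]
  for (nm in names(an$csr_cols)) {
    expect_equal(an$csr_cols[[nm]][1], unname(starts[nm]))
  }
})

test_that("anchors recover the planted CSR columns of a truth alignment", {
  for (seed in c(2, 29)) {
    fam <- generate_family(synthetic_config(n_sequences = 12, seed = seed))
    msa <- generate_truth_msa(fam)
    an <- locate_anchors(msa, synthetic_reference(fam))
    truth <- attr(msa, "anchor_truth")
    expect_equal(an$csr_cols, truth$csr_cols)
    expect_equal(unname(an$triad_cols), unname(truth$triad_cols))
  }
})

test_that("a reference lacking the catalytic Asp/Glu/Asp is rejected", {
  fam <- small_family(n = 3)
  msa <- generate_truth_msa(fam)
  ref <- synthetic_reference(fam)
  bad <- ref
  bad$triad[["nucleophile"]] <- bad$triad[["nucleophile"]] + 1L
  expect_error(locate_anchors(msa, bad), "catalytic triad mismatch")
  missing_row <- ref
  missing_row$accession <- "NOPE0001"
  expect_error(locate_anchors(msa, missing_row), "not found")
})

test_that("trimming keeps exactly the beta1-beta8 segment", {
  fam <- generate_family(synthetic_config(n_sequences = 5,
                                          nterm_range = c(10, 10),
                                          cterm_range = c(10, 10), seed = 9))
  msa <- generate_truth_msa(fam)
  an <- locate_anchors(msa, synthetic_reference(fam))
  trimmed <- trim_beta_segment(msa, an)
  expect_equal(trimmed$width, msa$width - 20)
  expect_equal(trimmed$row_ids, msa$row_ids)
  # anchors spanning the full width leave the alignment unchanged; the
  # reference coordinates are rebased to the trimmed sequence
  ref <- synthetic_reference(fam)
  shift <- ref$csr_starts[[1]] - 1L
  ref2 <- reference_annotation(ref$accession, ref$csr_starts - shift,
                               ref$triad - shift)
  an2 <- locate_anchors(trimmed, ref2)
  expect_equal(trim_beta_segment(trimmed, an2)$rows, trimmed$rows)
})

test_that("extracted fingerprints are always 55 characters", {
  fam <- small_family(n = 9, eps = 0.2, seed = 10)
  msa <- generate_truth_msa(fam)
  fp <- extract_fingerprints(msa, locate_anchors(msa, synthetic_reference(fam)))
  expect_true(all(nchar(fp$fingerprint) == 55))
  # per-CSR substrings concatenate back to the fingerprint
  lay <- csr_layout()
  rebuilt <- do.call(paste0, fp[lay$order])
  expect_equal(rebuilt, fp$fingerprint)
})

test_that("the reference's own fingerprint shows D/E/D at 28/37/46", {
  fam <- small_family(n = 5)
  msa <- generate_truth_msa(fam)
  fp <- extract_fingerprints(msa, locate_anchors(msa, synthetic_reference(fam)))
  chars <- strsplit(fp$fingerprint[1], "")[[1]]
  expect_equal(chars[c(28, 37, 46)], c("D", "E", "D"))
})

test_that("fingerprint recovery from truth alignments is exact for any seed", {
  for (seed in c(3, 71, 2024)) {
    fam <- generate_family(synthetic_config(n_sequences = 12, seed = seed,
                                            substitution_rate = 0.05))
    msa <- generate_truth_msa(fam)
    fp <- extract_fingerprints(msa,
                               locate_anchors(msa, synthetic_reference(fam)))
    expect_equal(fp$fingerprint, fam$truth$fingerprint)
  }
})

test_that("fully-gapped flanking columns do not change extraction", {
  fam <- small_family(n = 4)
  msa <- generate_truth_msa(fam)
  ref <- synthetic_reference(fam)
  fp1 <- extract_fingerprints(msa, locate_anchors(msa, ref))
  padded <- gh13_msa(msa$row_ids, paste0("--", unname(msa$rows), "---"))
  fp2 <- extract_fingerprints(padded, locate_anchors(padded, ref))
  expect_equal(fp2$fingerprint, fp1$fingerprint)
})

test_that("heuristic anchor inference recovers planted spans on truth data", {
  fam <- generate_family(synthetic_config(n_sequences = 30, seed = 12,
                                          substitution_rate = 0.25))
  msa <- generate_truth_msa(fam)
  an <- infer_anchors(msa)
  truth <- attr(msa, "anchor_truth")
  expect_equal(unname(an$triad_cols), unname(truth$triad_cols))
  expect_equal(an$csr_cols[["CSR-II"]], truth$csr_cols[["CSR-II"]])
  expect_equal(an$csr_cols[["CSR-IV"]], truth$csr_cols[["CSR-IV"]])
})
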