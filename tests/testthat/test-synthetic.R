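test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_sequences = 10, seed = 99)
  a <- generate_family(cfg)
  b <- generate_family(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$fingerprint, b$truth$fingerprint)
  c <- generate_family(synthetic_config(n_sequences = 10, seed = 100))
  expect_false(identical(a$records$residues, c$records$residues))
})

test_that("noise-free protected families reproduce the consensus fingerprint", {
  for (sf in c("GH13_1", "GH13_32", "GH13_24")) {
    cfg <- synthetic_config(n_sequences = 5, subfamily = sf,
                            substitution_rate = 0, protect_csr = TRUE,
                            seed = 2)
    fam <- generate_family(cfg)
    consensus <- paste(unlist(gh13csr:::resolve_motifs(cfg)), collapse = "")
    expect_equal(nchar(consensus), 55)
    expect_true(all(fam$truth$fingerprint == consensus))
  }
})

test_that("substitution counts follow the configured binomial rate", {
  eps <- 0.1
  fam <- generate_family(synthetic_config(n_sequences = 200,
                                          substitution_rate = eps, seed = 5))
  n_mut <- sum(fam$truth$n_mutable)
  n_sub <- sum(fam$truth$n_substitutions)
  se <- sqrt(eps * (1 - eps) * n_mut)
  expect_lt(abs(n_sub - eps * n_mut), 3 * se)
})

test_that("landmark positions are never mutated even without CSR protection", {
  lay <- csr_layout()
  fam <- generate_family(synthetic_config(n_sequences = 40,
                                          substitution_rate = 0.4,
                                          protect_csr = FALSE, seed = 8))
  fps <- do.call(rbind, strsplit(fam$truth$fingerprint, ""))
  expect_true(all(fps[, lay$triad["nucleophile"]] == "D"))
  expect_true(all(fps[, lay$triad["proton_donor"]] == "E"))
  expect_true(all(fps[, lay$triad["stabilizer"]] == "D"))
  expect_true(all(fps[, lay$chloride["arg1"]] == "R"))
})

test_that("chloride truth labels follow the planted triad", {
  capable <- generate_family(synthetic_config(n_sequences = 10,
                                              subfamily = "GH13_32",
                                              chloride_triad = "RNK", seed = 3))
  expect_true(all(capable$truth$chloride_capable))
  incapable <- generate_family(synthetic_config(n_sequences = 10,
                                                subfamily = "GH13_1",
                                                chloride_triad = "none",
                                                seed = 3))
  expect_false(any(incapable$truth$chloride_capable))
})

test_that("truth MSA slicing recovers every planted fingerprint", {
  for (seed in c(1, 17, 123)) {
    fam <- generate_family(synthetic_config(n_sequences = 15, seed = seed,
                                            substitution_rate = 0.15))
    msa <- generate_truth_msa(fam)
    cols <- unlist(attr(msa, "anchor_truth")$csr_cols, use.names = FALSE)
    m <- as.matrix(msa)
    sliced <- apply(m[, cols], 1, paste, collapse = "")
    expect_equal(unname(sliced), fam$truth$fingerprint)
  }
})

test_that("degenerate linker ranges give a gap-free truth alignment", {
  cfg <- synthetic_config(
    n_sequences = 4,
    linker_ranges = lapply(c(10, 18, 22, 12, 15, 28, 20), function(x) c(x, x)),
    nterm_range = c(6, 6), cterm_range = c(6, 6), seed = 1
  )
  msa <- generate_truth_msa(generate_family(cfg))
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
})

test_that("a single record aligns to itself without gaps", {
  fam <- small_family(n = 1)
  msa <- generate_truth_msa(fam)
  expect_equal(unname(msa$rows[1]), fam$records$residues[1])
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(substitution_rate = 1.5), "substitution_rate")
  bad_motifs <- default_csr_motifs("GH13_24")
  bad_motifs[["CSR-VIII"]] <- "TOOLONG"
  expect_error(synthetic_config(csr_motifs = bad_motifs), "span widths")
  expect_error(
    synthetic_config(sbs_plant = list(list(linker = 1, offset = 99,
                                           letter = "W"))),
    "minimum length"
  )
})

test_that("signal peptides shift coordinates but not fingerprints", {
  cfg0 <- synthetic_config(n_sequences = 4, seed = 6, signal_peptide = 0)
  cfg1 <- synthetic_config(n_sequences = 4, seed = 6, signal_peptide = 15)
  f0 <- generate_family(cfg0)
  f1 <- generate_family(cfg1)
  expect_equal(f1$truth$fingerprint, f0$truth$fingerprint)
  expect_equal(f1$truth$csr_starts[[1]], f0$truth$csr_starts[[1]] + 15L)
  expect_equal(substr(f1$records$residues[1], 16, 1000),
               f0$records$residues[1])
})

test_that("family FASTA + truth table export round-trips", {
  fam <- small_family(n = 4)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tt <- withr::local_tempfile(fileext = ".tsv")
  write_family(fam, fa, tt)
  back <- read_fasta(fa)
  expect_equal(back$residues, fam$records$residues)
  tab <- read.delim(tt)
  expect_equal(tab$fingerprint, fam$truth$fingerprint)
})
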