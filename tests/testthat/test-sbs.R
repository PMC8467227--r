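planted_family <- function(n = 10, fraction = 1, seed = 8, signal = 0) {
  generate_family(synthetic_config(
    n_sequences = n, seed = seed, signal_peptide = signal,
    sbs_plant = list(list(linker = 6L, offset = 8L, letter = "W",
                          fraction = fraction),
                     list(linker = 7L, offset = 5L, letter = "Y",
                          fraction = fraction))
  ))
}

test_that("a template maps onto its own gap-free row at its own positions", {
  fam <- planted_family(n = 1)
  msa <- generate_truth_msa(fam)  # single record: no gaps
  tpl <- synthetic_sbs_template(fam)
  mp <- map_template_columns(tpl, msa, fam$records$accession[1], "precursor")
  expect_equal(mp$column, mp$position)
  expect_equal(mp$letter, c("W", "Y"))
})

test_that("mapping verifies the template letters and the numbering mode", {
  fam <- planted_family(n = 6, signal = 12)
  msa <- generate_truth_msa(fam)
  tpl <- synthetic_sbs_template(fam)
  # rows retain the signal peptide: precursor numbering is correct
  mp <- map_template_columns(tpl, msa, fam$records$accession[1], "precursor")
  expect_equal(nrow(mp), 2)
  # mature numbering against a precursor row: letter check fails
  expect_error(
    map_template_columns(tpl, msa, fam$records$accession[1], "mature"),
    "template residue mismatch"
  )
  expect_error(
    map_template_columns(tpl, msa, "ABSENT01", "precursor"),
    "not found"
  )
})

test_that("correspondences agree with the planted truth per record", {
  fam <- planted_family(n = 20, fraction = 0.5, seed = 15)
  msa <- generate_truth_msa(fam)
  # use a record that actually received the plants as template row
  planted_rows <- which(vapply(fam$truth$sbs, function(s) all(s$planted), TRUE))
  expect_gt(length(planted_rows), 0)
  tpl <- synthetic_sbs_template(fam, planted_rows[1])
  mp <- map_template_columns(tpl, msa,
                             fam$truth$accession[planted_rows[1]], "precursor")
  cc <- sbs_correspondences(mp, msa)
  expect_equal(nrow(cc), 2 * 20)
  for (i in seq_len(20)) {
    # both the truth rows and the mapping rows follow the plant order
    want <- fam$truth$sbs[[i]]
    got <- cc[cc$accession == fam$truth$accession[i], ]
    got <- got[match(paste0(mp$letter, mp$position), got$template), ]
    expect_equal(got$observed, want$letter, info = i)
    expect_equal(got$aromatic, want$letter %in% c("F", "W", "Y"), info = i)
  }
})

test_that("the template row is a fixed point of the correspondence map", {
  fam <- planted_family(n = 5)
  msa <- generate_truth_msa(fam)
  tpl <- synthetic_sbs_template(fam)
  mp <- map_template_columns(tpl, msa, fam$records$accession[1], "precursor")
  cc <- sbs_correspondences(mp, msa)
  self <- cc[cc$accession == fam$records$accession[1], ]
  expect_equal(self$observed, mp$letter)
  expect_true(all(self$aromatic))
})

test_that("conservation summaries are permutation-invariant", {
  fam <- planted_family(n = 8, fraction = 0.6, seed = 44)
  msa <- generate_truth_msa(fam)
  planted_rows <- which(vapply(fam$truth$sbs, function(s) all(s$planted), TRUE))
  tpl <- synthetic_sbs_template(fam, planted_rows[1])
  mp <- map_template_columns(tpl, msa,
                             fam$truth$accession[planted_rows[1]], "precursor")
  cc <- sbs_correspondences(mp, msa)
  s1 <- conservation_summary(cc)
  s2 <- conservation_summary(cc[rev(seq_len(nrow(cc))), ])
  expect_equal(s1$aromatic_count, s2$aromatic_count)
  expect_equal(s1$n, s2$n)
  expect_equal(s1$aromatic_fraction,
               (s1$aromatic_count) / s1$n)
})

test_that("the animal-subfamily grid shows the three invariant tryptophans", {
  g <- read_sbs_grid(sbs_grid_path("gh13_24_sbs_grid.tsv"))
  s <- conservation_summary(g)
  expect_equal(unique(s$n), 23)
  for (res in c("W284", "W388", "W203")) {
    row <- s[s$template == res, ]
    expect_equal(unname(row$letters[[1]]["W"]), 23, info = res)
    expect_equal(row$aromatic_fraction, 1, info = res)
  }
  # the less conserved sites are not invariant
  expect_lt(s$aromatic_fraction[s$template == "W134"], 1)
})

test_that("the fungal-subfamily grid matches the described conservation", {
  g <- read_sbs_grid(sbs_grid_path("gh13_1_sbs_grid.tsv"))
  expect_equal(length(unique(g$accession)), 39)
  s <- conservation_summary(g)
  expect_equal(s$n, c(39, 39))
  # the template's own SBS pair is conserved in the classic aspergilli
  conserved_in <- c("BAD06002", "AAF14264", "BAD01051", "CAA31218",
                    "BAA01255", "ABG48762", "AAC49622", "AAN75021")
  for (acc in conserved_in) {
    got <- g[g$accession == acc, ]
    expect_equal(got$observed[got$template == "Y382"], "Y", info = acc)
    expect_equal(got$observed[got$template == "W385"], "W", info = acc)
  }
  # the raw-starch degrading yeast lacks the corresponding SBS
  sf <- g[g$accession == "ADD80242", ]
  expect_false(any(sf$aromatic))
})

test_that("the bacterial-subfamily grid loads with all twelve positions", {
  g <- read_sbs_grid(sbs_grid_path("gh13_5_sbs_grid.tsv"))
  expect_equal(length(unique(g$accession)), 35)
  expect_equal(length(unique(paste(g$pdb_code, g$template))), 12)
  s <- conservation_summary(g)
  # each template's own row self-matches
  own <- list(c("CAD26699", "2GJP"), c("AGN35141", "6TOZ"),
              c("ACL70573", "3BC9"))
  for (o in own) {
    rows <- g[g$accession == o[1] & g$pdb_code == o[2], ]
    expect_true(all(rows$observed == substr(rows$template, 1, 1)), info = o[2])
  }
  # gaps in the grid are tolerated and non-aromatic
  alk <- g[g$accession == "AAQ01675", ]
  expect_true(any(alk$observed == "-"))
  expect_false(any(alk$aromatic[alk$observed == "-"]))
})
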