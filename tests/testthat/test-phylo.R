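test_that("p-distance matches direct counts, with pairwise deletion", {
  msa <- gh13_msa(c("a", "b"), c("AAAA", "AAAT"))
  expect_equal(p_distance(msa)["a", "b"], 0.25)
  msa2 <- gh13_msa(c("a", "b"), c("A-AA", "AT-A"))
  # comparable columns: 1 and 4, both match
  expect_equal(p_distance(msa2)["a", "b"], 0)
  msa3 <- gh13_msa(c("a", "b", "c"), c("AC-G", "AG-G", "TTTT"))
  d <- p_distance(msa3)
  expect_equal(d["a", "b"], 1 / 3)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  # complete deletion drops any column with a gap
  expect_equal(p_distance(msa3, "complete")["a", "b"], 1 / 3)
  # identical rows are at distance zero
  expect_equal(p_distance(gh13_msa(c("x", "y"), c("MKL", "MKL")))["x", "y"], 0)
})

test_that("pairs without comparable columns get distance 1 with a warning", {
  msa <- gh13_msa(c("a", "b"), c("A--", "-TT"))
  expect_warning(d <- p_distance(msa), "no comparable")
  expect_equal(d["a", "b"], 1)
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)
})

test_that("NJ recovers the generating split of an additive 4-taxon matrix", {
  # tree ((A,B),(C,D)) with internal branch 1
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  d <- stats::cophenetic(tr)
  nj <- neighbor_joining(d)
  expect_true(same_topology(nj, tr))
})

test_that("NJ reconstructs random additive trees of 5-8 leaves", {
  gh13csr:::with_seed(20, {
    for (rep in 1:12) {
      n <- sample(5:8, 1)
      ra <- random_additive(n)
      nj <- neighbor_joining(ra$d)
      expect_true(same_topology(nj, ra$tree), info = rep)
    }
  })
})

test_that("NJ handles ties and degenerate matrices deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_true(same_topology(t1, t2))
  expect_true(all(t1$edge.length >= 0))
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("total tree length is invariant under leaf relabeling", {
  ra <- gh13csr:::with_seed(9, random_additive(6))
  perm <- gh13csr:::with_seed(10, sample(rownames(ra$d)))
  d2 <- ra$d[perm, perm]
  expect_equal(sum(neighbor_joining(ra$d)$edge.length),
               sum(neighbor_joining(d2)$edge.length), tolerance = 1e-9)
})

test_that("bootstrap supports are reproducible and bounded", {
  fam <- small_family(n = 8, eps = 0.15, seed = 19)
  msa <- generate_truth_msa(fam)
  t1 <- bootstrap_tree(msa, n_replicates = 25, seed = 7)
  t2 <- bootstrap_tree(msa, n_replicates = 25, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- as.integer(t1$node.label)
  expect_true(all(sup >= 0 & sup <= 25))
  # a single replicate gives supports in {0, 1}
  t3 <- bootstrap_tree(msa, n_replicates = 1, seed = 7)
  expect_true(all(as.integer(t3$node.label) %in% c(0L, 1L)))
})

test_that("duplicating all columns leaves the point-estimate tree unchanged", {
  fam <- small_family(n = 6, eps = 0.2, seed = 23)
  msa <- generate_truth_msa(fam)
  doubled <- gh13_msa(msa$row_ids, paste0(unname(msa$rows), unname(msa$rows)))
  t1 <- neighbor_joining(p_distance(msa))
  t2 <- neighbor_joining(p_distance(doubled))
  expect_true(same_topology(t1, t2))
})

test_that("a strongly divergent two-clade family gets near-full support", {
  base1 <- gh13csr:::with_seed(1, paste(sample(c("A", "C", "D", "E", "F"),
                                               120, TRUE), collapse = ""))
  base2 <- gh13csr:::with_seed(2, paste(sample(c("G", "H", "I", "K", "L"),
                                               120, TRUE), collapse = ""))
  perturb <- function(s, k, seed) {
    chars <- strsplit(s, "")[[1]]
    gh13csr:::with_seed(seed, {
      pos <- sample(seq_along(chars), k)
      chars[pos] <- sample(c("M", "N", "P", "Q"), k, TRUE)
    })
    paste(chars, collapse = "")
  }
  rows <- c(vapply(1:4, function(i) perturb(base1, 4, i), ""),
            vapply(1:4, function(i) perturb(base2, 4, 10 + i), ""))
  ids <- c(paste0("A", 1:4), paste0("B", 1:4))
  msa <- gh13_msa(ids, rows)
  tr <- bootstrap_tree(msa, n_replicates = 100, seed = 3)
  expect_gte(split_support(tr, paste0("B", 1:4)), 95)
})

test_that("the two coordinate systems give trees over the same taxa", {
  fam <- small_family(n = 10, eps = 0.15, seed = 27)
  msa <- generate_truth_msa(fam)
  an <- locate_anchors(msa, synthetic_reference(fam))
  fp <- extract_fingerprints(msa, an)
  segment <- trim_beta_segment(msa, an)
  both <- build_both_trees(segment, fp, n_replicates = 20, seed = 5)
  expect_setequal(both$segment_tree$tip.label, fam$records$accession)
  expect_setequal(both$csr_tree$tip.label, fam$records$accession)
  expect_equal(fingerprints_to_msa(fp)$width, 55)
  # identical inputs give identical trees and fully shared splits
  fp_as_msa <- fingerprints_to_msa(fp)
  same <- build_both_trees(fp_as_msa, fp, n_replicates = 20, seed = 5)
  expect_identical(ape::write.tree(same$segment_tree),
                   ape::write.tree(same$csr_tree))
  expect_equal(same$splits$segment_only, 0)
  expect_equal(same$splits$csr_only, 0)
  # mismatched taxa are rejected
  expect_error(build_both_trees(segment, fp[1:5, ], 10, 1), "different taxa")
})

test_that("linker-divergent subfamilies split in the segment tree, not the CSR tree", {
  shared <- default_csr_motifs("GH13_24")
  famA <- generate_family(synthetic_config(
    n_sequences = 6, subfamily = "GH13_24", csr_motifs = shared,
    chloride_triad = "RNR", substitution_rate = 0.05, protect_csr = FALSE,
    seed = 31, accession_prefix = "AAA"
  ))
  famB <- generate_family(synthetic_config(
    n_sequences = 6, subfamily = "GH13_1", csr_motifs = shared,
    chloride_triad = "RNR", substitution_rate = 0.05, protect_csr = FALSE,
    seed = 32, accession_prefix = "BBB"
  ))
  records <- rbind(famA$records, famB$records)
  class(records) <- c("gh13_records", "data.frame")
  msa <- progressive_msa(records)
  an <- locate_anchors(msa, synthetic_reference(famA))
  fp <- extract_fingerprints(msa, an)
  segment <- trim_beta_segment(msa, an)
  both <- build_both_trees(segment, fp, n_replicates = 50, seed = 6)
  groupB <- famB$records$accession
  seg_support <- split_support(both$segment_tree, groupB)
  csr_support <- split_support(both$csr_tree, groupB)
  expect_gt(seg_support, csr_support)
})
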