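# Profile construction and serialization.

test_that("single-sequence profile with zero pseudocount is one-hot", {
  p <- seq_profile("ACD", "x", pseudocount_weight = 0)
  expect_equal(p$n_cols, 3L)
  expect_equal(unname(p$freqs[1, "A"]), 1)
  expect_equal(unname(p$freqs[2, "C"]), 1)
  expect_equal(sum(p$freqs[3, ] > 0), 1L)
})

test_that("profile columns are normalised and pseudocounted exactly", {
  msa <- new_msa(c("r1", "r2"), c("AA", "AC"))
  p <- build_profile(msa, pseudocount_weight = 0.1)
  expect_true(all(abs(rowSums(p$freqs) - 1) < 1e-9))
  bA <- aa_background()[["A"]]
  expect_equal(unname(p$freqs[2, "A"]), (1 + 0.1 * bA) / (2 + 0.1))
  expect_equal(unname(p$freqs[1, "A"]), (2 + 0.1 * bA) / (2 + 0.1))
  expect_equal(p$n_seqs, 2L)
})

test_that("gaps and masked residues are excluded from the counts", {
  msa <- new_msa(c("r1", "r2"), c("A-", "AC"))
  p <- build_profile(msa, pseudocount_weight = 0.1)
  expect_equal(p$gap_frac, c(0, 0.5))
  bC <- aa_background()[["C"]]
  expect_equal(unname(p$freqs[2, "C"]), (1 + 0.1 * bC) / (1 + 0.1))

  # X behaves like an absent observation
  msx <- new_msa(c("r1", "r2"), c("XC", "AC"))
  px <- build_profile(msx, pseudocount_weight = 0.1)
  bA <- aa_background()[["A"]]
  expect_equal(unname(px$freqs[1, "A"]), (1 + 0.1 * bA) / (1 + 0.1))

  # cc_mask maps unaligned positions through the rows
  msa2 <- new_msa(c("r1", "r2"), c("AC", "AC"))
  mk <- list(r1 = c(TRUE, FALSE), r2 = c(TRUE, FALSE))
  pm <- build_profile(msa2, pseudocount_weight = 0.1, cc_mask = mk)
  expect_equal(pm$freqs[1, ], aa_background())
  expect_equal(pm$masked_cols, 1L)
})

test_that("an all-gap column warns and carries background", {
  msa <- new_msa(c("r1", "r2"), c("-C", "-C"))
  expect_warning(p <- build_profile(msa), "all-gap")
  expect_equal(p$freqs[1, ], aa_background())
})

test_that("profiles serialise losslessly to the TSV format", {
  msa <- new_msa(c("r1", "r2", "r3"), c("ACD-", "AC-E", "GCDE"))
  p <- build_profile(msa, source_id = "fam1")
  path <- withr::local_tempfile(fileext = ".prof")
  write_profile(p, path)
  q <- read_profile(path)
  expect_equal(q$source_id, "fam1")
  expect_equal(q$n_seqs, 3L)
  expect_equal(q$freqs, p$freqs, tolerance = 1e-8)
  expect_equal(q$gap_frac, p$gap_frac, tolerance = 1e-8)
  expect_equal(q$background, p$background, tolerance = 1e-8)
})
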