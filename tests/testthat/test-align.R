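# Pairwise global alignment and alignment statistics.

test_that("self- and single-residue alignments behave exactly", {
  m <- blosum62()
  aln <- pairwise_global_align("ACDE", "ACDE")
  expect_equal(aln$score, sum(m[cbind(c("A", "C", "D", "E"),
                                      c("A", "C", "D", "E"))]))
  st <- pairwise_stats(aln)
  expect_equal(st[["identity"]], 100)
  expect_equal(st[["similarity"]], 100)

  aln1 <- pairwise_global_align("A", "D")
  expect_equal(aln1$score, m["A", "D"])
  expect_equal(aln1$a_aln, "A")
  expect_equal(aln1$b_aln, "D")
})

test_that("global alignment score matches exhaustive enumeration", {
  m <- blosum62()
  withr::with_seed(101, {
    for (case in 1:60) {
      n <- sample(1:6, 1)
      k <- sample(1:6, 1)
      a <- sample.int(20, n, replace = TRUE)
      b <- sample.int(20, k, replace = TRUE)
      go <- sample(c(5, 10), 1)
      ge <- sample(c(1, 2), 1)
      got <- pairwise_global_align(
        paste(profhom:::AA_ALPHABET[a], collapse = ""),
        paste(profhom:::AA_ALPHABET[b], collapse = ""),
        gap_open = go, gap_extend = ge)$score
      expect_equal(got, oracle_global(a, b, m, go, ge),
                   info = paste("case", case))
    }
  })
})

test_that("identity and similarity are computed over gapless pairs", {
  st <- pairwise_stats(pairwise_global_align("AAAA", "GGGG"))
  expect_equal(st[["identity"]], 0)
  expect_true(st[["similarity"]] >= st[["identity"]])

  # similarity >= identity as a property over random pairs
  withr::with_seed(7, {
    for (i in 1:10) {
      aln <- pairwise_global_align(random_seq(30), random_seq(30))
      st <- pairwise_stats(aln)
      expect_gte(st[["similarity"]], st[["identity"]])
    }
  })
})

test_that("an alignment without gapless pairs is flagged undefined", {
  fake <- structure(list(a_aln = "A-", b_aln = "-G",
                         a_idx = c(1L, 0L), b_idx = c(0L, 1L),
                         score = 0, matrix = blosum62()),
                    class = "pairwise_alignment")
  st <- pairwise_stats(fake)
  expect_true(is.na(st[["identity"]]))
  expect_true(attr(st, "undefined"))
})

test_that("invalid residues are rejected with the offending character", {
  expect_error(pairwise_global_align("ACBJ", "ACDE"), "B")
})
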