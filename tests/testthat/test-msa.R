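# MSA construction, merging and trimming.

test_that("progressive alignment handles degenerate inputs", {
  one <- progressive_msa(c(s1 = "ACDEFG"))
  expect_equal(one$seqs, "ACDEFG")
  expect_equal(one$n_cols, 6L)

  three <- progressive_msa(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL",
                             c = "ACDEFGHIKL"))
  expect_equal(three$n_cols, 10L)
  expect_false(any(grepl("-", three$seqs, fixed = TRUE)))
})

test_that("progressive alignment recovers the true site pairing at
           shallow divergence", {
  pair_recovery <- function(est, truth, ids) {
    tm <- do.call(rbind, strsplit(truth$seqs[match(ids, truth$ids)], ""))
    em <- do.call(rbind, strsplit(est$seqs[match(ids, est$ids)], ""))
    accs <- c()
    for (r1 in 1:(length(ids) - 1)) for (r2 in (r1 + 1):length(ids)) {
      both_t <- which(tm[r1, ] != "-" & tm[r2, ] != "-")
      idx1 <- cumsum(tm[r1, ] != "-")
      idx2 <- cumsum(tm[r2, ] != "-")
      true_pairs <- paste(idx1[both_t], idx2[both_t])
      both_e <- which(em[r1, ] != "-" & em[r2, ] != "-")
      e1 <- cumsum(em[r1, ] != "-")
      e2 <- cumsum(em[r2, ] != "-")
      est_pairs <- paste(e1[both_e], e2[both_e])
      accs <- c(accs, mean(true_pairs %in% est_pairs))
    }
    accs
  }
  # without indels the alignment is exactly recoverable
  cfg0 <- small_sim_config(seed = 4, species_tree_depth = 0.4,
                           clade_split_depths = c(0.1, 0.2),
                           indel_rate = 0, p_loss = 0, p_lineage_dup = 0)
  ds0 <- simulate_dataset(cfg0)
  fam <- ds0$history$leaves[1]
  truth0 <- truth_msa(ds0, fam)
  ids0 <- truth0$ids[1:5]
  seqs0 <- vapply(ids0, function(pid) {
    tx <- ds0$truth$taxon[ds0$truth$protein_id == pid]
    ds0$proteomes[[tx]][[pid]]
  }, character(1))
  expect_true(all(pair_recovery(progressive_msa(seqs0), truth0,
                                ids0) == 1))
  # with indels, placement is ambiguous between equivalent-scoring gaps;
  # nearly all true homologous pairs must still be recovered
  cfg1 <- small_sim_config(seed = 4, species_tree_depth = 0.4,
                           clade_split_depths = c(0.1, 0.2),
                           indel_rate = 0.004, p_loss = 0,
                           p_lineage_dup = 0)
  ds1 <- simulate_dataset(cfg1)
  truth1 <- truth_msa(ds1, fam)
  ids1 <- truth1$ids[1:5]
  seqs1 <- vapply(ids1, function(pid) {
    tx <- ds1$truth$taxon[ds1$truth$protein_id == pid]
    ds1$proteomes[[tx]][[pid]]
  }, character(1))
  accs <- pair_recovery(progressive_msa(seqs1), truth1, ids1)
  expect_true(all(accs >= 0.9))
})

test_that("MSA-to-MSA alignment preserves within-MSA columns", {
  withr::with_seed(11, {
    base <- random_seq(40)
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(seq_along(ch), k)
      ch[pos] <- sample(profhom:::AA_ALPHABET, k, replace = TRUE)
      paste(ch, collapse = "")
    }
    msaA <- progressive_msa(c(a1 = base, a2 = mut(base, 6)))
    msaB <- progressive_msa(c(b1 = mut(base, 8), b2 = mut(base, 10),
                              b3 = mut(base, 5)))
    merged <- align_msa_to_msa(msaA, msaB)
    expect_equal(length(merged$ids), 5L)
    expect_equal(merged$ids, c(msaA$ids, msaB$ids))
    # restricting to msaA's rows and dropping gap-only columns recovers A
    m <- do.call(rbind, strsplit(merged$seqs[1:2], ""))
    keep <- colSums(m != "-") > 0
    back <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
    expect_equal(unname(back), msaA$seqs)
    # self-merge keeps the column count
    self <- align_msa_to_msa(msaA, msaA)
    expect_equal(self$n_cols, msaA$n_cols)
  })
})

test_that("gap-dominated columns are trimmed at the exact boundary", {
  # column 1: 4/5 gaps (= 0.8, retained); column 2: residues
  m5 <- new_msa(paste0("s", 1:5),
                c("AC", "-C", "-C", "-C", "-C"))
  tr <- trim_gappy_columns(m5, 0.8)
  expect_equal(tr$n_cols, 2L)
  # 5/6 gaps (0.833) -> dropped
  m6 <- new_msa(paste0("s", 1:6), c("AC", "-C", "-C", "-C", "-C", "-C"))
  tr6 <- trim_gappy_columns(m6, 0.8)
  expect_equal(tr6$n_cols, 1L)
  expect_equal(attr(tr6, "kept_cols"), 2L)

  # gap-free MSA unchanged
  gf <- new_msa(c("x", "y"), c("ACDE", "ACDE"))
  expect_equal(trim_gappy_columns(gf)$seqs, gf$seqs)

  # counting check: 10 columns, 3 with gap fraction 0.9
  withr::with_seed(3, {
    rows <- replicate(10, paste(sample(c(profhom:::AA_ALPHABET), 10,
                                       TRUE), collapse = ""))
    m <- do.call(rbind, strsplit(rows, ""))
    m[1:9, c(2, 5, 8)] <- "-"
    msa <- new_msa(paste0("r", 1:10), apply(m, 1, paste, collapse = ""))
    expect_equal(trim_gappy_columns(msa, 0.8)$n_cols, 7L)
  })
})

test_that("aligned FASTA round-trips", {
  msa <- new_msa(c("a", "b"), c("AC-DE", "ACD-E"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_msa(msa, path)
  back <- read_msa(path)
  expect_equal(back$ids, msa$ids)
  expect_equal(back$seqs, msa$seqs)
})
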