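# Reciprocal orthology workflow.

test_that("enrichment degenerates gracefully", {
  withr::with_seed(51, {
    s <- random_seq(80)
    db <- code_proteome(c(seedp = s))
    # zero iterations: single-sequence profile
    r0 <- build_search_profile("seedp", s, db, iters = 0)
    expect_equal(r0$members, "seedp")
    expect_equal(r0$profile$n_seqs, 1L)
    # database containing only the seed: fixed point immediately
    r1 <- build_search_profile("seedp", s, db, iters = 3)
    expect_equal(r1$members, "seedp")
    expect_equal(r1$msa$ids, "seedp")
  })
})

test_that("forward best hits follow e-value and tie-break order", {
  hits <- data.frame(target_id = c("t1", "t2", "t3", "x1"),
                     score = c(50, 80, 80, 90),
                     p_value = c(1e-3, 1e-6, 1e-6, 1e-9),
                     e_value = c(0.1, 1e-4, 1e-4, 1e-7),
                     stringsAsFactors = FALSE)
  best <- forward_best_hit(hits, c("t1", "t2", "t3"), e_max = 1e-3)
  expect_equal(best$target_id, "t2")  # ties by score then id
  expect_null(forward_best_hit(hits, c("t1"), e_max = 1e-5))
  expect_null(forward_best_hit(hits, c("t1", "t2", "t3"), e_max = 0))
})

test_that("reciprocal check accepts the seed-only proteome and rejects
           planted paralog confusion", {
  withr::with_seed(52, {
    s <- random_seq(120)
    db <- code_proteome(c(seedp = s))
    rc <- reciprocal_check("seedp", db, "seedp", "seedp",
                           recip_iters = 1)
    expect_equal(rc$status, "reciprocal_ok")
    expect_error(reciprocal_check("seedp", db, character(0), "seedp"),
                 "empty seed proteome")
    # two identical sequences in two taxa: reciprocal both ways
    db2 <- code_proteome(c(a1 = s, b1 = s))
    expect_equal(reciprocal_check("b1", db2, "a1", "a1",
                                  recip_iters = 1)$status,
                 "reciprocal_ok")
    expect_equal(reciprocal_check("a1", db2, "b1", "b1",
                                  recip_iters = 1)$status,
                 "reciprocal_ok")
    # paralog confusion: the seed proteome contains a closer relative of
    # the hit than the original query, so the back search must fail
    mut <- function(x, k) {
      ch <- strsplit(x, "")[[1]]
      pos <- sample(seq_along(ch), k)
      ch[pos] <- sample(profhom:::AA_ALPHABET, k, replace = TRUE)
      paste(ch, collapse = "")
    }
    anc <- random_seq(120)
    paralog <- mut(anc, 18)
    hit <- mut(paralog, 6)       # hit descends from the paralog
    seedq <- mut(anc, 60)        # the query is far from the hit
    db3 <- code_proteome(c(q = seedq, par = paralog, h = hit))
    rc3 <- reciprocal_check("h", db3, c("q", "par"), "q",
                            recip_iters = 1)
    expect_equal(rc3$status, "reciprocal_fail")
    expect_equal(rc3$back_hit, "par")
  })
})

test_that("single-sequence route enforces strict coverage > 40%", {
  withr::with_seed(53, {
    s <- random_seq(200)
    frag40 <- substr(s, 1, 80)    # exactly 40% of the query
    frag30 <- substr(s, 1, 60)
    ortho <- s
    db <- code_proteome(c(seedp = s, f40 = frag40, f30 = frag30,
                          ortho2 = ortho))
    # identical full-length ortholog: reciprocal ok
    r <- single_seq_reciprocal("seedp", "taxA", db, "ortho2", "taxB",
                               "seedp")
    expect_equal(r$status, "reciprocal_ok")
    expect_equal(r$target_id, "ortho2")
    # a fragment covering exactly 40% fails the strict threshold
    r40 <- single_seq_reciprocal("seedp", "taxA", db, "f40", "taxB",
                                 "seedp")
    expect_equal(r40$status, "absent")
    r30 <- single_seq_reciprocal("seedp", "taxA", db, "f30", "taxB",
                                 "seedp")
    expect_equal(r30$status, "absent")
  })
})

test_that("seed analyses combine by best e-value with conflict flags", {
  row <- function(fam, stax, tt, tid, e, method = "profile",
                  status = "reciprocal_ok") {
    data.frame(family = fam, seed_id = paste0(fam, "|", stax),
               seed_taxon = stax, target_taxon = tt, target_id = tid,
               e_value = e, method = method, status = status,
               stringsAsFactors = FALSE)
  }
  # single analysis: passthrough
  one <- combine_seed_analyses(row("f1", "s1", "t1", "p1", 1e-6))
  expect_equal(one$target_id, "p1")
  expect_equal(one$status, "reciprocal_ok")
  # three agreeing analyses: same target, min e recorded, method "both"
  three <- combine_seed_analyses(rbind(
    row("f1", "s1", "t1", "p1", 1e-6),
    row("f1", "s2", "t1", "p1", 1e-9, method = "single"),
    row("f1", "s3", "t1", "p1", 1e-3)))
  expect_equal(three$e_value, 1e-9)
  expect_equal(three$status, "reciprocal_ok")
  expect_equal(three$method, "both")
  # disagreement: lowest-e choice, flagged conflict
  conf <- combine_seed_analyses(rbind(
    row("f1", "s1", "t1", "p1", 1e-6),
    row("f1", "s2", "t1", "p2", 1e-4)))
  expect_equal(conf$target_id, "p1")
  expect_equal(conf$status, "conflict")
  # minimality: combined e-value never exceeds any single analysis
  expect_lte(conf$e_value, 1e-6)
  # all absent
  ab <- combine_seed_analyses(rbind(
    row("f1", "s1", "t1", NA_character_, NA, status = "absent"),
    row("f1", "s2", "t1", NA_character_, NA, status = "absent")))
  expect_equal(ab$status, "absent")
})

test_that("ortholog tables count co-orthologs and absences", {
  rows <- rbind(
    data.frame(family = "f1", seed_id = "a", seed_taxon = "s1",
               target_taxon = "t1", target_id = "p1", e_value = 1e-6,
               method = "profile", status = "reciprocal_ok", rank = 1L),
    data.frame(family = "f1", seed_id = "a", seed_taxon = "s1",
               target_taxon = "t1", target_id = "p1dup", e_value = 1e-5,
               method = "profile", status = "reciprocal_ok", rank = 2L),
    data.frame(family = "f2", seed_id = "b", seed_taxon = "s1",
               target_taxon = "t1", target_id = NA_character_,
               e_value = NA_real_, method = "profile", status = "absent",
               rank = 1L))
  tab <- build_ortholog_table(rows, families = c("f1", "f2"),
                              taxa = c("t1", "t2"))
  expect_equal(tab["f1", "t1"], 2L)   # lineage duplication -> 2
  expect_equal(tab["f2", "t1"], 0L)   # loss -> 0
  expect_equal(tab["f1", "t2"], 0L)
})

test_that("orthology is perfectly recovered in the zero-divergence limit", {
  cfg <- small_sim_config(seed = 12, sub_rate_scale = 1e-4, p_loss = 0,
                          p_lineage_dup = 0, n_taxa = 3)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth[ds$truth$taxon == "tax1", ]
  seeds <- data.frame(family = tr$family, seed_taxon = tr$taxon,
                      seed_id = tr$protein_id)
  seeds <- seeds[1:3, ]   # a subset of families keeps the test fast
  res <- run_orthology(ds$proteomes, seeds, seed = 77)
  ok <- res$combined[res$combined$status == "reciprocal_ok", ]
  # every (family, taxon) pair recovered with the true protein
  for (fam in seeds$family) {
    for (tx in names(ds$proteomes)) {
      row <- ok[ok$family == fam & ok$target_taxon == tx, ]
      expect_equal(nrow(row), 1L, info = paste(fam, tx))
      expect_equal(ds$truth$family[ds$truth$protein_id == row$target_id],
                   fam, info = paste(fam, tx))
    }
  }
  # precision: nothing assigned outside the true family
  all_ok <- res$per_seed[res$per_seed$status == "reciprocal_ok", ]
  fams <- ds$truth$family[match(all_ok$target_id, ds$truth$protein_id)]
  expect_true(all(fams == all_ok$family))
})
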