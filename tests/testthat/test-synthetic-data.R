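# Duplication-history simulation and sequence evolution.

test_that("the default history has the tetramer structure", {
  h <- simulate_history(sim_config())
  expect_equal(sort(unique(h$labels$class)),
               c("g51", "g52", "g53", "g54"))
  # exactly one complex carries only the g53/g54 half
  tab <- table(h$labels$complex)
  half <- names(tab)[tab == 2]
  expect_equal(length(half), 1L)
  expect_equal(sort(h$labels$class[h$labels$complex == half]),
               c("g53", "g54"))
  expect_equal(sum(tab == 4), 5L)
  expect_equal(length(h$leaves), 22L)
  # event times decrease from the root
  expect_equal(h$events$time[h$events$event_kind == "dimer_origin"], 1)
  expect_true(all(h$events$time <= 1 & h$events$time > 0))
  # the g53/g54 split is the shallowest inter-class split
  dd <- h$events[h$events$event_kind == "dimer_duplication", ]
  expect_lt(dd$time[dd$children == "g53+g54"],
            dd$time[dd$children == "g51+g52"])
  expect_true(any(h$events$event_kind == "subunit_loss"))
})

test_that("degenerate configurations simulate", {
  cfg <- sim_config(classes = "g53", complexes = "C1", half_complex = NULL)
  h <- simulate_history(cfg)
  expect_equal(h$leaves, "C1_g53")
  expect_match(h$newick, "C1_g53")
})

test_that("inconsistent depths raise configuration errors", {
  expect_error(sim_config(complex_radiation = c(0.2, 1.1)),
               "configuration error")
  expect_error(sim_config(class_split_depths = list(root = 1.0,
                                                    g51_g52 = 1.5,
                                                    g53_g54 = 0.9)),
               "configuration error")
  expect_error(sim_config(p_loss = 1.2), "configuration error")
})

test_that("simulation is deterministic and sensitive to the seed", {
  cfg <- small_sim_config(seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$proteomes, d2$proteomes)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(small_sim_config(seed = 10))
  expect_false(identical(d1$proteomes, d3$proteomes))
})

test_that("the no-mutation limit reproduces the seed sequences", {
  cfg <- small_sim_config(seed = 2, sub_rate_scale = 0, p_loss = 0,
                          p_lineage_dup = 0)
  ds <- simulate_dataset(cfg)
  for (fam in ds$history$leaves[1:3]) {
    ids <- ds$truth$protein_id[ds$truth$family == fam]
    seqs <- vapply(ids, function(pid) {
      tx <- ds$truth$taxon[ds$truth$protein_id == pid]
      ds$proteomes[[tx]][[pid]]
    }, character(1))
    expect_equal(length(unique(seqs)), 1L, info = fam)
  }
})

test_that("losses and duplications are recorded consistently", {
  ds <- simulate_dataset(sim_config(seed = 1))
  # every taxon misses at least one family at the default loss rate
  fam_by_taxon <- table(ds$truth$taxon[ds$truth$events == ""])
  n_fam <- length(ds$history$leaves)
  expect_true(all(fam_by_taxon < n_fam))
  expect_equal(sort(unique(ds$losses$taxon)), sort(names(ds$proteomes)))
  # truth rows match the proteome content exactly
  expect_equal(sum(lengths(ds$proteomes)), nrow(ds$truth))
  dups <- ds$truth[ds$truth$events == "lineage_dup", ]
  expect_true(all(grepl("\\|d2$", dups$protein_id)))
})

test_that("mean ortholog identity is non-increasing in tree depth", {
  meds <- vapply(c(0.6, 1.5, 3.0), function(d) {
    cfg <- small_sim_config(seed = 5, species_tree_depth = d,
                            clade_split_depths = c(0.1, 0.25),
                            p_loss = 0, p_lineage_dup = 0)
    mean(ortholog_identity_stats(simulate_dataset(cfg))$identity)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("datasets round-trip through disk", {
  ds <- simulate_dataset(small_sim_config(seed = 3, n_taxa = 3))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_equal(length(list.files(dir, pattern = "\\.fasta$")), 3L)
  back <- read_dataset(dir)
  expect_equal(back$proteomes, ds$proteomes)
  expect_equal(back$truth$protein_id, ds$truth$protein_id)
  expect_equal(back$truth$family, ds$truth$family)
  expect_equal(back$history$newick, ds$history$newick)
  # truth.tsv row count equals the total protein count
  tt <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tt), sum(lengths(ds$proteomes)))
  # byte-identical rewrite
  dir2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(small_sim_config(seed = 3, n_taxa = 3)),
                dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})

test_that("the site genealogy reconstructs a valid truth MSA", {
  ds <- simulate_dataset(small_sim_config(seed = 8))
  fam <- ds$history$leaves[2]
  msa <- truth_msa(ds, fam)
  ids <- ds$truth$protein_id[ds$truth$family == fam]
  expect_setequal(msa$ids, ids)
  # degapped rows equal the proteome sequences
  for (i in seq_along(msa$ids)) {
    pid <- msa$ids[i]
    tx <- ds$truth$taxon[ds$truth$protein_id == pid]
    expect_equal(gsub("-", "", msa$seqs[i], fixed = TRUE),
                 unname(ds$proteomes[[tx]][[pid]]))
  }
})
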