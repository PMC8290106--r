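# Heptad coiled-coil scoring and masking.

test_that("ideal heptad repeats score as coiled coil, poly-G does not", {
  ann <- cc_scores(ideal_heptad(8))
  expect_true(all(ann$prob > 0.9))
  gg <- cc_scores(paste(rep("G", 56), collapse = ""))
  expect_true(all(gg$prob < 0.1))
})

test_that("short sequences are scored with a shortened window", {
  one <- cc_scores("L")
  expect_equal(length(one$prob), 1L)
  expect_false(is.na(one$prob))
  short <- cc_scores(substr(ideal_heptad(2), 1, 10))
  expect_equal(length(short$prob), 10L)
})

test_that("masking obeys the threshold and is monotone in it", {
  seq <- paste0(ideal_heptad(6), random_seq(80, seed = 21))
  masked <- cc_mask(seq, threshold = 0.5)
  expect_equal(masked$n_cc_residues, sum(masked$prob > 0.5))
  expect_gte(masked$n_cc_residues, 0.9 * 42)
  expect_true(grepl("^X", masked$masked_seq))
  # monotone: higher threshold never masks more
  prev <- Inf
  for (th in c(0.2, 0.5, 0.8, 0.99)) {
    n <- cc_mask(seq, threshold = th)$n_cc_residues
    expect_lte(n, prev)
    prev <- n
  }
  expect_equal(cc_mask(seq, threshold = 1 - 1e-9)$n_cc_residues, 0L)
})

test_that("heptad order carries the signal: shuffles score lower", {
  seq <- ideal_heptad(8)
  obs <- mean(cc_scores(seq)$prob)
  ch <- strsplit(seq, "")[[1]]
  withr::with_seed(31, {
    null <- replicate(100, {
      mean(cc_scores(paste(sample(ch), collapse = ""))$prob)
    })
  })
  expect_gt(obs, max(null))
})

test_that("simulated proteins carry their coiled coil at the N-terminus", {
  ds <- simulate_dataset(small_sim_config(seed = 6))
  pid <- ds$truth$protein_id[1]
  tx <- ds$truth$taxon[1]
  ann <- cc_mask(list(id = pid, seq = ds$proteomes[[tx]][[pid]]))
  expect_gt(ann$n_cc_residues, 0)
  expect_lte(median(which(ann$mask)), 40)
})

test_that("invalid residues are named in the error", {
  expect_error(cc_scores("ACDZ"), "Z")
})
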