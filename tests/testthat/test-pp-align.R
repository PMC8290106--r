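# Profile-profile local alignment and empirical significance.

test_that("one-hot identical columns score 2*log2(1/b) and self-hits
           dominate", {
  bg <- aa_background()
  p <- onehot_profile(c("L", "K", "W"), "q")
  hit <- pp_local_align(p, p)
  # the W column alone scores 2*log2(1/b_W)
  pw <- onehot_profile("W", "w")
  hw <- pp_local_align(pw, pw)
  expect_equal(hw$score, 2 * log2(1 / bg[["W"]]), tolerance = 1e-9)
  # self-hit dominates hits against other profiles
  others <- list(onehot_profile(c("A", "C", "D"), "o1"),
                 onehot_profile(c("E", "F", "G"), "o2"))
  for (o in others)
    expect_gt(hit$score, pp_local_align(p, o)$score)
  expect_equal(hit$q_start, 1L)
  expect_equal(hit$q_end, 3L)
})

test_that("profile-profile local score matches exhaustive enumeration", {
  withr::with_seed(202, {
    for (case in 1:40) {
      n <- sample(2:5, 1)
      m <- sample(2:5, 1)
      S <- matrix(rnorm(n * m, 0, 4), n, m)
      gs1 <- runif(n, 0.4, 1)
      gs2 <- runif(m, 0.4, 1)
      got <- profhom:::dp_scoremat_cpp(S, gs1, gs2, 4, 1, TRUE,
                                       FALSE)$score
      expect_equal(got, oracle_local(S, 4, 1, gs1, gs2),
                   tolerance = 1e-9, info = paste("case", case))
    }
  })
})

test_that("profile-profile scores are symmetric", {
  withr::with_seed(17, {
    for (i in 1:8) {
      msa1 <- progressive_msa(c(a = random_seq(50), b = random_seq(50)))
      msa2 <- progressive_msa(c(c = random_seq(45), d = random_seq(45)))
      p1 <- build_profile(msa1, source_id = "p1")
      p2 <- build_profile(msa2, source_id = "p2")
      s12 <- pp_local_align(p1, p2)$score
      s21 <- pp_local_align(p2, p1)$score
      expect_equal(s12, s21, tolerance = 1e-6)
    }
  })
})

test_that("empirical p-values respect the rank-based floor and ceiling", {
  withr::with_seed(5, {
    p1 <- seq_profile(random_seq(40), "q")
    p2 <- seq_profile(random_seq(40), "t")
    hit <- empirical_significance(p1, p2, n_shuffles = 19, seed = 3)
    expect_gte(hit$p_value, 1 / 20)
    expect_lte(hit$p_value, 1)
    # a hit below all nulls gets p = 1: force with a zero-score hit
    fake <- pp_local_align(p1, p2)
    fake$score <- -1
    h2 <- empirical_significance(p1, p2, n_shuffles = 19, seed = 3,
                                 hit = fake)
    expect_equal(h2$p_value, 1)
    expect_error(empirical_significance(p1, p2, n_shuffles = 5),
                 "n_shuffles")
  })
})

test_that("identical profiles give the minimal empirical p", {
  withr::with_seed(6, {
    p1 <- seq_profile(random_seq(60), "q")
    hit <- empirical_significance(p1, p1, n_shuffles = 39, seed = 8,
                                  n_targets = 10)
    expect_equal(hit$p_value, 1 / 40)
    expect_equal(hit$e_value, 10 / 40)
  })
})
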