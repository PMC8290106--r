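# Shared fixtures: reduced simulation configurations and small profiles.

# small, fast simulation (3 complexes, shorter proteins) for unit tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seq_length = 260L, cc_length = 28L,
             complexes = c("C1", "C2", "C3"), seed = seed, ...)
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(profhom:::AA_ALPHABET, n, replace = TRUE,
                                  prob = aa_background()), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a profile with given one-hot columns
onehot_profile <- function(residues, id = "p", pseudocount = 0) {
  seq <- paste(residues, collapse = "")
  seq_profile(seq, id, pseudocount_weight = pseudocount)
}

# ideal heptad repeat built from the propensity table itself
ideal_heptad <- function(n_repeats = 8) {
  tab <- profhom:::CC_PROPENSITY
  unit <- vapply(1:7, function(p) rownames(tab)[which.max(tab[, p])],
                 character(1))
  paste(rep(unit, n_repeats), collapse = "")
}
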