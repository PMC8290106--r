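# Database search machinery: a query (profile or single sequence) scanned
# against a set of single sequences, with e-values calibrated on a
# shuffle null.
#
# Scoring a profile against a single pseudocounted sequence profile
# reduces to a position-specific scoring matrix lookup: with target
# frequencies f2 = (1[a] + w*b) / (1 + w), the co-emission score
# sum_a f1_a f2_a / b_a collapses to (f1[a]/b[a] + w) / (1 + w), so the
# whole database scan runs as sequence-vs-PSSM Smith-Waterman. E-values
# come from a Gumbel (type-I extreme value) fit, by the method of
# moments, to the scores of column-shuffled queries against a
# deterministic subsample of the database - the standard calibration for
# local-alignment score maxima. The empirical rank-based p-value of
# [empirical_significance()] is exact but floored at 1/(n_shuffles + 1);
# the fitted tail is what makes small search thresholds meaningful.

#' Integer-code a proteome
#' @param proteome Named character vector of sequences.
#' @return Named list of integer vectors.
#' @export
code_proteome <- function(proteome) {
  lapply(proteome, aa_index)
}

# PSSM (20 x L, half-bits) for scoring single sequences against a profile
profile_pssm <- function(profile, pseudocount_weight = 0.1) {
  w <- pseudocount_weight
  t(2 * log2((sweep(profile$freqs, 2L, profile$background, "/") + w) /
               (1 + w)))
}

#' Search a profile against a sequence database
#'
#' Scores the profile against every target by local alignment and
#' calibrates e-values on a Gumbel fit to column-shuffled query scores
#' against a subsample of the database.
#'
#' @param profile A `profile` query.
#' @param db_codes Named list of integer-coded target sequences (see
#'   [code_proteome()]).
#' @param seed Seed for the shuffle null (deterministic searches).
#' @param n_null_targets,n_null_shuffles Null sample size: each shuffle is
#'   scored against this many subsampled targets.
#' @param gap_open,gap_extend,band Alignment parameters (band = banded DP
#'   half-width; 0 = full matrix).
#' @param pseudocount_weight Background admixture applied to the
#'   implicit single-sequence target profiles.
#' @param calibrate When `FALSE`, skip the null entirely and return
#'   score-ranked hits with `NA` significance (rank-1 by score equals
#'   rank-1 by e-value, so threshold-free reciprocal checks need no
#'   null).
#' @return Data frame (one row per target, sorted by decreasing score):
#'   `target_id`, `score`, `p_value` (Gumbel tail), `e_value`
#'   (`p * n_targets`).
#' @export
search_profile <- function(profile, db_codes, seed = 1L,
                           n_null_targets = 18L, n_null_shuffles = 1L,
                           gap_open = 10, gap_extend = 1, band = 64L,
                           pseudocount_weight = 1, calibrate = TRUE) {
  pssm <- profile_pssm(profile, pseudocount_weight)
  scores <- sw_pssm_batch_cpp(pssm, unname(db_codes), gap_open, gap_extend,
                              NULL, band)
  nt <- length(db_codes)
  if (!calibrate) {
    out <- data.frame(target_id = names(db_codes), score = scores,
                      p_value = NA_real_, e_value = NA_real_,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$target_id), ]
    rownames(out) <- NULL
    return(out)
  }
  nulls <- with_seed(child_seed(seed, profile$source_id), {
    idx <- if (nt <= n_null_targets) seq_len(nt)
      else sort(sample.int(nt, n_null_targets))
    out <- numeric(0)
    for (k in seq_len(n_null_shuffles)) {
      ord <- sample.int(profile$n_cols)
      out <- c(out, sw_pssm_batch_cpp(pssm, unname(db_codes[idx]),
                                      gap_open, gap_extend, ord, band))
    }
    out
  })
  fit <- gumbel_fit(nulls)
  p <- gumbel_tail(scores, fit)
  out <- data.frame(target_id = names(db_codes), score = scores,
                    p_value = p, e_value = p * nt,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target_id), ]
  rownames(out) <- NULL
  attr(out, "gumbel") <- fit
  out
}

#' Search a single sequence against a sequence database
#'
#' Global (Needleman-Wunsch) scoring of one query sequence against every
#' target, with the same shuffled-query Gumbel calibration as
#' [search_profile()].
#'
#' @param query_codes Integer-coded query sequence.
#' @param db_codes Named list of integer-coded targets.
#' @param seed Seed for the shuffle null.
#' @inheritParams search_profile
#' @param matrix Substitution matrix.
#' @param query_id Used to derive the null seed.
#' @return Data frame as in [search_profile()].
#' @export
search_sequence <- function(query_codes, db_codes, seed = 1L,
                            query_id = "query", matrix = blosum62(),
                            n_null_targets = 18L, n_null_shuffles = 1L,
                            gap_open = 10, gap_extend = 1, band = 64L) {
  scores <- nw_batch_cpp(query_codes, unname(db_codes), matrix, gap_open,
                         gap_extend, NULL, band)
  nt <- length(db_codes)
  nulls <- with_seed(child_seed(seed, query_id), {
    idx <- if (nt <= n_null_targets) seq_len(nt)
      else sort(sample.int(nt, n_null_targets))
    out <- numeric(0)
    for (k in seq_len(n_null_shuffles)) {
      ord <- sample.int(length(query_codes))
      out <- c(out, nw_batch_cpp(query_codes, unname(db_codes[idx]),
                                 matrix, gap_open, gap_extend, ord, band))
    }
    out
  })
  fit <- gumbel_fit(nulls)
  p <- gumbel_tail(scores, fit)
  out <- data.frame(target_id = names(db_codes), score = scores,
                    p_value = p, e_value = p * nt,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target_id), ]
  rownames(out) <- NULL
  attr(out, "gumbel") <- fit
  out
}

# align one additional ungapped sequence into an MSA (profile-to-sequence
# global alignment via the PSSM shortcut)
.align_msa_seq <- function(msa, id, seq, gap_open = 10, gap_extend = 1,
                           pseudocount_weight = 1, band = 64L) {
  prof <- build_profile(msa, pseudocount_weight = pseudocount_weight)
  codes <- aa_index(seq)
  pssm <- profile_pssm(prof, pseudocount_weight)
  S <- t(pssm[codes, , drop = FALSE])  # n_cols x target length
  res <- dp_scoremat_cpp(S, 1 - prof$gap_frac, rep(1, length(codes)),
                         gap_open, gap_extend, FALSE, TRUE, NULL,
                         max(band, abs(prof$n_cols - length(codes)) + 30L))
  ma <- .msa_char_matrix(msa)
  cb <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n_out <- length(res$a_idx)
  out <- matrix("-", nrow(ma) + 1L, n_out)
  sel <- res$a_idx > 0L
  out[seq_len(nrow(ma)), sel] <- ma[, res$a_idx[sel], drop = FALSE]
  selb <- res$b_idx > 0L
  out[nrow(ma) + 1L, selb] <- cb[res$b_idx[selb]]
  new_msa(c(msa$ids, id), apply(out, 1L, paste, collapse = ""))
}
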