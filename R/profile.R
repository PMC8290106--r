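# Column-frequency profiles and profile-profile local alignment.
#
# A profile is the package's stand-in for a profile HMM: per-column
# pseudocounted residue frequencies plus per-column gap fractions. Profile
# comparison is Smith-Waterman over the log-odds co-emission score
#   s(i, j) = 2 * log2( sum_a f1_ia * f2_ja / b_a )   (half-bits),
# with affine gap costs scaled down in columns that are already gappy in
# the source MSA.

#' Build a frequency profile from an MSA
#'
#' Per column, residue counts (gaps and masked `X` residues excluded) are
#' mixed with the background: `(counts + w * background) / (n_obs + w)`
#' where `n_obs` is the number of observed residues in that column. Columns
#' with no observed residue carry plain background frequencies (a warning
#' is issued for all-gap columns). An optional coiled-coil mask (per-row
#' logical vectors over unaligned positions) excludes masked residues from
#' the counts exactly like `X`.
#'
#' @param msa An `msa` object.
#' @param pseudocount_weight Background admixture weight (default 0.1).
#' @param cc_mask Optional named list (by row id) of per-residue logical
#'   vectors from [cc_mask()]; `TRUE` positions are excluded.
#' @param background Residue background; defaults to [aa_background()].
#' @param source_id Identifier recorded on the profile.
#' @return An object of class `profile` with fields `source_id`, `n_cols`,
#'   `freqs` (n_cols x 20), `gap_frac`, `background`, `n_seqs`,
#'   `masked_cols` (columns carrying background because every residue was
#'   masked).
#' @export
build_profile <- function(msa, pseudocount_weight = 0.1, cc_mask = NULL,
                          background = aa_background(),
                          source_id = msa$ids[1L]) {
  stopifnot(inherits(msa, "msa"))
  m <- .msa_char_matrix(msa)
  if (!is.null(cc_mask)) {
    for (r in seq_along(msa$ids)) {
      mk <- cc_mask[[msa$ids[r]]]
      if (is.null(mk)) next
      pos <- 0L
      for (cl in seq_len(ncol(m))) {
        if (m[r, cl] != "-") {
          pos <- pos + 1L
          if (pos <= length(mk) && mk[pos]) m[r, cl] <- "X"
        }
      }
    }
  }
  L <- ncol(m)
  gap_frac <- colMeans(m == "-")
  obs <- m != "-" & m != "X"
  idx <- match(m[obs], AA_ALPHABET)
  if (anyNA(idx)) stop("invalid residue character(s): ",
                       paste(unique(m[obs][is.na(idx)]), collapse = ", "))
  cols <- col(m)[obs]
  counts <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  tab <- table(factor(cols, levels = seq_len(L)), factor(idx, levels = 1:20))
  counts[] <- as.numeric(tab)
  n_obs <- as.integer(rowSums(counts))
  freqs <- (counts + pseudocount_weight * rep(background, each = L)) /
    (n_obs + pseudocount_weight)
  empty <- n_obs == 0L
  if (any(empty)) freqs[empty, ] <- rep(unname(background),
                                        each = sum(empty))
  dimnames(freqs) <- list(NULL, AA_ALPHABET)
  all_gap <- sum(empty & gap_frac == 1)
  if (all_gap > 0L)
    warning(all_gap, " all-gap column(s) set to background frequencies")
  structure(list(source_id = source_id, n_cols = L, freqs = freqs,
                 gap_frac = gap_frac, background = background,
                 n_seqs = length(msa$ids), n_obs = n_obs,
                 masked_cols = which(n_obs == 0L & gap_frac < 1)),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("profile", x$source_id, ":", x$n_cols, "columns from", x$n_seqs,
      "sequence(s)\n")
  invisible(x)
}

#' Single-sequence profile
#'
#' Convenience wrapper building a profile from one ungapped sequence.
#' @param seq Amino-acid string (may contain `X` for masked residues).
#' @param id Profile identifier.
#' @inheritParams build_profile
#' @return A `profile`.
#' @export
seq_profile <- function(seq, id, pseudocount_weight = 0.1,
                        background = aa_background()) {
  build_profile(new_msa(id, seq), pseudocount_weight = pseudocount_weight,
                background = background, source_id = id)
}

#' Co-emission score matrix between two profiles (half-bits)
#' @param p1,p2 `profile` objects (matching backgrounds assumed).
#' @return Matrix of `2 * log2(sum_a f1_ia * f2_ja / b_a)` values.
#' @export
pp_cell_scores <- function(p1, p2) {
  w2 <- sweep(p2$freqs, 2L, p1$background, "/")
  s <- tcrossprod(p1$freqs, w2)
  2 * log2(pmax(s, 1e-12))
}

.empty_hit <- function(qid, tid) {
  data.frame(query_id = qid, target_id = tid, score = 0, p_value = NA_real_,
             e_value = NA_real_, q_start = 0L, q_end = 0L, t_start = 0L,
             t_end = 0L, aln_len = 0L, n_pairs = 0L, q_coverage = 0,
             stringsAsFactors = FALSE)
}

#' Profile-profile local alignment
#'
#' Smith-Waterman over the co-emission score with affine gap costs; the
#' cost of aligning a profile column to a gap is scaled by `1 -` that
#' column's gap fraction, so columns that are already gappy in their source
#' MSA are cheap to skip. An empty optimal alignment yields score 0 and
#' empty spans.
#'
#' @param p1,p2 `profile` objects (query, target).
#' @param gap_open,gap_extend Gap penalties (half-bits).
#' @return One-row data frame: ids, `score`, placeholder `p_value` and
#'   `e_value` (see [empirical_significance()]), 1-based inclusive spans
#'   `q_start`/`q_end`/`t_start`/`t_end`, `aln_len` (alignment columns),
#'   `n_pairs` (gapless pairs) and `q_coverage` (query span / query
#'   length).
#' @export
pp_local_align <- function(p1, p2, gap_open = 10, gap_extend = 1) {
  S <- pp_cell_scores(p1, p2)
  res <- dp_scoremat_cpp(S, 1 - p1$gap_frac, 1 - p2$gap_frac, gap_open,
                         gap_extend, TRUE, TRUE)
  if (res$score <= 0) return(.empty_hit(p1$source_id, p2$source_id))
  data.frame(query_id = p1$source_id, target_id = p2$source_id,
             score = res$score, p_value = NA_real_, e_value = NA_real_,
             q_start = res$q_start, q_end = res$q_end,
             t_start = res$t_start, t_end = res$t_end,
             aln_len = res$aln_len, n_pairs = res$n_pairs,
             q_coverage = (res$q_end - res$q_start + 1L) / p1$n_cols,
             stringsAsFactors = FALSE)
}

#' Empirical significance of a profile-profile hit
#'
#' The null is generated by shuffling the column order of the target
#' profile (`n_shuffles` seeded permutations) and rescoring; the p-value is
#' the rank-based estimate `(1 + #{null >= observed}) / (n_shuffles + 1)`,
#' so it is bounded below by `1 / (n_shuffles + 1)`. The e-value is the
#' Bonferroni scale-up `p * n_targets`.
#'
#' @param p1,p2 `profile` objects.
#' @param n_shuffles Number of column shuffles (>= 19).
#' @param seed Integer seed for the permutations.
#' @param n_targets Number of targets in the search the hit came from.
#' @param hit Optional precomputed [pp_local_align()] row to fill in.
#' @param gap_open,gap_extend Gap penalties.
#' @return The hit row with `p_value` and `e_value` filled; attribute
#'   `null_scores` carries the null sample.
#' @export
empirical_significance <- function(p1, p2, n_shuffles = 200, seed = 1L,
                                   n_targets = 1L, hit = NULL,
                                   gap_open = 10, gap_extend = 1) {
  stopifnot(n_shuffles >= 19L)
  if (is.null(hit)) hit <- pp_local_align(p1, p2, gap_open, gap_extend)
  S <- pp_cell_scores(p1, p2)
  gs1 <- 1 - p1$gap_frac
  gs2 <- 1 - p2$gap_frac
  null_scores <- numeric(n_shuffles)
  with_seed(seed, {
    for (k in seq_len(n_shuffles)) {
      perm <- sample.int(p2$n_cols)
      null_scores[k] <- dp_scoremat_cpp(S, gs1, gs2, gap_open, gap_extend,
                                        TRUE, FALSE, perm)$score
    }
  })
  p <- (1 + sum(null_scores >= hit$score)) / (n_shuffles + 1)
  hit$p_value <- p
  hit$e_value <- p * n_targets
  attr(hit, "null_scores") <- null_scores
  hit
}

#' Serialize / read a profile as tab-separated text
#'
#' Header lines (`# key value`) carry `source_id`, `n_seqs` and the
#' background; then one row per column: index, gap fraction, observed
#' count, 20 residue frequencies.
#' @param profile A `profile`.
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` a
#'   `profile`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# source_id", profile$source_id),
    paste("# n_seqs", profile$n_seqs),
    paste("# background", paste(formatC(profile$background, digits = 10,
                                        format = "g"), collapse = " ")),
    paste(c("col", "gap_frac", "n_obs", AA_ALPHABET), collapse = "\t")),
    con)
  df <- data.frame(seq_len(profile$n_cols),
                   formatC(profile$gap_frac, digits = 10, format = "g"),
                   profile$n_obs)
  for (k in 1:20) df[[k + 3L]] <- formatC(profile$freqs[, k], digits = 10,
                                          format = "g")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- function(key) sub(paste0("# ", key, " "), "",
                          hdr[startsWith(hdr, paste0("# ", key, " "))])
  body <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t")
  freqs <- as.matrix(body[, 4:23])
  dimnames(freqs) <- list(NULL, AA_ALPHABET)
  bg <- as.numeric(strsplit(kv("background"), " ")[[1]])
  names(bg) <- AA_ALPHABET
  n_obs <- as.integer(body$n_obs)
  structure(list(source_id = kv("source_id"), n_cols = nrow(body),
                 freqs = freqs, gap_frac = as.numeric(body$gap_frac),
                 background = bg, n_seqs = as.integer(kv("n_seqs")),
                 n_obs = n_obs,
                 masked_cols = which(n_obs == 0L & body$gap_frac < 1)),
            class = "profile")
}
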