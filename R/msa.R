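# Multiple sequence alignments: construction, merging, trimming, I/O.

#' Construct an MSA object
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Gapped sequences (gap character `-`), all the same length.
#' @return An object of class `msa` with fields `ids`, `seqs`, `n_cols`.
#' @export
new_msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L) stop("all MSA rows must have equal length")
  structure(list(ids = as.character(ids), seqs = unname(toupper(seqs)),
                 n_cols = as.integer(nc)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", length(x$ids), "rows x", x$n_cols, "columns\n")
  invisible(x)
}

.msa_char_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
}

#' Drop columns dominated by gaps
#'
#' Removes exactly the columns whose gap fraction strictly exceeds
#' `max_gap_frac` (a column at the boundary is retained). Row order is
#' preserved.
#'
#' @param msa An `msa` object.
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.8).
#' @return The trimmed `msa`; attribute `kept_cols` holds the retained
#'   original column indices.
#' @export
trim_gappy_columns <- function(msa, max_gap_frac = 0.8) {
  stopifnot(inherits(msa, "msa"))
  m <- .msa_char_matrix(msa)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  out <- new_msa(msa$ids, apply(m[, keep, drop = FALSE], 1L, paste,
                                collapse = ""))
  attr(out, "kept_cols") <- keep
  out
}

#' Align two MSAs column-wise (profile-profile global alignment)
#'
#' Aligns the column profiles of `msaA` and `msaB` globally with affine
#' gaps; existing within-MSA columns are never broken, only whole-column
#' gaps are inserted.
#'
#' @param msaA,msaB `msa` objects.
#' @param gap_open,gap_extend Gap penalties (half-bits).
#' @param pseudocount_weight Pseudocount weight for the merge profiles.
#' @return A merged `msa` containing the rows of `msaA` then `msaB`.
#' @export
align_msa_to_msa <- function(msaA, msaB, gap_open = 10, gap_extend = 1,
                             pseudocount_weight = 1) {
  stopifnot(inherits(msaA, "msa"), inherits(msaB, "msa"))
  p1 <- build_profile(msaA, pseudocount_weight = pseudocount_weight)
  p2 <- build_profile(msaB, pseudocount_weight = pseudocount_weight)
  S <- pp_cell_scores(p1, p2)
  res <- dp_scoremat_cpp(S, 1 - p1$gap_frac, 1 - p2$gap_frac,
                         gap_open, gap_extend, FALSE, TRUE)
  ma <- .msa_char_matrix(msaA)
  mb <- .msa_char_matrix(msaB)
  n_out <- length(res$a_idx)
  take <- function(m, idx) {
    out <- matrix("-", nrow(m), n_out)
    sel <- idx > 0L
    out[, sel] <- m[, idx[sel], drop = FALSE]
    out
  }
  merged <- rbind(take(ma, res$a_idx), take(mb, res$b_idx))
  new_msa(c(msaA$ids, msaB$ids), apply(merged, 1L, paste, collapse = ""))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by average-linkage clustering of pairwise global
#' alignment distances (1 - fractional identity) and merges alignments
#' leaf-to-root with profile-profile global alignment. A single sequence is
#' returned unchanged.
#'
#' @param seqs Named character vector of ungapped sequences (names become
#'   row ids), or a list of records with `$id` and `$seq`.
#' @param gap_open,gap_extend Gap penalties.
#' @param pseudocount_weight Passed to the merge profiles.
#' @return An `msa` object.
#' @export
progressive_msa <- function(seqs, gap_open = 10, gap_extend = 1,
                            pseudocount_weight = 1) {
  if (is.list(seqs)) {
    ids <- vapply(seqs, function(x) x$id, character(1))
    seqs <- setNames(vapply(seqs, function(x) x$seq, character(1)), ids)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  n <- length(seqs)
  if (n == 1L) return(new_msa(names(seqs), unname(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- pairwise_global_align(seqs[[i]], seqs[[j]],
                                   gap_open = gap_open,
                                   gap_extend = gap_extend)
      st <- pairwise_stats(aln)
      idn <- if (is.na(st[["identity"]])) 0 else st[["identity"]] / 100
      d[i, j] <- d[j, i] <- 1 - idn
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  nodes <- vector("list", n - 1L)
  get_msa <- function(k) {
    if (k < 0L) new_msa(names(seqs)[-k], unname(seqs[-k])) else nodes[[k]]
  }
  for (step in seq_len(n - 1L)) {
    a <- get_msa(hc$merge[step, 1L])
    b <- get_msa(hc$merge[step, 2L])
    nodes[[step]] <- align_msa_to_msa(a, b, gap_open = gap_open,
                                      gap_extend = gap_extend,
                                      pseudocount_weight =
                                        pseudocount_weight)
  }
  nodes[[n - 1L]]
}

#' Read / write aligned FASTA
#'
#' @param msa An `msa` object.
#' @param path Output or input file path.
#' @return `write_msa` returns `path` invisibly; `read_msa` an `msa`.
#' @export
write_msa <- function(msa, path) {
  x <- Biostrings::BStringSet(setNames(msa$seqs, msa$ids))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_msa
#' @export
read_msa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  new_msa(names(x), as.character(x))
}
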