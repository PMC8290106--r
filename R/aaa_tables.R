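# Amino-acid alphabet, background frequencies and the substitution model.
#
# The 20-letter alphabet is kept in fixed alphabetical order everywhere;
# sequences are coded as integer indices into it. The substitution model is
# reconstructed from the BLOSUM62 log-odds matrix shipped with Biostrings:
# joint pair probabilities q_ab are recovered as p_a * p_b * 2^(S_ab/2)
# (BLOSUM62 is in half-bits) and renormalised; the background used across
# the package is the marginal of that joint, which makes the conditional
# replacement process exactly stationary with respect to it.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# standard BLOSUM62 residue frequencies (Henikoff & Henikoff), used only as
# the seed for reconstructing the joint; the package background is derived
# from the joint's marginals.
.BLOSUM62_SEED_FREQS <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

#' Convert an amino-acid string to integer codes
#'
#' @param seq A single character string over the 20-letter amino-acid
#'   alphabet. `X` is accepted when `allow_x = TRUE` and coded as `NA`.
#' @param allow_x Whether masked residues (`X`) are tolerated.
#' @return Integer vector of indices into [AA_ALPHABET] (`NA` for `X`).
#' @keywords internal
aa_index <- function(seq, allow_x = FALSE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- chars[is.na(idx)]
    if (allow_x) {
      ok <- bad == "X"
      if (all(ok)) return(idx)
      bad <- bad[!ok]
    }
    stop("invalid residue character(s): ", paste(unique(bad), collapse = ", "))
  }
  idx
}

#' The BLOSUM62 substitution matrix restricted to the 20-letter alphabet
#' @return 20 x 20 numeric matrix in [AA_ALPHABET] order (half-bit log-odds).
#' @export
blosum62 <- function() {
  if (is.null(.ph$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    storage.mode(m) <- "double"
    .ph$blosum62 <- m
  }
  .ph$blosum62
}

.aa_joint <- function() {
  if (is.null(.ph$joint)) {
    s <- blosum62()
    p <- .BLOSUM62_SEED_FREQS[AA_ALPHABET]
    q <- outer(p, p) * 2^(s / 2)
    q <- q / sum(q)
    .ph$joint <- q
  }
  .ph$joint
}

#' Background amino-acid frequencies used throughout the package
#'
#' Marginals of the off-diagonal BLOSUM62-derived joint pair
#' distribution; the stationary distribution of the simulator's
#' replacement process.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  if (is.null(.ph$background)) {
    q <- .aa_joint()
    diag(q) <- 0
    bg <- rowSums(q)
    .ph$background <- bg / sum(bg)
  }
  .ph$background
}

#' Conditional replacement probabilities P(b | a)
#'
#' Row-normalised off-diagonal BLOSUM62-derived joint: a replacement
#' event always changes the residue (branch lengths therefore read as
#' expected substitutions per site), but the replacement is biased
#' towards biochemically exchangeable residues. The symmetric joint
#' makes the process reversible with [aa_background()] as its
#' stationary distribution.
#' @return 20 x 20 stochastic matrix (rows sum to 1, zero diagonal).
#' @export
aa_conditional <- function() {
  if (is.null(.ph$conditional)) {
    q <- .aa_joint()
    diag(q) <- 0
    .ph$conditional <- q / rowSums(q)
  }
  .ph$conditional
}
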