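# Brute-force alignment oracles: exhaustive enumeration of alignment
# paths, scored directly from their gap-run structure. Deliberately
# independent of the package's dynamic-programming kernels.

# all global alignment paths of an n x m problem as move strings
# (D = diagonal, U = consume a, L = consume b)
enumerate_paths <- function(n, m) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(list(character(0)))
    out <- list()
    if (i > 0 && j > 0)
      out <- c(out, lapply(rec(i - 1, j - 1), function(p) c(p, "D")))
    if (i > 0)
      out <- c(out, lapply(rec(i - 1, j), function(p) c(p, "U")))
    if (j > 0)
      out <- c(out, lapply(rec(i, j - 1), function(p) c(p, "L")))
    out
  }
  rec(n, m)
}

# score one path: substitution scores on D moves; each maximal run of k
# consecutive U (or L) moves costs open + (k - 1) * ext
score_path <- function(path, a, b, sub, open, ext) {
  i <- 0; j <- 0
  s <- 0
  runs <- rle(path)
  for (r in seq_along(runs$values)) {
    mv <- runs$values[r]
    k <- runs$lengths[r]
    if (mv == "D") {
      for (q in seq_len(k)) {
        i <- i + 1; j <- j + 1
        s <- s + sub[a[i], b[j]]
      }
    } else {
      s <- s - (open + (k - 1) * ext)
      if (mv == "U") i <- i + k else j <- j + k
    }
  }
  s
}

oracle_global <- function(a, b, sub, open, ext) {
  paths <- enumerate_paths(length(a), length(b))
  max(vapply(paths, score_path, numeric(1), a = a, b = b, sub = sub,
             open = open, ext = ext))
}

# local alignment: best over all substring pairs, paths forced to start
# and end with a diagonal move; empty alignment scores 0
oracle_local <- function(S, open, ext, gs1 = rep(1, nrow(S)),
                         gs2 = rep(1, ncol(S))) {
  n <- nrow(S); m <- ncol(S)
  best <- 0
  score_local_path <- function(path, i0, j0) {
    i <- i0 - 1; j <- j0 - 1
    s <- 0
    runs <- rle(path)
    for (r in seq_along(runs$values)) {
      mv <- runs$values[r]
      k <- runs$lengths[r]
      if (mv == "D") {
        for (q in seq_len(k)) {
          i <- i + 1; j <- j + 1
          s <- s + S[i, j]
        }
      } else if (mv == "U") {
        for (q in seq_len(k)) {
          i <- i + 1
          s <- s - (if (q == 1) open else ext) * gs1[i]
        }
      } else {
        for (q in seq_len(k)) {
          j <- j + 1
          s <- s - (if (q == 1) open else ext) * gs2[j]
        }
      }
    }
    s
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m)) {
    for (i1 in i0:n) for (j1 in j0:m) {
      for (p in enumerate_paths(i1 - i0 + 1, j1 - j0 + 1)) {
        if (p[1] != "D" || p[length(p)] != "D") next
        best <- max(best, score_local_path(p, i0, j0))
      }
    }
  }
  best
}
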