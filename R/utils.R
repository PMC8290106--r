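# Small internal utilities.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG, evaluates `expr`, and restores the caller's RNG state so
#' package internals never perturb user-level random streams.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Derive a reproducible child seed from a base seed and a label.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 7919 + h %% 104729) %% 2147483587)
}

# Method-of-moments Gumbel fit; returns location mu and scale beta.
gumbel_fit <- function(x) {
  beta <- stats::sd(x) * sqrt(6) / pi
  if (!is.finite(beta) || beta <= 0) beta <- 1e-6
  mu <- mean(x) - 0.5772156649 * beta
  c(mu = mu, beta = beta)
}

# Upper-tail probability P(X >= s) for a Gumbel(mu, beta) maximum null.
gumbel_tail <- function(s, fit) {
  z <- (s - fit[["mu"]]) / fit[["beta"]]
  -expm1(-exp(-z))
}

.log_line <- function(log_con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  invisible(NULL)
}
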