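# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do
#' not disturb the global RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# abort with a message assembled from parts
stop2 <- function(...) stop(paste0(...), call. = FALSE)

# is x a single non-missing logical?
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# column-wise z-scores with sample (n-1) SD; zero-variance columns -> 0
zscore_cols <- function(M) {
  mu <- colMeans(M)
  s <- apply(M, 2L, sd)
  degenerate <- !is.finite(s) | s < .Machine$double.eps^0.5
  s[degenerate] <- 1
  Z <- sweep(sweep(M, 2L, mu, "-"), 2L, s, "/")
  Z[, degenerate] <- 0
  attr(Z, "degenerate") <- degenerate
  Z
}
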