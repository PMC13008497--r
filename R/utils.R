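# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Column-wise Pearson correlation between matched columns of two matrices.
# Returns NaN for zero-variance columns (callers decide how to flag).
#' @keywords internal
#' @noRd
col_pearson <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  cx <- sweep(x, 2L, colMeans(x), "-")
  cy <- sweep(y, 2L, colMeans(y), "-")
  num <- colSums(cx * cy)
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  r <- num / den
  r[!is.finite(r)] <- NA_real_
  r
}

#' @keywords internal
#' @noRd
col_ranks <- function(x) apply(x, 2L, rank)

#' @keywords internal
#' @noRd
col_spearman <- function(x, y) col_pearson(col_ranks(x), col_ranks(y))

# Two-sided Spearman p-values: exact permutation distribution (via cor.test)
# for n <= 9, t approximation on rho otherwise.
#' @keywords internal
#' @noRd
spearman_pvalue <- function(rho, x = NULL, y = NULL, n) {
  if (n <= 9L) {
    stopifnot(!is.null(x), !is.null(y))
    p <- vapply(seq_len(ncol(x)), function(j) {
      if (is.na(rho[j])) return(NA_real_)
      suppressWarnings(
        stats::cor.test(x[, j], y[, j], method = "spearman")$p.value
      )
    }, numeric(1))
    return(p)
  }
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[is.na(rho)] <- NA_real_
  pmin(p, 1)
}

#' @keywords internal
#' @noRd
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# Compact "a, b, c, ... (+k more)" for error messages naming offenders.
#' @keywords internal
#' @noRd
name_some <- function(x, limit = 5L) {
  x <- as.character(x)
  if (length(x) <= limit) return(paste(x, collapse = ", "))
  sprintf("%s, ... (+%d more)", paste(x[seq_len(limit)], collapse = ", "),
          length(x) - limit)
}
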