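# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators stay pure in (input, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stopf("`%s` must be a single finite number in [%s, %s]", name, min, max)
  invisible(x)
}

#' Library-size normalize a count matrix
#'
#' Scales each cell (row) to a fixed total count, then applies `log1p`. This is
#' the standard normalization applied before log-fold-change, Wilcoxon and
#' Moran's I computations throughout the package.
#'
#' @param counts numeric matrix, cells in rows, genes in columns.
#' @param scale target total per cell (default `1e4`).
#' @param log apply `log1p` after scaling (default `TRUE`).
#' @return matrix of the same shape. Cells with zero total counts are left at
#'   zero with a warning.
#' @export
normalize_expression <- function(counts, scale = 1e4, log = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- rowSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warnf("%d cell(s) have zero total counts; left as zeros", sum(zero))
    tot[zero] <- 1
  }
  out <- counts / tot * scale
  if (log) out <- log1p(out)
  out
}
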