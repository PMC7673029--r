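# Cluster/population frequency normalization, condition-change matrices and
# factorial testing of composition effects.

#' Column-normalize a count table to percentages
#'
#' Converts per-sample cluster frequencies to percentages by column
#' normalization, making samples of different depth comparable.
#'
#' @param counts numeric matrix (rows = populations/clusters, columns =
#'   samples), non-negative.
#' @return matrix of percentages; each column sums to 100. A zero-total
#'   column becomes `NA` with a warning.
#' @export
column_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warnf("column(s) with zero total: %s",
          paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
    tot[zero] <- NA_real_
  }
  sweep(counts, 2, tot, "/") * 100
}

#' Composition change between two conditions, in percentage points
#'
#' Entry-wise difference `b - a` of two percentage tables over the same
#' populations, the quantity plotted as a population-change heatmap.
#'
#' @param a,b percentage matrices (or tables from [column_normalize()]) with
#'   identical row sets; `a` is the baseline.
#' @param long return heatmap-ready long format (`population`, `column`,
#'   `change`) instead of a matrix.
#' @return change matrix (or long data frame) in absolute percentage points.
#' @export
composition_change <- function(a, b, long = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!setequal(rownames(a), rownames(b)) || is.null(rownames(a)))
    stopf("row sets differ: only in a: %s; only in b: %s",
          paste(setdiff(rownames(a), rownames(b)), collapse = ", "),
          paste(setdiff(rownames(b), rownames(a)), collapse = ", "))
  b <- b[rownames(a), , drop = FALSE]
  ch <- b - a
  if (!long) return(ch)
  data.frame(
    population = rep(rownames(ch), ncol(ch)),
    column = rep(colnames(ch) %||% as.character(seq_len(ncol(ch))),
                 each = nrow(ch)),
    change = as.vector(ch), stringsAsFactors = FALSE
  )
}

#' Sidak multiplicity adjustment
#'
#' `p' = 1 - (1 - p)^m` for a family of `m` comparisons.
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param m family size (default: `length(p)`).
#' @return adjusted p-values, always in `[p, min(1, m * p)]`.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  assert_scalar_number(m, "m", 1)
  1 - (1 - p)^m
}

#' Two-way ANOVA with Sidak-corrected pairwise comparisons
#'
#' Fits `value ~ A * B` on per-animal observations (e.g. a population's
#' percentage per animal, factors region and age or condition), reports
#' Type-II sums of squares per effect (appropriate for the unbalanced group
#' sizes typical of animal cohorts), and computes the requested pairwise
#' contrasts from the pooled residual variance: for cell means m1, m2 with n1,
#' n2 observations, `t = (m1 - m2) / sqrt(MSE * (1/n1 + 1/n2))` on the
#' model's residual degrees of freedom, with Sidak adjustment over the whole
#' comparison family.
#'
#' @param data data frame of observations.
#' @param response,factor_a,factor_b column names.
#' @param comparisons either `"within_a"` (default: all pairs of `factor_b`
#'   levels within each level of `factor_a`, the study's per-region
#'   age/condition contrasts), `"within_b"` (the converse), or a data frame
#'   with columns `a`, `b1`, `b2` naming explicit cells.
#' @return object of class `anova_result`: list with `effects` (term,
#'   sum_sq, df, statistic, p), `comparisons` (contrast table with raw and
#'   Sidak-adjusted p and the family size `m`), and the fitted `model`.
#' @export
two_way_anova_sidak <- function(data, response, factor_a, factor_b,
                                comparisons = "within_a") {
  data <- as.data.frame(data)
  for (v in c(response, factor_a, factor_b))
    if (!v %in% names(data)) stopf("column `%s` not found", v)
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stopf("both factors need at least 2 levels")
  y <- data[[response]]
  fit <- stats::lm(y ~ A * B)
  aov2 <- car::Anova(fit, type = 2)
  effects <- data.frame(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals"),
    sum_sq = aov2[["Sum Sq"]], df = aov2[["Df"]],
    statistic = aov2[["F value"]], p = aov2[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  dfres <- stats::df.residual(fit)

  if (is.character(comparisons) && length(comparisons) == 1L) {
    if (comparisons == "within_b") {  # swap roles, reuse the within_a builder
      tmp <- A; A <- B; B <- tmp
      lab <- c(factor_b, factor_a)
    } else if (comparisons == "within_a") {
      lab <- c(factor_a, factor_b)
    } else stopf("unknown comparisons mode `%s`", comparisons)
    pairs <- utils::combn(levels(B), 2)
    comparisons <- do.call(rbind, lapply(levels(A), function(al)
      data.frame(a = al, b1 = pairs[1, ], b2 = pairs[2, ],
                 stringsAsFactors = FALSE)))
  } else {
    lab <- c(factor_a, factor_b)
    comparisons <- as.data.frame(comparisons)
  }
  m <- nrow(comparisons)
  cmp <- lapply(seq_len(m), function(i) {
    a <- comparisons$a[i]; b1 <- comparisons$b1[i]; b2 <- comparisons$b2[i]
    i1 <- A == a & B == b1; i2 <- A == a & B == b2
    n1 <- sum(i1); n2 <- sum(i2)
    if (n1 == 0L || n2 == 0L)
      stopf("empty cell in comparison %s: %s vs %s", a, b1, b2)
    est <- mean(y[i1]) - mean(y[i2])
    tval <- est / sqrt(mse * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tval), dfres)
    data.frame(a = a, b1 = b1, b2 = b2, estimate = est, t = tval,
               df = dfres, p = p, stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, cmp)
  cmp$p_sidak <- sidak_adjust(cmp$p, m)
  cmp$m <- m
  names(cmp)[1:3] <- c(lab[1], paste0(lab[2], "_1"), paste0(lab[2], "_2"))
  structure(list(effects = effects, comparisons = cmp, model = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (Type II sums of squares)\n")
  print(x$effects, row.names = FALSE)
  cat(sprintf("\nPairwise comparisons (Sidak-adjusted, m = %d)\n",
              x$comparisons$m[1]))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
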