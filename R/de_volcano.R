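# Single-cell QC filtering, Wilcoxon differential expression, BH-FDR,
# 2D-volcano construction, pathway embedding and marker finding.

#' QC presets for single-cell filtering
#'
#' `corpus_callosum`: 200-3000 detected genes, mitochondrial fraction < 5%.
#' `spinal_cord`: 500-7000 detected genes, mitochondrial fraction < 10%.
#'
#' @param name preset name.
#' @return list with `min_genes`, `max_genes`, `max_mito`.
#' @export
qc_preset <- function(name = c("corpus_callosum", "spinal_cord")) {
  switch(match.arg(name),
         corpus_callosum = list(min_genes = 200L, max_genes = 3000L,
                                max_mito = 0.05),
         spinal_cord = list(min_genes = 500L, max_genes = 7000L,
                            max_mito = 0.10))
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Keeps cells with `min_genes <= detected genes <= max_genes` and
#' mitochondrial UMI fraction strictly below `max_mito`. The report
#' attributes each removed cell to the first criterion it fails, in the
#' order min_genes, max_genes, mito, so kept + removed counts always equal
#' the input.
#'
#' @param counts cells x genes count matrix.
#' @param meta cell metadata data frame with a `mito_fraction` column,
#'   rows matching `counts`.
#' @param min_genes,max_genes,max_mito thresholds; superseded by `preset`.
#' @param preset optional preset name, see [qc_preset()].
#' @return object of class `qc_result`: list with filtered `counts` and
#'   `meta`, and `report` (input/kept counts, per-criterion removals,
#'   thresholds used).
#' @export
qc_filter <- function(counts, meta, min_genes = 200L, max_genes = 3000L,
                      max_mito = 0.05, preset = NULL) {
  if (!is.null(preset)) {
    th <- qc_preset(preset)
    min_genes <- th$min_genes; max_genes <- th$max_genes; max_mito <- th$max_mito
  }
  if (min_genes <= 0 || max_genes <= 0 || min_genes >= max_genes)
    stopf("need 0 < min_genes < max_genes")
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(meta)) stopf("meta rows must match counts rows")
  if (!"mito_fraction" %in% names(meta)) stopf("meta needs `mito_fraction`")
  detected <- rowSums(counts > 0)
  fail_min <- detected < min_genes
  fail_max <- !fail_min & detected > max_genes
  fail_mito <- !fail_min & !fail_max & meta$mito_fraction >= max_mito
  keep <- !(fail_min | fail_max | fail_mito)
  if (!any(keep)) warnf("QC filter removed every cell")
  report <- list(
    n_input = nrow(counts), n_kept = sum(keep),
    removed_min_genes = sum(fail_min), removed_max_genes = sum(fail_max),
    removed_mito = sum(fail_mito),
    thresholds = list(min_genes = min_genes, max_genes = max_genes,
                      max_mito = max_mito)
  )
  structure(list(counts = counts[keep, , drop = FALSE],
                 meta = meta[keep, , drop = FALSE], report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<qc_result> kept %d/%d cells (removed: %d low-gene, ",
                     "%d high-gene, %d high-mito)\n"),
              r$n_kept, r$n_input, r$removed_min_genes, r$removed_max_genes,
              r$removed_mito))
  invisible(x)
}

#' Per-gene log2 fold change between two cell groups
#'
#' `log2((mean_A + pc) / (mean_B + pc))` on normalized expression;
#' antisymmetric under swapping the groups.
#'
#' @param a,b normalized-expression matrices (cells x genes) for the two
#'   groups, same gene columns.
#' @param pseudocount stabilizer added to both means (default 1 on the
#'   normalized scale).
#' @return named numeric vector of per-gene LFCs.
#' @export
log_fold_change <- function(a, b, pseudocount = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stopf("both groups must be non-empty")
  if (ncol(a) != ncol(b)) stopf("gene sets differ between groups")
  log2((colMeans(a) + pseudocount) / (colMeans(b) + pseudocount))
}

#' Wilcoxon rank-sum p-value
#'
#' `mode = "exact"` enumerates all assignments of the pooled observations to
#' the two groups (midranks for ties) and returns the tail probability of
#' the rank-sum statistic (two-sided: probability of a rank sum at least as
#' far from its null mean as observed); it is intended for small samples.
#' `mode = "approx"` uses the normal approximation with tie correction and
#' continuity correction. `mode = "auto"` (default) picks exact when the
#' combined sample size is at most 10. The approximation tracks the exact
#' one-sided tail to within 0.05 at any group sizes; a two-sided p doubles
#' both tails, and with them the discrepancy.
#'
#' @param a,b numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param alternative `"two.sided"` (default) or `"greater"` (first group
#'   shifted up).
#' @return p-value.
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "approx"),
                          alternative = c("two.sided", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) stopf("both groups must be non-empty")
  if (mode == "auto") mode <- if (n <= 10L) "exact" else "approx"
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  if (mode == "exact") {
    if (n1 == 1L && n2 == 1L) {
      warnf("single-unit groups: exact rank-sum p is 1")
      return(1)
    }
    r <- rank(pooled)
    combos <- utils::combn(n, n1)
    W <- colSums(matrix(r[combos], nrow = n1))
    w_obs <- sum(r[seq_len(n1)])
    if (alternative == "greater") return(mean(W >= w_obs - 1e-9))
    mu <- n1 * (n + 1) / 2
    mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE,
                       alternative = alternative)$p.value
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; order-preserving and never below the raw p.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon differential expression within a population
#'
#' Normalizes the whole matrix (see [normalize_expression()]), restricts to
#' the cells of `population` (a cluster/population label; `NULL` = all
#' cells), and compares the two condition groups per gene. In
#' `"per_sample_average"` mode each sample's mean normalized expression is
#' the test unit instead of single cells (tests on averaged expression per
#' cluster); the exact rank-sum enumeration then engages automatically at
#' the small resulting sample sizes.
#'
#' @param counts cells x genes count matrix.
#' @param meta cell metadata with `condition`, `cluster` and (for the
#'   averaged mode) `sample` columns.
#' @param conditions length-2 character: conditions A and B to compare.
#' @param population cluster/population label to restrict to, or `NULL`.
#' @param mode `"per_cell"` (default) or `"per_sample_average"`.
#' @param pseudocount LFC pseudocount.
#' @return data frame of class `de_result`: `gene`, `lfc` (A over B), `p`,
#'   `q` (BH), `n_a`, `n_b`, with the comparison stored in attributes.
#' @export
wilcoxon_de <- function(counts, meta, conditions, population = NULL,
                        mode = c("per_cell", "per_sample_average"),
                        pseudocount = 1) {
  mode <- match.arg(mode)
  if (length(conditions) != 2L) stopf("conditions must name exactly 2 groups")
  norm <- normalize_expression(counts)
  keep <- if (is.null(population)) rep(TRUE, nrow(norm)) else
    meta$cluster == population
  norm <- norm[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  ga <- meta$condition == conditions[1]
  gb <- meta$condition == conditions[2]
  if (!any(ga) || !any(gb))
    stopf("empty condition group in population `%s`", population %||% "all")
  if (mode == "per_sample_average") {
    agg <- function(mask) {
      s <- factor(meta$sample[mask])
      t(vapply(levels(s), function(l)
        colMeans(norm[mask, , drop = FALSE][s == l, , drop = FALSE]),
        numeric(ncol(norm))))
    }
    A <- agg(ga); B <- agg(gb)
  } else {
    A <- norm[ga, , drop = FALSE]; B <- norm[gb, , drop = FALSE]
  }
  p <- vapply(seq_len(ncol(norm)), function(g)
    rank_sum_test(A[, g], B[, g]), numeric(1))
  out <- data.frame(
    gene = colnames(norm), lfc = log_fold_change(A, B, pseudocount),
    p = p, q = bh_fdr(p), n_a = nrow(A), n_b = nrow(B),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "conditions") <- conditions
  attr(out, "mode") <- mode
  class(out) <- c("de_result", "data.frame")
  out
}

#' Combine two DE comparisons into a 2D-volcano table
#'
#' Genes present in both comparisons get one point whose coordinates are the
#' two log fold changes; the annotated p-value is the lower of the two raw
#' p-values (with the corresponding lower q reported alongside) and the
#' significance flag marks q < 0.01. Genes missing from either comparison
#' are excluded and listed in the `excluded` attribute.
#'
#' @param de1,de2 [wilcoxon_de()] results (comparisons 1 and 2).
#' @param sig_q significance threshold on the BH q (default 0.01).
#' @return data frame of class `volcano2d`: `gene`, `lfc1`, `lfc2`, `p1`,
#'   `p2`, `q1`, `q2`, `p` (min), `q` (min), `significant`.
#' @export
volcano2d <- function(de1, de2, sig_q = 0.01) {
  common <- intersect(de1$gene, de2$gene)
  if (!length(common)) stopf("the two comparisons share no genes")
  excluded <- setdiff(union(de1$gene, de2$gene), common)
  if (length(excluded))
    message(sprintf("volcano2d: excluded %d gene(s) missing from one comparison",
                    length(excluded)))
  i1 <- match(common, de1$gene); i2 <- match(common, de2$gene)
  out <- data.frame(
    gene = common,
    lfc1 = de1$lfc[i1], lfc2 = de2$lfc[i2],
    p1 = de1$p[i1], p2 = de2$p[i2],
    q1 = de1$q[i1], q2 = de2$q[i2],
    stringsAsFactors = FALSE
  )
  out$p <- pmin(out$p1, out$p2)
  out$q <- pmin(out$q1, out$q2)
  out$significant <- out$q < sig_q
  attr(out, "excluded") <- excluded
  class(out) <- c("volcano2d", "data.frame")
  out
}

#' Embed gene sets (pathways) into a 2D-volcano
#'
#' A pathway's coordinates are the arithmetic means of its member genes' log
#' fold changes on each axis, restricted to members present in the volcano
#' table; sets with no member present are excluded and listed in the
#' `excluded` attribute.
#'
#' @param gene_sets named list of character vectors (or a data frame with
#'   columns `set`, `gene`).
#' @param volcano a [volcano2d()] table.
#' @return data frame: `pathway`, `lfc1`, `lfc2`, `n_genes`.
#' @export
pathway_embed <- function(gene_sets, volcano) {
  if (is.data.frame(gene_sets))
    gene_sets <- split(gene_sets$gene, gene_sets$set)
  rows <- list(); excluded <- character(0)
  for (s in names(gene_sets)) {
    members <- intersect(gene_sets[[s]], volcano$gene)
    if (!length(members)) { excluded <- c(excluded, s); next }
    i <- match(members, volcano$gene)
    rows[[s]] <- data.frame(pathway = s, lfc1 = mean(volcano$lfc1[i]),
                            lfc2 = mean(volcano$lfc2[i]),
                            n_genes = length(members),
                            stringsAsFactors = FALSE)
  }
  if (length(excluded))
    message(sprintf("pathway_embed: excluded %d set(s) with no gene in the table",
                    length(excluded)))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(pathway = character(0), lfc1 = numeric(0), lfc2 = numeric(0),
               n_genes = integer(0))
  attr(out, "excluded") <- excluded
  out
}

#' Read gene sets from a two-column TSV or a GMT file
#'
#' @param path file path; `.gmt` files use the set / description / members
#'   layout, anything else is read as headerless `set<TAB>gene` pairs.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- strsplit(readLines(path), "\t")
    stats::setNames(lapply(lines, function(l) l[-(1:2)]),
                    vapply(lines, `[[`, character(1), 1))
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("set", "gene"),
                            stringsAsFactors = FALSE)
    split(df$gene, df$set)
  }
}

#' One-vs-rest cluster marker finding
#'
#' For each cluster, compares its cells against all others per gene
#' (Wilcoxon rank-sum, normal approximation), keeps genes with log2 fold
#' change at least `min_lfc` (default 0.25) and BH q below `max_q` (default
#' 0.01), ranks them by the z score of the cluster's mean normalized
#' expression against the gene's global mean and SD, and reports the top
#' `top_n` per cluster.
#'
#' @param counts cells x genes count matrix.
#' @param clusters per-cell cluster labels.
#' @param min_lfc fold-change cutoff on log2 scale (default 0.25).
#' @param max_q BH q cutoff (default 0.01).
#' @param top_n markers reported per cluster (default 20).
#' @param pseudocount LFC pseudocount.
#' @return data frame: `cluster`, `gene`, `lfc`, `p`, `q`, `z`, `rank`.
#'   Clusters with fewer than 2 cells are skipped with a warning.
#' @export
find_markers <- function(counts, clusters, min_lfc = 0.25, max_q = 0.01,
                         top_n = 20L, pseudocount = 1) {
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2L) stopf("need at least 2 clusters")
  norm <- normalize_expression(counts)
  gmean <- colMeans(norm)
  gsd <- apply(norm, 2, stats::sd)
  rows <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    if (sum(in_cl) < 2L) {
      warnf("cluster %s has fewer than 2 cells; skipped", cl)
      next
    }
    A <- norm[in_cl, , drop = FALSE]
    B <- norm[!in_cl, , drop = FALSE]
    p <- vapply(seq_len(ncol(norm)), function(g)
      rank_sum_test(A[, g], B[, g], mode = "approx"), numeric(1))
    q <- bh_fdr(p)
    lfc <- log_fold_change(A, B, pseudocount)
    z <- ifelse(gsd > 0, (colMeans(A) - gmean) / gsd, 0)
    keep <- which(lfc >= min_lfc & q < max_q)
    keep <- keep[order(-z[keep])]
    keep <- utils::head(keep, top_n)
    if (length(keep))
      rows[[cl]] <- data.frame(cluster = cl, gene = colnames(norm)[keep],
                               lfc = lfc[keep], p = p[keep], q = q[keep],
                               z = z[keep], rank = seq_along(keep),
                               row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(cluster = character(0), gene = character(0), lfc = numeric(0),
               p = numeric(0), q = numeric(0), z = numeric(0),
               rank = integer(0))
}
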