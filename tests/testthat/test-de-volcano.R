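# QC filtering, rank-sum testing, BH-FDR, 2D-volcano, pathway embedding
# and marker finding.

test_that("QC presets keep exactly the in-range cells", {
  counts <- matrix(0L, 3, 4000)
  counts[1, 1:150] <- 1L   # 150 detected genes: below corpus callosum floor
  counts[2, 1:250] <- 1L   # in range
  counts[3, 1:3500] <- 1L  # above the 3000 ceiling
  meta <- data.frame(cell = c("a", "b", "c"), mito_fraction = 0)
  qc <- qc_filter(counts, meta, preset = "corpus_callosum")
  expect_equal(qc$meta$cell, "b")
  expect_equal(qc$report$removed_min_genes, 1L)
  expect_equal(qc$report$removed_max_genes, 1L)

  # spinal cord mito bound is strict: 6% passes a 10% ceiling, 10% does not
  counts2 <- matrix(1L, 3, 600)
  meta2 <- data.frame(cell = 1:3, mito_fraction = c(0.06, 0.10, 0.02))
  qc2 <- qc_filter(counts2, meta2, preset = "spinal_cord")
  expect_equal(qc2$meta$cell, c(1L, 3L))

  # all cells within bounds is the identity
  qc3 <- qc_filter(counts2, meta2, min_genes = 10, max_genes = 1000,
                   max_mito = 0.5)
  expect_equal(nrow(qc3$counts), 3L)
})

test_that("QC report attributes removals to the first failing criterion", {
  cfg <- expr_sim_config(n_cells = 300L, n_genes = 150L, n_de = 5L,
                         n_marker = 2L, n_spatial = 5L, seed = 3)
  sim <- gen_expression_matrix(cfg)
  qc <- qc_filter(sim$counts, sim$meta, min_genes = 50, max_genes = 140,
                  max_mito = 0.1)
  r <- qc$report
  expect_equal(r$n_kept + r$removed_min_genes + r$removed_max_genes +
                 r$removed_mito, r$n_input)
  # the planted low-size outliers fall to the min-genes criterion
  low <- sim$truth$cells$outlier_low
  detected <- rowSums(sim$counts > 0)
  expect_true(all(detected[low] < 50))
})

test_that("log fold change matches direct evaluation and is antisymmetric", {
  a <- matrix(3, 5, 2); b <- matrix(1, 5, 2)
  colnames(a) <- colnames(b) <- c("g1", "g2")
  expect_equal(unname(log_fold_change(a, b)), c(1, 1))  # log2(4/2)
  expect_equal(log_fold_change(a, a), c(g1 = 0, g2 = 0))
  set.seed(1)
  ra <- matrix(rexp(20), 5); rb <- matrix(rexp(20), 5)
  expect_equal(log_fold_change(ra, rb), -log_fold_change(rb, ra))
  expect_error(log_fold_change(ra[0, ], rb), "non-empty")
})

test_that("exact rank-sum p matches full enumeration and wilcox.test", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6), mode = "exact"), 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6), mode = "exact"),
               stats::wilcox.test(c(1, 2, 3), c(4, 5, 6),
                                  exact = TRUE)$p.value)
  # tie-free random cases agree with wilcox.test's exact path
  set.seed(2)
  for (r in 1:20) {
    a <- sample(100, 4); b <- sample(100, 5) + 0.5
    expect_equal(rank_sum_test(a, b, mode = "exact"),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  expect_equal(rank_sum_test(c(2, 2), c(2, 2)), 1)  # constant input
  expect_warning(p1 <- rank_sum_test(1, 2, mode = "exact"), "single-unit")
  expect_equal(p1, 1)
})

test_that("normal approximation tracks exact enumeration at small n", {
  # every distinct tie-free rank configuration with 2..4 units per group:
  # one-sided tails agree within 0.05; the two-sided p doubles both tails
  # and with them the bound
  worst1 <- worst2 <- 0
  for (n1 in 2:4) for (n2 in 2:4) {
    n <- n1 + n2
    combos <- utils::combn(n, n1)
    for (ci in seq_len(ncol(combos))) {
      a <- combos[, ci]
      b <- setdiff(seq_len(n), a)
      worst1 <- max(worst1, abs(
        rank_sum_test(a, b, mode = "approx", alternative = "greater") -
          rank_sum_test(a, b, mode = "exact", alternative = "greater")))
      worst2 <- max(worst2, abs(rank_sum_test(a, b, mode = "approx") -
                                  rank_sum_test(a, b, mode = "exact")))
    }
  }
  expect_lt(worst1, 0.05)
  expect_lt(worst2, 0.10)
})

test_that("BH-FDR matches the hand step-up computation and its bounds", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(order(q[order(p)]), seq_len(100))  # order-preserving
  expect_error(bh_fdr(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("per-cell Wilcoxon is calibrated on null data", {
  set.seed(5)
  n <- 60
  counts <- matrix(rpois(n * 1000, 5), n, 1000,
                   dimnames = list(NULL, sprintf("g%04d", 1:1000)))
  meta <- data.frame(condition = rep(c("a", "b"), each = n / 2),
                     cluster = 1, mito_fraction = 0)
  de <- wilcoxon_de(counts, meta, conditions = c("a", "b"), population = 1)
  rate <- mean(de$p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("planted DE genes are recovered with high sensitivity and low FDR", {
  cfg <- expr_sim_config(n_cells = 800L, n_genes = 200L, seed = 6)
  sim <- gen_expression_matrix(cfg)
  de <- wilcoxon_de(sim$counts, sim$meta,
                    conditions = c("injury", "control"),
                    population = cfg$de_cluster)
  tg <- sim$truth$genes
  hits <- de$gene[de$q < 0.01]
  sens <- mean(tg$gene[tg$de] %in% hits)
  fdr <- if (length(hits)) mean(!tg$de[match(hits, tg$gene)]) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.05)
  # recovered effect direction matches the planted sign
  up <- tg$gene[tg$de & tg$true_lfc > 0]
  expect_true(all(de$lfc[match(up, de$gene)] > 0))
})

test_that("per-sample-average mode collapses units to samples", {
  cfg <- expr_sim_config(n_cells = 200L, n_genes = 60L, n_de = 5L,
                         n_marker = 2L, n_spatial = 5L, seed = 7)
  sim <- gen_expression_matrix(cfg)
  de <- wilcoxon_de(sim$counts, sim$meta,
                    conditions = c("injury", "control"),
                    population = 1, mode = "per_sample_average")
  expect_equal(de$n_a[1], length(unique(
    sim$meta$sample[sim$meta$condition == "injury" & sim$meta$cluster == 1])))
})

test_that("volcano2d takes the lowest p and logs excluded genes", {
  de1 <- data.frame(gene = c("a", "b", "c"), lfc = c(1, -1, 2),
                    p = c(0.01, 0.5, 0.2), q = c(0.03, 0.6, 0.3))
  de2 <- data.frame(gene = c("a", "b", "d"), lfc = c(0.5, 0.2, 3),
                    p = c(0.05, 0.4, 0.001), q = c(0.1, 0.5, 0.004))
  expect_message(v <- volcano2d(de1, de2), "excluded 2")
  expect_equal(v$gene, c("a", "b"))
  expect_equal(v$p, c(0.01, 0.4))  # lowest of the two comparisons
  expect_setequal(attr(v, "excluded"), c("c", "d"))
  expect_equal(v$p[v$p1 == v$p2], v$p1[v$p1 == v$p2])
  expect_error(volcano2d(de1[0, ], de2), "no genes")
})

test_that("pathway embedding averages member LFCs and drops empty sets", {
  v <- data.frame(gene = c("g1", "g2", "g3"), lfc1 = c(1, 3, 5),
                  lfc2 = c(2, 4, 6), p = 0.1)
  sets <- list(two = c("g1", "g2"), one = "g3", none = c("zz"))
  expect_message(pe <- pathway_embed(sets, v), "excluded 1")
  expect_equal(pe$lfc1[pe$pathway == "two"], 2)
  expect_equal(pe$lfc2[pe$pathway == "two"], 3)
  expect_equal(pe$lfc1[pe$pathway == "one"], 5)  # singleton equals the gene
  expect_equal(pe$n_genes, c(2L, 1L))
  expect_false("none" %in% pe$pathway)
})

test_that("gene sets round-trip through TSV and GMT", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("s1\tg1", "s1\tg2", "s2\tg3"), tsv)
  gs <- read_gene_sets(tsv)
  expect_equal(gs$s1, c("g1", "g2"))
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("s1\tdesc\tg1\tg2", "s2\tdesc\tg3"), gmt)
  expect_equal(read_gene_sets(gmt), list(s1 = c("g1", "g2"), s2 = "g3"))
})

test_that("find_markers surfaces planted cluster markers and honors cutoffs", {
  cfg <- expr_sim_config(n_cells = 400L, n_genes = 100L, n_de = 0L,
                         n_marker = 5L, marker_fold = 10, n_spatial = 0L,
                         seed = 8)
  sim <- gen_expression_matrix(cfg)
  mk <- find_markers(sim$counts, sim$meta$cluster)
  tg <- sim$truth$genes
  for (k in 1:4) {
    planted <- tg$gene[!is.na(tg$marker_cluster) & tg$marker_cluster == k]
    found <- mk$gene[mk$cluster == as.character(k)]
    expect_gte(length(intersect(planted, found)), 4L)
  }
  # a flat gene is never reported as a marker
  flat <- tg$gene[is.na(tg$marker_cluster)][1]
  expect_false(flat %in% mk$gene)
  expect_true(all(mk$lfc >= 0.25))
  expect_true(all(mk$q < 0.01))
})
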