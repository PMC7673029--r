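# Moran's I on embedding graphs: sparse vs dense oracle, Monte-Carlo
# calibration, iterative filtering and hierarchical subclustering.

test_that("kNN graph matches hand geometry on collinear points", {
  coords <- cbind(c(0, 1, 3), 0, 0)
  g <- knn_graph(coords, k = 1)
  W <- as.matrix(g$W)
  # 1<->2 mutual, 3 -> 2; union symmetrization adds 2 -> 3
  expect_true(W[1, 2] > 0 && W[2, 1] > 0)
  expect_true(W[3, 2] > 0 && W[2, 3] > 0)
  expect_equal(W[1, 3], 0)
  expect_equal(unname(Matrix::rowSums(g$W)), rep(1, 3))  # row-standardized
  expect_identical(as.matrix(knn_graph(coords, k = 1)$W), W)  # deterministic
  expect_error(knn_graph(coords, k = 3), "k must")
})

test_that("alternating values on an even ring give Moran's I of -1", {
  g <- ring_graph(20)
  x <- rep(c(1, -1), 10)
  expect_equal(morans_i(x, g), -1, tolerance = 1e-12)
})

test_that("a smooth function of position has positive I; constants error", {
  set.seed(4)
  coords <- matrix(rnorm(150), 50, 3)
  g <- knn_graph(coords, k = 6)
  expect_gt(morans_i(coords[, 1], g), 0)
  expect_error(morans_i(rep(2, 50), g), "constant")
})

test_that("sparse Moran's I equals the dense double-sum oracle", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(10:60, 1)
    coords <- matrix(rnorm(n * 3), n, 3)
    g <- knn_graph(coords, k = sample(2:5, 1))
    x <- rnorm(n)
    expect_equal(morans_i(x, g), dense_morans_i(x, g), tolerance = 1e-10)
  }
})

test_that("Monte-Carlo p honors the add-one bound and detects structure", {
  set.seed(12)
  coords <- matrix(rnorm(240), 80, 3)
  g <- knn_graph(coords, k = 8)
  smooth <- coords[, 1]  # maximally structured relative to the graph
  res <- mc_pvalue(smooth, g, nperm = 999, seed = 13)
  expect_equal(res$p, 0.001)  # 1 / (nperm + 1)
  noise <- rnorm(80)
  res2 <- mc_pvalue(noise, g, nperm = 99, seed = 14)
  expect_gte(res2$p, 1 / 100)
  expect_lte(res2$p, 1)
})

test_that("blocked matrix Monte-Carlo agrees with the single-gene path", {
  set.seed(15)
  coords <- matrix(rnorm(180), 60, 3)
  g <- knn_graph(coords, k = 6)
  X <- cbind(a = coords[, 1] + rnorm(60, 0, 0.3), b = rnorm(60))
  res <- morans_i_mc(X, g, nperm = 499, seed = 16)
  expect_equal(res$i[1], morans_i(X[, "a"], g), tolerance = 1e-12)
  expect_equal(res$i[2], morans_i(X[, "b"], g), tolerance = 1e-12)
  expect_lt(res$p[1], 0.01)
  expect_gt(res$p[2], 0.05)
})

test_that("null permutation p-values are uniform (KS calibration)", {
  set.seed(17)
  coords <- matrix(rnorm(240), 80, 3)
  g <- knn_graph(coords, k = 8)
  X <- matrix(rnorm(80 * 300), 80, 300)  # 300 i.i.d. null genes
  res <- morans_i_mc(X, g, nperm = 199, seed = 18)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))  # discrete p ties
  # 1% critical value for the KS D statistic
  expect_lt(unname(ks$statistic), 1.63 / sqrt(300))
  # type-I error at alpha = 0.05 within 3 Monte-Carlo SEs
  expect_lt(abs(mean(res$p <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("iterative filter keeps planted spatial genes and drops noise", {
  sim <- gen_expression_matrix(
    expr_sim_config(n_cells = 400L, n_genes = 200L, n_marker = 0L,
                    n_de = 0L, n_spatial = 20L, seed = 21))
  g <- knn_graph(sim$embedding, k = 15)
  norm <- normalize_expression(sim$counts)
  filt <- iterative_spatial_filter(norm, g, alpha = 0.01, nperm = 499,
                                   seed = 22)
  planted <- sim$truth$genes$gene[sim$truth$genes$spatial]
  noise <- setdiff(colnames(norm), planted)
  expect_gte(length(intersect(filt$final, planted)), 18L)
  expect_lte(length(intersect(filt$final, noise)), 0.05 * length(noise))
  # retained sets are nested under a fixed graph
  for (r in seq_len(filt$n_rounds - 1))
    expect_true(all(filt$rounds[[r + 1]] %in% filt$rounds[[r]]))
})

test_that("an all-noise matrix retains about alpha of its genes", {
  set.seed(23)
  coords <- matrix(rnorm(300), 100, 3)
  g <- knn_graph(coords, k = 10)
  X <- matrix(rnorm(100 * 200), 100, 200)
  res <- morans_i_mc(X, g, nperm = 199, seed = 24)
  kept <- sum(res$p <= 0.05)
  expect_lte(kept, 200 * 0.05 + 3 * sqrt(200 * 0.05 * 0.95))
})

test_that("empty retained sets stop the filter with a warning", {
  set.seed(25)
  coords <- matrix(rnorm(120), 40, 3)
  g <- knn_graph(coords, k = 5)
  X <- matrix(rnorm(40 * 10), 40, 10)
  expect_warning(
    filt <- iterative_spatial_filter(X, g, alpha = 1 / 1000, nperm = 99,
                                     seed = 26),
    "no genes retained"
  )
  expect_length(filt$final, 0L)
})

test_that("hierarchical subclustering separates planted blobs perfectly", {
  set.seed(27)
  n <- 60
  truth <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10) + 8 * truth %o% rep(1, 10)
  labels <- hierarchical_subcluster(X, 2)
  expect_equal(adjusted_rand(labels, truth), 1)
  expect_identical(hierarchical_subcluster(X, 2), labels)  # deterministic
  expect_true(all(hierarchical_subcluster(X, 1) == 1L))
  expect_error(hierarchical_subcluster(X, n + 1), "between 1")
})

test_that("the re-embedding hook is called and rebuilds the graph", {
  sim <- gen_expression_matrix(
    expr_sim_config(n_cells = 150L, n_genes = 60L, n_marker = 0L, n_de = 0L,
                    n_spatial = 10L, seed = 28))
  g <- knn_graph(sim$embedding, k = 10)
  norm <- normalize_expression(sim$counts)
  calls <- 0L
  hook <- function(xr) { calls <<- calls + 1L; sim$embedding }
  filt <- iterative_spatial_filter(norm, g, alpha = 0.05, nperm = 99,
                                   max_rounds = 3, seed = 29, reembed = hook,
                                   k = 10)
  expect_gte(calls, 1L)
  expect_gt(length(filt$final), 0L)
})
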