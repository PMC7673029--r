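# Count-matrix simulation: clustered cells across conditions with planted
# DE genes, QC outliers, a 3D embedding and spatially autocorrelated genes.

#' Configuration for the count-matrix simulator
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_clusters number of planted clusters (equal proportions).
#' @param conditions character vector of condition labels; cells are split
#'   evenly and independently of cluster.
#' @param n_de number of planted DE genes.
#' @param de_lfc true log2 fold change of DE genes between the second and the
#'   first condition, applied within `de_cluster` (signs alternate).
#' @param de_cluster cluster (integer) in which the DE effect is planted.
#' @param n_marker number of planted cluster marker genes per cluster
#'   (`marker_fold`-fold elevated in their cluster).
#' @param marker_fold fold elevation of marker genes in their cluster.
#' @param n_spatial number of planted spatially autocorrelated genes: their
#'   log-mean is a linear function of the first embedding coordinate.
#' @param spatial_strength slope of the spatial genes' bounded gradient
#'   (`1 + 0.9 tanh(strength * s)`) per unit of standardized first embedding
#'   coordinate; signs alternate across spatial genes.
#' @param spatial_deterministic if `TRUE`, spatial gene values are the exact
#'   (rounded) mean function of the embedding, with no sampling noise.
#' @param base_shape,base_rate gamma hyperparameters for baseline gene means.
#' @param dispersion negative-binomial size for counts (`Inf` = Poisson).
#' @param mito_base mean mitochondrial fraction of ordinary cells.
#' @param outlier_mito_frac fraction of cells planted as high-mito outliers
#'   (fractions drawn in 0.1..0.4).
#' @param outlier_low_frac,outlier_high_frac fractions of cells with strongly
#'   shrunken / inflated library size (QC gene-count outliers).
#' @param embedding_sep distance between cluster blob centers in the 3D
#'   embedding (blob sd = 1).
#' @param seed default seed.
#' @return object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_cells = 1000L, n_genes = 200L, n_clusters = 4L,
                            conditions = c("control", "injury"),
                            n_de = 20L, de_lfc = 1, de_cluster = 1L,
                            n_marker = 5L, marker_fold = 10,
                            n_spatial = 20L, spatial_strength = 1.5,
                            spatial_deterministic = FALSE,
                            base_shape = 2, base_rate = 1,
                            dispersion = 10,
                            mito_base = 0.02, outlier_mito_frac = 0.05,
                            outlier_low_frac = 0.02, outlier_high_frac = 0.02,
                            embedding_sep = 10, seed = 1L) {
  if (n_clusters < 2L) stopf("need at least 2 clusters")
  if (length(conditions) < 2L) stopf("need at least 2 conditions")
  if (n_de + n_marker * n_clusters + n_spatial > n_genes)
    stopf("planted genes exceed n_genes")
  structure(as.list(environment()), class = "expr_sim_config")
}

#' Simulate a cells x genes count matrix with known ground truth
#'
#' Counts are negative binomial around per-cluster gene means. Planted
#' structure, all recorded in the returned ground truth: cluster marker genes
#' (elevated `marker_fold`-fold in one cluster), condition-DE genes (true
#' log2 fold change `de_lfc` between conditions inside `de_cluster`),
#' mitochondrial-fraction outliers, library-size outliers (low/high detected
#' gene counts), a cluster-separated 3D Gaussian-blob embedding, and
#' spatially autocorrelated genes whose log-mean follows the first embedding
#' coordinate.
#'
#' @param config an [expr_sim_config()].
#' @param seed integer seed.
#' @return list of class `expr_sim`: `counts` (cells x genes integer matrix),
#'   `meta` (cell metadata: `cell`, `sample`, `condition`, `cluster`,
#'   `mito_fraction`), `embedding` (cells x 3), `truth` (list with `genes`
#'   data frame: `gene`, `de`, `true_lfc`, `marker_cluster`, `spatial`,
#'   `spatial_strength`; and `cells` data frame with outlier flags).
#' @export
gen_expression_matrix <- function(config = expr_sim_config(),
                                  seed = config$seed) {
  stopifnot(inherits(config, "expr_sim_config"))
  with_seed(seed, {
    n <- config$n_cells; G <- config$n_genes; K <- config$n_clusters
    genes <- sprintf("gene%03d", seq_len(G))
    cluster <- rep_len(seq_len(K), n)
    # shuffled so condition is independent of the cluster cycle
    condition <- sample(rep_len(config$conditions, n))
    # two samples per condition, assigned independently of cluster
    sample_id <- paste0(condition, "_s", sample(1:2, n, replace = TRUE))

    base <- stats::rgamma(G, shape = config$base_shape, rate = config$base_rate)
    names(base) <- genes

    # gene roles: markers first, then DE, then spatial, rest background
    idx <- seq_len(G)
    marker_idx <- utils::head(idx, config$n_marker * K)
    idx <- setdiff(idx, marker_idx)
    de_idx <- utils::head(idx, config$n_de)
    idx <- setdiff(idx, de_idx)
    spatial_idx <- utils::head(idx, config$n_spatial)
    marker_cluster <- rep(NA_integer_, G)
    if (length(marker_idx))
      marker_cluster[marker_idx] <- rep_len(seq_len(K), length(marker_idx))
    # planted effects live in moderately expressed genes: floor their baseline
    base[c(marker_idx, de_idx)] <- pmax(base[c(marker_idx, de_idx)], 2)
    de_sign <- rep_len(c(1, -1), length(de_idx))
    true_lfc <- rep(0, G)
    true_lfc[de_idx] <- config$de_lfc * de_sign

    # embedding: Gaussian blobs at random well-separated centers
    centers <- matrix(stats::rnorm(K * 3), K, 3)
    centers <- centers / sqrt(rowSums(centers^2)) * config$embedding_sep / 2
    embedding <- centers[cluster, ] + matrix(stats::rnorm(n * 3), n, 3)
    colnames(embedding) <- paste0("dim", 1:3)
    s1 <- as.numeric(scale(embedding[, 1]))

    # per-cell per-gene means
    mu <- matrix(base, n, G, byrow = TRUE, dimnames = list(NULL, genes))
    for (g in marker_idx)
      mu[cluster == marker_cluster[g], g] <-
        mu[cluster == marker_cluster[g], g] * config$marker_fold
    in_de <- cluster == config$de_cluster & condition == config$conditions[2]
    for (j in seq_along(de_idx))
      mu[in_de, de_idx[j]] <- mu[in_de, de_idx[j]] * 2^(config$de_lfc * de_sign[j])
    # Spatial genes follow a bounded smooth gradient of the first embedding
    # coordinate; signs alternate so the planted genes do not shift cell
    # totals along the gradient (which would leak spatial structure into
    # every gene after library-size normalization).
    spatial_strength <- rep(0, G)
    if (length(spatial_idx)) {
      signed <- config$spatial_strength * rep_len(c(1, -1), length(spatial_idx))
      spatial_strength[spatial_idx] <- signed
      for (j in seq_along(spatial_idx)) {
        g <- spatial_idx[j]
        mu[, g] <- (base[g] + 0.5) * (1 + 0.9 * tanh(signed[j] * s1))
      }
    }

    # library-size outliers
    size_factor <- rep(1, n)
    n_low <- round(config$outlier_low_frac * n)
    n_high <- round(config$outlier_high_frac * n)
    n_mito <- round(config$outlier_mito_frac * n)
    out_cells <- sample.int(n, n_low + n_high + n_mito)
    low_cells <- out_cells[seq_len(n_low)]
    high_cells <- out_cells[n_low + seq_len(n_high)]
    mito_cells <- out_cells[n_low + n_high + seq_len(n_mito)]
    size_factor[low_cells] <- 0.05
    size_factor[high_cells] <- 20
    mu <- mu * size_factor

    counts <- matrix(0L, n, G, dimnames = list(NULL, genes))
    for (g in seq_len(G)) {
      counts[, g] <- if (g %in% spatial_idx && config$spatial_deterministic)
        as.integer(round(mu[, g]))
      else if (is.finite(config$dispersion))
        stats::rnbinom(n, mu = mu[, g], size = config$dispersion)
      else stats::rpois(n, mu[, g])
    }

    mito <- pmin(pmax(stats::rnorm(n, config$mito_base, config$mito_base / 4),
                      0), 1)
    mito[mito_cells] <- stats::runif(n_mito, 0.1, 0.4)

    meta <- data.frame(
      cell = sprintf("cell%04d", seq_len(n)), sample = sample_id,
      condition = condition, cluster = cluster, mito_fraction = mito,
      stringsAsFactors = FALSE
    )
    rownames(counts) <- meta$cell
    truth <- list(
      genes = data.frame(
        gene = genes, de = true_lfc != 0, true_lfc = true_lfc,
        marker_cluster = marker_cluster,
        spatial = spatial_strength != 0,
        spatial_strength = spatial_strength, stringsAsFactors = FALSE
      ),
      cells = data.frame(
        cell = meta$cell, cluster = cluster, condition = condition,
        mito_fraction = mito, size_factor = size_factor,
        outlier_mito = seq_len(n) %in% mito_cells,
        outlier_low = seq_len(n) %in% low_cells,
        outlier_high = seq_len(n) %in% high_cells, stringsAsFactors = FALSE
      )
    )
    structure(list(counts = counts, meta = meta, embedding = embedding,
                   truth = truth, config = config),
              class = "expr_sim")
  })
}

#' Write / read a cells x genes count matrix as MatrixMarket + TSV
#'
#' Writes `matrix.mtx` (genes in rows, cells in columns, the common
#' exchange convention), `genes.tsv` and `cells.tsv` into `dir`.
#'
#' @param counts cells x genes matrix with row and column names.
#' @param dir output directory (created if needed).
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @return `read_counts_mtx` returns the cells x genes matrix.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  out <- t(as.matrix(m))
  dimnames(out) <- list(cells, genes)
  out
}
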