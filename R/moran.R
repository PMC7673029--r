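# Moran's I over a kNN graph on a low-dimensional embedding, Monte-Carlo
# significance, iterative spatial feature filtering and hierarchical
# subclustering. The manifold here is the 3D embedding of a single-cell
# dataset: spatially autocorrelated genes on that manifold are the ones that
# vary smoothly across the cell state space, and iterating the filter
# concentrates the feature set on them before subclustering.

#' Build a kNN neighbor graph on an embedding
#'
#' Connects every cell to its `k` nearest Euclidean neighbors (distance ties
#' broken toward the lower cell index), symmetrizes by union, and
#' row-standardizes the weights so each connected row sums to 1.
#'
#' @param coords numeric matrix, cells x dimensions (typically 3).
#' @param k number of neighbors, `1 <= k < N`.
#' @return object of class `embedding_graph`: list with `W` (sparse
#'   row-standardized weight matrix), `S0` (total weight), `coords`, `k`,
#'   `n`.
#' @export
knn_graph <- function(coords, k = 15) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(!is.finite(coords))) stopf("coordinates must be finite")
  if (k < 1 || k >= n) stopf("k must satisfy 1 <= k < N (N = %d)", n)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  idx <- seq_len(n)
  nb <- vapply(idx, function(i) order(D[i, ], idx)[seq_len(k)], integer(k))
  i <- rep(idx, each = k)
  j <- as.vector(nb)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A <- pmin(A + Matrix::t(A), 1)  # union symmetrization
  as_embedding_graph(A, coords = coords, k = k)
}

#' Construct an embedding graph from an adjacency/weight matrix
#'
#' Row-standardizes a non-negative weight matrix (zero diagonal enforced) so
#' it can be used by [morans_i()]. Intended for hand-built graphs such as
#' rings or lattices; [knn_graph()] is the usual entry point.
#'
#' @param W square matrix (dense or sparse) of non-negative weights.
#' @param coords optional coordinates kept for re-embedding hooks.
#' @param k neighbor count annotation.
#' @return an `embedding_graph`.
#' @export
as_embedding_graph <- function(W, coords = NULL, k = NA_integer_) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(W) != ncol(W)) stopf("W must be square")
  Matrix::diag(W) <- 0
  rs <- Matrix::rowSums(W)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(x = scale) %*% W
  structure(list(W = W, S0 = sum(W), n = nrow(W), coords = coords, k = k),
            class = "embedding_graph")
}

#' @export
print.embedding_graph <- function(x, ...) {
  cat(sprintf("<embedding_graph> %d cells, k = %s, S0 = %.1f\n",
              x$n, x$k, x$S0))
  invisible(x)
}

#' Moran's I spatial autocorrelation on a graph
#'
#' `I = (N / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2`. Positive values mean neighboring cells carry similar values
#' (smooth variation across the manifold); the statistic is undefined for a
#' constant vector.
#'
#' @param x numeric vector of per-cell values.
#' @param graph an `embedding_graph`.
#' @return observed I (numeric scalar).
#' @export
morans_i <- function(x, graph) {
  stopifnot(inherits(graph, "embedding_graph"))
  if (length(x) != graph$n) stopf("x must have one value per cell")
  if (any(!is.finite(x))) stopf("x must be finite")
  z <- x - mean(x)
  den <- sum(z^2)
  if (den == 0) stopf("Moran's I is undefined for constant input")
  (graph$n / graph$S0) * sum(z * as.numeric(graph$W %*% z)) / den
}

# Observed I for every column of a centered matrix.
morans_i_cols <- function(Zc, graph, den = colSums(Zc^2)) {
  (graph$n / graph$S0) * colSums(Zc * as.matrix(graph$W %*% Zc)) / den
}

#' Monte-Carlo permutation p-value for Moran's I
#'
#' The null distribution is generated by uniform random relabelings of `x`
#' over the cells; significance uses the add-one estimator
#' `p = (1 + #\{I_perm >= I_obs\}) / (1 + nperm)`, so p is never exactly zero
#' and is bounded below by `1 / (nperm + 1)`.
#'
#' @param x per-cell values (non-constant).
#' @param graph an `embedding_graph`.
#' @param nperm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `i` (observed), `p`, `nperm`.
#' @export
mc_pvalue <- function(x, graph, nperm = 999, seed = NULL) {
  if (nperm < 1) stopf("nperm must be >= 1")
  obs <- morans_i(x, graph)
  with_seed(seed, {
    z <- x - mean(x)
    den <- sum(z^2)
    hits <- 0L
    for (b in seq_len(nperm)) {
      zp <- z[sample.int(length(z))]
      ib <- (graph$n / graph$S0) * sum(zp * as.numeric(graph$W %*% zp)) / den
      if (ib >= obs) hits <- hits + 1L
    }
    list(i = obs, p = (1 + hits) / (1 + nperm), nperm = nperm)
  })
}

#' Moran's I Monte-Carlo test for every gene of a matrix
#'
#' Blocked implementation of [mc_pvalue()] over all columns at once: each
#' permutation reorders the cells of the whole centered matrix and updates
#' every gene's exceedance count, which makes testing hundreds of genes with
#' hundreds of permutations cheap.
#'
#' @param x cells x genes numeric matrix (e.g. normalized expression);
#'   constant columns are returned with `i = NA`, `p = 1`.
#' @param graph an `embedding_graph`.
#' @param nperm permutations (default 999).
#' @param seed integer seed.
#' @return data frame: `gene`, `i` (observed Moran's I), `p` (add-one
#'   Monte-Carlo p).
#' @export
morans_i_mc <- function(x, graph, nperm = 999, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != graph$n) stopf("x must have one row per cell")
  genes <- colnames(x) %||% as.character(seq_len(ncol(x)))
  Zc <- sweep(x, 2, colMeans(x))
  den <- colSums(Zc^2)
  ok <- den > 0
  obs <- rep(NA_real_, ncol(x))
  p <- rep(1, ncol(x))
  if (any(ok)) {
    Zok <- Zc[, ok, drop = FALSE]
    dok <- den[ok]
    iobs <- morans_i_cols(Zok, graph, dok)
    hits <- integer(sum(ok))
    with_seed(seed, {
      for (b in seq_len(nperm)) {
        perm <- sample.int(graph$n)
        Zp <- Zok[perm, , drop = FALSE]
        ib <- morans_i_cols(Zp, graph, dok)
        hits <- hits + (ib >= iobs)
      }
    })
    obs[ok] <- iobs
    p[ok] <- (1 + hits) / (1 + nperm)
  }
  data.frame(gene = genes, i = obs, p = p, stringsAsFactors = FALSE)
}

#' Iterative Moran's I spatial feature filter
#'
#' Round 1 tests every gene on the graph; each round keeps the genes whose
#' Monte-Carlo p is at most `alpha`, optionally recomputes the embedding and
#' graph from the retained gene subset via the `reembed` hook, and repeats on
#' the survivors until the retained set stops changing or `max_rounds` is
#' reached. With a fixed graph the retained sets are nested across rounds.
#'
#' @param x cells x genes matrix of normalized expression.
#' @param graph an `embedding_graph` for round 1.
#' @param alpha retention threshold on the Monte-Carlo p (default 0.01).
#' @param nperm permutations per round (default 999).
#' @param max_rounds iteration cap (default 30).
#' @param seed integer seed (drives all rounds).
#' @param reembed optional hook `function(x_retained) -> coords`; when
#'   supplied the graph is rebuilt with [knn_graph()] on its output between
#'   rounds (as when re-embedding the cells on the filtered features), using
#'   `k`.
#' @param k neighbor count for rebuilt graphs.
#' @return object of class `spatial_filter`: list with `rounds` (list of
#'   retained gene vectors per round), `final` (character vector), `moran`
#'   (last round's Moran table), `n_rounds`.
#' @export
iterative_spatial_filter <- function(x, graph, alpha = 0.01, nperm = 999,
                                     max_rounds = 30, seed = NULL,
                                     reembed = NULL, k = 15) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stopf("need at least one gene")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  retained <- colnames(x)
  rounds <- list()
  moran <- NULL
  with_seed(seed, {
    for (r in seq_len(max_rounds)) {
      res <- morans_i_mc(x[, retained, drop = FALSE], graph, nperm = nperm,
                         seed = NULL)
      keep <- res$gene[res$p <= alpha & !is.na(res$i)]
      moran <- res
      rounds[[r]] <- keep
      if (length(keep) == 0L) {
        warnf("no genes retained after round %d; stopping", r)
        retained <- keep
        break
      }
      stable <- setequal(keep, retained)
      retained <- keep
      if (stable) break
      if (!is.null(reembed) && r < max_rounds)
        graph <- knn_graph(reembed(x[, retained, drop = FALSE]), k = k)
    }
  })
  structure(list(rounds = rounds, final = retained, moran = moran,
                 n_rounds = length(rounds)),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d round(s); %d gene(s) retained\n",
              x$n_rounds, length(x$final)))
  invisible(x)
}

#' Hierarchical subclustering on a filtered gene set
#'
#' Scales each retained gene to zero mean and unit variance, then cuts a
#' Ward-linkage agglomerative clustering (Euclidean distance) at
#' `n_clusters`. Deterministic for fixed input.
#'
#' @param x cells x genes matrix (typically the filter's retained genes).
#' @param n_clusters number of clusters, `1 <= n_clusters <= N`.
#' @return integer vector of per-cell cluster labels.
#' @export
hierarchical_subcluster <- function(x, n_clusters) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stopf("need at least one gene")
  if (n_clusters < 1 || n_clusters > nrow(x))
    stopf("n_clusters must be between 1 and the number of cells")
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0  # constant genes carry no signal
  hc <- stats::hclust(stats::dist(xs), method = "ward.D2")
  unname(stats::cutree(hc, k = n_clusters))
}
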