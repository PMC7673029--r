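# ISS measurement simulation: rolling-circle-product spots with 4-cycle,
# 4-channel one-hot intensities, crosstalk, noise and background spots.

#' Simulate ISS spot intensities for a tissue
#'
#' For every cell and every gene its population expresses, a spot count is
#' drawn (Poisson at the configured mean, or negative binomial when
#' `config$dispersion` is finite) and each spot is placed uniformly inside the
#' nucleus disk. A spot's cycles x channels intensity matrix is one-hot on its
#' barcode's channel per cycle at `amplitude`, with a `crosstalk` fraction of
#' the amplitude on the three other channels, plus independent additive
#' Gaussian noise (sd = `noise * amplitude`) truncated at zero. Background
#' spots (expected count `config$background_rate`) carry barcodes drawn
#' uniformly from the full 4^L space and belong to no cell.
#'
#' @param tissue a [gen_tissue()] result.
#' @param book a [barcode_book]; every expressed gene must be present.
#' @param config a [sim_config()] (defaults to the tissue's).
#' @param seed integer seed.
#' @return list with `spots` (data frame: `spot_id`, `x`, `y`,
#'   `cycle{c}_ch{k}` intensity columns) and `ledger` (ground truth per spot:
#'   `spot_id`, `cell` (NA for background), `gene` (NA for background),
#'   `barcode`).
#' @export
gen_iss_spots <- function(tissue, book = default_barcode_book(),
                          config = attr(tissue, "config"),
                          seed = config$seed) {
  stopifnot(inherits(book, "barcode_book"), inherits(config, "sim_config"))
  expr <- config$expression
  expressed <- colnames(expr)[colSums(expr[unique(tissue$population), ,
                                           drop = FALSE]) > 0]
  missing <- setdiff(expressed, names(book$genes))
  if (length(missing))
    stopf("gene(s) expressed by the tissue but missing from the barcode book: %s",
          paste(missing, collapse = ", "))
  L <- config$cycles
  alphabet <- book$alphabet

  with_seed(seed, {
    cell_id <- integer(0); gene <- character(0)
    sx <- numeric(0); sy <- numeric(0)
    for (i in seq_len(nrow(tissue))) {
      mu <- expr[tissue$population[i], ]
      mu <- mu[mu > 0]
      if (!length(mu)) next
      counts <- if (is.finite(config$dispersion))
        stats::rnbinom(length(mu), mu = mu, size = config$dispersion)
      else stats::rpois(length(mu), mu)
      tot <- sum(counts)
      if (tot == 0L) next
      rad <- tissue$radius[i] * sqrt(stats::runif(tot))
      ang <- stats::runif(tot, 0, 2 * pi)
      cell_id <- c(cell_id, rep.int(i, tot))
      gene <- c(gene, rep.int(names(mu), counts))
      sx <- c(sx, tissue$x[i] + rad * cos(ang))
      sy <- c(sy, tissue$y[i] + rad * sin(ang))
    }
    barcode <- unname(book$genes[gene])

    n_bg <- stats::rpois(1, config$background_rate)
    if (n_bg > 0) {
      bg_codes <- vapply(seq_len(n_bg), function(i)
        paste(sample(alphabet, L, replace = TRUE), collapse = ""),
        character(1))
      cell_id <- c(cell_id, rep.int(NA_integer_, n_bg))
      gene <- c(gene, rep.int(NA_character_, n_bg))
      barcode <- c(barcode, bg_codes)
      sx <- c(sx, stats::runif(n_bg, 0, config$field[1] - 1))
      sy <- c(sy, stats::runif(n_bg, 0, config$field[2] - 1))
    }

    n <- length(barcode)
    inten <- matrix(0, n, L * 4L)
    colnames(inten) <- as.vector(t(outer(seq_len(L), 0:3, function(c, k)
      sprintf("cycle%d_ch%d", c, k))))
    if (n > 0) {
      base_idx <- matrix(match(unlist(strsplit(barcode, "")), alphabet),
                         nrow = n, byrow = TRUE)
      amp <- config$amplitude
      for (c in seq_len(L)) {
        block <- matrix(config$crosstalk * amp, n, 4L)
        block[cbind(seq_len(n), base_idx[, c])] <- amp
        if (config$noise > 0)
          block <- block + matrix(stats::rnorm(n * 4L, 0, config$noise * amp),
                                  n, 4L)
        inten[, (c - 1L) * 4L + 1:4] <- pmax(block, 0)
      }
    }
    spots <- data.frame(spot_id = seq_len(n), x = sx, y = sy)
    spots <- cbind(spots, as.data.frame(inten))
    ledger <- data.frame(spot_id = seq_len(n), cell = cell_id, gene = gene,
                         barcode = barcode, stringsAsFactors = FALSE)
    list(spots = spots, ledger = ledger)
  })
}

#' Simulate RNAscope-style puncta counts per cell
#'
#' Draws per-cell marker puncta counts from population-specific negative
#' binomial models (Poisson in the infinite-dispersion limit). The default
#' means straddle the molecule cutoffs used for population calling: the
#' on-target population sits at three times its cutoff, everything else at a
#' third of it. Sox10 status (from immunostaining in the emulated assay) is a
#' boolean set by population.
#'
#' @param tissue a [gen_tissue()] result.
#' @param means population x marker matrix of mean puncta counts; defaults to
#'   3x cutoff on-target and cutoff/3 off-target for Ptgds (12), Klk6 (4),
#'   Egr2 (3) and Ptprz1 (7).
#' @param dispersion negative-binomial size; `Inf` = Poisson.
#' @param sox10_positive named logical: which populations are Sox10+
#'   (defaults to all but "Other").
#' @param seed integer seed.
#' @return list with `cells` (data frame: `cell`, `region`, `sox10`, one
#'   count column per marker) and `truth` (`cell`, `population`).
#' @export
gen_puncta_counts <- function(tissue,
                              means = default_puncta_means(),
                              dispersion = 20,
                              sox10_positive = NULL,
                              seed = attr(tissue, "config")$seed) {
  pops <- unique(tissue$population)
  bad <- setdiff(pops, rownames(means))
  if (length(bad))
    stopf("no puncta means configured for population(s): %s",
          paste(bad, collapse = ", "))
  if (is.null(sox10_positive))
    sox10_positive <- stats::setNames(rownames(means) != "Other",
                                      rownames(means))
  with_seed(seed, {
    n <- nrow(tissue)
    counts <- matrix(0L, n, ncol(means),
                     dimnames = list(NULL, colnames(means)))
    for (p in pops) {
      idx <- which(tissue$population == p)
      for (m in colnames(means)) {
        mu <- means[p, m]
        counts[idx, m] <- if (mu == 0) 0L
        else if (is.finite(dispersion))
          stats::rnbinom(length(idx), mu = mu, size = dispersion)
        else stats::rpois(length(idx), mu)
      }
    }
    cells <- data.frame(cell = tissue$cell, region = tissue$region,
                        sox10 = unname(sox10_positive[tissue$population]),
                        stringsAsFactors = FALSE)
    cells <- cbind(cells, as.data.frame(counts))
    list(cells = cells,
         truth = data.frame(cell = tissue$cell,
                            population = tissue$population,
                            stringsAsFactors = FALSE))
  })
}

#' @rdname gen_puncta_counts
#' @export
default_puncta_means <- function() {
  cutoffs <- c(Ptgds = 12, Klk6 = 4, Egr2 = 3, Ptprz1 = 7)
  on_target <- c("MOL5/6" = "Ptgds", "MOL2" = "Klk6", "MOL1" = "Egr2",
                 "OPC/COP" = "Ptprz1")
  pops <- c(names(on_target), "Other")
  m <- matrix(rep(cutoffs / 3, each = length(pops)), nrow = length(pops),
              dimnames = list(pops, names(cutoffs)))
  for (p in names(on_target)) m[p, on_target[p]] <- 3 * cutoffs[on_target[p]]
  m
}
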