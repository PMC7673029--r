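# Tissue-level simulation: nucleus packing, region/population assignment,
# and rendering to DAPI-like images with ground-truth labels.

#' Generate a synthetic tissue of non-overlapping nuclei
#'
#' Places `n_cells` disk nuclei uniformly in the field by rejection sampling
#' under a hard minimum center distance of
#' `2 * max(radius_range) + margin`, keeps every disk fully inside the field,
#' assigns each cell the region strip containing its center, and draws its
#' population label from the region's configured proportions.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param max_tries rejection-sampling budget per cell before giving up with
#'   an infeasible-packing error.
#' @return object of class `tissue`: a data frame with columns `cell`, `x`,
#'   `y` (0-based pixel coordinates of the center), `radius`, `region`,
#'   `population`, with the config attached as attribute `config`.
#' @export
gen_tissue <- function(config, seed = config$seed, max_tries = 500L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_cells
    w <- config$field[1]; h <- config$field[2]
    rmax <- config$radius_range[2]
    min_dist <- 2 * rmax + config$margin
    xs <- numeric(n); ys <- numeric(n); rs <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- stats::runif(1, rmax, w - 1 - rmax)
        y <- stats::runif(1, rmax, h - 1 - rmax)
        if (placed == 0L ||
            all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >
                min_dist^2)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stopf(paste0("infeasible packing: could not place nucleus %d of %d ",
                     "after %d tries (field %dx%d, min center distance %.1f)"),
              i, n, max_tries, w, h, min_dist)
      placed <- placed + 1L
      xs[i] <- x; ys[i] <- y
      rs[i] <- stats::runif(1, config$radius_range[1], config$radius_range[2])
    }
    region <- region_of(xs, config$regions)
    population <- character(n)
    for (r in config$regions$region) {
      idx <- which(region == r)
      if (length(idx)) {
        lineage <- stats::runif(length(idx)) < config$lineage_fraction[r]
        population[idx] <- "Other"
        if (any(lineage)) {
          p <- config$proportions[[r]]
          population[idx[lineage]] <- sample(names(p), sum(lineage),
                                             replace = TRUE, prob = p)
        }
      }
    }
    out <- data.frame(cell = seq_len(n), x = xs, y = ys, radius = rs,
                      region = region, population = population,
                      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("tissue", "data.frame")
    out
  })
}

# Region strip containing each x coordinate (0-based; strip is [xmin, xmax)).
region_of <- function(x, regions) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(regions)))
    out[x >= regions$xmin[i] & x < regions$xmax[i]] <- regions$region[i]
  out
}

#' Render a tissue to a nuclei-stain image plus true label image
#'
#' Each nucleus becomes a filled disk of its radius at constant foreground
#' intensity on a dim background, emulating a DAPI channel; the companion
#' label image carries the ground-truth cell id at every nucleus pixel.
#' Images are matrices indexed `[row, col]` = `[y + 1, x + 1]` with 0-based
#' pixel-center coordinates.
#'
#' @param tissue a [gen_tissue()] result.
#' @param foreground,background intensities on a 0..1 scale.
#' @return list with `image` (numeric matrix) and `labels` (integer matrix,
#'   0 = background).
#' @export
render_nuclei_image <- function(tissue, foreground = 0.8, background = 0.05) {
  config <- attr(tissue, "config")
  w <- config$field[1]; h <- config$field[2]
  img <- matrix(background, nrow = h, ncol = w)
  lab <- matrix(0L, nrow = h, ncol = w)
  for (i in seq_len(nrow(tissue))) {
    cx <- tissue$x[i]; cy <- tissue$y[i]; r <- tissue$radius[i]
    cols <- max(1L, floor(cx - r) + 1L):min(w, ceiling(cx + r) + 1L)
    rows <- max(1L, floor(cy - r) + 1L):min(h, ceiling(cy + r) + 1L)
    for (cc in cols) {
      dy2 <- r^2 - (cc - 1 - cx)^2
      if (dy2 < 0) next
      inside <- rows[(rows - 1 - cy)^2 <= dy2]
      img[inside, cc] <- foreground
      lab[inside, cc] <- tissue$cell[i]
    }
  }
  list(image = img, labels = lab)
}

#' Write a grayscale or label image as 16-bit TIFF
#'
#' Grayscale images are expected on a 0..1 scale; label images are stored as
#' `label / 65535` so they round-trip exactly through [read_label_tiff()].
#'
#' @param image numeric matrix (`[row, col]`).
#' @param path output file.
#' @export
write_image_tiff <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param labels integer label matrix (0 = background, labels < 65536).
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stopf("labels exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read images written by [write_image_tiff()] / [write_label_tiff()]
#'
#' @param path TIFF file path.
#' @return numeric matrix on 0..1 scale, or integer label matrix.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname read_image_tiff
#' @export
read_label_tiff <- function(path) {
  img <- read_image_tiff(path)
  matrix(as.integer(round(img * 65535)), nrow = nrow(img))
}
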