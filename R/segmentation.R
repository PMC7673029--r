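# Nuclei segmentation, label expansion into cell territories, and
# spot-to-cell assignment.

#' Segment nuclei by watershed on the distance transform
#'
#' Foreground is selected with Otsu's threshold, the Euclidean distance
#' transform is computed inside the foreground, and the watershed is flooded
#' from its regional maxima, splitting touching nuclei at distance-map
#' ridges. `min_sep` is the neighborhood radius used when detecting maxima:
#' two seeds closer than this merge into one object.
#'
#' @param image 2D numeric matrix (`[row, col]`), any non-negative scale.
#' @param min_sep minimum seed separation in pixels; set near the expected
#'   nucleus radius.
#' @param tolerance minimum distance-map depth separating two objects.
#' @return integer label matrix (class `matrix`), 0 = background, labels
#'   1..N.
#' @export
segment_nuclei <- function(image, min_sep = 5, tolerance = 1) {
  if (length(dim(image)) != 2L || !is.numeric(image))
    stopf("image must be a 2D numeric matrix")
  rng <- range(image)
  if (rng[2] <= rng[1])
    return(matrix(0L, nrow(image), ncol(image)))  # flat image: nothing to find
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  if (!any(mask)) return(matrix(0L, nrow(image), ncol(image)))
  d <- EBImage::distmap(EBImage::Image(mask * 1))
  w <- EBImage::watershed(d, tolerance = tolerance, ext = max(1, round(min_sep)))
  matrix(as.integer(EBImage::imageData(w)), nrow = nrow(image))
}

#' Expand labels into surrounding background by nearest-label assignment
#'
#' Every background pixel within Euclidean distance `radius` of at least one
#' labelled pixel receives the label of its nearest labelled pixel; exact
#' distance ties go to the lower label id. Existing labels are never
#' overwritten, so nuclei keep their identity and territories are nested in
#' the radius: the expansion at radius r1 is contained in the expansion at
#' any r2 >= r1.
#'
#' @param labels integer label matrix (0 = background).
#' @param radius maximum expansion distance in pixels (>= 0).
#' @return integer label matrix of expanded territories.
#' @export
expand_labels <- function(labels, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius < 0)
    stopf("radius must be a single non-negative number")
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (radius == 0) return(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  out <- labels
  best <- matrix(Inf, nrow(labels), ncol(labels))
  bg <- labels == 0L
  pad <- as.integer(ceiling(radius)) + 1L
  pix <- which(labels > 0L, arr.ind = TRUE)
  for (l in ids) {
    # a label can only claim pixels within `radius`, so the distance
    # transform runs on a window cropped to the label's padded bounding box
    pl <- pix[labels[pix] == l, , drop = FALSE]
    rr <- max(1L, min(pl[, 1]) - pad):min(nrow(labels), max(pl[, 1]) + pad)
    cc <- max(1L, min(pl[, 2]) - pad):min(ncol(labels), max(pl[, 2]) + pad)
    win <- labels[rr, cc, drop = FALSE]
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image((win != l) * 1)))
    take <- bg[rr, cc] & d <= radius & d < best[rr, cc]
    if (any(take)) {
      sub_out <- out[rr, cc]; sub_out[take] <- l
      out[rr, cc] <- sub_out
      sub_best <- best[rr, cc]; sub_best[take] <- d[take]
      best[rr, cc] <- sub_best
    }
  }
  out
}

#' Assign decoded spots to cell territories
#'
#' Each spot with status `assigned` is mapped to the territory label under
#' its coordinates (nearest pixel center; coordinates are 0-based with
#' x = column, y = row) and increments that cell's count for its gene; spots
#' over background are tallied per gene as unassigned. Every territory label
#' becomes a row even if it received no spots. Each cell is annotated with
#' the region strip containing its centroid.
#'
#' @param decoded a [decode_spots()] result (or any data frame with `x`, `y`,
#'   `gene`, `status`, `spot_id`).
#' @param territories integer label matrix from [expand_labels()] (or
#'   [segment_nuclei()]).
#' @param regions optional region data frame (`region`, `xmin`, `xmax`) as in
#'   [sim_config()].
#' @param genes optional character vector fixing the gene (column) set.
#' @return object of class `cell_by_gene`: list with `counts` (cells x genes
#'   integer matrix, rownames = label ids), `cells` (data frame: `cell`, `x`,
#'   `y` centroid, `region`), `unassigned` (named per-gene counts), `genes`.
#' @export
assign_spots <- function(decoded, territories, regions = NULL, genes = NULL) {
  h <- nrow(territories); w <- ncol(territories)
  keep <- decoded$status == "assigned"
  d <- decoded[keep, , drop = FALSE]
  col <- as.integer(round(d$x)) + 1L
  row <- as.integer(round(d$y)) + 1L
  oob <- col < 1L | col > w | row < 1L | row > h
  if (any(oob))
    stopf("spot(s) out of image bounds: %s",
          paste(utils::head(d$spot_id[oob], 20), collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(d$gene))
  ids <- sort(unique(territories[territories > 0L]))
  counts <- matrix(0L, length(ids), length(genes),
                   dimnames = list(as.character(ids), genes))
  unassigned <- stats::setNames(integer(length(genes)), genes)
  if (nrow(d)) {
    lab <- territories[cbind(row, col)]
    gi <- match(d$gene, genes)
    hit <- lab > 0L
    if (any(hit)) {
      t3 <- table(factor(lab[hit], levels = ids),
                  factor(d$gene[hit], levels = genes))
      counts <- matrix(as.integer(t3), nrow = length(ids),
                       dimnames = list(as.character(ids), genes))
    }
    if (any(!hit)) {
      tu <- table(factor(d$gene[!hit], levels = genes))
      unassigned <- stats::setNames(as.integer(tu), genes)
    }
  }
  cents <- label_centroids(territories, ids)
  region <- if (!is.null(regions)) region_of(cents$x, regions) else
    rep(NA_character_, length(ids))
  structure(
    list(counts = counts,
         cells = data.frame(cell = ids, x = cents$x, y = cents$y,
                            region = region, stringsAsFactors = FALSE),
         unassigned = unassigned, genes = genes),
    class = "cell_by_gene"
  )
}

# Centroids of labelled pixels in 0-based (x = col - 1, y = row - 1) coords.
label_centroids <- function(labels, ids = sort(unique(labels[labels > 0L]))) {
  pix <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[pix]
  fx <- tapply(pix[, "col"] - 1, factor(lab, levels = ids), mean)
  fy <- tapply(pix[, "row"] - 1, factor(lab, levels = ids), mean)
  data.frame(cell = ids, x = as.numeric(fx), y = as.numeric(fy))
}

#' @export
print.cell_by_gene <- function(x, ...) {
  cat(sprintf("<cell_by_gene> %d cells x %d genes, %d unassigned spot(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$unassigned)))
  invisible(x)
}
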