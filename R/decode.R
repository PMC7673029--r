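# ISS barcode decoding: per-cycle base calling with quality scores,
# per-spot thresholding and gene lookup.

#' Call bases and quality scores for one spot
#'
#' For each sequencing cycle the called base is the one whose channel has the
#' highest fluorescence intensity; its quality score is the maximum signal
#' divided by the sum of all signals in that cycle. With four channels the
#' score ranges from 0.25 (uninformative, all channels equal) to 1
#' (unambiguous, one-hot). Argmax ties are broken toward the lowest channel
#' index in the fixed A, C, G, T channel order; a cycle with no signal at all
#' is assigned quality 0 (and base "A" by the tie rule), which forces the spot
#' below any positive quality threshold.
#'
#' @param intensity numeric matrix, cycles x 4 channels, non-negative finite
#'   intensities; channel columns in A, C, G, T order.
#' @return list with `barcode` (character) and `qualities` (numeric, one per
#'   cycle).
#' @examples
#' call_bases(rbind(c(8, 4, 2, 2)))  # base "A", quality 0.5
#' @export
call_bases <- function(intensity) {
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != 4L) stopf("intensity matrix must have 4 channels")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("intensities must be non-negative and finite")
  alphabet <- c("A", "C", "G", "T")
  idx <- max.col(intensity, ties.method = "first")
  tot <- rowSums(intensity)
  mx <- intensity[cbind(seq_len(nrow(intensity)), idx)]
  q <- ifelse(tot > 0, mx / tot, 0)
  list(barcode = paste(alphabet[idx], collapse = ""), qualities = q)
}

# Extract the N x L x 4 intensity array from a spots table with
# cycle{c}_ch{k} columns (cycles 1-based, channels 0-based).
spot_intensity_array <- function(spots, cycles = 4L, channels = 4L) {
  cols <- outer(seq_len(cycles), seq_len(channels) - 1L,
                function(c, k) sprintf("cycle%d_ch%d", c, k))
  missing <- setdiff(as.vector(cols), names(spots))
  if (length(missing))
    stopf("spots table is missing intensity columns: %s",
          paste(missing, collapse = ", "))
  arr <- array(NA_real_, c(nrow(spots), cycles, channels))
  for (c in seq_len(cycles)) for (k in seq_len(channels))
    arr[, c, k] <- spots[[cols[c, k]]]
  if (any(!is.finite(arr)) || any(arr < 0))
    stopf("intensities must be non-negative and finite")
  arr
}

#' Decode a table of ISS spots against a barcode book
#'
#' Calls bases per cycle (see [call_bases()]), combines per-cycle qualities
#' into an overall spot quality Q = min over cycles, thresholds at `q_min`,
#' and looks the surviving barcodes up in the book. Each spot receives one of
#' three statuses: `low_quality` (Q < `q_min`), `assigned` (barcode found in
#' the book) or `unexpected` (good quality but barcode absent from the book).
#' Coordinates are carried through so assigned spots can be mapped to cells.
#'
#' @param spots data frame with columns `spot_id`, `x`, `y` and intensity
#'   columns `cycle{c}_ch{k}` (cycles 1..L, channels 0..3 in A,C,G,T order).
#' @param book a [barcode_book].
#' @param q_min quality threshold in \[0, 1\]; default 0.5, the midpoint
#'   between a random four-channel call (0.25) and a perfect one (1).
#' @param per_cycle if `TRUE`, threshold each cycle's quality instead of the
#'   per-spot minimum (the two are equivalent for the minimum combiner; the
#'   switch exists because the thresholding granularity is a configuration
#'   choice).
#' @return data frame of class `decoded_spots`: `spot_id`, `x`, `y`,
#'   `barcode`, per-cycle qualities `q_cycle{c}`, overall `quality`, `gene`
#'   (NA unless assigned) and `status`.
#' @export
decode_spots <- function(spots, book, q_min = 0.5, per_cycle = FALSE) {
  stopifnot(inherits(book, "barcode_book"))
  if (length(book$genes) == 0L) stopf("barcode book is empty")
  assert_scalar_number(q_min, "q_min", 0, 1)
  L <- book$length
  arr <- spot_intensity_array(spots, cycles = L)
  n <- nrow(spots)
  alphabet <- book$alphabet

  bases <- matrix("A", n, L)
  quals <- matrix(0, n, L)
  for (c in seq_len(L)) {
    M <- arr[, c, , drop = TRUE]
    if (n == 1L) M <- matrix(M, nrow = 1L)
    idx <- max.col(M, ties.method = "first")
    tot <- rowSums(M)
    mx <- M[cbind(seq_len(n), idx)]
    bases[, c] <- alphabet[idx]
    quals[, c] <- ifelse(tot > 0, mx / tot, 0)
  }
  barcode <- apply(bases, 1L, paste, collapse = "")
  if (n == 0L) barcode <- character(0)
  quality <- if (n) apply(quals, 1L, min) else numeric(0)

  pass <- if (per_cycle) {
    if (n) apply(quals >= q_min, 1L, all) else logical(0)
  } else quality >= q_min
  lookup <- stats::setNames(names(book$genes), book$genes)
  gene <- unname(lookup[barcode])
  status <- ifelse(!pass, "low_quality",
                   ifelse(is.na(gene), "unexpected", "assigned"))
  gene[status != "assigned"] <- NA_character_

  out <- data.frame(
    spot_id = spots$spot_id, x = spots$x, y = spots$y,
    barcode = barcode, stringsAsFactors = FALSE
  )
  colnames(quals) <- sprintf("q_cycle%d", seq_len(L))
  out <- cbind(out, as.data.frame(quals))
  out$quality <- quality
  out$gene <- gene
  out$status <- status
  class(out) <- c("decoded_spots", "data.frame")
  out
}

#' Tabulate decoded barcode frequencies
#'
#' Counts how often each barcode sequence was seen, partitioned by decoding
#' status: assigned barcodes are labelled with their gene, the rest with the
#' status category (`unexpected`, `low_quality`). Totals equal the number of
#' input spots.
#'
#' @param decoded output of [decode_spots()].
#' @return data frame with columns `barcode`, `label` and `count`, sorted by
#'   decreasing count.
#' @export
barcode_frequency <- function(decoded) {
  if (nrow(decoded) == 0L)
    return(data.frame(barcode = character(0), label = character(0),
                      count = integer(0)))
  label <- ifelse(decoded$status == "assigned", decoded$gene, decoded$status)
  tab <- as.data.frame(table(barcode = decoded$barcode, label = label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  tab <- data.frame(barcode = tab$barcode, label = tab$label,
                    count = as.integer(tab$Freq))
  tab[order(-tab$count, tab$barcode), , drop = FALSE]
}
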