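#' Barcode books: gene-to-barcode dictionaries
#'
#' An in situ sequencing (ISS) experiment tags each targeted gene with a fixed
#' length barcode over the alphabet A, C, G, T; one base is read out per
#' sequencing cycle, each base reporting in a fixed fluorescence channel
#' (A = Cy5, C = Texas Red, G = Cy3, T = AF488, i.e. channels 0..3 in the
#' order A, C, G, T).
#'
#' @param barcodes named character vector: names are gene symbols, values are
#'   barcode strings of equal length over `{A,C,G,T}`.
#' @return an object of class `barcode_book` with elements `genes` (the named
#'   barcode vector), `length` (barcode length L) and `alphabet`.
#' @examples
#' barcode_book(c(Klk6 = "ACGT", Ptgds = "TGCA"))
#' @export
barcode_book <- function(barcodes) {
  if (length(barcodes) == 0L) stopf("barcode book is empty")
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
    stopf("barcodes must be a named character vector (gene -> barcode)")
  barcodes <- vapply(barcodes, as.character, character(1))
  L <- unique(nchar(barcodes))
  if (length(L) != 1L) stopf("all barcodes must have the same length")
  if (anyDuplicated(barcodes)) stopf("barcodes must be unique across genes")
  if (anyDuplicated(names(barcodes))) stopf("gene names must be unique")
  bad <- grepl("[^ACGT]", barcodes)
  if (any(bad))
    stopf("barcodes contain characters outside {A,C,G,T}: %s",
          paste(names(barcodes)[bad], collapse = ", "))
  structure(
    list(genes = barcodes, length = L, alphabet = c("A", "C", "G", "T")),
    class = "barcode_book"
  )
}

#' @export
print.barcode_book <- function(x, ...) {
  cat(sprintf("<barcode_book> %d genes, barcode length %d\n",
              length(x$genes), x$length))
  invisible(x)
}

#' Default synthetic 12-gene barcode book
#'
#' A synthetic book covering the oligodendrocyte-lineage marker panel used by
#' the simulator (lineage gates Sox10/Plp1, population markers and Pdgfra).
#' The barcodes themselves are arbitrary unique 4-mers, not the probes of any
#' real assay.
#'
#' @return a [barcode_book] with 12 genes and 4-base barcodes.
#' @export
default_barcode_book <- function() {
  barcode_book(c(
    Sox10  = "ACGT", Plp1  = "TGCA", Anxa5 = "AACC", Klk6   = "GGTT",
    Hopx   = "CAGT", Ptgds = "TTAA", Car2  = "CCGG", Grm3   = "GATC",
    Ptprz1 = "CTAG", Egr2  = "AGCT", Aspa  = "TCGA", Pdgfra = "GTCA"
  ))
}

#' Read / write a barcode book as CSV
#'
#' The CSV has two columns, `gene` and `barcode`.
#'
#' @param path file path.
#' @return `read_barcode_book` returns a [barcode_book].
#' @export
read_barcode_book <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "barcode") %in% names(df)))
    stopf("barcode book CSV must have columns `gene` and `barcode`")
  barcode_book(stats::setNames(df$barcode, df$gene))
}

#' @rdname read_barcode_book
#' @param book a [barcode_book].
#' @export
write_barcode_book <- function(book, path) {
  stopifnot(inherits(book, "barcode_book"))
  utils::write.csv(
    data.frame(gene = names(book$genes), barcode = unname(book$genes)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
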