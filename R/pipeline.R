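# End-to-end spatial quantification: simulate -> decode -> segment ->
# type -> compose.

#' Run a full synthetic ISS quantification experiment
#'
#' Generates a tissue, renders its nuclei image, simulates ISS spots,
#' decodes them, segments and expands nuclei, assigns spots to cells, calls
#' populations and computes per-region composition — the complete chain the
#' quantification applies to a tissue section.
#'
#' @param config a [sim_config()].
#' @param book a [barcode_book].
#' @param q_min decoding quality threshold.
#' @param expansion territory expansion radius in pixels (default 10).
#' @param rules iss-mode `marker_rules`.
#' @param seed integer seed.
#' @param use_true_labels if `TRUE`, skip watershed segmentation and expand
#'   the ground-truth label image instead (isolates downstream stages from
#'   segmentation error).
#' @return list with every intermediate: `tissue`, `images`, `sim` (spots +
#'   ledger), `decoded`, `labels`, `territories`, `cbg`, `calls`,
#'   `composition`.
#' @export
run_iss_experiment <- function(config = sim_config(),
                               book = default_barcode_book(),
                               q_min = 0.5, expansion = 10,
                               rules = default_iss_rules(),
                               seed = config$seed,
                               use_true_labels = FALSE) {
  tissue <- gen_tissue(config, seed = seed)
  images <- render_nuclei_image(tissue)
  sim <- gen_iss_spots(tissue, book, config, seed = seed + 1L)
  decoded <- decode_spots(sim$spots, book, q_min = q_min)
  labels <- if (use_true_labels) images$labels else
    segment_nuclei(images$image, min_sep = mean(config$radius_range))
  territories <- expand_labels(labels, expansion)
  cbg <- assign_spots(decoded, territories, regions = config$regions,
                      genes = names(book$genes))
  calls <- classify_iss(cbg, rules)
  composition <- population_percentages(calls, denominator = "lineage")
  list(tissue = tissue, images = images, sim = sim, decoded = decoded,
       labels = labels, territories = territories, cbg = cbg, calls = calls,
       composition = composition)
}

#' Write / read an ISS spots table as CSV
#' @param spots spots data frame (`spot_id`, `x`, `y`, intensity columns).
#' @param path CSV path.
#' @export
write_spots_csv <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a decoded-spots table or composition table as CSV
#' @param x table to write.
#' @param path CSV path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
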