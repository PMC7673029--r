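# Marker-based oligodendrocyte population calling and regional composition.

#' Marker rule sets for population calling
#'
#' Two quantification modes are supported, mirroring the two assays they
#' serve:
#'
#' * **puncta** mode (RNAscope-style): a cell is lineage if Sox10-positive
#'   (immunostain boolean); each population is flagged when one marker's
#'   puncta count reaches its molecule cutoff. Defaults: MOL5/6 Ptgds >= 12,
#'   MOL2 Klk6 >= 4, MOL1 Egr2 >= 3, OPC/COP Ptprz1 >= 7.
#' * **iss** mode (decoded read counts): a cell is lineage when Sox10 and
#'   Plp1 reads both reach threshold `t`; a MOL population is flagged when
#'   additionally at least one of its marker pairs is fully at threshold
#'   (triple/quadruple co-expression); OPC/COP requires Sox10 and Ptprz1 but
#'   not Plp1. Default `t` = 1 read.
#'
#' Flags are non-exclusive: each population's percentage is computed
#' independently over the lineage denominator, so one cell may carry several
#' flags.
#'
#' @return a list of class `marker_rules` describing gates and per-population
#'   rules.
#' @export
default_puncta_rules <- function() {
  structure(list(
    mode = "puncta",
    populations = list(
      "MOL5/6"  = list(marker = "Ptgds",  cutoff = 12L),
      "MOL2"    = list(marker = "Klk6",   cutoff = 4L),
      "MOL1"    = list(marker = "Egr2",   cutoff = 3L),
      "OPC/COP" = list(marker = "Ptprz1", cutoff = 7L)
    )
  ), class = "marker_rules")
}

#' @rdname default_puncta_rules
#' @param threshold ISS positivity threshold `t` (decoded reads per gene per
#'   cell) applied to gates and markers alike.
#' @export
default_iss_rules <- function(threshold = 1L) {
  structure(list(
    mode = "iss",
    threshold = as.integer(threshold),
    gates = c("Sox10", "Plp1"),
    populations = list(
      "MOL2"    = list(pairs = list(c("Anxa5", "Klk6"), c("Anxa5", "Hopx")),
                       gates = c("Sox10", "Plp1")),
      "MOL5/6"  = list(pairs = list(c("Ptgds", "Car2"), c("Ptgds", "Grm3")),
                       gates = c("Sox10", "Plp1")),
      "OPC/COP" = list(pairs = list("Ptprz1"), gates = "Sox10")
    )
  ), class = "marker_rules")
}

#' Read / write marker rules as YAML
#' @param path file path.
#' @export
read_rules <- function(path) {
  r <- yaml::read_yaml(path)
  r$populations <- lapply(r$populations, function(p) {
    if (!is.null(p$pairs)) p$pairs <- lapply(p$pairs, unlist)
    if (!is.null(p$gates)) p$gates <- unlist(p$gates)
    p
  })
  if (!is.null(r$gates)) r$gates <- unlist(r$gates)
  structure(r, class = "marker_rules")
}

#' @rdname read_rules
#' @param rules a `marker_rules` object.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' Call populations from puncta counts (molecule cutoffs)
#'
#' Lineage is the Sox10 immunostain boolean; a population flag is set iff the
#' cell is lineage and its marker count reaches the cutoff (boundary
#' inclusive: count == cutoff flags, count == cutoff - 1 does not). When a
#' reporter column is present (fate-mapping mode, e.g. GFP), it is carried
#' through so percentages can be computed over reporter-positive lineage
#' cells.
#'
#' @param cells data frame with columns `cell`, logical `sox10`, one count
#'   column per rule marker, optionally `region`, logical `reporter` and/or
#'   `aspa`.
#' @param rules a puncta-mode `marker_rules` (default
#'   [default_puncta_rules()]).
#' @return data frame of class `cell_type_calls`: `cell`, `region` (if
#'   present), `lineage`, one logical column per population, plus any
#'   `reporter`/`aspa` columns.
#' @export
classify_puncta <- function(cells, rules = default_puncta_rules()) {
  if (!"sox10" %in% names(cells)) stopf("cells table must have a `sox10` column")
  markers <- vapply(rules$populations, function(p) p$marker, character(1))
  missing <- setdiff(markers, names(cells))
  if (length(missing))
    stopf("missing marker column(s): %s", paste(missing, collapse = ", "))
  out <- data.frame(cell = cells$cell, stringsAsFactors = FALSE)
  if ("region" %in% names(cells)) out$region <- cells$region
  out$lineage <- as.logical(cells$sox10)
  for (pop in names(rules$populations)) {
    rule <- rules$populations[[pop]]
    out[[pop]] <- out$lineage & cells[[rule$marker]] >= rule$cutoff
  }
  for (extra in intersect(c("reporter", "aspa"), names(cells)))
    out[[extra]] <- as.logical(cells[[extra]])
  class(out) <- c("cell_type_calls", "data.frame")
  attr(out, "populations") <- names(rules$populations)
  out
}

#' Call populations from ISS read counts (co-expression gating)
#'
#' Lineage requires Sox10 and Plp1 reads both at threshold; a MOL population
#' is flagged only under triple/quadruple co-expression — both genes of at
#' least one configured marker pair at threshold on top of the lineage gate.
#' OPC/COP uses the Sox10-only gate with Ptprz1 (Plp1 is not required for
#' progenitors).
#'
#' @param cbg a `cell_by_gene` object from [assign_spots()], or a cells x
#'   genes count matrix with a `cells` data frame supplied via `cells`.
#' @param rules an iss-mode `marker_rules` (default [default_iss_rules()]).
#' @param cells optional cell metadata when `cbg` is a bare matrix.
#' @return `cell_type_calls` data frame as in [classify_puncta()].
#' @export
classify_iss <- function(cbg, rules = default_iss_rules(), cells = NULL) {
  if (inherits(cbg, "cell_by_gene")) {
    counts <- cbg$counts
    cells <- cbg$cells
  } else {
    counts <- as.matrix(cbg)
    if (is.null(cells))
      cells <- data.frame(cell = rownames(counts) %||% seq_len(nrow(counts)))
  }
  t <- rules$threshold
  need <- unique(c(rules$gates,
                   unlist(lapply(rules$populations, function(p)
                     c(p$gates, unlist(p$pairs))))))
  missing <- setdiff(need, colnames(counts))
  if (length(missing))
    stopf("missing gene column(s): %s", paste(missing, collapse = ", "))
  pos <- function(g) counts[, g] >= t
  out <- data.frame(cell = cells$cell, stringsAsFactors = FALSE)
  if ("region" %in% names(cells)) out$region <- cells$region
  lineage <- Reduce(`&`, lapply(rules$gates, pos))
  out$lineage <- lineage
  for (pop in names(rules$populations)) {
    rule <- rules$populations[[pop]]
    gate <- Reduce(`&`, lapply(rule$gates %||% rules$gates, pos))
    anypair <- Reduce(`|`, lapply(rule$pairs, function(pr)
      Reduce(`&`, lapply(pr, pos))))
    out[[pop]] <- gate & anypair
  }
  class(out) <- c("cell_type_calls", "data.frame")
  attr(out, "populations") <- names(rules$populations)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-region population percentages
#'
#' For each region, a population's percentage is 100 x (flagged cells) /
#' (denominator cells). The denominator mode reproduces the study's
#' quantification variants: `"lineage"` (Sox10+ OL lineage cells, the
#' default), `"all"` (all nuclei), `"aspa"` (mature OLs, Aspa+ cells),
#' `"reporter_lineage"` (reporter-positive lineage cells, fate-mapping mode),
#' or the name of any logical column of `calls`.
#'
#' @param calls a `cell_type_calls` data frame with a `region` column.
#' @param denominator denominator mode (see above).
#' @param populations which flag columns to report (default: all from the
#'   rules used).
#' @return data frame of class `composition`: `region`, `population`,
#'   `n_population`, `n_denominator`, `percentage` (NA with a warning when a
#'   region has an empty denominator).
#' @export
population_percentages <- function(calls, denominator = "lineage",
                                   populations = attr(calls, "populations")) {
  if (!"region" %in% names(calls)) stopf("calls must carry a `region` column")
  den <- switch(denominator,
    all = rep(TRUE, nrow(calls)),
    lineage = calls$lineage,
    reporter_lineage = {
      if (!"reporter" %in% names(calls))
        stopf("reporter_lineage denominator needs a `reporter` column")
      calls$lineage & calls$reporter
    },
    {
      if (!denominator %in% names(calls))
        stopf("unknown denominator `%s`", denominator)
      as.logical(calls[[denominator]])
    })
  regions <- unique(calls$region)
  rows <- list()
  for (r in regions) {
    in_r <- calls$region == r
    n_den <- sum(den & in_r)
    if (n_den == 0L)
      warnf("region %s has an empty `%s` denominator", r, denominator)
    for (pop in populations) {
      n_pop <- sum(calls[[pop]] & den & in_r)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, population = pop, n_population = n_pop,
        n_denominator = n_den,
        percentage = if (n_den > 0L) 100 * n_pop / n_den else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("composition", "data.frame")
  out
}
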