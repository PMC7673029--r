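# Simulation configuration for the spatial (tissue / ISS / puncta) generators.

#' Default per-population ISS expression means
#'
#' Mean decoded-spot counts per cell for each simulated population over the
#' 12-gene panel. Mature populations share the lineage gates (Sox10, Plp1) and
#' differ in their marker pairs (MOL2: Anxa5/Klk6/Hopx; MOL5/6:
#' Ptgds/Car2/Grm3; MOL1: Egr2); OPC/COP express Sox10, Ptprz1 and Pdgfra
#' with moderate Plp1 (committed precursors switch Plp1 on); "Other" models
#' Sox10-negative non-oligodendrocyte nuclei.
#'
#' @return numeric matrix, populations x genes.
#' @export
default_iss_means <- function() {
  genes <- c("Sox10", "Plp1", "Anxa5", "Klk6", "Hopx", "Ptgds",
             "Car2", "Grm3", "Ptprz1", "Egr2", "Aspa", "Pdgfra")
  m <- matrix(0, nrow = 5, ncol = length(genes),
              dimnames = list(c("MOL2", "MOL5/6", "MOL1", "OPC/COP", "Other"),
                              genes))
  m["MOL2",    c("Sox10", "Plp1", "Anxa5", "Klk6", "Hopx", "Aspa")] <-
    c(8, 10, 6, 6, 3, 4)
  m["MOL5/6",  c("Sox10", "Plp1", "Ptgds", "Car2", "Grm3", "Aspa")] <-
    c(8, 10, 12, 6, 3, 4)
  m["MOL1",    c("Sox10", "Plp1", "Egr2", "Aspa")] <- c(8, 10, 5, 4)
  m["OPC/COP", c("Sox10", "Plp1", "Ptprz1", "Pdgfra")] <- c(8, 6, 7, 6)
  m
}

#' Configuration for the spatial tissue simulator
#'
#' Describes a rectangular field partitioned into axis-aligned region strips
#' (e.g. white and gray matter), populated with non-overlapping disk nuclei
#' whose population identity is drawn from region-specific proportions. The
#' defaults encode the structure the downstream quantification is built to
#' recover: MOL2 enriched in white matter (30%) and MOL5/6 in gray matter
#' (60%).
#'
#' @param field integer vector `c(width, height)` in pixels.
#' @param n_cells number of nuclei to place.
#' @param radius_range `c(min, max)` nucleus radius in pixels.
#' @param margin packing margin: nucleus centers keep pairwise distance
#'   greater than `2 * max(radius_range) + margin`, so territories expanded by
#'   up to `margin / 2` pixels cannot collide.
#' @param regions data frame with columns `region`, `xmin`, `xmax` defining
#'   non-overlapping vertical strips covering `[0, width)`; a cell belongs to
#'   the strip containing its center x (0-based pixel coordinates,
#'   x = column).
#' @param lineage_fraction named numeric: per region, the fraction of nuclei
#'   that are oligodendrocyte-lineage cells; the rest are labelled "Other"
#'   (Sox10-negative non-lineage nuclei).
#' @param proportions named list: region -> named numeric vector of population
#'   fractions *among lineage cells*, summing to 1. Stating the mix on the
#'   lineage denominator makes the planted values directly the estimand of
#'   [population_percentages()] with its default lineage denominator.
#' @param expression population x gene matrix of mean ISS spot counts per
#'   cell (see [default_iss_means()]).
#' @param dispersion negative-binomial size for spot counts; `Inf` (default)
#'   gives Poisson counts.
#' @param amplitude signal amplitude of the true channel in intensity units.
#' @param noise additive Gaussian noise sd as a fraction of `amplitude`,
#'   independent per channel, truncated at 0.
#' @param crosstalk fraction of `amplitude` leaking into each wrong channel.
#' @param background_rate expected number of background spots (random
#'   barcodes drawn uniformly from the full 4^L space, placed uniformly in
#'   the field, attached to no cell).
#' @param cycles,channels barcode length and channel count.
#' @param seed default seed used when a generator is called without one.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(field = c(512L, 512L),
                       n_cells = 150L,
                       radius_range = c(6, 9),
                       margin = 10,
                       regions = data.frame(
                         region = c("WM", "GM"),
                         xmin = c(0, field[1] / 2),
                         xmax = c(field[1] / 2, field[1])
                       ),
                       lineage_fraction = c(WM = 0.75, GM = 0.80),
                       proportions = list(
                         WM = c("MOL2" = 0.30, "MOL5/6" = 0.25, "MOL1" = 0.15,
                                "OPC/COP" = 0.30),
                         GM = c("MOL2" = 0.10, "MOL5/6" = 0.60, "MOL1" = 0.10,
                                "OPC/COP" = 0.20)
                       ),
                       expression = default_iss_means(),
                       dispersion = Inf,
                       amplitude = 1,
                       noise = 0.05,
                       crosstalk = 0.02,
                       background_rate = 0,
                       cycles = 4L,
                       channels = 4L,
                       seed = 1L) {
  field <- as.integer(field)
  if (length(field) != 2L || any(field < 8L)) stopf("field must be c(width, height), each >= 8")
  assert_scalar_number(n_cells, "n_cells", 0)
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    stopf("radius_range must be c(min, max) with 0 < min <= max")
  assert_scalar_number(margin, "margin", 0)
  if (!all(c("region", "xmin", "xmax") %in% names(regions)))
    stopf("regions must have columns region, xmin, xmax")
  regions <- regions[order(regions$xmin), , drop = FALSE]
  if (any(regions$xmax <= regions$xmin)) stopf("each region needs xmin < xmax")
  if (regions$xmin[1] > 0 || utils::tail(regions$xmax, 1) < field[1] ||
      (nrow(regions) > 1 &&
       any(abs(regions$xmin[-1] - regions$xmax[-nrow(regions)]) > 1e-9)))
    stopf("regions must partition [0, width) without gaps or overlaps")
  if (is.null(names(lineage_fraction)) ||
      !all(regions$region %in% names(lineage_fraction)) ||
      any(lineage_fraction < 0 | lineage_fraction > 1))
    stopf("lineage_fraction must be named per region with values in [0, 1]")
  missing_prop <- setdiff(regions$region, names(proportions))
  if (length(missing_prop))
    stopf("proportions missing for region(s): %s",
          paste(missing_prop, collapse = ", "))
  for (r in regions$region) {
    p <- proportions[[r]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stopf("proportions for region %s must be named, non-negative and sum to 1", r)
    bad <- setdiff(names(p), rownames(expression))
    if (length(bad))
      stopf("population(s) %s in region %s have no expression row",
            paste(bad, collapse = ", "), r)
  }
  if (any(lineage_fraction < 1) && !"Other" %in% rownames(expression))
    stopf("expression needs an \"Other\" row when lineage_fraction < 1")
  assert_scalar_number(noise, "noise", 0)
  assert_scalar_number(crosstalk, "crosstalk", 0, 1)
  assert_scalar_number(background_rate, "background_rate", 0)
  assert_scalar_number(amplitude, "amplitude", min = 1e-12)
  structure(
    list(field = field, n_cells = as.integer(n_cells),
         radius_range = radius_range, margin = margin, regions = regions,
         lineage_fraction = lineage_fraction,
         proportions = proportions, expression = expression,
         dispersion = dispersion, amplitude = amplitude, noise = noise,
         crosstalk = crosstalk, background_rate = background_rate,
         cycles = as.integer(cycles), channels = as.integer(channels),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %dx%d px, %d cells, %d region(s): %s\n",
              x$field[1], x$field[2], x$n_cells, nrow(x$regions),
              paste(x$regions$region, collapse = ", ")))
  invisible(x)
}

#' Write a configuration echo as YAML
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg$regions <- as.list(cfg$regions)
  cfg$expression <- list(populations = rownames(config$expression),
                         genes = colnames(config$expression),
                         means = as.vector(config$expression))
  cfg$proportions <- lapply(cfg$proportions, as.list)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
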