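#' Cell biovolume from measured dimensions
#'
#' Rods and ovoids are modelled as a cylinder with hemispherical caps,
#' `V = (pi/4) * w^2 * (l - w/3)`; spheres as `V = (pi/6) * d^3` (with the
#' diameter taken from the length column). The rod formula degenerates
#' continuously to the sphere formula when `l = w`. Dimensions are in
#' micrometers, volumes in cubic micrometers.
#'
#' @param length cell length (or sphere diameter), um; vectorised.
#' @param width cell width, um; ignored for spheres.
#' @param shape `"rod"`, `"sphere"` or `"ovoid"`; recycled.
#' @return numeric vector of volumes in um^3.
#' @examples
#' cell_volume(1, 1, "sphere")          # pi/6
#' cell_volume(0.92, 0.28, "rod")       # ~0.051
#' @export
cell_volume <- function(length, width = length, shape = "rod") {
  n <- max(base::length(length), base::length(width), base::length(shape))
  length <- rep_len(length, n)
  width <- rep_len(width, n)
  shape <- rep_len(shape, n)
  if (any(!shape %in% c("rod", "sphere", "ovoid")))
    stop("shape must be rod, sphere or ovoid")
  if (any(length <= 0) || any(width <= 0))
    stop("dimensions must be positive")
  sphere <- shape == "sphere"
  if (any(!sphere & width > length + 1e-12))
    stop("width must not exceed length for rods/ovoids")
  v <- numeric(n)
  v[sphere] <- pi / 6 * length[sphere]^3
  v[!sphere] <- pi / 4 * width[!sphere]^2 * (length[!sphere] - width[!sphere] / 3)
  v
}

cell_table_volumes <- function(cells) {
  needed <- c("population", "shape", "length_um", "width_um")
  if (!all(needed %in% names(cells)))
    stop("`cells` must have columns: ", paste(needed, collapse = ", "))
  cell_volume(cells$length_um, cells$width_um, cells$shape)
}

#' Volume percentiles for one cell population
#'
#' Median and 5th/95th percentiles of per-cell biovolumes, the summary
#' plotted as box limits in CARD-FISH cell-size figures. Percentiles use
#' linear interpolation between order statistics (R's default, type 7),
#' pinned here for reproducibility.
#'
#' @param cells a cell-measurement data.frame (see [simulate_cells()]).
#' @param population population label; `NULL` summarises all rows.
#' @return list with `population`, `n`, `volume_p5`, `volume_median`,
#'   `volume_p95`, `volume_mean`; an empty population yields `n = 0` and
#'   `NA` summaries rather than an error.
#' @export
population_summary <- function(cells, population = NULL) {
  sel <- if (is.null(population)) rep(TRUE, nrow(cells))
         else cells$population == population
  sub <- cells[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(population = population, n = 0L, volume_p5 = NA_real_,
                volume_median = NA_real_, volume_p95 = NA_real_,
                volume_mean = NA_real_))
  }
  v <- cell_table_volumes(sub)
  q <- quantile(v, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  list(population = population, n = nrow(sub), volume_p5 = q[1],
       volume_median = q[2], volume_p95 = q[3], volume_mean = mean(v))
}

#' Abundance and biomass share of a focal population
#'
#' Computes the focal population's share of cell counts (abundance) and of
#' summed biovolume (biomass, with volume as the biomass proxy under
#' constant density), and their ratio. Algebraically the ratio equals the
#' mean focal volume divided by the mean volume over all cells, so a
#' population of large cells can contribute, say, almost 20% of community
#' biomass at only 10% abundance (ratio near 2).
#'
#' @param cells a cell-measurement data.frame; must be non-empty and contain
#'   the focal population.
#' @param focal focal population label.
#' @return A `population_biomass`: list with `abundance_pct`, `biomass_pct`,
#'   `ratio`, per-population volume percentiles (`focal`, `all` from
#'   [population_summary()]) and cell counts.
#' @examples
#' cells <- rbind(
#'   data.frame(cell_id = sprintf("f%03d", 1:100), population = "focal",
#'              shape = "sphere", length_um = 0.52416, width_um = 0.52416),
#'   data.frame(cell_id = sprintf("b%03d", 1:900), population = "other",
#'              shape = "sphere", length_um = 0.40, width_um = 0.40))
#' biomass_share(cells, "focal")
#' @export
biomass_share <- function(cells, focal) {
  if (nrow(cells) == 0L) stop("empty cell table")
  is_focal <- cells$population == focal
  if (!any(is_focal)) stop("no cells in focal population ", focal)
  v <- cell_table_volumes(cells)
  abundance_pct <- 100 * sum(is_focal) / nrow(cells)
  biomass_pct <- 100 * sum(v[is_focal]) / sum(v)
  structure(list(focal_population = focal,
                 n_focal = sum(is_focal), n_all = nrow(cells),
                 abundance_pct = abundance_pct, biomass_pct = biomass_pct,
                 ratio = biomass_pct / abundance_pct,
                 focal = population_summary(cells, focal),
                 all = population_summary(cells, NULL)),
            class = "population_biomass")
}

#' @export
print.population_biomass <- function(x, ...) {
  cat(sprintf(
    "<population_biomass> %s: %.1f%% of cells, %.1f%% of biomass (ratio %.2f)\n",
    x$focal_population, x$abundance_pct, x$biomass_pct, x$ratio))
  cat(sprintf("  focal volume median %.4g um^3 (p5 %.4g, p95 %.4g; n = %d)\n",
              x$focal$volume_median, x$focal$volume_p5, x$focal$volume_p95,
              x$focal$n))
  invisible(x)
}

#' Optional carbon conversion for biovolumes
#'
#' Allometric carbon content per cell, `C = a * V^b` (femtograms with the
#' common defaults a = 120 fg um^-3, b = 0.72 for aquatic bacteria). Off by
#' default everywhere: [biomass_share()] uses raw biovolume as the biomass
#' proxy, and this helper is provided only as a post-hoc transform.
#'
#' @param volume biovolume(s), um^3.
#' @param a,b allometric coefficients.
#' @return carbon per cell, fg.
#' @export
carbon_content <- function(volume, a = 120, b = 0.72) {
  a * volume^b
}
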