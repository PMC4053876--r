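#' Zonal population-exposure statistics for PM2.5
#'
#' Two provincial summary statistics combine a concentration raster with a
#' population raster over a zone (province) mask:
#'
#' * **PW-PM2.5** (population-weighted concentration):
#'   \eqn{\sum_i PM_i P_i / \sum_i P_i} over the zone's valid cells —
#'   the mean concentration experienced per resident (ug/m3).
#' * **PC-PM2.5** (per-capita concentration statistic):
#'   \eqn{\sum_i PM_i P_i / n}, the population-concentration product
#'   normalised by the zone's valid cell count `n` (ug/m3 x persons per
#'   cell). An alternative simple-mean reading \eqn{\sum_i PM_i / n} is
#'   available via `form = "simple_mean"` for sensitivity checks.
#'
#' Cells masked in the concentration or population raster are excluded and
#' do not count towards `n`. Zones with zero total population have an
#' undefined PW (reported as `NA`, never 0).
#'
#' @param pm [grid_field()] of PM2.5 concentration (ug/m3).
#' @param pop [grid_field()] of population (persons per cell; see
#'   [density_to_count()] for density-style inputs).
#' @param zones A [zone_mask()] aligned with the rasters.
#' @return A tibble with one row per zone present in the mask.
#' @examples
#' tr <- grid_transform(0, 1, 1)
#' pm <- grid_field(matrix(c(10, 100), 1), transform = tr)
#' pop <- grid_field(matrix(c(3, 1), 1), transform = tr)
#' z <- zone_mask(matrix(c(1L, 1L), 1), transform = tr)
#' pw_pm25(pm, pop, z) # 32.5
#' pc_pm25(pm, pop, z) # 65
#' @export
pw_pm25 <- function(pm, pop, zones) {
  zonal_core(pm, pop, zones)[c("zone", "zone_name", "pw_pm25")]
}

#' @rdname pw_pm25
#' @param form `"population_product"` (default) or `"simple_mean"`.
#' @export
pc_pm25 <- function(pm, pop, zones, form = c("population_product",
                                             "simple_mean")) {
  form <- match.arg(form)
  out <- zonal_core(pm, pop, zones, pc_form = form)
  out[c("zone", "zone_name", "pc_pm25")]
}

zonal_core <- function(pm, pop, zones,
                       pc_form = "population_product") {
  stopifnot(inherits(pm, "grid_field"), inherits(pop, "grid_field"),
            inherits(zones, "zone_mask"))
  align_check(list(pm = pm, population = pop), zones = zones)
  valid <- pm$mask & pop$mask & zones$labels > 0L
  df <- tibble::tibble(
    zone = as.vector(zones$labels)[as.vector(valid)],
    pm = as.vector(pm$values)[as.vector(valid)],
    pop = as.vector(pop$values)[as.vector(valid)]
  )
  present <- sort(unique(as.vector(zones$labels[zones$labels > 0L])))
  out <- df |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      n_valid_cells = dplyr::n(),
      total_population = sum(.data$pop),
      pw_pm25 = if (sum(.data$pop) > 0) {
        sum(.data$pm * .data$pop) / sum(.data$pop)
      } else NA_real_,
      pc_pm25 = if (pc_form == "population_product") {
        sum(.data$pm * .data$pop) / dplyr::n()
      } else mean(.data$pm),
      .groups = "drop"
    )
  empty <- setdiff(present, out$zone)
  if (length(empty)) {
    warning("zone(s) with no valid cells omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  if (any(out$total_population == 0)) {
    warning("zone(s) with zero population: PW-PM2.5 undefined for zone(s) ",
            paste(out$zone[out$total_population == 0], collapse = ", "),
            call. = FALSE)
  }
  out$zone_name <- unname(zones$zone_names[as.character(out$zone)])
  dplyr::select(out, "zone", "zone_name", dplyr::everything())
}

#' Full zonal exposure report
#'
#' Assembles both exposure statistics with cell counts, total population and
#' ranks per zone (rank 1 = highest value of the statistic), ready to write
#' as CSV.
#'
#' @inheritParams pw_pm25
#' @inheritParams pc_pm25
#' @return Tibble of class `zonal_exposure` with columns `zone`,
#'   `zone_name`, `n_valid_cells`, `total_population`, `pc_pm25`,
#'   `pw_pm25`, `rank_pc`, `rank_pw`.
#' @export
zonal_report <- function(pm, pop, zones, form = c("population_product",
                                                  "simple_mean")) {
  form <- match.arg(form)
  out <- zonal_core(pm, pop, zones, pc_form = form) |>
    dplyr::mutate(
      rank_pc = rank(-.data$pc_pm25, ties.method = "min", na.last = "keep"),
      rank_pw = rank(-.data$pw_pm25, ties.method = "min", na.last = "keep")
    ) |>
    dplyr::select("zone", "zone_name", "n_valid_cells", "total_population",
                  "pc_pm25", "pw_pm25", "rank_pc", "rank_pw")
  class(out) <- c("zonal_exposure", class(out))
  attr(out, "pc_form") <- form
  out
}

#' Convert a population-density raster to per-cell counts
#'
#' Gridded population products ship either persons per cell or persons per
#' km^2; the exposure statistics expect counts. Multiplies density by each
#' cell's area on a sphere (cells at higher latitude are smaller).
#'
#' @param density [grid_field()] in persons per km^2, on a geographic grid
#'   (degrees).
#' @param radius_km Earth radius, km.
#' @return [grid_field()] in persons per cell.
#' @export
density_to_count <- function(density, radius_km = 6371) {
  stopifnot(inherits(density, "grid_field"))
  tr <- density$transform
  cc <- cell_centers(density)
  # spherical cell area: R^2 * dlon * (sin(lat_top) - sin(lat_bottom))
  deg <- pi / 180
  lat_top <- (cc$y - tr$dy / 2) * deg
  lat_bot <- (cc$y + tr$dy / 2) * deg
  area <- radius_km^2 * (tr$dx * deg) * abs(sin(lat_top) - sin(lat_bot))
  grid_field(density$values * area, mask = density$mask, transform = tr,
             crs = density$crs, variable = density$variable,
             units = "persons/cell")
}
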