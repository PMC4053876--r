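#' Configuration of the synthetic study region
#'
#' One `sim_config` drives the whole synthetic fixture set: co-registered
#' predictor rasters, ground-truth PM surfaces, population density, zone
#' labels and sampled station tables. A single `seed` makes every product
#' bit-reproducible; sub-generators draw from seeds derived by the documented
#' splitting rule `sub_seed(seed, k) = (seed + 99991 * k) mod (2^31 - 1)`.
#'
#' @param rows,cols Grid shape; at least 4 each. Default 40 x 40.
#' @param cell_size Cell size in degrees (default 0.1, the satellite aerosol
#'   product grid).
#' @param xmin,ymax Geographic origin (upper-left corner), degrees.
#' @param seed Integer master seed.
#' @param smoothness Spatial correlation length of the predictor fields, in
#'   cells (Gaussian smoothing kernel width).
#' @param noise_sd Observation noise added to station PM records and to the
#'   truth surfaces, ug/m3. Default 8, a plausible scale for annual-mean
#'   ground PM records.
#' @param n_stations Number of ground stations sampled.
#' @param n_zones Number of contiguous zones ("provinces").
#' @param truth Named coefficient list of the ground-truth PM function; see
#'   [truth_spec()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rows = 40, cols = 40, cell_size = 0.1,
                       xmin = 100, ymax = 40, seed = 1,
                       smoothness = 5, noise_sd = 8,
                       n_stations = 300, n_zones = 8,
                       truth = truth_spec()) {
  stopifnot(is.numeric(rows), is.numeric(cols), rows >= 4, cols >= 4,
            cell_size > 0, n_zones >= 1, noise_sd >= 0, n_stations >= 1,
            smoothness >= 1)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         cell_size = cell_size, xmin = xmin, ymax = ymax,
         seed = as.integer(seed), smoothness = smoothness,
         noise_sd = noise_sd, n_stations = as.integer(n_stations),
         n_zones = as.integer(n_zones), truth = truth),
    class = "sim_config"
  )
}

sub_seed <- function(seed, k) as.integer((seed + 99991 * k) %% 2147483647)

config_transform <- function(config) {
  grid_transform(config$xmin, config$ymax, config$cell_size)
}

#' Coefficients of the synthetic ground-truth PM function
#'
#' The truth surfaces are a smooth nonlinear function of the predictor
#' fields, increasing in aerosol optical thickness (AOT) and relative
#' humidity (hygroscopic particle growth), decreasing in boundary-layer
#' height (vertical dilution) and wind speed (ventilation), with a mild skin
#' temperature term:
#'
#' \deqn{PM_{2.5} = b + g_A \, AOT \, (1 + g_R (RH/100)^2)
#'       \frac{H}{HPBL + H_0} \frac{W_0}{WS + W_0} + g_T (SKT - T_0)}
#'
#' and \eqn{PM_{10} = PM_{2.5} + c_0 + c_A \, AOT \, (1.05 - SSA) \, c_s},
#' a non-negative coarse-mode addition (absorbing, low-SSA aerosol loads
#' carry the dust/coarse signal), so `PM10_true >= PM25_true` everywhere.
#'
#' @param pm25_base Background fine PM, ug/m3 (`b`).
#' @param aot_gain Gain on the AOT term (`g_A`).
#' @param rh_gain Relative-humidity amplification (`g_R`).
#' @param hpbl_scale,hpbl_ref Boundary-layer dilution scale `H` and offset
#'   `H_0`, m.
#' @param ws_ref Wind ventilation scale `W_0`, m/s.
#' @param skt_gain,skt_ref Skin-temperature slope `g_T` (ug/m3 per K) and
#'   reference `T_0` (K).
#' @param coarse_base,coarse_aot_gain,coarse_scale Coarse-mode coefficients
#'   `c_0`, `c_A`, `c_s`.
#' @return Named list of coefficients.
#' @export
truth_spec <- function(pm25_base = 20, aot_gain = 250, rh_gain = 1.5,
                       hpbl_scale = 1000, hpbl_ref = 500, ws_ref = 3,
                       skt_gain = 0.4, skt_ref = 285,
                       coarse_base = 15, coarse_aot_gain = 60,
                       coarse_scale = 4) {
  as.list(environment())
}

# Separable truncated-Gaussian smoothing of a matrix; kernel sd = width,
# support 3*width, edge-renormalised. Implemented as banded row/col operators.
smooth_matrix <- function(m, width) {
  k1 <- function(n) {
    half <- max(1L, ceiling(3 * width))
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= half, exp(-d^2 / (2 * width^2)), 0)
    })
    K / rowSums(K)
  }
  k1(nrow(m)) %*% m %*% t(k1(ncol(m)))
}

# Standardised spatially correlated Gaussian field.
gaussian_field <- function(rows, cols, smoothness, seed) {
  z <- withr::with_seed(seed, matrix(stats::rnorm(rows * cols), rows, cols))
  s <- smooth_matrix(z, smoothness)
  (s - mean(s)) / stats::sd(s)
}

#' Simulate co-registered predictor rasters and ground-truth PM surfaces
#'
#' Emits the eight screened predictors — `lat`, `lon`, `WS` (wind speed,
#' m/s), `RH` (relative humidity, %), `SKT` (skin temperature, K), `HPBL`
#' (boundary-layer height, m), `AOT` (aerosol optical thickness), `SSA`
#' (single scattering albedo) — plus `PM25_true` and `PM10_true` (ug/m3).
#' Predictors are spatially correlated (smoothed white noise) and clipped to
#' physical ranges; the truth surfaces follow [truth_spec()] with additive
#' Gaussian noise of sd `config$noise_sd` (set it to 0 for an exact function
#' of the predictors).
#'
#' @param config A [sim_config()].
#' @return Named list of [grid_field()]s, mutually aligned.
#' @export
simulate_fields <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$rows; c <- config$cols; w <- config$smoothness
  tr <- config_transform(config)
  gf <- function(values, variable, units = "") {
    grid_field(values, transform = tr, variable = variable, units = units)
  }
  z <- lapply(1:7, function(k) {
    gaussian_field(r, c, w, sub_seed(config$seed, k))
  })
  cc_tmp <- cell_centers(gf(matrix(0, r, c), "tmp"))
  ws   <- pmax(4 + 2 * z[[1]], 0)
  rh   <- pmin(pmax(65 + 15 * z[[2]], 5), 100)
  skt  <- 288 + 8 * z[[3]]
  hpbl <- pmax(800 + 300 * z[[4]], 50)
  aot  <- 0.6 * exp(0.6 * z[[5]])
  ssa  <- pmin(pmax(0.92 + 0.03 * z[[6]], 0.70), 1.0)
  ts <- config$truth
  pm25 <- ts$pm25_base +
    ts$aot_gain * aot * (1 + ts$rh_gain * (rh / 100)^2) *
      (ts$hpbl_scale / (hpbl + ts$hpbl_ref)) * (ts$ws_ref / (ws + ts$ws_ref)) +
    ts$skt_gain * (skt - ts$skt_ref)
  coarse <- ts$coarse_base +
    ts$coarse_aot_gain * aot * (1.05 - ssa) * ts$coarse_scale
  if (config$noise_sd > 0) {
    e <- withr::with_seed(sub_seed(config$seed, 7),
                          matrix(stats::rnorm(r * c, sd = config$noise_sd),
                                 r, c))
    pm25 <- pm25 + e
  }
  pm25 <- pmax(pm25, 1)
  pm10 <- pm25 + coarse
  list(
    lat = gf(cc_tmp$y, "lat", "degrees"),
    lon = gf(cc_tmp$x, "lon", "degrees"),
    WS = gf(ws, "WS", "m/s"),
    RH = gf(rh, "RH", "%"),
    SKT = gf(skt, "SKT", "K"),
    HPBL = gf(hpbl, "HPBL", "m"),
    AOT = gf(aot, "AOT"),
    SSA = gf(ssa, "SSA"),
    PM25_true = gf(pm25, "PM25_true", "ug/m3"),
    PM10_true = gf(pm10, "PM10_true", "ug/m3")
  )
}

#' Simulate a clustered population-density surface
#'
#' A log-normal rural background (lightly smoothed) with `n_zones`
#' high-density urban clusters (Gaussian bumps at well-separated centres),
#' emulating a gridded population product. Values are persons per cell; the
#' total is attached as the `"total_population"` attribute.
#'
#' @param config A [sim_config()].
#' @return A non-negative [grid_field()].
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$rows; c <- config$cols
  bg <- withr::with_seed(
    sub_seed(config$seed, 11),
    matrix(stats::rlnorm(r * c, meanlog = log(20), sdlog = 1), r, c))
  bg <- smooth_matrix(bg, max(1, config$smoothness / 3))
  centers <- pick_separated_cells(config, k = 12, n = config$n_zones,
                                  min_dist = 5)
  pop <- bg
  peak <- 20 * stats::quantile(bg, 0.99)
  ri <- matrix(seq_len(r), r, c)
  ci <- matrix(seq_len(c), r, c, byrow = TRUE)
  for (j in seq_len(nrow(centers))) {
    d2 <- (ri - centers[j, 1])^2 + (ci - centers[j, 2])^2
    pop <- pop + peak * exp(-d2 / (2 * 1.5^2))
  }
  out <- grid_field(pop, transform = config_transform(config),
                    variable = "population", units = "persons/cell")
  attr(out, "total_population") <- sum(pop)
  out
}

# Draw n cell (row, col) centres at least min_dist apart (greedy, seeded).
pick_separated_cells <- function(config, k, n, min_dist) {
  r <- config$rows; c <- config$cols
  withr::with_seed(sub_seed(config$seed, k), {
    chosen <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(chosen) < n && tries < 10000) {
      tries <- tries + 1
      cand <- c(sample.int(r, 1), sample.int(c, 1))
      if (nrow(chosen) == 0 ||
          all((chosen[, 1] - cand[1])^2 + (chosen[, 2] - cand[2])^2 >=
                min_dist^2)) {
        chosen <- rbind(chosen, cand)
      }
    }
    if (nrow(chosen) < n) { # dense grids: fall back to any distinct cells
      idx <- sample.int(r * c, n)
      chosen <- cbind((idx - 1) %% r + 1, (idx - 1) %/% r + 1)
    }
    chosen
  })
}

#' Simulate a contiguous zonal partition
#'
#' Voronoi partition of the grid around `n_zones` seeded cell centres: every
#' cell is labelled with its nearest centre (1..n_zones), giving contiguous,
#' exhaustive zones that stand in for provinces.
#'
#' @param config A [sim_config()].
#' @return A [zone_mask()] with labels `1..n_zones` covering all cells.
#' @export
simulate_zones <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$rows; c <- config$cols
  if (config$n_zones > r * c) {
    stop("n_zones exceeds the number of cells", call. = FALSE)
  }
  centers <- pick_separated_cells(config, k = 13, n = config$n_zones,
                                  min_dist = max(2, min(r, c) %/%
                                                   (config$n_zones)))
  ri <- matrix(seq_len(r), r, c)
  ci <- matrix(seq_len(c), r, c, byrow = TRUE)
  d2 <- array(0, c(r, c, nrow(centers)))
  for (j in seq_len(nrow(centers))) {
    d2[, , j] <- (ri - centers[j, 1])^2 + (ci - centers[j, 2])^2
  }
  labels <- apply(d2, c(1, 2), which.min)
  zone_mask(matrix(as.integer(labels), r, c),
            zone_names = stats::setNames(
              paste0("province_", seq_len(config$n_zones)),
              as.character(seq_len(config$n_zones))),
            transform = config_transform(config))
}

#' Sample ground stations from the synthetic truth surface
#'
#' Draws `n_stations` valid cells without replacement; each record copies the
#' cell's predictor values and observes `truth + N(0, noise_sd)` for the
#' requested pollutant.
#'
#' @param fields Output of [simulate_fields()] (predictors plus truth).
#' @param config The same [sim_config()].
#' @param pollutant `"PM2.5"` or `"PM10"`.
#' @return A [as_station_table()] tibble with the eight predictor columns.
#' @export
sample_stations <- function(fields, config, pollutant = c("PM2.5", "PM10")) {
  stopifnot(inherits(config, "sim_config"))
  pollutant <- match.arg(pollutant)
  pred_names <- c("lat", "lon", "WS", "RH", "SKT", "HPBL", "AOT", "SSA")
  stopifnot(all(c(pred_names, "PM25_true", "PM10_true") %in% names(fields)))
  align_check(fields)
  truth <- if (pollutant == "PM2.5") fields$PM25_true else fields$PM10_true
  valid <- which(as.vector(combined_mask(fields)))
  if (config$n_stations > length(valid)) {
    stop("requested ", config$n_stations, " stations but only ",
         length(valid), " valid cells", call. = FALSE)
  }
  offs <- if (pollutant == "PM2.5") 0L else 2L
  cells <- withr::with_seed(sub_seed(config$seed, 21 + offs),
                            sample(valid, config$n_stations))
  noise <- withr::with_seed(
    sub_seed(config$seed, 22 + offs),
    stats::rnorm(config$n_stations, sd = config$noise_sd))
  vals <- lapply(fields[pred_names], function(f) f$values[cells])
  tab <- tibble::tibble(
    id = sprintf("st%04d", seq_along(cells)),
    pollutant = pollutant,
    observed_pm = pmax(truth$values[cells] + noise, 0),
    !!!vals
  )
  as_station_table(tab, predictors = pred_names)
}

#' Generate the full synthetic fixture set
#'
#' Convenience wrapper running [simulate_fields()], [simulate_population()],
#' [simulate_zones()] and [sample_stations()] for both pollutants from one
#' config.
#'
#' @param config A [sim_config()].
#' @return List with `fields`, `population`, `zones`, `stations_pm25`,
#'   `stations_pm10`, and the `config`.
#' @export
simulate_all <- function(config = sim_config()) {
  fields <- simulate_fields(config)
  list(
    fields = fields,
    population = simulate_population(config),
    zones = simulate_zones(config),
    stations_pm25 = sample_stations(fields, config, "PM2.5"),
    stations_pm10 = sample_stations(fields, config, "PM10"),
    config = config
  )
}
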