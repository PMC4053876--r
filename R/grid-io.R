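#' Read a raster grid from an ESRI ASCII grid file
#'
#' Grids are exchanged in the ESRI ASCII grid format (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values from north to south. The
#' format is plain text and interoperable with GDAL/QGIS. Cells equal to the
#' file's no-data value are masked.
#'
#' @param path Path to an existing `.asc` file.
#' @param variable Variable name to attach to the returned field.
#' @param units Unit string to attach.
#' @param crs CRS label; the format itself carries none, so the caller's label
#'   (or the sidecar convention of [write_grid()]) is used.
#' @return A [grid_field()].
#' @seealso [write_grid()] for the inverse; round-trips preserve values, mask
#'   and transform exactly.
#' @export
read_grid <- function(path, variable = "", units = "", crs = NULL) {
  if (!file.exists(path)) {
    stop("grid file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_asc_header(lines, path)
  body <- lines[-seq_len(hdr$n_header)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    stop("malformed ASCII grid ", path, ": expected ", hdr$nrows,
         " data rows, found ", length(body), call. = FALSE)
  }
  vals <- vapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != hdr$ncols) {
      stop("malformed ASCII grid ", path, ": a data row has ", length(v),
           " values, expected ", hdr$ncols, call. = FALSE)
    }
    v
  }, numeric(hdr$ncols), USE.NAMES = FALSE)
  values <- t(matrix(vals, nrow = hdr$ncols)) # rows north -> south
  mask <- values != hdr$nodata
  values[!mask] <- NA_real_
  if (is.null(crs)) {
    sidecar <- sidecar_path(path)
    crs <- if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$crs)) as.character(meta$crs) else "WGS84 (EPSG:4326)"
    } else "WGS84 (EPSG:4326)"
  }
  grid_field(values, mask = mask,
             transform = grid_transform(
               xmin = hdr$xllcorner,
               ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
               dx = hdr$cellsize, dy = -hdr$cellsize),
             crs = crs, variable = variable, units = units)
}

parse_asc_header <- function(lines, path) {
  if (length(lines) < 7) {
    stop("not an ASCII grid (too short): ", path, call. = FALSE)
  }
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  hdr <- list()
  i <- 0
  for (ln in lines[1:6]) {
    i <- i + 1
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2 || !(tolower(parts[1]) %in% keys)) {
      stop("not an ASCII grid (unrecognised header line ", i, "): ", path,
           call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  if (!setequal(names(hdr), keys) || anyNA(unlist(hdr))) {
    stop("not an ASCII grid (incomplete header): ", path, call. = FALSE)
  }
  if (hdr$cellsize <= 0) {
    stop("malformed ASCII grid ", path, ": cellsize must be positive",
         call. = FALSE)
  }
  list(ncols = as.integer(hdr$ncols), nrows = as.integer(hdr$nrows),
       xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = hdr$nodata_value, n_header = 6L)
}

sidecar_path <- function(path) sub("\\.[A-Za-z0-9]+$", ".json", path)

#' Write a grid field to an ESRI ASCII grid file
#'
#' Values are written at full double precision so that
#' `read_grid(write_grid(f))` reproduces values, mask and transform exactly.
#' Masked cells are written as the no-data value. A JSON sidecar
#' (`<stem>.json`) records the CRS label, variable and units, which the
#' format itself cannot carry. Square cells are required (`dx == -dy`), as in
#' the format.
#'
#' @param field A [grid_field()].
#' @param path Output path; parent directory must exist.
#' @param nodata No-data sentinel; adjusted automatically if it collides with
#'   a valid value.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(field, path, nodata = -9999) {
  stopifnot(inherits(field, "grid_field"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  tr <- field$transform
  if (abs(tr$dx + tr$dy) > 1e-12 * tr$dx) {
    stop("ASCII grid requires square cells (dx == -dy); got dx = ", tr$dx,
         ", dy = ", tr$dy, call. = FALSE)
  }
  vals <- field$values
  vals[!field$mask] <- NA_real_
  while (any(vals == nodata, na.rm = TRUE)) nodata <- nodata * 2 - 1
  vals[is.na(vals)] <- nodata
  hdr <- c(
    paste("ncols", ncol(vals)),
    paste("nrows", nrow(vals)),
    paste("xllcorner", format(tr$xmin, digits = 17)),
    paste("yllcorner", format(tr$ymax + nrow(vals) * tr$dy, digits = 17)),
    paste("cellsize", format(tr$dx, digits = 17)),
    paste("NODATA_value", format(nodata, digits = 17))
  )
  rows <- apply(vals, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, rows), path)
  jsonlite::write_json(
    list(crs = field$crs, variable = field$variable, units = field$units),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read / write a zone mask (integer ASCII grid + JSON name sidecar)
#'
#' Zone masks travel as an integer ESRI ASCII grid of labels (0 = outside all
#' zones) with a JSON sidecar mapping `{id: name}`.
#'
#' @param path `.asc` path.
#' @return [read_zones()] returns a [zone_mask()].
#' @export
read_zones <- function(path) {
  f <- read_grid(path, variable = "zone")
  labels <- f$values
  labels[!f$mask] <- 0
  if (any(abs(labels - round(labels)) > 1e-9, na.rm = TRUE)) {
    stop("zone grid contains non-integer labels: ", path, call. = FALSE)
  }
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  zone_names <- NULL
  sidecar <- sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$zone_names)) {
      zone_names <- unlist(meta$zone_names)
    }
  }
  zone_mask(labels, zone_names = zone_names, transform = f$transform,
            crs = f$crs)
}

#' @rdname read_zones
#' @param zones A [zone_mask()].
#' @export
write_zones <- function(zones, path) {
  stopifnot(inherits(zones, "zone_mask"))
  f <- grid_field(matrix(as.numeric(zones$labels), nrow(zones$labels)),
                  transform = zones$transform, crs = zones$crs,
                  variable = "zone")
  write_grid(f, path)
  jsonlite::write_json(
    list(crs = zones$crs, variable = "zone",
         zone_names = as.list(zones$zone_names)),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Ground-station observation tables
#'
#' A station table is a tibble with one monitoring record per row: columns
#' `id`, `lat`, `lon`, `pollutant` (`"PM2.5"` or `"PM10"`), `observed_pm`
#' (ug/m3, non-negative) plus one numeric column per predictor. The predictor
#' column names are stored in the `"predictors"` attribute.
#'
#' `as_station_table()` validates a data frame; `read_stations()` reads and
#' validates a CSV, rejecting rows whose `observed_pm` is not numeric (row
#' numbers reported) and dropping rows with missing predictor values (count
#' reported).
#'
#' @param x A data frame with the mandatory columns above.
#' @param predictors Character vector of predictor column names; defaults to
#'   every non-mandatory numeric column.
#' @return A tibble of class `station_table`.
#' @export
as_station_table <- function(x, predictors = NULL) {
  x <- tibble::as_tibble(x)
  mandatory <- c("id", "lat", "lon", "pollutant", "observed_pm")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols)) {
    stop("station table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(x), mandatory)
    predictors <- predictors[vapply(x[predictors], is.numeric, logical(1))]
  }
  absent <- setdiff(predictors, names(x))
  if (length(absent)) {
    stop("predictor column(s) not in table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(predictors)) {
    stop("predictor names must be unique", call. = FALSE)
  }
  if (any(x$observed_pm < 0, na.rm = TRUE)) {
    stop("observed_pm must be non-negative", call. = FALSE)
  }
  structure(x, predictors = predictors,
            class = c("station_table", class(x)))
}

#' @rdname as_station_table
#' @param path CSV path with a header row.
#' @export
read_stations <- function(path, predictors = NULL) {
  if (!file.exists(path)) {
    stop("station file does not exist: ", path, call. = FALSE)
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("id", "lat", "lon", "pollutant", "observed_pm")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols)) {
    stop("station CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$observed_pm)) {
    parsed <- suppressWarnings(as.numeric(x$observed_pm))
    bad <- which(is.na(parsed) & !is.na(x$observed_pm))
    if (length(bad)) {
      warning("rejected ", length(bad),
              " row(s) with non-numeric observed_pm (rows ",
              paste(bad, collapse = ", "), ")", call. = FALSE)
    }
    x$observed_pm <- parsed
  }
  x <- dplyr::filter(x, !is.na(.data$observed_pm))
  tab <- as_station_table(x, predictors = predictors)
  pred <- attr(tab, "predictors")
  complete <- stats::complete.cases(tab[pred])
  if (any(!complete)) {
    message("dropped ", sum(!complete),
            " station row(s) with missing predictor values")
    tab <- as_station_table(tab[complete, , drop = FALSE], predictors = pred)
  }
  tab
}

#' @rdname as_station_table
#' @param table A `station_table`.
#' @export
write_stations <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

station_predictors <- function(table) {
  p <- attr(table, "predictors")
  if (is.null(p)) stop("not a station_table (use as_station_table())",
                       call. = FALSE)
  p
}
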