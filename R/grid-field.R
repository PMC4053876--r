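#' Affine georeference for a north-up raster grid
#'
#' Describes the placement of a regular grid on a coordinate plane using the
#' dominant raster convention: the origin is the *upper-left corner* of the
#' upper-left cell, the x step `dx` is positive (eastwards) and the y step
#' `dy` is negative (southwards), so row 1 is the northernmost row.
#'
#' @param xmin x coordinate (e.g. longitude, degrees) of the grid's left edge.
#' @param ymax y coordinate (e.g. latitude, degrees) of the grid's top edge.
#' @param dx Cell width in coordinate units; must be strictly positive.
#' @param dy Cell height; must be strictly negative (north-up convention).
#' @return An object of class `grid_transform`.
#' @examples
#' grid_transform(xmin = 100, ymax = 45, dx = 0.1, dy = -0.1)
#' @export
grid_transform <- function(xmin, ymax, dx, dy = -dx) {
  stopifnot(is.numeric(xmin), is.numeric(ymax), is.numeric(dx), is.numeric(dy))
  if (!is.finite(dx) || dx <= 0) {
    stop("`dx` must be strictly positive, got ", dx, call. = FALSE)
  }
  if (!is.finite(dy) || dy >= 0) {
    stop("`dy` must be strictly negative (row 1 is the northernmost row), got ",
         dy, call. = FALSE)
  }
  structure(
    list(xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         dx = as.numeric(dx), dy = as.numeric(dy)),
    class = "grid_transform"
  )
}

#' @export
print.grid_transform <- function(x, ...) {
  cat(sprintf("<grid_transform> origin (%.6g, %.6g), cell %.6g x %.6g\n",
              x$xmin, x$ymax, x$dx, x$dy))
  invisible(x)
}

transforms_equal <- function(a, b, tol = 1e-9) {
  all(abs(c(a$xmin - b$xmin, a$ymax - b$ymax, a$dx - b$dx, a$dy - b$dy)) <= tol)
}

#' A 2-D georeferenced raster field with a validity mask
#'
#' `grid_field` is the package's raster container: a numeric matrix of cell
#' values, a logical mask of the same shape (`TRUE` = valid), an affine
#' [grid_transform()] and a free-text CRS label. Masked-invalid cells are
#' excluded from every statistic computed downstream, and any cell masked in
#' any input of a multi-field computation is masked in the output.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param mask Logical matrix of the same shape, or `NULL` to mark every
#'   finite cell valid (non-finite values are masked automatically).
#' @param transform A [grid_transform()].
#' @param crs CRS label, free text; defaults to geographic WGS84.
#' @param variable Optional variable name (e.g. `"AOT"`, `"PM2.5"`).
#' @param units Optional unit string (e.g. `"ug/m3"`).
#' @return An object of class `grid_field`.
#' @examples
#' f <- grid_field(matrix(1:12, 3, 4), transform = grid_transform(0, 3, 1))
#' grid_values(f)
#' @export
grid_field <- function(values, mask = NULL,
                       transform = grid_transform(0, nrow(values), 1),
                       crs = "WGS84 (EPSG:4326)", variable = "", units = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("`values` must have at least one row and one column", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- is.finite(values)
  }
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!identical(dim(mask), dim(values))) {
    stop("`values` (", nrow(values), "x", ncol(values), ") and `mask` (",
         nrow(mask), "x", ncol(mask), ") must have identical shape",
         call. = FALSE)
  }
  mask <- mask & is.finite(values)
  stopifnot(inherits(transform, "grid_transform"))
  structure(
    list(values = values, mask = mask, transform = transform,
         crs = as.character(crs), variable = as.character(variable),
         units = as.character(units)),
    class = "grid_field"
  )
}

#' @rdname grid_field
#' @param field,x A `grid_field`.
#' @export
grid_values <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  out <- field$values
  out[!field$mask] <- NA_real_
  out
}

#' @rdname grid_field
#' @export
grid_shape <- function(field) dim(field$values)

#' @export
print.grid_field <- function(x, ...) {
  v <- grid_values(x)
  cat(sprintf("<grid_field%s> %d x %d cells, %d masked\n",
              if (nzchar(x$variable)) paste0(" ", x$variable) else "",
              nrow(v), ncol(v), sum(!x$mask)))
  print(x$transform)
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng))) {
    cat(sprintf("  values in [%.4g, %.4g]%s\n", rng[1], rng[2],
                if (nzchar(x$units)) paste0(" ", x$units) else ""))
  }
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param field A [grid_field()] or [zone_mask()].
#' @return List with matrices `x` (e.g. longitude) and `y` (latitude), the
#'   coordinates of each cell centre.
#' @export
cell_centers <- function(field) {
  tr <- field$transform
  d <- if (inherits(field, "zone_mask")) dim(field$labels) else dim(field$values)
  x <- tr$xmin + (seq_len(d[2]) - 0.5) * tr$dx
  y <- tr$ymax + (seq_len(d[1]) - 0.5) * tr$dy
  list(x = matrix(x, d[1], d[2], byrow = TRUE),
       y = matrix(y, d[1], d[2], byrow = FALSE))
}

#' Convert a grid field to a long tibble
#'
#' One row per cell with row/column indices, cell-centre coordinates, the
#' value (`NA` where masked) and the mask flag — the tidy surface over the
#' matrix container, convenient for dplyr summaries and ggplot2.
#'
#' @param field A [grid_field()].
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`, `valid`.
#' @export
grid_to_tibble <- function(field) {
  stopifnot(inherits(field, "grid_field"))
  cc <- cell_centers(field)
  d <- dim(field$values)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(cc$x),
    y = as.vector(cc$y),
    value = as.vector(grid_values(field)),
    valid = as.vector(field$mask)
  )
}

#' Integer zone labels partitioning a grid
#'
#' Zone masks carry per-cell non-negative integer labels (0 = outside all
#' zones) plus an id-to-name lookup. They must share shape and transform with
#' the `grid_field` stack they partition.
#'
#' @param labels Integer matrix of zone identifiers; 0 means "outside".
#' @param zone_names Named character vector mapping id (as name) to zone name;
#'   every nonzero label present in `labels` must appear.
#' @param transform A [grid_transform()].
#' @param crs CRS label.
#' @return An object of class `zone_mask`.
#' @export
zone_mask <- function(labels, zone_names = NULL,
                      transform = grid_transform(0, nrow(labels), 1),
                      crs = "WGS84 (EPSG:4326)") {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) {
    stop("zone labels must be non-negative (0 = outside all zones)",
         call. = FALSE)
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(zone_names)) {
    zone_names <- stats::setNames(paste0("zone_", ids), as.character(ids))
  }
  missing_ids <- setdiff(as.character(ids), names(zone_names))
  if (length(missing_ids)) {
    stop("zone ids present in labels but absent from zone_names: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(transform, "grid_transform"))
  structure(
    list(labels = labels, zone_names = zone_names, transform = transform,
         crs = as.character(crs)),
    class = "zone_mask"
  )
}

#' @export
print.zone_mask <- function(x, ...) {
  cat(sprintf("<zone_mask> %d x %d cells, %d zones\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(x$labels[x$labels > 0L]))))
  invisible(x)
}

#' Check that grid fields (and optionally a zone mask) are co-registered
#'
#' No resampling is performed anywhere in the package: inputs must share shape
#' and transform exactly (within `tol` on the transform), and this check
#' enforces it. Returns invisibly when everything agrees; otherwise raises an
#' error naming the first mismatching pair.
#'
#' @param fields A list of [grid_field()] objects (named or not), or a single
#'   field.
#' @param zones Optional [zone_mask()] checked against the first field.
#' @param tol Absolute tolerance on transform components.
#' @return Invisibly `TRUE` on success.
#' @export
align_check <- function(fields, zones = NULL, tol = 1e-9) {
  if (inherits(fields, "grid_field")) fields <- list(fields)
  if (!length(fields)) stop("need at least one field", call. = FALSE)
  ok <- vapply(fields, inherits, logical(1), what = "grid_field")
  if (!all(ok)) stop("`fields` must all be grid_field objects", call. = FALSE)
  nms <- names(fields)
  if (is.null(nms) || any(!nzchar(nms))) nms <- paste0("field ", seq_along(fields))
  ref <- fields[[1]]
  for (i in seq_along(fields)[-1]) {
    f <- fields[[i]]
    if (!identical(dim(f$values), dim(ref$values))) {
      stop(sprintf("alignment error: %s is %dx%d but %s is %dx%d",
                   nms[1], nrow(ref$values), ncol(ref$values),
                   nms[i], nrow(f$values), ncol(f$values)), call. = FALSE)
    }
    if (!transforms_equal(f$transform, ref$transform, tol)) {
      stop(sprintf("alignment error: transforms of %s and %s differ",
                   nms[1], nms[i]), call. = FALSE)
    }
  }
  if (!is.null(zones)) {
    stopifnot(inherits(zones, "zone_mask"))
    if (!identical(dim(zones$labels), dim(ref$values))) {
      stop(sprintf("alignment error: zone mask is %dx%d but %s is %dx%d",
                   nrow(zones$labels), ncol(zones$labels),
                   nms[1], nrow(ref$values), ncol(ref$values)), call. = FALSE)
    }
    if (!transforms_equal(zones$transform, ref$transform, tol)) {
      stop(sprintf("alignment error: transforms of the zone mask and %s differ",
                   nms[1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Union-of-invalid mask across a list of aligned fields.
combined_mask <- function(fields) {
  Reduce(`&`, lapply(fields, function(f) f$mask))
}
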