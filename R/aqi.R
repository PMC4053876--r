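#' Breakpoint tables for individual air-quality indexes
#'
#' An individual air-quality index (IAQI) maps a pollutant concentration to
#' an index value by piecewise-linear interpolation through an ordered table
#' of (concentration, index) breakpoints. `breakpoint_table()` builds and
#' validates one table; `default_breakpoints()` returns the 24-hour PM
#' ladders of the Chinese ambient air quality index standard (HJ 633-2012),
#' up to index 500. Tables are data, not code: edit or supply your own via
#' [read_breakpoints()].
#'
#' @param pollutant Pollutant name, e.g. `"PM2.5"`.
#' @param concentration Strictly increasing concentrations (ug/m3) starting
#'   at 0.
#' @param index Strictly increasing index values starting at 0, same length.
#' @return A tibble of class `breakpoint_table` with attributes `pollutant`
#'   and `cap_index` (the last index value, returned for concentrations
#'   beyond the table).
#' @examples
#' default_breakpoints("PM2.5")
#' @export
breakpoint_table <- function(pollutant, concentration, index) {
  if (length(concentration) != length(index) || length(index) < 2) {
    stop("need at least 2 (concentration, index) pairs of equal length",
         call. = FALSE)
  }
  if (concentration[1] != 0 || index[1] != 0) {
    stop("first breakpoint pair must be (0, 0)", call. = FALSE)
  }
  if (any(diff(concentration) <= 0) || any(diff(index) <= 0)) {
    stop("concentrations and index values must be strictly increasing",
         call. = FALSE)
  }
  structure(
    tibble::tibble(concentration = as.numeric(concentration),
                   index = as.numeric(index)),
    pollutant = as.character(pollutant),
    cap_index = as.numeric(index[length(index)]),
    class = c("breakpoint_table", class(tibble::tibble()))
  )
}

#' @rdname breakpoint_table
#' @export
default_breakpoints <- function(pollutant = c("PM2.5", "PM10")) {
  pollutant <- match.arg(pollutant)
  idx <- c(0, 50, 100, 150, 200, 300, 400, 500)
  conc <- switch(pollutant,
    "PM2.5" = c(0, 35, 75, 115, 150, 250, 350, 500),
    "PM10" = c(0, 50, 150, 250, 350, 420, 500, 600))
  breakpoint_table(pollutant, conc, idx)
}

#' @rdname breakpoint_table
#' @param path JSON file with fields `pollutant`, `concentration`, `index`.
#' @export
read_breakpoints <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  breakpoint_table(doc$pollutant, doc$concentration, doc$index)
}

#' @rdname breakpoint_table
#' @param table A `breakpoint_table`.
#' @export
write_breakpoints <- function(table, path) {
  jsonlite::write_json(
    list(pollutant = attr(table, "pollutant"),
         concentration = table$concentration, index = table$index),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Individual air-quality index by breakpoint interpolation
#'
#' Locates the breakpoint segment containing each concentration and
#' interpolates linearly:
#' \deqn{IAQI = I_{lo} + (I_{hi} - I_{lo}) \frac{C - C_{lo}}{C_{hi} - C_{lo}}}
#' Concentrations above the last breakpoint return the table's cap index.
#' The result is real-valued by default; set `integer_ceiling = TRUE` for
#' the reporting convention of rounding up to the next integer.
#'
#' @param concentration Numeric vector of concentrations (ug/m3), >= 0.
#' @param table A [breakpoint_table()].
#' @param integer_ceiling Round up to integers? Default `FALSE`.
#' @return Numeric vector of index values.
#' @examples
#' iaqi(c(35, 55), default_breakpoints("PM2.5"))
#' @export
iaqi <- function(concentration, table, integer_ceiling = FALSE) {
  stopifnot(inherits(table, "breakpoint_table"))
  if (any(concentration < 0, na.rm = TRUE)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  conc <- table$concentration
  idx <- table$index
  seg <- findInterval(concentration, conc, rightmost.closed = FALSE)
  seg[seg >= length(conc)] <- length(conc) # above table: cap
  seg[seg < 1] <- 1
  lo <- conc[seg]; hi <- conc[pmin(seg + 1, length(conc))]
  ilo <- idx[seg]; ihi <- idx[pmin(seg + 1, length(conc))]
  out <- ifelse(concentration >= conc[length(conc)],
                attr(table, "cap_index"),
                ilo + (ihi - ilo) * (concentration - lo) / (hi - lo))
  out[is.na(concentration)] <- NA_real_
  if (integer_ceiling) out <- ceiling(out)
  out
}

#' @rdname iaqi
#' @param field A [grid_field()] of concentrations.
#' @return `iaqi_grid()` returns a [grid_field()] of index values.
#' @export
iaqi_grid <- function(field, table, integer_ceiling = FALSE) {
  stopifnot(inherits(field, "grid_field"))
  v <- field$values
  v[!field$mask] <- NA_real_
  out <- matrix(iaqi(as.vector(v), table, integer_ceiling),
                nrow(v), ncol(v))
  grid_field(out, mask = field$mask, transform = field$transform,
             crs = field$crs,
             variable = paste0("I", attr(table, "pollutant")), units = "")
}

#' Index-proportional raw weights of a composite particulate index
#'
#' Each pollutant's raw weight is its share of the summed individual
#' indexes, \eqn{Q_i = I_i / \sum_j I_j}, so \eqn{0 \le Q_i \le 1} and the
#' weights sum to 1.
#'
#' @param indexes Numeric vector of individual index values, >= 0 with at
#'   least one positive entry.
#' @return Numeric weight vector summing to 1 (names preserved).
#' @export
raw_weights <- function(indexes) {
  if (any(indexes < 0, na.rm = TRUE) || anyNA(indexes)) {
    stop("indexes must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(indexes)
  if (total <= 0) {
    stop("weighting undefined: all individual indexes are zero",
         call. = FALSE)
  }
  indexes / total
}

#' Extreme-value weight modification
#'
#' Counts the extreme raw weights — `s`, the number with
#' \eqn{0 \le Q_i < } `low_cut`, and `t`, the number with `high_cut`
#' \eqn{< Q_i \le 1}. When both kinds are present (an extreme-dominance
#' configuration such as a dust storm, where the coarse-particle index
#' dwarfs the fine one), the near-zero weights are truncated to 0 and the
#' remainder renormalised to sum 1, so the composite follows the dominant
#' pollutant instead of being diluted. Otherwise the weights pass through
#' unchanged. The operation is idempotent.
#'
#' @param Q Raw weight vector summing to 1 (see [raw_weights()]).
#' @param low_cut,high_cut Extreme-weight cutoffs; defaults 0.05 and 0.5.
#' @return List with `P` (modified weights, sum 1), `s` and `t`.
#' @export
modify_weights <- function(Q, low_cut = 0.05, high_cut = 0.5) {
  if (abs(sum(Q) - 1) > 1e-8) {
    stop("weights must sum to 1 (got ", format(sum(Q)), ")", call. = FALSE)
  }
  s <- sum(Q >= 0 & Q < low_cut)
  t <- sum(Q > high_cut & Q <= 1)
  P <- Q
  if (s >= 1 && t >= 1) {
    P[Q < low_cut] <- 0
    P <- P / sum(P)
  }
  list(P = P, s = as.integer(s), t = as.integer(t))
}

#' Composite particulate air-quality index (PAQI)
#'
#' Combines individual particulate indexes into one composite:
#' raw index-proportional weights ([raw_weights()]), extreme-value weight
#' modification ([modify_weights()]), then the weighted sum
#' \eqn{PAQI = \sum_i P_i I_i}. Accepts any number of pollutants >= 2
#' (the scheme extends to further particulate fractions).
#'
#' @param indexes Named or unnamed numeric vector of individual index
#'   values (length >= 2).
#' @param low_cut,high_cut Extreme-weight cutoffs, see [modify_weights()].
#' @return An `index_bundle`: list with `indexes`, `Q`, `s`, `t`, `P` and
#'   `paqi`. `tidy()` returns a per-pollutant tibble.
#' @examples
#' paqi(c(PM10 = 300, PM2.5 = 100))$paqi # 250
#' paqi(c(PM10 = 480, PM2.5 = 20))$paqi  # 480: dust-storm dominance
#' @export
paqi <- function(indexes, low_cut = 0.05, high_cut = 0.5) {
  if (length(indexes) < 2) {
    stop("need at least 2 individual indexes", call. = FALSE)
  }
  Q <- raw_weights(indexes)
  mod <- modify_weights(Q, low_cut = low_cut, high_cut = high_cut)
  structure(
    list(indexes = indexes, Q = Q, s = mod$s, t = mod$t, P = mod$P,
         paqi = sum(mod$P * indexes)),
    class = "index_bundle"
  )
}

#' @export
print.index_bundle <- function(x, ...) {
  cat(sprintf("<index_bundle> PAQI = %.4g (s = %d, t = %d)\n",
              x$paqi, x$s, x$t))
  invisible(x)
}

#' @rdname paqi
#' @param x An `index_bundle`.
#' @param ... Unused.
#' @export
tidy.index_bundle <- function(x, ...) {
  nm <- names(x$indexes)
  if (is.null(nm)) nm <- paste0("pollutant_", seq_along(x$indexes))
  tibble::tibble(pollutant = nm, index = unname(x$indexes),
                 Q = unname(x$Q), P = unname(x$P))
}

#' @rdname paqi
#' @export
glance.index_bundle <- function(x, ...) {
  tibble::tibble(paqi = x$paqi, s = x$s, t = x$t,
                 n_pollutants = length(x$indexes))
}

#' Composite index over gridded individual indexes
#'
#' Cell-wise [paqi()] over a stack of aligned individual-index fields;
#' cells masked in any input are masked in the output.
#'
#' @param index_fields Named list of at least 2 aligned [grid_field()]s of
#'   individual index values.
#' @inheritParams paqi
#' @return A [grid_field()] of composite index values.
#' @export
paqi_grid <- function(index_fields, low_cut = 0.05, high_cut = 0.5) {
  if (length(index_fields) < 2) {
    stop("need at least 2 individual-index fields", call. = FALSE)
  }
  align_check(index_fields)
  mask <- combined_mask(index_fields)
  d <- dim(mask)
  I <- do.call(cbind, lapply(index_fields, function(f) as.vector(f$values)))
  I[!as.vector(mask), ] <- NA_real_
  total <- rowSums(I)
  Q <- I / total
  s <- rowSums(Q >= 0 & Q < low_cut)
  t <- rowSums(Q > high_cut & Q <= 1)
  P <- Q
  trunc_rows <- which(s >= 1 & t >= 1)
  if (length(trunc_rows)) {
    Pt <- P[trunc_rows, , drop = FALSE]
    Pt[Q[trunc_rows, , drop = FALSE] < low_cut] <- 0
    P[trunc_rows, ] <- Pt / rowSums(Pt)
  }
  vals <- rowSums(P * I)
  vals[!is.finite(vals)] <- NA_real_ # all-zero index cells stay undefined
  grid_field(matrix(vals, d[1], d[2]), mask = mask & is.finite(vals),
             transform = index_fields[[1]]$transform,
             crs = index_fields[[1]]$crs, variable = "PAQI")
}

#' Air-quality category of an index value
#'
#' Assigns each index value to the half-open category interval containing
#' it: with the default scheme, `[0, 50)` excellent, `[50, 100)` good,
#' `[100, 150)` lightly polluted, `[150, 200)` moderately polluted,
#' `[200, 300)` heavily polluted and `[300, Inf)` severely polluted. A value
#' exactly on a bound belongs to the upper category. Bounds are
#' configurable.
#'
#' @param value Numeric vector of index values, >= 0.
#' @param scheme Named numeric vector of ascending category upper bounds;
#'   the last must be `Inf`.
#' @return Ordered factor of category labels (best to worst).
#' @examples
#' classify(c(0, 150, 199, 200))
#' @export
classify <- function(value, scheme = default_categories()) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("index values must be non-negative", call. = FALSE)
  }
  stopifnot(!is.null(names(scheme)), !is.unsorted(scheme),
            is.infinite(scheme[length(scheme)]))
  cut_points <- scheme[-length(scheme)]
  lev <- names(scheme)
  idx <- findInterval(value, cut_points, left.open = FALSE) + 1
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' @rdname classify
#' @export
default_categories <- function() {
  c("excellent" = 50, "good" = 100, "lightly polluted" = 150,
    "moderately polluted" = 200, "heavily polluted" = 300,
    "severely polluted" = Inf)
}
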