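#' Stepwise predictor screening by partial-F tests
#'
#' Screens candidate network inputs on an ordinary linear model of
#' `observed_pm`: forward selection with backward elimination, governed by
#' the partial-F p-value of each candidate (`alpha_enter` to come in,
#' `alpha_remove` to be dropped). The procedure is deterministic given the
#' table. Constant candidates are dropped with a warning; a candidate whose
#' entry would make the design singular is skipped.
#'
#' @param table A [as_station_table()] tibble (or any data frame with an
#'   `observed_pm` column and the candidate columns).
#' @param candidates Character vector of candidate predictor columns
#'   (at least 2).
#' @param alpha_enter Entry threshold on the partial-F p-value (default
#'   0.05).
#' @param alpha_remove Removal threshold (default 0.10); must be at least
#'   `alpha_enter`.
#' @return A `stepwise_report`: list with `selected` (in entry order),
#'   `candidates`, `steps` (tibble of actions with p-values and model R^2)
#'   and the thresholds. `tidy()` returns the step tibble.
#' @export
stepwise_select <- function(table, candidates = NULL,
                            alpha_enter = 0.05, alpha_remove = 0.10) {
  if (is.null(candidates)) candidates <- station_predictors(table)
  if (length(candidates) < 2) {
    stop("need at least 2 candidate predictors", call. = FALSE)
  }
  if (alpha_enter > alpha_remove) {
    stop("alpha_enter must not exceed alpha_remove", call. = FALSE)
  }
  stopifnot("observed_pm" %in% names(table),
            all(candidates %in% names(table)))
  df <- as.data.frame(table[c("observed_pm", candidates)])
  if (nrow(df) < 10 * length(candidates)) {
    warning("fewer than 10 rows per candidate predictor (n = ", nrow(df),
            "); selection may be unstable", call. = FALSE)
  }
  const <- candidates[vapply(df[candidates],
                             function(v) stats::sd(v) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant candidate(s): ",
            paste(const, collapse = ", "), call. = FALSE)
    candidates <- setdiff(candidates, const)
  }

  fit_of <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(vars, response = "observed_pm")
    } else observed_pm ~ 1
    stats::lm(fml, data = df)
  }
  partial_p <- function(base_vars, var) {
    big <- fit_of(c(base_vars, var))
    if (anyNA(stats::coef(big))) return(NA_real_) # singular design: skip
    small <- fit_of(base_vars)
    stats::anova(small, big)$`Pr(>F)`[2]
  }

  selected <- character(0)
  steps <- list()
  step_no <- 0L
  repeat {
    changed <- FALSE
    # forward: best entry candidate
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      p_in <- vapply(pool, function(v) partial_p(selected, v), numeric(1))
      p_in <- p_in[!is.na(p_in)]
      if (length(p_in) && min(p_in) < alpha_enter) {
        var <- names(p_in)[which.min(p_in)]
        selected <- c(selected, var)
        step_no <- step_no + 1L
        steps[[step_no]] <- tibble::tibble(
          step = step_no, action = "enter", predictor = var,
          p_value = min(p_in),
          r_squared = summary(fit_of(selected))$r.squared)
        changed <- TRUE
      }
    }
    # backward: worst retained candidate
    if (length(selected) > 1) {
      p_out <- vapply(selected, function(v) {
        partial_p(setdiff(selected, v), v)
      }, numeric(1))
      if (any(!is.na(p_out)) && max(p_out, na.rm = TRUE) > alpha_remove) {
        var <- names(p_out)[which.max(p_out)]
        selected <- setdiff(selected, var)
        step_no <- step_no + 1L
        steps[[step_no]] <- tibble::tibble(
          step = step_no, action = "remove", predictor = var,
          p_value = max(p_out, na.rm = TRUE),
          r_squared = summary(fit_of(selected))$r.squared)
        changed <- TRUE
      }
    }
    if (!changed || step_no > 4 * length(candidates)) break
  }
  structure(
    list(selected = selected, candidates = candidates,
         steps = if (length(steps)) dplyr::bind_rows(steps) else {
           tibble::tibble(step = integer(), action = character(),
                          predictor = character(), p_value = numeric(),
                          r_squared = numeric())
         },
         alpha_enter = alpha_enter, alpha_remove = alpha_remove),
    class = "stepwise_report"
  )
}

#' @export
print.stepwise_report <- function(x, ...) {
  cat(sprintf("<stepwise_report> selected %d of %d candidates: %s\n",
              length(x$selected), length(x$candidates),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @rdname stepwise_select
#' @param x A `stepwise_report`.
#' @param ... Unused.
#' @export
tidy.stepwise_report <- function(x, ...) x$steps

#' @rdname stepwise_select
#' @export
glance.stepwise_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = length(x$candidates),
    n_selected = length(x$selected),
    alpha_enter = x$alpha_enter, alpha_remove = x$alpha_remove,
    final_r_squared = if (nrow(x$steps)) {
      utils::tail(x$steps$r_squared, 1)
    } else NA_real_
  )
}
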