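#' Validation metrics: Pearson correlation and absolute percentage error
#'
#' Compares estimated against observed concentrations with the two summary
#' measures used to judge the retrieval: the Pearson correlation coefficient
#' `r`, and the mean absolute percentage error
#' \deqn{APE = \frac{100}{n}\sum_i |Y_{est,i} - Y_{obs,i}| / Y_{obs,i}}
#' (the mean of per-record absolute percentage errors, in percent).
#'
#' @param pred Numeric vector of estimated concentrations.
#' @param obs Numeric vector of observed concentrations, strictly positive
#'   (the percentage error is undefined at zero).
#' @return One-row tibble with columns `r`, `ape` (percent) and `n`.
#' @examples
#' validate(c(110, 220, 330), c(100, 200, 300)) # r = 1, ape = 10
#' @export
validate <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  if (length(obs) < 2) stop("need at least 2 records", call. = FALSE)
  if (anyNA(pred) || anyNA(obs)) {
    stop("pred and obs must not contain missing values", call. = FALSE)
  }
  bad <- which(obs <= 0)
  if (length(bad)) {
    stop("APE undefined: observed value is not strictly positive at record ",
         bad[1], call. = FALSE)
  }
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("correlation undefined: zero variance in pred or obs",
         call. = FALSE)
  }
  tibble::tibble(
    r = stats::cor(pred, obs),
    ape = mean(abs(pred - obs) / obs) * 100,
    n = length(obs)
  )
}
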