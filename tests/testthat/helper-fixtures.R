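# Shared fixture builders; everything is generated in code.

unit_transform <- function(rows) grid_transform(0, rows, 1)

make_field <- function(values, ...) {
  grid_field(values, transform = unit_transform(nrow(values)), ...)
}

# Small synthetic config for fast pipeline-level tests.
small_config <- function(seed = 7, ...) {
  sim_config(rows = 16, cols = 16, n_stations = 60, n_zones = 4,
             smoothness = 3, seed = seed, ...)
}

# Station table whose target is an exact (optionally noisy) linear function
# of a subset of candidate predictors.
linear_station_table <- function(n = 200, p = 4, active = c(1, 2),
                                 coefs = c(3, -2), intercept = 100,
                                 noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    y <- intercept + as.vector(X[, active, drop = FALSE] %*% coefs) +
      rnorm(n, sd = noise_sd)
    tab <- tibble::tibble(
      id = sprintf("s%03d", seq_len(n)), lat = runif(n, 20, 40),
      lon = runif(n, 100, 120), pollutant = "PM2.5",
      observed_pm = y - min(y) + 1 # keep strictly positive
    )
    as_station_table(dplyr::bind_cols(tab, tibble::as_tibble(X)),
                     predictors = colnames(X))
  })
}
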