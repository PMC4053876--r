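test_that("a linear network reproduces ordinary least squares", {
  tab <- linear_station_table(n = 150, p = 3, active = 1:3,
                              coefs = c(2, -1, 0.5), noise_sd = 2, seed = 4)
  X <- as.matrix(tab[paste0("x", 1:3)])
  y <- tab$observed_pm
  Xs <- scale(X); ys <- scale(y)
  fit <- lm_fit_network(Xs, drop(ys), layer_sizes = c(3, 1), max_iter = 200)
  ols <- stats::lm.fit(cbind(1, Xs), drop(ys))
  par <- fit$theta # row-major W (3 weights) then bias
  expect_equal(unname(par[1:3]), unname(ols$coefficients[2:4]),
               tolerance = 1e-6)
  expect_equal(unname(par[4]), unname(ols$coefficients[1]),
               tolerance = 1e-6)
})

test_that("accepted steps never increase the training SSE", {
  tab <- linear_station_table(n = 80, p = 2, active = 1:2, coefs = c(1, 2),
                              noise_sd = 3, seed = 8)
  Xs <- scale(as.matrix(tab[c("x1", "x2")]))
  ys <- drop(scale(tab$observed_pm))
  fit <- lm_fit_network(Xs, ys, layer_sizes = c(2, 4, 1), max_iter = 60)
  expect_true(all(diff(fit$sse_trajectory) <= 0))
})

test_that("the Levenberg-Marquardt path matches an independent optimiser", {
  skip_if_not_installed("minpack.lm")
  tab <- linear_station_table(n = 100, p = 2, active = 1:2,
                              coefs = c(3, -2), noise_sd = 1, seed = 12)
  Xs <- scale(as.matrix(tab[c("x1", "x2")]))
  ys <- drop(scale(tab$observed_pm))
  mine <- lm_fit_network(Xs, ys, layer_sizes = c(2, 1), max_iter = 100)
  ref <- minpack.lm::nls.lm(
    par = rep(0, 3),
    fn = function(p) drop(Xs %*% p[1:2]) + p[3] - ys)
  expect_equal(unname(mine$theta), unname(ref$par), tolerance = 1e-6)
})

test_that("training is deterministic and recovers a noiseless linear target", {
  tab <- linear_station_table(n = 200, p = 3, active = c(1, 3),
                              coefs = c(2, 4), noise_sd = 0, seed = 5)
  fit1 <- train_lm(tab, layer_sizes = c(3, 1, 1), n_runs = 3, seed = 42,
                   max_iter = 150)
  fit2 <- train_lm(tab, layer_sizes = c(3, 1, 1), n_runs = 3, seed = 42,
                   max_iter = 150)
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_identical(fit1$model$biases, fit2$model$biases)
  expect_gte(glance(fit1$report)$best_r, 0.999)
})

test_that("validation r rises towards 1 with the iteration budget", {
  cfg <- sim_config(rows = 20, cols = 20, n_stations = 150, seed = 31,
                    noise_sd = 0)
  sim <- simulate_all(cfg)
  rs <- vapply(c(1, 4, 40), function(mi) {
    glance(train_lm(sim$stations_pm25, n_runs = 2, seed = 2,
                    max_iter = mi)$report)$best_r
  }, numeric(1))
  expect_true(all(diff(rs) >= -1e-9))
  expect_gte(rs[3], 0.99)
})

test_that("standardisation round-trips within floating tolerance", {
  withr::with_seed(2, {
    M <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  })
  st <- paqr:::standardize_stats(M)
  Ms <- paqr:::apply_standardize(M, st)
  back <- sweep(sweep(Ms, 2, st$scale, "*"), 2, st$center, "+")
  expect_equal(back, M, tolerance = 1e-12)
})

test_that("grid prediction honours constant inputs and mask propagation", {
  cfg <- small_config(seed = 13)
  sim <- simulate_all(cfg)
  fit <- train_lm(sim$stations_pm25, n_runs = 3, seed = 1, max_iter = 50)
  # constant fields equal to one station's predictors -> constant raster
  st1 <- sim$stations_pm25[1, ]
  const_fields <- lapply(fit$model$predictor_names, function(nm) {
    grid_field(matrix(st1[[nm]], 4, 4), transform = unit_transform(4))
  })
  names(const_fields) <- fit$model$predictor_names
  pg <- predict_grid(fit$model, const_fields)
  fitted1 <- predict(fit$model, st1)
  expect_equal(as.vector(pg$values), rep(max(fitted1, 0), 16))
  # fully masked predictor -> fully masked output
  masked <- const_fields
  masked$AOT <- grid_field(matrix(0.5, 4, 4),
                           mask = matrix(FALSE, 4, 4),
                           transform = unit_transform(4))
  pg2 <- predict_grid(fit$model, masked)
  expect_true(all(!pg2$mask))
  expect_error(predict_grid(fit$model, const_fields[-1]),
               "missing predictor")
})

test_that("negative predictions are floored at zero with a count", {
  # a linear model extrapolated far below the training range goes negative
  tab <- linear_station_table(n = 100, p = 2, active = 1, coefs = 50,
                              noise_sd = 0.1, seed = 3)
  fit <- train_lm(tab, layer_sizes = c(2, 1), n_runs = 2, seed = 1)
  fields <- list(
    x1 = grid_field(matrix(-100, 2, 2), transform = unit_transform(2)),
    x2 = grid_field(matrix(0, 2, 2), transform = unit_transform(2)))
  pg <- predict_grid(fit$model, fields)
  expect_true(all(pg$values == 0))
  expect_equal(attr(pg, "n_floored"), 4)
})

test_that("models round-trip through JSON serialisation", {
  cfg <- small_config(seed = 17)
  sim <- simulate_all(cfg)
  fit <- train_lm(sim$stations_pm25, layer_sizes = c(8, 5, 1), n_runs = 2,
                  seed = 3, max_iter = 40)
  path <- withr::local_tempfile(fileext = ".json")
  write_ann(fit$model, path)
  back <- read_ann(path)
  expect_equal(back$weights, fit$model$weights)
  expect_equal(back$biases, fit$model$biases)
  newdata <- sim$stations_pm25[1:10, ]
  expect_equal(predict(back, newdata), predict(fit$model, newdata))
  expect_equal(tidy(back), tidy(fit$model))
})

test_that("tidy and glance expose network structure and run history", {
  tab <- linear_station_table(n = 60, p = 2, active = 1, coefs = 2,
                              noise_sd = 1, seed = 6)
  fit <- train_lm(tab, layer_sizes = c(2, 3, 1), n_runs = 4, seed = 1,
                  max_iter = 30)
  td <- tidy(fit$model)
  expect_equal(nrow(td), 2 * 3 + 3 + 3 + 1) # weights + biases per layer
  g <- glance(fit$model)
  expect_equal(g$n_hidden_nodes, 3)
  expect_equal(nrow(tidy(fit$report)), 4)
  expect_equal(glance(fit$report)$best_run, fit$report$best_run)
  expect_equal(glance(fit$report)$best_r, max(tidy(fit$report)$r))
})

test_that("validation metrics match hand arithmetic and guard their domain", {
  res <- validate(c(10, 20, 30), c(10, 20, 30))
  expect_equal(res$r, 1)
  expect_equal(res$ape, 0)
  res2 <- validate(c(110, 220, 330), c(100, 200, 300))
  expect_equal(res2$r, 1)
  expect_equal(res2$ape, 10)
  expect_equal(validate(-c(10, 20, 30), c(10, 20, 30))$r, -1)
  expect_error(validate(c(1, 2), c(0, 2)), "record 1")
  expect_error(validate(c(1, 1), c(2, 3)), "zero variance")
  expect_error(validate(1:3, 1:2), "equal length")
})
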