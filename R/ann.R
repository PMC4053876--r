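#' Feed-forward PM estimation network
#'
#' The concentration estimator is a fully connected feed-forward network with
#' tanh hidden units and a single linear output, trained by damped
#' Gauss-Newton (Levenberg-Marquardt) minimisation of the sum of squared
#' errors on standardised inputs and target. `ann_model` objects bundle the
#' weights with the standardisation statistics so prediction is
#' self-contained.
#'
#' @name ann_model
#' @keywords internal
NULL

new_ann_model <- function(layer_sizes, weights, biases, input_stats,
                          target_stats, predictor_names,
                          pollutant = "PM2.5", activation = "tanh") {
  stopifnot(length(weights) == length(layer_sizes) - 1,
            length(biases) == length(weights))
  layer_sizes <- as.integer(layer_sizes)
  for (l in seq_along(weights)) {
    stopifnot(all(dim(weights[[l]]) == c(layer_sizes[l + 1], layer_sizes[l])),
              length(biases[[l]]) == layer_sizes[l + 1])
  }
  stopifnot(all(predictor_names %in% input_stats$predictor),
            all(input_stats$scale != 0), target_stats$scale != 0)
  structure(
    list(layer_sizes = as.integer(layer_sizes), weights = weights,
         biases = biases, activation = activation,
         input_stats = input_stats, target_stats = target_stats,
         predictor_names = predictor_names, pollutant = pollutant),
    class = "ann_model"
  )
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model %s> layers %s, %d parameters, %s hidden units\n",
              x$pollutant, paste(x$layer_sizes, collapse = "-"),
              n_params(x$layer_sizes), x$activation))
  cat("  predictors:", paste(x$predictor_names, collapse = ", "), "\n")
  invisible(x)
}

n_params <- function(layer_sizes) {
  L <- length(layer_sizes)
  sum(layer_sizes[-1] * layer_sizes[-L]) + sum(layer_sizes[-1])
}

# --- parameter packing -----------------------------------------------------
# theta concatenates, layer by layer, the row-major entries of W_l then b_l.

pack_params <- function(weights, biases) {
  unlist(lapply(seq_along(weights), function(l) {
    c(as.vector(t(weights[[l]])), biases[[l]])
  }))
}

unpack_params <- function(theta, layer_sizes) {
  theta <- unname(theta)
  weights <- list(); biases <- list(); pos <- 0
  for (l in seq_len(length(layer_sizes) - 1)) {
    nw <- layer_sizes[l + 1] * layer_sizes[l]
    weights[[l]] <- matrix(theta[pos + seq_len(nw)],
                           nrow = layer_sizes[l + 1], byrow = TRUE)
    pos <- pos + nw
    biases[[l]] <- theta[pos + seq_len(layer_sizes[l + 1])]
    pos <- pos + layer_sizes[l + 1]
  }
  list(weights = weights, biases = biases)
}

# --- forward pass and Jacobian --------------------------------------------

# X: n x p matrix of (standardised) inputs. Returns activations per layer.
forward_pass <- function(X, weights, biases) {
  L <- length(weights)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% t(weights[[l]]) +
      matrix(biases[[l]], nrow(X), length(biases[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  acts
}

# Jacobian of the network output wrt theta (n x n_params), via backprop of
# dy/dz through the layers; columns follow the pack_params() ordering.
network_jacobian <- function(acts, weights) {
  L <- length(weights)
  n <- nrow(acts[[1]])
  # D[[l]] = dy/dZ_l, n x n_l
  D <- vector("list", L)
  D[[L]] <- matrix(1, n, 1)
  if (L > 1) {
    for (l in seq(L - 1, 1)) {
      D[[l]] <- (D[[l + 1]] %*% weights[[l + 1]]) * (1 - acts[[l + 1]]^2)
    }
  }
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    n_out <- ncol(D[[l]]); n_in <- ncol(acts[[l]])
    JW <- D[[l]][, rep(seq_len(n_out), each = n_in), drop = FALSE] *
      acts[[l]][, rep(seq_len(n_in), times = n_out), drop = FALSE]
    blocks[[l]] <- cbind(JW, D[[l]])
  }
  do.call(cbind, blocks)
}

#' Levenberg-Marquardt least-squares fit of a feed-forward network
#'
#' Core optimiser: minimises the training sum of squared errors with the
#' classical Marquardt damping schedule — damping `lambda` starts at
#' `lambda0`, is divided by 10 on every accepted step and multiplied by 10 on
#' every rejected one, aborting above `lambda_max`. Accepted steps never
#' increase the SSE; the full trajectory of accepted SSE values is returned.
#'
#' @param X Numeric matrix of standardised inputs (n x p).
#' @param y Numeric vector of standardised targets, length n.
#' @param layer_sizes Integer vector `(p, hidden..., 1)`; `c(p, 1)` fits a
#'   plain linear model.
#' @param theta0 Initial parameter vector; defaults to seeded small-uniform.
#' @param max_iter Maximum number of accepted iterations.
#' @param tol Convergence tolerance on the gradient max-norm and on the
#'   relative SSE decrease.
#' @param lambda0,lambda_max Initial and abort damping values.
#' @param init_seed Seed for the default initialisation.
#' @param X_val,y_val Optional held-out set enabling validation-based early
#'   stopping, the standard guard against noise interpolation in L-M
#'   back-propagation training: the returned `theta` is the iterate with the
#'   lowest validation SSE, and optimisation stops after `patience`
#'   consecutive accepted steps without a validation improvement.
#' @param patience Consecutive non-improving accepted steps tolerated before
#'   early stop (only with a validation set).
#' @return List with `theta`, `sse_trajectory` (accepted training SSE
#'   values, non-increasing), `iterations`, `converged`, `lambda` (last
#'   value) and `diverged`.
#' @export
lm_fit_network <- function(X, y, layer_sizes, theta0 = NULL,
                           max_iter = 100, tol = 1e-8,
                           lambda0 = 1e-3, lambda_max = 1e10,
                           init_seed = 1,
                           X_val = NULL, y_val = NULL, patience = 6) {
  stopifnot(is.matrix(X), ncol(X) == layer_sizes[1],
            layer_sizes[length(layer_sizes)] == 1, length(y) == nrow(X))
  m <- n_params(layer_sizes)
  if (is.null(theta0)) {
    theta0 <- withr::with_seed(init_seed, stats::runif(m, -0.5, 0.5))
  }
  stopifnot(length(theta0) == m)
  theta <- theta0
  par <- unpack_params(theta, layer_sizes)
  acts <- forward_pass(X, par$weights, par$biases)
  r <- drop(acts[[length(acts)]]) - y
  sse <- sum(r^2)
  if (!is.finite(sse)) {
    return(list(theta = theta, sse_trajectory = sse, iterations = 0L,
                converged = FALSE, lambda = lambda0, diverged = TRUE))
  }
  use_val <- !is.null(X_val) && !is.null(y_val)
  val_sse <- function(par) {
    out <- forward_pass(X_val, par$weights, par$biases)
    sum((drop(out[[length(out)]]) - y_val)^2)
  }
  best_val <- if (use_val) val_sse(par) else Inf
  best_theta <- theta
  n_worse <- 0L
  lambda <- lambda0
  traj <- sse
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    J <- network_jacobian(acts, par$weights)
    g <- drop(crossprod(J, r))
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (lambda <= lambda_max) {
      H <- JtJ + diag(lambda, m)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta - step
        par_new <- unpack_params(theta_new, layer_sizes)
        acts_new <- forward_pass(X, par_new$weights, par_new$biases)
        r_new <- drop(acts_new[[length(acts_new)]]) - y
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          rel_drop <- (sse - sse_new) / max(sse, .Machine$double.eps)
          theta <- theta_new; par <- par_new; acts <- acts_new
          r <- r_new; sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          traj <- c(traj, sse)
          accepted <- TRUE
          if (rel_drop < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) break # lambda overflow: no further descent possible
    iter <- iter + 1L
    if (use_val) {
      v <- val_sse(par)
      if (v < best_val) {
        best_val <- v
        best_theta <- theta
        n_worse <- 0L
      } else {
        n_worse <- n_worse + 1L
        if (n_worse >= patience) break
      }
    }
    if (converged) break
  }
  if (use_val) theta <- best_theta
  list(theta = theta, sse_trajectory = traj, iterations = iter,
       converged = converged, lambda = lambda,
       diverged = !is.finite(sse))
}

# --- standardisation -------------------------------------------------------

standardize_stats <- function(M) {
  center <- colMeans(M)
  scale <- apply(M, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardize <- function(M, stats) {
  sweep(sweep(M, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Train the PM estimation network with repeated random sampling
#'
#' Runs `n_runs` independent training repetitions. Each run draws a random
#' train/validation split at `split_fraction`, standardises inputs and target
#' by the training-split statistics, initialises weights from a seeded
#' small-uniform scheme and fits by [lm_fit_network()] with validation-based
#' early stopping on the run's held-out split (the standard guard against
#' noise interpolation in L-M back-propagation training). The returned model
#' is the run with the highest validation Pearson correlation; the report
#' records every run.
#'
#' @param table A [as_station_table()] tibble (at least 20 rows).
#' @param layer_sizes `(n_predictors, hidden..., 1)`; default one hidden
#'   layer of 16 tanh nodes. `c(p, 1)` trains a plain linear model.
#' @param n_runs Number of random-sampling repetitions (default 50).
#' @param split_fraction Training fraction per run (default 0.8).
#' @param seed Master seed; per-run seeds are derived from it.
#' @param max_iter,tol Passed to [lm_fit_network()].
#' @param predictors Predictor columns; defaults to the table's predictor
#'   attribute.
#' @return List with `model` (an `ann_model`) and `report` (a
#'   `train_report`).
#' @export
train_lm <- function(table, layer_sizes = NULL, n_runs = 50,
                     split_fraction = 0.8, seed = 1,
                     max_iter = 100, tol = 1e-8, predictors = NULL) {
  if (is.null(predictors)) predictors <- station_predictors(table)
  n <- nrow(table)
  if (n < 20) stop("need at least 20 station records, got ", n, call. = FALSE)
  p <- length(predictors)
  if (is.null(layer_sizes)) layer_sizes <- c(p, 16, 1)
  if (layer_sizes[1] != p) {
    stop("layer_sizes must start with the predictor count (", p, ")",
         call. = FALSE)
  }
  if (layer_sizes[length(layer_sizes)] != 1) {
    stop("layer_sizes must end with a single output node", call. = FALSE)
  }
  stopifnot(split_fraction > 0, split_fraction < 1, n_runs >= 1)
  X_all <- as.matrix(table[predictors])
  y_all <- table$observed_pm
  pollutant <- if ("pollutant" %in% names(table)) {
    as.character(table$pollutant[1])
  } else "PM2.5"

  runs <- vector("list", n_runs)
  best <- NULL; best_r <- -Inf; last_lambda <- NA_real_
  n_train <- max(2L, round(split_fraction * n))
  for (run in seq_len(n_runs)) {
    run_seed <- sub_seed(seed, 1000 + run)
    idx <- withr::with_seed(run_seed, sample.int(n, n_train))
    in_stats <- standardize_stats(X_all[idx, , drop = FALSE])
    t_stats <- list(center = mean(y_all[idx]),
                    scale = max(stats::sd(y_all[idx]), .Machine$double.eps))
    Xs <- apply_standardize(X_all[idx, , drop = FALSE], in_stats)
    ys <- (y_all[idx] - t_stats$center) / t_stats$scale
    val_idx <- setdiff(seq_len(n), idx)
    Xv <- apply_standardize(X_all[val_idx, , drop = FALSE], in_stats)
    yv <- (y_all[val_idx] - t_stats$center) / t_stats$scale
    fit <- lm_fit_network(Xs, ys, layer_sizes, max_iter = max_iter,
                          tol = tol, init_seed = sub_seed(run_seed, 1),
                          X_val = Xv, y_val = yv)
    last_lambda <- fit$lambda
    par <- unpack_params(fit$theta, layer_sizes)
    pred_v <- drop(forward_pass(Xv, par$weights, par$biases)[[
      length(layer_sizes)]]) * t_stats$scale + t_stats$center
    obs_v <- y_all[val_idx]
    r_v <- if (fit$diverged || stats::sd(pred_v) == 0 ||
               stats::sd(obs_v) == 0) {
      NA_real_
    } else stats::cor(pred_v, obs_v)
    ape_v <- if (fit$diverged || any(obs_v <= 0)) NA_real_ else {
      mean(abs(pred_v - obs_v) / obs_v) * 100
    }
    runs[[run]] <- tibble::tibble(
      run = run, r = r_v, ape = ape_v, iterations = fit$iterations,
      converged = fit$converged, final_sse = utils::tail(fit$sse_trajectory, 1)
    )
    if (!is.na(r_v) && r_v > best_r) {
      best_r <- r_v
      best <- list(fit = fit, in_stats = in_stats, t_stats = t_stats,
                   run = run)
    }
  }
  run_tbl <- dplyr::bind_rows(runs)
  if (is.null(best)) {
    stop("training diverged in every run (last damping lambda = ",
         format(last_lambda), ")", call. = FALSE)
  }
  par <- unpack_params(best$fit$theta, layer_sizes)
  model <- new_ann_model(
    layer_sizes, par$weights, par$biases,
    input_stats = tibble::tibble(predictor = predictors,
                                 center = unname(best$in_stats$center),
                                 scale = unname(best$in_stats$scale)),
    target_stats = list(center = best$t_stats$center,
                        scale = best$t_stats$scale),
    predictor_names = predictors, pollutant = pollutant
  )
  report <- structure(
    list(runs = run_tbl, best_run = best$run, n_runs = n_runs,
         split_fraction = split_fraction,
         loss_trajectory = best$fit$sse_trajectory),
    class = "train_report"
  )
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d runs (split %.2f); best run %d: r = %.4f\n",
              x$n_runs, x$split_fraction, x$best_run,
              x$runs$r[x$best_run]))
  invisible(x)
}

#' Predict PM at station records or arbitrary predictor tables
#'
#' @param object An `ann_model`.
#' @param newdata Data frame containing every predictor column.
#' @param ... Unused.
#' @return Numeric vector of concentrations (ug/m3), not floored.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  missing_p <- setdiff(object$predictor_names, names(newdata))
  if (length(missing_p)) {
    stop("newdata is missing predictor(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[object$predictor_names])
  stats_in <- list(center = stats::setNames(object$input_stats$center,
                                            object$input_stats$predictor),
                   scale = stats::setNames(object$input_stats$scale,
                                           object$input_stats$predictor))
  Xs <- apply_standardize(X, list(
    center = stats_in$center[object$predictor_names],
    scale = stats_in$scale[object$predictor_names]))
  out <- forward_pass(Xs, object$weights, object$biases)
  drop(out[[length(out)]]) * object$target_stats$scale +
    object$target_stats$center
}

#' Predict a concentration grid from predictor rasters
#'
#' Applies the network cell-wise to a stack of aligned predictor fields.
#' The output mask is the union of the input masks (a cell masked anywhere is
#' masked in the output); negative predictions are floored at zero and the
#' floored-cell count is attached as the `"n_floored"` attribute.
#'
#' @param model An `ann_model`.
#' @param fields Named list of [grid_field()]s covering every predictor.
#' @return A [grid_field()] of concentrations (ug/m3).
#' @export
predict_grid <- function(model, fields) {
  stopifnot(inherits(model, "ann_model"))
  missing_p <- setdiff(model$predictor_names, names(fields))
  if (length(missing_p)) {
    stop("missing predictor field(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  fields <- fields[model$predictor_names]
  align_check(fields)
  mask <- combined_mask(fields)
  d <- dim(mask)
  X <- do.call(cbind, lapply(fields, function(f) as.vector(f$values)))
  colnames(X) <- model$predictor_names
  pred <- rep(NA_real_, prod(d))
  valid <- as.vector(mask)
  if (any(valid)) {
    pred[valid] <- predict(model,
                           tibble::as_tibble(X[valid, , drop = FALSE]))
  }
  n_floored <- sum(pred < 0, na.rm = TRUE)
  pred[pred < 0] <- 0
  out <- grid_field(matrix(pred, d[1], d[2]), mask = mask,
                    transform = fields[[1]]$transform,
                    crs = fields[[1]]$crs,
                    variable = model$pollutant, units = "ug/m3")
  attr(out, "n_floored") <- n_floored
  out
}

# --- broom-style accessors -------------------------------------------------

#' Tidy the weights of a fitted network
#'
#' @param x An `ann_model`.
#' @param ... Unused.
#' @return Tibble with one row per weight/bias: `layer`, `from`, `to`,
#'   `term`, `estimate`.
#' @export
tidy.ann_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$weights), function(l) {
    W <- x$weights[[l]]; b <- x$biases[[l]]
    from_names <- if (l == 1) x$predictor_names else {
      paste0("h", l - 1, "_", seq_len(ncol(W)))
    }
    to_names <- if (l == length(x$weights)) "output" else {
      paste0("h", l, "_", seq_len(nrow(W)))
    }
    dplyr::bind_rows(
      tidyr::expand_grid(to = to_names, from = from_names) |>
        dplyr::mutate(layer = l, term = "weight",
                      estimate = as.vector(t(W))),
      tibble::tibble(layer = l, from = "(bias)", to = to_names,
                     term = "bias", estimate = b)
    )
  }) |>
    dplyr::select("layer", "from", "to", "term", "estimate")
}

#' @rdname tidy.ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(
    pollutant = x$pollutant,
    n_inputs = x$layer_sizes[1],
    n_hidden_layers = length(x$layer_sizes) - 2L,
    n_hidden_nodes = sum(x$layer_sizes[-c(1, length(x$layer_sizes))]),
    n_params = n_params(x$layer_sizes),
    activation = x$activation
  )
}

#' Tidy / summarise a training report
#'
#' @param x A `train_report` from [train_lm()].
#' @param ... Unused.
#' @return `tidy()`: the per-run tibble (run, validation `r`, `ape`,
#'   iterations, convergence, final SSE). `glance()`: one-row summary.
#' @export
tidy.train_report <- function(x, ...) x$runs

#' @rdname tidy.train_report
#' @export
glance.train_report <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs, split_fraction = x$split_fraction,
    best_run = x$best_run, best_r = x$runs$r[x$best_run],
    best_ape = x$runs$ape[x$best_run],
    mean_r = mean(x$runs$r, na.rm = TRUE),
    n_diverged = sum(is.na(x$runs$r))
  )
}

# --- serialization ---------------------------------------------------------

#' Save / load a fitted network as JSON
#'
#' The whole model (layer sizes, weights, biases, standardisation statistics,
#' predictor names, pollutant) round-trips through a single JSON document.
#'
#' @param model An `ann_model`.
#' @param path Output `.json` path.
#' @return `write_ann()` returns `path` invisibly; `read_ann()` the model.
#' @export
write_ann <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  doc <- list(
    format = "paqr-ann-1",
    layer_sizes = model$layer_sizes,
    activation = model$activation,
    pollutant = model$pollutant,
    predictor_names = model$predictor_names,
    weights = lapply(model$weights, function(W) apply(W, 1, identity,
                                                      simplify = FALSE)),
    biases = model$biases,
    input_stats = list(predictor = model$input_stats$predictor,
                       center = model$input_stats$center,
                       scale = model$input_stats$scale),
    target_stats = model$target_stats
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "paqr-ann-1") {
    stop("not a paqr ANN model file: ", path, call. = FALSE)
  }
  layer_sizes <- as.integer(doc$layer_sizes)
  weights <- lapply(seq_along(doc$weights), function(l) {
    W <- doc$weights[[l]]
    if (is.list(W)) W <- do.call(rbind, W)
    if (is.null(dim(W))) W <- matrix(W, nrow = 1)
    matrix(as.numeric(W), layer_sizes[l + 1], layer_sizes[l])
  })
  biases <- doc$biases
  if (!is.list(biases)) biases <- list(as.numeric(biases))
  biases <- lapply(biases, as.numeric)
  new_ann_model(
    layer_sizes, weights, biases,
    input_stats = tibble::as_tibble(doc$input_stats),
    target_stats = as.list(doc$target_stats),
    predictor_names = as.character(doc$predictor_names),
    pollutant = doc$pollutant, activation = doc$activation
  )
}
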