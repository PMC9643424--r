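# End-to-end QSPR regression pipeline: preprocessing (PCA + min-max/tanh),
# model fit/predict in property units, R^2 / Q^2, ten-fold cross-validation.

#' Fit the preprocessing transforms
#'
#' Fits, on training data only: (1) PCA on the descriptor matrix (centered,
#' covariance-based), retaining `n_components` components; (2) per-component
#' min-max scaling of the scores to \eqn{[-\pi, \pi]} (circuit rotation
#' angles); (3) target scaling, min-max to \eqn{[-1, 1]} followed by `tanh`,
#' so the training range maps to \eqn{[-\tanh 1, \tanh 1] \approx [-0.76,
#' 0.76]}. Squashing below the readout's \eqn{[-1, 1]} range leaves headroom
#' to predict new samples outside the training range of the property.
#' Constant (zero-variance) descriptor columns are dropped with a warning.
#'
#' @param dataset A [qspr_dataset()].
#' @param n_components Number of principal components to retain (default 4).
#' @return A `qcl_preprocessor`: rotation, centering vector, per-component
#'   score ranges, target range, kept column names, and the cumulative
#'   explained-variance ratio of the retained components
#'   (`$cumulative_evr`).
#' @export
fit_preprocessor <- function(dataset, n_components = 4L) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  X <- dataset$X
  n_components <- as.integer(n_components)
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(X)[v == 0], collapse = ", "), call. = FALSE)
    X <- X[, v > 0, drop = FALSE]
  }
  if (n_components > ncol(X)) {
    stop("`n_components` exceeds the number of usable descriptors",
         call. = FALSE)
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  x_min <- apply(scores, 2L, min)
  x_max <- apply(scores, 2L, max)
  if (any(x_max - x_min <= 0)) {
    stop("a retained principal component has zero score range", call. = FALSE)
  }
  if (stats::var(dataset$y) == 0) {
    stop("target has zero variance; scaling undefined", call. = FALSE)
  }
  structure(list(
    rotation = pca$rotation[, seq_len(n_components), drop = FALSE],
    center = pca$center,
    kept_columns = colnames(X),
    n_components = n_components,
    evr = evr,
    cumulative_evr = sum(evr[seq_len(n_components)]),
    x_min = x_min, x_max = x_max,
    y_min = min(dataset$y), y_max = max(dataset$y)
  ), class = "qcl_preprocessor")
}

#' @export
print.qcl_preprocessor <- function(x, ...) {
  cat(sprintf(
    "<qcl_preprocessor: %d PCs (cumulative explained variance %.4f)>\n",
    x$n_components, x$cumulative_evr))
  invisible(x)
}

#' Apply the fitted feature transform
#'
#' Projects descriptors onto the retained principal components and min-max
#' scales each to \eqn{[-\pi, \pi]} using the training ranges. New samples
#' falling outside a training range are clipped to the boundary angle.
#'
#' @param pre A [fit_preprocessor()] result.
#' @param X Descriptor matrix or data frame (same columns as training).
#' @return Matrix of scaled features, entries in \eqn{[-\pi, \pi]}.
#' @export
transform_x <- function(pre, X) {
  stopifnot(inherits(pre, "qcl_preprocessor"))
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && all(pre$kept_columns %in% colnames(X))) {
    X <- X[, pre$kept_columns, drop = FALSE]
  } else if (ncol(X) != length(pre$kept_columns)) {
    stop("descriptor columns do not match the fitted preprocessor",
         call. = FALSE)
  }
  scores <- sweep(X, 2L, pre$center) %*% pre$rotation
  out <- sweep(sweep(scores, 2L, pre$x_min), 2L, pre$x_max - pre$x_min, "/")
  out <- -pi + 2 * pi * out
  out[out > pi] <- pi
  out[out < -pi] <- -pi
  out
}

#' Target transform and its inverse
#'
#' `transform_y()` maps the property to the readout scale:
#' \eqn{y' = \tanh(m(y))} where \eqn{m} min-max scales the training range to
#' \eqn{[-1, 1]}. `inverse_transform_y()` maps predictions back to property
#' units via \eqn{m^{-1}(\mathrm{atanh}(\hat y))}; values with
#' \eqn{|\hat y| \ge 1} (possible with sampled readout) are clipped to
#' \eqn{\pm(1 - 10^{-9})} with a warning so the inverse stays finite.
#'
#' @param pre A [fit_preprocessor()] result.
#' @param y Property values (for `transform_y`).
#' @param y_scaled Model outputs in \eqn{(-1, 1)} (for
#'   `inverse_transform_y`).
#' @return Numeric vector.
#' @export
transform_y <- function(pre, y) {
  stopifnot(inherits(pre, "qcl_preprocessor"))
  tanh(-1 + 2 * (y - pre$y_min) / (pre$y_max - pre$y_min))
}

#' @rdname transform_y
#' @export
inverse_transform_y <- function(pre, y_scaled) {
  stopifnot(inherits(pre, "qcl_preprocessor"))
  lim <- 1 - 1e-9
  if (any(abs(y_scaled) >= 1)) {
    warning("prediction(s) at or beyond the tanh range; clipping before atanh",
            call. = FALSE)
    y_scaled <- pmin(lim, pmax(-lim, y_scaled))
  }
  u <- atanh(y_scaled)
  pre$y_min + (u + 1) / 2 * (pre$y_max - pre$y_min)
}

#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - \sum_i (y_i - y_{calc,i})^2 / \sum_i (y_i - \bar y)^2.}
#' Applied to in-sample calculated values this is the training \eqn{R^2};
#' applied to pooled out-of-fold predictions it is \eqn{Q^2}
#' (see [q_squared_cv()]). At most 1; unbounded below.
#'
#' @param y Observed values.
#' @param y_calc Calculated/predicted values, same length.
#' @return Numeric scalar.
#' @examples
#' r_squared(c(0, 1, 2), c(1, 1, 1))  # 0
#' @export
r_squared <- function(y, y_calc) {
  stopifnot(length(y) == length(y_calc))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: target has zero variance", call. = FALSE)
  }
  1 - sum((y - y_calc)^2) / ss_tot
}

#' Fit a quantum circuit learning regression model
#'
#' End-to-end fit: preprocess (PCA to `n_components`, min-max/tanh scaling),
#' then optimize the ansatz parameters against the scaled data with the
#' chosen optimizer, and package everything needed for prediction.
#'
#' @param dataset A [qspr_dataset()].
#' @param ansatz `"original"` (layered, [build_original_ansatz()]) or
#'   `"mera"` ([build_mera_ansatz()]; requires `n_components = 4`).
#' @param layers Number of layers `L` for the original ansatz (ignored for
#'   MERA).
#' @param optimizer `"sgd"` (single-sample Adam with parameter-shift
#'   gradients, [train_sgd()]) or `"nelder_mead"` (full batch,
#'   [train_nelder_mead()]).
#' @param shots `"exact"` or shots per expectation during training.
#' @param n_steps SGD steps / Nelder-Mead maximum objective evaluations.
#' @param seed Integer seed controlling initialization, sample selection and
#'   shot noise.
#' @param n_components Retained principal components (= qubits).
#' @param repetitions,entangler Encoder structure, see [encoding_spec()].
#' @param lr Adam learning rate (SGD only).
#' @param eval_every Learning-curve evaluation stride, see [train_sgd()].
#' @param theta0 Optional initial parameter vector.
#' @return A `qcl_model`: preprocessor, optimized `theta`, circuit and
#'   encoding specs, the full training trace, and configuration metadata.
#' @export
qcl_fit <- function(dataset, ansatz = c("original", "mera"), layers = 2L,
                    optimizer = c("sgd", "nelder_mead"), shots = "exact",
                    n_steps = 200L, seed = 1L, n_components = 4L,
                    repetitions = 2L, entangler = "linear", lr = 0.05,
                    eval_every = 10L, theta0 = NULL) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  ansatz <- match.arg(ansatz)
  optimizer <- match.arg(optimizer)
  pre <- fit_preprocessor(dataset, n_components)
  Xs <- transform_x(pre, dataset$X)
  ys <- transform_y(pre, dataset$y)
  circuit <- switch(ansatz,
    original = build_original_ansatz(n_components, layers,
                                     entangler = entangler),
    mera = {
      if (n_components != 4L) {
        stop("the MERA ansatz requires n_components = 4", call. = FALSE)
      }
      build_mera_ansatz(4L)
    })
  encoding <- encoding_spec(n_components, repetitions, entangler)
  training <- if (optimizer == "sgd") {
    train_sgd(Xs, ys, circuit, encoding, shots = shots, n_steps = n_steps,
              seed = seed, lr = lr, theta0 = theta0, eval_every = eval_every)
  } else {
    train_nelder_mead(Xs, ys, circuit, encoding, shots = shots,
                      max_iter = n_steps, seed = seed, theta0 = theta0,
                      eval_every = eval_every)
  }
  structure(list(
    ansatz_name = ansatz, layers = if (ansatz == "original") layers else NA,
    theta = training$theta, preprocessor = pre, circuit = circuit,
    encoding = encoding, training = training, optimizer = optimizer,
    shots = shots, seed = seed, n_components = n_components
  ), class = "qcl_model")
}

#' @export
print.qcl_model <- function(x, ...) {
  cat(sprintf(
    "<qcl_model: %s ansatz%s, %d parameters, optimizer = %s, shots = %s>\n",
    x$ansatz_name,
    if (!is.na(x$layers)) sprintf(" (L = %d)", x$layers) else "",
    n_trainable(x$circuit), x$optimizer,
    if (identical(x$shots, "exact")) "exact" else x$shots))
  invisible(x)
}

#' Predict properties with a fitted model
#'
#' Transforms descriptors with the stored preprocessor, evaluates the
#' circuit readout per sample, and maps the result back to property units.
#' Evaluation uses the exact statevector expectation by default (no
#' sampling noise in reported metrics); pass a shot count to emulate
#' measured predictions.
#'
#' @param object A `qcl_model` from [qcl_fit()].
#' @param newdata Descriptor matrix or data frame.
#' @param shots `"exact"` or a positive integer.
#' @param ... Unused.
#' @return Numeric vector of predicted property values.
#' @export
predict.qcl_model <- function(object, newdata, shots = "exact", ...) {
  Xs <- transform_x(object$preprocessor, newdata)
  preds <- vapply(seq_len(nrow(Xs)), function(i) {
    predict_one(Xs[i, ], object$theta, object$circuit, object$encoding, shots)
  }, numeric(1))
  inverse_transform_y(object$preprocessor, preds)
}

#' Cross-validated predictive performance (Q-squared)
#'
#' Ten-fold (by default) cross-validation: folds are assigned by a seeded
#' shuffle; within each fold the preprocessor is re-fitted on the training
#' rows only (no leakage; test-fold features outside the training angle
#' range are clipped to \eqn{[-\pi, \pi]}), the model is trained, and the
#' held-out rows are predicted. \eqn{Q^2} applies the [r_squared()] formula
#' to the pooled out-of-fold predictions.
#'
#' @param dataset A [qspr_dataset()].
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Seed for fold assignment and per-fold training.
#' @param predict_shots Readout mode for the held-out predictions
#'   (default exact).
#' @param ... Model configuration forwarded to [qcl_fit()] (`ansatz`,
#'   `layers`, `optimizer`, `shots`, `n_steps`, ...).
#' @return A `qcl_cv` object: `q2`, a `predictions` data frame
#'   (`row`, `fold`, `y`, `y_pred`), the fold assignment, and the per-fold
#'   fitted preprocessors.
#' @export
q_squared_cv <- function(dataset, k = 10L, seed = 1L,
                         predict_shots = "exact", ...) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  n <- nrow(dataset$X)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("`k` must be in 2..n", call. = FALSE)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  preds <- rep(NA_real_, n)
  fold_pre <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    sub <- qspr_dataset(dataset$X[train, , drop = FALSE], dataset$y[train],
                        meta = dataset$meta)
    model <- qcl_fit(sub, seed = seed * 1000L + f, ...)
    fold_pre[[f]] <- model$preprocessor
    preds[test] <- predict(model, dataset$X[test, , drop = FALSE],
                           shots = predict_shots)
  }
  structure(list(
    q2 = r_squared(dataset$y, preds),
    predictions = data.frame(row = seq_len(n), fold = folds,
                             y = dataset$y, y_pred = preds),
    folds = folds, fold_preprocessors = fold_pre, k = k, seed = seed
  ), class = "qcl_cv")
}

#' @export
print.qcl_cv <- function(x, ...) {
  cat(sprintf("<qcl_cv: %d-fold, Q2 = %.4f>\n", x$k, x$q2))
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' Persists everything needed to reproduce predictions: optimized
#' parameters, preprocessor (rotation, centering, ranges), circuit and
#' encoding configuration, and training metadata. The circuit is rebuilt
#' from its architecture name on load.
#'
#' @param model A `qcl_model`.
#' @param path JSON file path.
#' @return `model_to_json()` returns `path` invisibly; `model_from_json()` a
#'   `qcl_model` (without the training trace).
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "qcl_model"))
  pre <- model$preprocessor
  doc <- list(
    ansatz = model$ansatz_name,
    layers = if (is.na(model$layers)) NULL else model$layers,
    theta = model$theta,
    optimizer = model$optimizer,
    shots = model$shots,
    seed = model$seed,
    n_components = model$n_components,
    encoding = unclass(model$encoding),
    preprocessor = list(
      rotation = pre$rotation, center = pre$center,
      kept_columns = pre$kept_columns, n_components = pre$n_components,
      evr = pre$evr, cumulative_evr = pre$cumulative_evr,
      x_min = pre$x_min, x_max = pre$x_max,
      y_min = pre$y_min, y_max = pre$y_max
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  p <- doc$preprocessor
  rotation <- as.matrix(p$rotation)
  rownames(rotation) <- p$kept_columns
  pre <- structure(list(
    rotation = rotation, center = stats::setNames(p$center, p$kept_columns),
    kept_columns = p$kept_columns, n_components = p$n_components,
    evr = p$evr, cumulative_evr = p$cumulative_evr,
    x_min = p$x_min, x_max = p$x_max, y_min = p$y_min, y_max = p$y_max
  ), class = "qcl_preprocessor")
  circuit <- if (doc$ansatz == "mera") build_mera_ansatz(4L) else {
    build_original_ansatz(doc$n_components, doc$layers,
                          entangler = doc$encoding$entangler)
  }
  encoding <- encoding_spec(doc$encoding$n_qubits, doc$encoding$repetitions,
                            doc$encoding$entangler)
  structure(list(
    ansatz_name = doc$ansatz,
    layers = if (is.null(doc$layers)) NA else doc$layers,
    theta = doc$theta, preprocessor = pre, circuit = circuit,
    encoding = encoding, training = NULL, optimizer = doc$optimizer,
    shots = doc$shots, seed = doc$seed, n_components = doc$n_components
  ), class = "qcl_model")
}
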