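# Scripted experiment designs: layer sweep, shot sweep (learning curves per
# optimizer and shot count), and ansatz comparison at equal parameter count.
# Each driver returns plain data frames and can write CSV outputs plus a
# JSON manifest sufficient to reproduce the run.

.write_manifest <- function(out_dir, experiment, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    experiment = experiment,
    config = config,
    package = "qclr",
    package_version = as.character(utils::packageVersion("qclr")),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.write_csv_out <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  invisible(NULL)
}

#' Layer sweep: training accuracy versus circuit depth
#'
#' Trains the layered ansatz at each depth `L` (exact readout by default)
#' over several seeds and reports the in-sample training \eqn{R^2} in
#' property units. Mirrors the depth-sweep experiment: accuracy rises with
#' `L` as the variational family gains expressive power. Training failures
#' for individual (L, seed) cells are recorded and the sweep continues.
#'
#' @param dataset A [qspr_dataset()].
#' @param layers Integer vector of depths to sweep.
#' @param seeds Integer vector of training seeds (medians over seeds are the
#'   robust summary; single runs depend on the random initialization).
#' @param optimizer,shots,n_steps,lr Forwarded to [qcl_fit()].
#' @param out_dir Optional output directory (writes `layer_sweep.csv`,
#'   `layer_sweep_summary.csv`, `manifest.json`).
#' @return List with `results` (one row per L x seed: `L`, `seed`, `n_params`,
#'   `r2`, `error`) and `summary` (`L`, `median_r2`, `n_ok`).
#' @export
run_layer_sweep <- function(dataset, layers = c(1L, 2L, 4L, 8L),
                            seeds = 1:3, optimizer = "sgd", shots = "exact",
                            n_steps = 250L, lr = 0.05, out_dir = NULL) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  grid <- expand.grid(seed = seeds, L = layers)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    L <- grid$L[i]; seed <- grid$seed[i]
    out <- data.frame(L = L, seed = seed, n_params = NA_integer_,
                      r2 = NA_real_, error = NA_character_)
    tryCatch({
      model <- qcl_fit(dataset, ansatz = "original", layers = L,
                       optimizer = optimizer, shots = shots,
                       n_steps = n_steps, seed = seed, lr = lr,
                       eval_every = n_steps)
      out$n_params <- n_trainable(model$circuit)
      out$r2 <- r_squared(dataset$y, predict(model, dataset$X))
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  results <- do.call(rbind, rows)
  ok <- results[!is.na(results$r2), ]
  summary <- do.call(rbind, lapply(sort(unique(results$L)), function(L) {
    r <- ok$r2[ok$L == L]
    data.frame(L = L, median_r2 = if (length(r)) stats::median(r) else NA_real_,
               n_ok = length(r))
  }))
  .write_manifest(out_dir, "layer_sweep",
                  list(layers = layers, seeds = seeds, optimizer = optimizer,
                       shots = shots, n_steps = n_steps, lr = lr,
                       dataset_meta = dataset$meta))
  .write_csv_out(results, out_dir, "layer_sweep.csv")
  .write_csv_out(summary, out_dir, "layer_sweep_summary.csv")
  list(results = results, summary = summary)
}

#' Shot sweep: learning curves per optimizer and shot count
#'
#' For each optimizer and each shot count (plus an exact-readout baseline),
#' trains from the *same* random initialization and records the learning
#' curve. The per-step \eqn{R^2} is always evaluated with the exact
#' statevector at the current parameters, so the curves compare the
#' optimization trajectories themselves, free of sampling noise in the
#' metric. SGD steps cost `shots * (1 + 2 * n_params)` shots; Nelder-Mead
#' objective evaluations cost `shots * n_samples`.
#'
#' @param dataset A [qspr_dataset()].
#' @param shots_levels Shot counts to sweep (default 100, 1000, 10000).
#' @param optimizers Subset of `c("sgd", "nelder_mead")`.
#' @param include_exact Also run each optimizer with exact readout.
#' @param ansatz,layers Circuit choice, as in [qcl_fit()].
#' @param n_steps SGD steps and Nelder-Mead maximum objective evaluations.
#' @param seed Seed for the shared initialization and per-run noise.
#' @param lr,eval_every As in [train_sgd()].
#' @param out_dir Optional output directory (`shot_sweep.csv`,
#'   `manifest.json`).
#' @return Data frame with columns `optimizer`, `shots`, `step`, `loss`,
#'   `r2`, `cum_shots`, `shots_per_step`.
#' @export
run_shot_sweep <- function(dataset, shots_levels = c(100L, 1000L, 10000L),
                           optimizers = c("sgd", "nelder_mead"),
                           include_exact = TRUE, ansatz = "mera",
                           layers = 2L, n_steps = 200L, seed = 1L, lr = 0.05,
                           eval_every = 5L, out_dir = NULL) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  optimizers <- match.arg(optimizers, several.ok = TRUE)
  pre <- fit_preprocessor(dataset, 4L)
  Xs <- transform_x(pre, dataset$X)
  ys <- transform_y(pre, dataset$y)
  circuit <- if (ansatz == "mera") build_mera_ansatz(4L) else {
    build_original_ansatz(4L, layers)
  }
  encoding <- encoding_spec(4L, 2L)
  theta0 <- random_parameters(circuit, seed = seed)
  levels <- c(if (include_exact) list("exact"), as.list(shots_levels))
  rows <- list()
  for (opt in optimizers) {
    for (sh in levels) {
      res <- if (opt == "sgd") {
        train_sgd(Xs, ys, circuit, encoding, shots = sh, n_steps = n_steps,
                  seed = seed, lr = lr, theta0 = theta0,
                  eval_every = eval_every)
      } else {
        train_nelder_mead(Xs, ys, circuit, encoding, shots = sh,
                          max_iter = n_steps, seed = seed, theta0 = theta0,
                          eval_every = eval_every)
      }
      tr <- res$trace
      per_step <- if (identical(sh, "exact")) NA_integer_ else {
        if (opt == "sgd") {
          shots_per_step(sh, "sgd_param_shift",
                         n_trainable = n_trainable(circuit))
        } else {
          shots_per_step(sh, "nelder_mead", n_samples = nrow(Xs))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        optimizer = opt,
        shots = if (identical(sh, "exact")) "exact" else as.character(sh),
        step = tr$step, loss = tr$loss, r2 = tr$r2,
        cum_shots = tr$cum_shots, shots_per_step = per_step)
    }
  }
  curves <- do.call(rbind, rows)
  .write_manifest(out_dir, "shot_sweep",
                  list(shots_levels = shots_levels, optimizers = optimizers,
                       include_exact = include_exact, ansatz = ansatz,
                       layers = layers, n_steps = n_steps, seed = seed,
                       lr = lr, eval_every = eval_every,
                       dataset_meta = dataset$meta))
  .write_csv_out(curves, out_dir, "shot_sweep.csv")
  curves
}

#' Ansatz comparison at equal parameter count
#'
#' Compares the layered ansatz at `L = 2` against the four-qubit MERA — both
#' carrying 24 trainable parameters — on training \eqn{R^2} and
#' cross-validated \eqn{Q^2}, with seeds shared between the arms so the
#' comparison is paired.
#'
#' @param dataset A [qspr_dataset()].
#' @param seeds Integer vector of shared seeds.
#' @param optimizer,shots,n_steps,lr Forwarded to [qcl_fit()].
#' @param cv Also run k-fold cross-validation per arm (slower).
#' @param k Number of CV folds.
#' @param out_dir Optional output directory (`ansatz_compare_metrics.csv`,
#'   `ansatz_compare_predictions.csv`, `manifest.json`).
#' @return List with `metrics` (`arm`, `seed`, `n_params`, `r2`, `q2`) and
#'   `predictions` (per-sample `y`, `y_pred` for `set = "train"` and, when
#'   `cv = TRUE`, `set = "cv"`).
#' @export
run_ansatz_compare <- function(dataset, seeds = 1:3, optimizer = "sgd",
                               shots = "exact", n_steps = 250L, lr = 0.05,
                               cv = TRUE, k = 10L, out_dir = NULL) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  arms <- list(original_L2 = list(ansatz = "original", layers = 2L),
               mera = list(ansatz = "mera", layers = 2L))
  metrics <- list(); preds <- list()
  for (arm in names(arms)) {
    a <- arms[[arm]]
    for (seed in seeds) {
      model <- qcl_fit(dataset, ansatz = a$ansatz, layers = a$layers,
                       optimizer = optimizer, shots = shots,
                       n_steps = n_steps, seed = seed, lr = lr,
                       eval_every = n_steps)
      y_hat <- predict(model, dataset$X)
      q2 <- NA_real_
      if (cv) {
        cv_res <- q_squared_cv(dataset, k = k, seed = seed,
                               ansatz = a$ansatz, layers = a$layers,
                               optimizer = optimizer, shots = shots,
                               n_steps = n_steps, lr = lr,
                               eval_every = n_steps)
        q2 <- cv_res$q2
        preds[[length(preds) + 1L]] <- data.frame(
          arm = arm, seed = seed, set = "cv",
          row = cv_res$predictions$row, y = cv_res$predictions$y,
          y_pred = cv_res$predictions$y_pred)
      }
      metrics[[length(metrics) + 1L]] <- data.frame(
        arm = arm, seed = seed, n_params = n_trainable(model$circuit),
        r2 = r_squared(dataset$y, y_hat), q2 = q2)
      preds[[length(preds) + 1L]] <- data.frame(
        arm = arm, seed = seed, set = "train",
        row = seq_along(dataset$y), y = dataset$y, y_pred = y_hat)
    }
  }
  metrics <- do.call(rbind, metrics)
  predictions <- do.call(rbind, preds)
  .write_manifest(out_dir, "ansatz_compare",
                  list(seeds = seeds, optimizer = optimizer, shots = shots,
                       n_steps = n_steps, lr = lr, cv = cv, k = k,
                       dataset_meta = dataset$meta))
  .write_csv_out(metrics, out_dir, "ansatz_compare_metrics.csv")
  .write_csv_out(predictions, out_dir, "ansatz_compare_predictions.csv")
  list(metrics = metrics, predictions = predictions)
}

#' Plot a learning curve
#'
#' Base-graphics plot of the exact training \eqn{R^2} (or loss) against the
#' optimization step for a `qcl_training` trace.
#'
#' @param x A `qcl_training` object.
#' @param what `"r2"` or `"loss"`.
#' @param ... Passed to [plot()].
#' @export
plot.qcl_training <- function(x, what = c("r2", "loss"), ...) {
  what <- match.arg(what)
  tr <- x$trace[!is.na(x$trace[[what]]), ]
  plot(tr$step, tr[[what]], type = "l", xlab = "optimization step",
       ylab = if (what == "r2") expression(R^2) else "MSE loss", ...)
  invisible(x)
}
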