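# Loss evaluation, gradients (parameter-shift and finite-difference),
# Adam-SGD and Nelder-Mead optimizers, and shot-budget accounting.
#
# All functions here work in the *scaled* spaces produced by the
# preprocessor: x in [-pi, pi]^n, y in [-0.76, 0.76] (see qcl_preprocessor).

.check_shots_arg <- function(shots) {
  if (identical(shots, "exact")) return("exact")
  if (is.numeric(shots) && length(shots) == 1L && is.finite(shots) &&
      shots >= 1) {
    return(as.integer(shots))
  }
  stop('`shots` must be "exact" or a positive integer', call. = FALSE)
}

# expectation of Z on the readout qubit after encoder(x) + ansatz(theta),
# starting from |0...0>; hot path shared by all training code
.forward_value <- function(enc_gates, ansatz, theta, shots = "exact") {
  n_qubits <- ansatz$n_qubits
  slots <- ansatz$trainable_slots
  gates <- ansatz$gates
  for (k in seq_along(theta)) {
    gates[[slots$gate[k]]]$angles[slots$angle[k]] <- theta[k]
  }
  amp <- complex(2L^n_qubits)
  amp[1L] <- 1 + 0i
  for (g in enc_gates) amp <- .apply_gate_raw(amp, n_qubits, g)
  for (g in gates) amp <- .apply_gate_raw(amp, n_qubits, g)
  if (identical(shots, "exact")) {
    .z_exact_raw(amp, n_qubits, ansatz$readout_qubit)
  } else {
    .z_sampled_raw(amp, n_qubits, ansatz$readout_qubit, shots)
  }
}

# pre-build the encoder gate lists for every row of a scaled feature matrix
.encoder_cache <- function(X_scaled, encoding) {
  lapply(seq_len(nrow(X_scaled)), function(i) {
    build_encoder(X_scaled[i, ], encoding)$gates
  })
}

#' Predict the scaled target for one sample
#'
#' Runs the encoder for `x_scaled` followed by the ansatz bound at `theta`
#' on \eqn{|0\dots0\rangle} and returns the Pauli-Z expectation of the
#' ansatz's readout qubit — the model output in the scaled target space
#' \eqn{[-1, 1]}.
#'
#' @param x_scaled Scaled feature vector, entries in \eqn{[-\pi, \pi]}.
#' @param theta Trainable parameter vector for the ansatz.
#' @param ansatz A variational [qcl_circuit()] with a readout qubit.
#' @param encoding An [encoding_spec()] matching the ansatz width.
#' @param shots `"exact"` for a statevector expectation, or a positive
#'   integer shot count for a sampled estimate (uses R's RNG).
#' @return A single numeric value in \eqn{[-1, 1]}.
#' @export
predict_one <- function(x_scaled, theta, ansatz,
                        encoding = encoding_spec(ansatz$n_qubits),
                        shots = "exact") {
  stopifnot(inherits(ansatz, "qcl_circuit"))
  if (is.na(ansatz$readout_qubit)) {
    stop("ansatz has no readout qubit", call. = FALSE)
  }
  if (length(theta) != n_trainable(ansatz)) {
    stop(sprintf("`theta` must have length %d", n_trainable(ansatz)),
         call. = FALSE)
  }
  shots <- .check_shots_arg(shots)
  enc <- build_encoder(x_scaled, encoding)
  .forward_value(enc$gates, ansatz, theta, shots)
}

#' Mean-squared-error loss of the circuit model
#'
#' \eqn{L(\theta) = \mathrm{mean}_i (y_i - B(x_i; \theta))^2} over the batch,
#' where \eqn{B} is the readout expectation. `batch = NULL` uses every sample
#' (full batch); an index vector restricts to those rows (single-sample SGD
#' passes one index).
#'
#' @param theta Parameter vector.
#' @param X_scaled Matrix of scaled features (rows = samples).
#' @param y_scaled Scaled target vector in \eqn{[-0.76, 0.76]}.
#' @param ansatz,encoding,shots As in [predict_one()].
#' @param batch Optional integer vector of row indices.
#' @return Non-negative numeric loss.
#' @export
mse_loss <- function(theta, X_scaled, y_scaled, ansatz,
                     encoding = encoding_spec(ansatz$n_qubits),
                     shots = "exact", batch = NULL) {
  X_scaled <- as.matrix(X_scaled)
  if (nrow(X_scaled) == 0L) stop("empty batch", call. = FALSE)
  stopifnot(length(y_scaled) == nrow(X_scaled))
  shots <- .check_shots_arg(shots)
  idx <- if (is.null(batch)) seq_len(nrow(X_scaled)) else as.integer(batch)
  if (length(idx) == 0L) stop("empty batch", call. = FALSE)
  preds <- vapply(idx, function(i) {
    predict_one(X_scaled[i, ], theta, ansatz, encoding, shots)
  }, numeric(1))
  mean((y_scaled[idx] - preds)^2)
}

#' Parameter-shift gradient of the readout expectation
#'
#' Exact gradient of \eqn{B(\theta)} for circuits whose trainable slots are
#' Pauli-rotation angles (every RY/RZ angle directly, and each of the three
#' \eqn{U_3} angles through its \eqn{R_Z R_Y R_Z} decomposition):
#' \deqn{dB/d\theta_k = \tfrac12\,[B(\theta_k + \pi/2) - B(\theta_k - \pi/2)].}
#' With `shots = "exact"` this equals the analytic derivative; with finite
#' shots each shifted evaluation is sampled independently.
#'
#' @inheritParams predict_one
#' @return Numeric gradient vector, one entry per trainable slot.
#' @export
parameter_shift_gradient <- function(theta, x_scaled, ansatz,
                                     encoding = encoding_spec(ansatz$n_qubits),
                                     shots = "exact") {
  shots <- .check_shots_arg(shots)
  enc_gates <- build_encoder(x_scaled, encoding)$gates
  .ps_gradient(enc_gates, ansatz, theta, shots)
}

.ps_gradient <- function(enc_gates, ansatz, theta, shots) {
  vapply(seq_along(theta), function(k) {
    up <- theta; up[k] <- up[k] + pi / 2
    dn <- theta; dn[k] <- dn[k] - pi / 2
    (.forward_value(enc_gates, ansatz, up, shots) -
       .forward_value(enc_gates, ansatz, dn, shots)) / 2
  }, numeric(1))
}

#' Central finite-difference gradient of the readout expectation
#'
#' Numerical oracle \eqn{[B(\theta_k + h) - B(\theta_k - h)] / 2h} per slot,
#' with exact readout. Used to cross-check the parameter-shift rule; not a
#' training gradient.
#'
#' @inheritParams predict_one
#' @param h Step size (> 0).
#' @return Numeric gradient vector.
#' @export
finite_difference_gradient <- function(theta, x_scaled, ansatz,
                                       encoding = encoding_spec(ansatz$n_qubits),
                                       h = 1e-6) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a positive number", call. = FALSE)
  }
  enc_gates <- build_encoder(x_scaled, encoding)$gates
  vapply(seq_along(theta), function(k) {
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    (.forward_value(enc_gates, ansatz, up, "exact") -
       .forward_value(enc_gates, ansatz, dn, "exact")) / (2 * h)
  }, numeric(1))
}

#' One Adam update
#'
#' Standard bias-corrected first/second-moment update. Pass `state = NULL`
#' on the first step; feed the returned `state` back on subsequent steps.
#'
#' @param theta Current parameter vector.
#' @param grad Gradient of the loss at `theta` (must be finite).
#' @param state Optimizer state (`NULL`, or the `state` from the previous
#'   step: list with `m`, `v`, `t`).
#' @param lr Learning rate \eqn{\alpha} (default 0.05, suited to noisy
#'   few-parameter objectives).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return List with updated `theta` and `state`.
#' @export
adam_step <- function(theta, grad, state = NULL, lr = 0.05,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (length(grad) != length(theta)) stop("shape mismatch", call. = FALSE)
  if (any(!is.finite(grad))) {
    stop("non-finite gradient in Adam update", call. = FALSE)
  }
  if (is.null(state)) {
    state <- list(m = numeric(length(theta)), v = numeric(length(theta)),
                  t = 0L)
  }
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  m_hat <- state$m / (1 - beta1^state$t)
  v_hat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * m_hat / (sqrt(v_hat) + eps), state = state)
}

#' Shots consumed per optimization step
#'
#' Full-batch Nelder-Mead evaluates the readout expectation for every sample
#' once per objective evaluation: `shots * n_samples`. Single-sample SGD
#' with the parameter-shift rule needs one forward evaluation plus two
#' shifted evaluations per trainable parameter: `shots + 2 * shots *
#' n_trainable` (4,900 at 100 shots and 24 parameters).
#'
#' @param shots Shots per expectation estimate.
#' @param method `"nelder_mead"` or `"sgd_param_shift"`.
#' @param n_samples Number of training samples (Nelder-Mead).
#' @param n_trainable Number of trainable parameters (SGD).
#' @return Integer shot count for one step.
#' @examples
#' shots_per_step(10000, "nelder_mead", n_samples = 86)      # 860000
#' shots_per_step(100, "sgd_param_shift", n_trainable = 24)  # 4900
#' @export
shots_per_step <- function(shots, method = c("nelder_mead", "sgd_param_shift"),
                           n_samples = NULL, n_trainable = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(shots), shots >= 1)
  if (method == "nelder_mead") {
    stopifnot(!is.null(n_samples), n_samples >= 1)
    as.integer(shots * n_samples)
  } else {
    stopifnot(!is.null(n_trainable), n_trainable >= 1)
    as.integer(shots + 2 * shots * n_trainable)
  }
}

# exact full-training-set R^2 in the scaled target space, for learning curves
.training_r2_scaled <- function(enc_list, ansatz, theta, y_scaled) {
  preds <- vapply(enc_list, function(eg) {
    .forward_value(eg, ansatz, theta, "exact")
  }, numeric(1))
  1 - sum((y_scaled - preds)^2) / sum((y_scaled - mean(y_scaled))^2)
}

.new_training_result <- function(theta, trace, theta_path, optimizer, shots,
                                 seed, extra = list()) {
  structure(c(list(theta = theta, trace = trace, theta_path = theta_path,
                   optimizer = optimizer, shots = shots, seed = seed),
              extra),
            class = "qcl_training")
}

#' @export
print.qcl_training <- function(x, ...) {
  final_r2 <- rev(x$trace$r2[!is.na(x$trace$r2)])[1]
  cat(sprintf(
    "<qcl_training: %s, %d step(s), shots = %s, final training R2 = %s>\n",
    x$optimizer, nrow(x$trace),
    if (identical(x$shots, "exact")) "exact" else x$shots,
    if (length(final_r2)) sprintf("%.4f", final_r2) else "NA"))
  invisible(x)
}

#' Train by single-sample SGD with parameter-shift gradients
#'
#' Runs `n_steps` Adam updates. Each step draws one training sample
#' uniformly at random, estimates its readout expectation \eqn{B} (one
#' evaluation at `shots`), estimates \eqn{dB/d\theta} by the parameter-shift
#' rule (two evaluations per parameter), and applies the chain rule for the
#' squared error, \eqn{dL/d\theta = -2 (y - B)\, dB/d\theta}, through one
#' Adam update. This keeps the per-step shot cost at
#' `shots * (1 + 2 * n_trainable)` independent of the dataset size, which is
#' what makes the method practical on hardware.
#'
#' The learning curve records the exact (statevector) training
#' \eqn{R^2} in the scaled target space every `eval_every` steps, so the
#' curve itself carries no sampling noise.
#'
#' @param X_scaled,y_scaled Preprocessed training data.
#' @param ansatz,encoding,shots As in [predict_one()].
#' @param n_steps Number of SGD steps (\eqn{\ge 1}).
#' @param seed Optional integer seed; applied locally to sample selection,
#'   initialization and shot noise, and recorded in the result.
#' @param lr Adam learning rate.
#' @param theta0 Optional initial parameters (default: uniform on
#'   \eqn{[0, 2\pi)}).
#' @param eval_every Evaluate the exact training \eqn{R^2} every this many
#'   steps (other rows hold `NA`); the final step is always evaluated.
#' @return A `qcl_training` object: final `theta`; `trace` data frame with
#'   columns `step`, `sample`, `loss`, `r2`, `cum_shots`; `theta_path`
#'   (steps x parameters matrix); optimizer metadata.
#' @export
train_sgd <- function(X_scaled, y_scaled, ansatz,
                      encoding = encoding_spec(ansatz$n_qubits),
                      shots = 100, n_steps = 200, seed = NULL, lr = 0.05,
                      theta0 = NULL, eval_every = 1L) {
  if (!is.numeric(n_steps) || n_steps < 1) {
    stop("`n_steps` must be >= 1", call. = FALSE)
  }
  run <- function() {
    .train_sgd_impl(as.matrix(X_scaled), y_scaled, ansatz, encoding,
                    .check_shots_arg(shots), as.integer(n_steps), lr, theta0,
                    as.integer(eval_every), seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.train_sgd_impl <- function(X, y, ansatz, encoding, shots, n_steps, lr,
                            theta0, eval_every, seed) {
  n <- nrow(X)
  stopifnot(n >= 1L, length(y) == n)
  enc_list <- .encoder_cache(X, encoding)
  p <- n_trainable(ansatz)
  theta <- if (is.null(theta0)) stats::runif(p, 0, 2 * pi) else {
    stopifnot(length(theta0) == p); as.numeric(theta0)
  }
  per_step <- if (identical(shots, "exact")) NA_integer_ else {
    shots_per_step(shots, "sgd_param_shift", n_trainable = p)
  }
  state <- NULL
  trace <- data.frame(step = seq_len(n_steps), sample = NA_integer_,
                      loss = NA_real_, r2 = NA_real_, cum_shots = NA_real_)
  theta_path <- matrix(NA_real_, n_steps, p)
  for (s in seq_len(n_steps)) {
    i <- sample.int(n, 1L)
    b <- .forward_value(enc_list[[i]], ansatz, theta, shots)
    grad_b <- .ps_gradient(enc_list[[i]], ansatz, theta, shots)
    grad <- -2 * (y[i] - b) * grad_b
    loss <- (y[i] - b)^2
    if (!is.finite(loss)) {
      stop("non-finite loss at step ", s, "; trace preserved up to previous step",
           call. = FALSE)
    }
    upd <- adam_step(theta, grad, state, lr = lr)
    theta <- upd$theta; state <- upd$state
    trace$sample[s] <- i
    trace$loss[s] <- loss
    trace$cum_shots[s] <- if (is.na(per_step)) NA_real_ else per_step * s
    theta_path[s, ] <- theta
    if (s %% eval_every == 0L || s == n_steps) {
      trace$r2[s] <- .training_r2_scaled(enc_list, ansatz, theta, y)
    }
  }
  .new_training_result(theta, trace, theta_path, "sgd_param_shift", shots,
                       seed, list(lr = lr, encoding = encoding))
}

#' Train by full-batch Nelder-Mead
#'
#' Derivative-free simplex optimization (via [stats::optim()]) of the
#' full-batch MSE: every objective evaluation estimates the readout
#' expectation once per training sample, consuming `shots * n_samples` shots
#' per step. This is the conventional baseline; with finite shots the
#' objective is stochastic, which degrades the simplex updates — the effect
#' the parameter-shift SGD is designed to avoid.
#'
#' @inheritParams train_sgd
#' @param max_iter Maximum number of objective evaluations
#'   (passed to `optim(control = list(maxit = ))`).
#' @param reltol Relative convergence tolerance on the simplex function
#'   values.
#' @return A `qcl_training` object; one trace row per objective evaluation
#'   (`sample` is `NA`: full batch).
#' @export
train_nelder_mead <- function(X_scaled, y_scaled, ansatz,
                              encoding = encoding_spec(ansatz$n_qubits),
                              shots = "exact", max_iter = 500, seed = NULL,
                              theta0 = NULL, reltol = 1e-4, eval_every = 1L) {
  if (!is.numeric(max_iter) || max_iter < 1) {
    stop("`max_iter` must be >= 1", call. = FALSE)
  }
  run <- function() {
    .train_nm_impl(as.matrix(X_scaled), y_scaled, ansatz, encoding,
                   .check_shots_arg(shots), as.integer(max_iter), reltol,
                   theta0, as.integer(eval_every), seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.train_nm_impl <- function(X, y, ansatz, encoding, shots, max_iter, reltol,
                           theta0, eval_every, seed) {
  n <- nrow(X)
  stopifnot(n >= 1L, length(y) == n)
  enc_list <- .encoder_cache(X, encoding)
  p <- n_trainable(ansatz)
  theta <- if (is.null(theta0)) stats::runif(p, 0, 2 * pi) else {
    stopifnot(length(theta0) == p); as.numeric(theta0)
  }
  per_step <- if (identical(shots, "exact")) NA_integer_ else {
    shots_per_step(shots, "nelder_mead", n_samples = n)
  }
  rec <- new.env(parent = emptyenv())
  rec$loss <- numeric(); rec$theta <- list(); rec$r2 <- numeric()
  budget_exhausted <- structure(
    class = c("qclr_budget_exhausted", "condition"),
    list(message = "objective evaluation budget exhausted", call = NULL))
  objective <- function(th) {
    if (length(rec$loss) >= max_iter) stop(budget_exhausted)
    preds <- vapply(enc_list, function(eg) {
      .forward_value(eg, ansatz, th, shots)
    }, numeric(1))
    val <- mean((y - preds)^2)
    if (!is.finite(val)) {
      stop("non-finite loss in Nelder-Mead objective; trace preserved",
           call. = FALSE)
    }
    k <- length(rec$loss) + 1L
    rec$loss[k] <- val
    rec$theta[[k]] <- th
    rec$r2[k] <- if (k %% eval_every == 0L) {
      .training_r2_scaled(enc_list, ansatz, th, y)
    } else NA_real_
    val
  }
  # optim's Nelder-Mead treats maxit per iteration and can overrun it by a
  # few evaluations; a hard cap keeps the shot accounting exact
  fit <- tryCatch(
    stats::optim(theta, objective, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = reltol)),
    qclr_budget_exhausted = function(cond) {
      best <- which.min(rec$loss)
      list(par = rec$theta[[best]], value = rec$loss[best], convergence = 1L)
    })
  n_eval <- length(rec$loss)
  trace <- data.frame(step = seq_len(n_eval), sample = NA_integer_,
                      loss = rec$loss, r2 = rec$r2,
                      cum_shots = if (is.na(per_step)) NA_real_ else
                        per_step * seq_len(n_eval))
  if (n_eval > 0L && is.na(trace$r2[n_eval])) {
    trace$r2[n_eval] <- .training_r2_scaled(enc_list, ansatz,
                                            rec$theta[[n_eval]], y)
  }
  theta_path <- do.call(rbind, rec$theta)
  .new_training_result(fit$par, trace, theta_path, "nelder_mead", shots, seed,
                       list(convergence = fit$convergence,
                            final_loss = fit$value, encoding = encoding))
}

#' Export a learning trace to CSV
#'
#' Writes the per-step columns (`step`, `sample`, `loss`, `r2`, `cum_shots`)
#' of a `qcl_training` trace; optionally the parameter snapshots as a JSON
#' sidecar (`<path>.theta.json`).
#'
#' @param result A `qcl_training` object.
#' @param path Output CSV path.
#' @param theta_snapshots Also write the per-step parameter matrix as JSON.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path, theta_snapshots = FALSE) {
  stopifnot(inherits(result, "qcl_training"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  if (theta_snapshots) {
    jsonlite::write_json(result$theta_path, paste0(path, ".theta.json"),
                         digits = NA)
  }
  invisible(path)
}
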