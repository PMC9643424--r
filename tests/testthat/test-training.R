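test_that("predict_one composes encoder and ansatz on |0...0>", {
  a <- build_mera_ansatz()
  # zero angles + zero features: identity circuit, readout +1
  expect_equal(predict_one(rep(0, 4), rep(0, 24), a), 1, tolerance = 1e-12)
  o <- build_original_ansatz(4, 2)
  expect_equal(predict_one(rep(0, 4), rep(0, 24), o), 1, tolerance = 1e-12)
  # always a bounded expectation
  withr::with_seed(21, {
    for (i in 1:5) {
      v <- predict_one(stats::runif(4, -pi, pi),
                       stats::runif(24, 0, 2 * pi), a)
      expect_true(v >= -1 && v <= 1)
    }
  })
  # sampled readout is reproducible under a fixed seed
  x <- rep(0.3, 4); th <- rep(1, 24)
  v1 <- withr::with_seed(5, predict_one(x, th, a, shots = 100))
  v2 <- withr::with_seed(5, predict_one(x, th, a, shots = 100))
  expect_identical(v1, v2)
  expect_error(predict_one(x, rep(0, 23), a), "length 24")
  expect_error(predict_one(x, th, a, shots = 0), "positive integer")
})

test_that("MSE loss matches its definition", {
  probe <- ry_probe_circuit(); enc <- ry_probe_encoding()
  X <- matrix(0, 3, 1)
  # theta = 2pi/3 makes the prediction cos(2pi/3) = -0.5 for every sample
  expect_equal(mse_loss(2 * pi / 3, X[1, , drop = FALSE], 0.5, probe, enc),
               1.0, tolerance = 1e-12)
  # predictions equal to the targets give zero loss
  y_hit <- rep(cos(0.4), 3)
  expect_equal(mse_loss(0.4, X, y_hit, probe, enc), 0, tolerance = 1e-12)
  # full batch equals the mean of per-sample losses
  y <- c(-0.2, 0.1, 0.6)
  per_sample <- vapply(1:3, function(i) {
    mse_loss(0.4, X, y, probe, enc, batch = i)
  }, numeric(1))
  expect_equal(mse_loss(0.4, X, y, probe, enc), mean(per_sample),
               tolerance = 1e-12)
  expect_error(mse_loss(0.4, X[0, , drop = FALSE], numeric(0), probe, enc),
               "empty batch")
})

test_that("sampled loss converges to the exact loss at high shot counts", {
  d <- tiny_dataset(n = 5, seed = 30)
  pre <- fit_preprocessor(d, 4)
  Xs <- transform_x(pre, d$X); ys <- transform_y(pre, d$y)
  a <- build_mera_ansatz()
  th <- random_parameters(a, seed = 13)
  exact <- mse_loss(th, Xs, ys, a)
  sampled <- withr::with_seed(14, mse_loss(th, Xs, ys, a, shots = 1e6))
  expect_lt(abs(sampled - exact), 1e-2)
})

test_that("parameter-shift rule reproduces the closed-form RY gradient", {
  probe <- ry_probe_circuit(); enc <- ry_probe_encoding()
  x0 <- 0
  # B(theta) = cos(theta): dB/dtheta = -sin(theta)
  expect_equal(parameter_shift_gradient(0, x0, probe, enc), 0,
               tolerance = 1e-12)
  expect_equal(parameter_shift_gradient(pi / 2, x0, probe, enc), -1,
               tolerance = 1e-12)
  expect_equal(parameter_shift_gradient(pi / 3, x0, probe, enc),
               -sin(pi / 3), tolerance = 1e-12)
  expect_equal(finite_difference_gradient(pi / 3, x0, probe, enc),
               -sin(pi / 3), tolerance = 1e-4)
  expect_error(finite_difference_gradient(0.2, x0, probe, enc, h = 0),
               "positive")
})

test_that("parameter-shift matches finite differences on the full circuits", {
  withr::with_seed(17, {
    for (build in list(function() build_original_ansatz(4, 1),
                       build_mera_ansatz)) {
      a <- build()
      x <- stats::runif(4, -pi, pi)
      th <- stats::runif(n_trainable(a), 0, 2 * pi)
      ps <- parameter_shift_gradient(th, x, a)
      fd <- finite_difference_gradient(th, x, a, h = 1e-6)
      expect_lt(max(abs(ps - fd)), 1e-4)
    }
  })
})

test_that("Adam updates behave as expected", {
  th <- c(1, -2, 0.5)
  # zero gradient leaves parameters unchanged
  upd <- adam_step(th, c(0, 0, 0))
  expect_equal(upd$theta, th)
  # constant gradient: step magnitude approaches the learning rate
  state <- NULL; cur <- th
  for (i in 1:100) {
    upd <- adam_step(cur, c(1, 1, 1), state, lr = 0.05)
    delta <- upd$theta - cur
    cur <- upd$theta; state <- upd$state
  }
  expect_equal(abs(delta), rep(0.05, 3), tolerance = 1e-3)
  expect_error(adam_step(th, c(1, NA, 0)), "non-finite")
  expect_error(adam_step(th, c(1, 2)), "shape")
})

test_that("SGD training traces record steps, losses and shot budgets", {
  d <- tiny_dataset(n = 20)
  pre <- fit_preprocessor(d, 4)
  Xs <- transform_x(pre, d$X); ys <- transform_y(pre, d$y)
  a <- build_mera_ansatz()
  res <- train_sgd(Xs, ys, a, shots = 100, n_steps = 12, seed = 3,
                   eval_every = 6)
  expect_s3_class(res, "qcl_training")
  expect_equal(nrow(res$trace), 12)
  expect_equal(res$trace$step, 1:12)
  expect_true(all(res$trace$sample %in% seq_len(20)))
  # 4,900 shots per step at 100 shots and 24 parameters
  expect_equal(res$trace$cum_shots, 4900 * (1:12))
  expect_true(all(diff(res$trace$cum_shots) > 0))
  expect_equal(dim(res$theta_path), c(12, 24))
  expect_false(is.na(res$trace$r2[12]))  # final step always evaluated
  # identical trajectories under the same seed
  res2 <- train_sgd(Xs, ys, a, shots = 100, n_steps = 12, seed = 3,
                    eval_every = 6)
  expect_identical(res$theta, res2$theta)
  expect_identical(res$trace, res2$trace)
  expect_error(train_sgd(Xs, ys, a, n_steps = 0), ">= 1")
})

test_that("SGD with exact gradients learns the synthetic mapping", {
  d <- tiny_dataset(n = 30)
  pre <- fit_preprocessor(d, 4)
  Xs <- transform_x(pre, d$X); ys <- transform_y(pre, d$y)
  res <- train_sgd(Xs, ys, build_mera_ansatz(), shots = "exact",
                   n_steps = 200, seed = 1, eval_every = 200)
  expect_gt(res$trace$r2[200], 0)
  expect_true(all(is.na(res$trace$cum_shots)))  # exact readout: no shots
})

test_that("Nelder-Mead reduces the exact loss and accounts for shots", {
  d <- tiny_dataset(n = 15)
  pre <- fit_preprocessor(d, 4)
  Xs <- transform_x(pre, d$X); ys <- transform_y(pre, d$y)
  a <- build_mera_ansatz()
  res <- train_nelder_mead(Xs, ys, a, shots = "exact", max_iter = 120,
                           seed = 2, eval_every = 60)
  # deterministic objective: best-so-far is non-increasing, final <= initial
  expect_lte(res$final_loss, res$trace$loss[1])
  expect_true(all(diff(cummin(res$trace$loss)) <= 0))
  # finite-shot budget: shots x n_samples per objective evaluation
  res_s <- train_nelder_mead(Xs, ys, a, shots = 100, max_iter = 40, seed = 2,
                             eval_every = 40)
  expect_equal(res_s$trace$cum_shots,
               100 * 15 * seq_len(nrow(res_s$trace)))
  expect_error(train_nelder_mead(Xs, ys, a, max_iter = 0), ">= 1")
})

test_that("shot budget arithmetic matches the published step costs", {
  expect_equal(shots_per_step(10000, "nelder_mead", n_samples = 86), 860000)
  expect_equal(shots_per_step(100, "sgd_param_shift", n_trainable = 24), 4900)
  expect_equal(shots_per_step(1, "nelder_mead", n_samples = 1), 1)
  expect_equal(shots_per_step(100, "sgd_param_shift", n_trainable = 96),
               100 + 2 * 100 * 96)
})

test_that("training traces export to CSV with parameter snapshots", {
  d <- tiny_dataset(n = 12)
  pre <- fit_preprocessor(d, 4)
  res <- train_sgd(transform_x(pre, d$X), transform_y(pre, d$y),
                   build_mera_ansatz(), shots = "exact", n_steps = 5,
                   seed = 1, eval_every = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path, theta_snapshots = TRUE)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("step", "sample", "loss", "r2", "cum_shots"))
  expect_equal(nrow(back), 5)
  theta_path <- jsonlite::fromJSON(paste0(path, ".theta.json"))
  expect_equal(dim(theta_path), c(5, 24))
})
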