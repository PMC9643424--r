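test_that("encoder has the published structure and no trainable slots", {
  enc <- build_encoder(rep(0, 4), encoding_spec(4, 2))
  kinds <- vapply(enc$gates, `[[`, "", "kind")
  expect_equal(sum(kinds %in% c("RY", "RZ")), 16)  # 2 reps x 4 qubits x 2
  expect_equal(sum(kinds == "CNOT"), 6)            # 2 linear chains of 3
  expect_equal(n_trainable(enc), 0)
  # zero angles: CNOT chains fix |0000>, so the encoder acts as the identity
  out <- run_circuit(enc)
  expect_equal(out$amplitudes, qcl_state(4)$amplitudes, tolerance = 1e-12)
  # a repetition is a rotation block followed by its chain
  enc1 <- build_encoder(rep(0.5, 3), encoding_spec(3, 1))
  expect_equal(vapply(enc1$gates, `[[`, "", "kind"),
               c("RY", "RZ", "RY", "RZ", "RY", "RZ", "CNOT", "CNOT"))
})

test_that("encoder validates its inputs", {
  expect_error(build_encoder(c(0, 0, 0, pi + 0.1), encoding_spec(4)),
               "\\[-pi, pi\\]")
  expect_error(build_encoder(c(0, NA, 0, 0), encoding_spec(4)), "pi")
  expect_error(build_encoder(rep(0, 3), encoding_spec(4)), "per qubit")
})

test_that("layered ansatz obeys the 3nL parameter-count formula", {
  for (n in 2:6) for (L in 1:8) {
    a <- build_original_ansatz(n, L)
    expect_equal(n_trainable(a), 3 * n * L)
    expect_equal(a$readout_qubit, n)
  }
  expect_equal(n_trainable(build_original_ansatz(4, 1)), 12)
  expect_equal(n_trainable(build_original_ansatz(4, 8)), 96)
  expect_error(build_original_ansatz(4, 0), ">= 1")
  # all angles zero: CNOT chains only, readout on |0...0> stays +1
  a <- bind_parameters(build_original_ansatz(4, 2), rep(0, 24))
  s <- run_circuit(a)
  expect_equal(z_expectation_exact(s, a$readout_qubit)$value, 1,
               tolerance = 1e-12)
})

test_that("MERA ansatz has 24 parameters and reads out the third qubit", {
  a <- build_mera_ansatz()
  expect_equal(n_trainable(a), 24)
  kinds <- vapply(a$gates, `[[`, "", "kind")
  expect_equal(sum(kinds == "U3"), 8)
  expect_equal(sum(kinds == "CNOT"), 4)
  expect_equal(a$readout_qubit, 3)
  expect_error(build_mera_ansatz(5), "4 qubits")
  s <- run_circuit(bind_parameters(a, rep(0, 24)))
  expect_equal(z_expectation_exact(s, 3)$value, 1, tolerance = 1e-12)
})

test_that("parameter binding follows the canonical slot order", {
  a <- build_mera_ansatz()
  theta <- seq_len(24) / 10
  bound <- bind_parameters(a, theta)
  expect_equal(circuit_parameters(bound), theta)
  # idempotent when re-binding the current values
  expect_identical(bind_parameters(bound, theta), bound)
  expect_error(bind_parameters(a, rep(0, 23)), "length 24")
  expect_error(bind_parameters(a, c(rep(0, 23), NA)), "finite")
  # layered ansatz at L = 2 carries the same 24-parameter count as MERA
  expect_silent(bind_parameters(build_original_ansatz(4, 2), theta))
})

test_that("encoder + ansatz composition yields a unit-norm state", {
  withr::with_seed(33, {
    x <- stats::runif(4, -pi, pi)
    enc <- build_encoder(x, encoding_spec(4, 2))
    a <- bind_parameters(build_mera_ansatz(), stats::runif(24, 0, 2 * pi))
    s <- run_circuit(a, run_circuit(enc))
    expect_unit_norm(s)
  })
})

test_that("circuits serialize to JSON and back without loss", {
  a <- bind_parameters(build_mera_ansatz(),
                       withr::with_seed(9, stats::runif(24, 0, 2 * pi)))
  json <- circuit_to_json(a)
  b <- circuit_from_json(json)
  expect_equal(b$n_qubits, a$n_qubits)
  expect_equal(b$readout_qubit, a$readout_qubit)
  expect_equal(b$trainable_slots, a$trainable_slots)
  expect_equal(circuit_parameters(b), circuit_parameters(a))
  expect_equal(run_circuit(b)$amplitudes, run_circuit(a)$amplitudes,
               tolerance = 1e-12)
  # file round-trip, including an encoder with no readout qubit
  path <- withr::local_tempfile(fileext = ".json")
  enc <- build_encoder(c(0.2, -0.4), encoding_spec(2, 1))
  circuit_to_json(enc, path)
  enc2 <- circuit_from_json(path)
  expect_true(is.na(enc2$readout_qubit))
  expect_equal(run_circuit(enc2)$amplitudes, run_circuit(enc)$amplitudes,
               tolerance = 1e-12)
})

test_that("random initial parameters cover [0, 2pi) reproducibly", {
  a <- build_original_ansatz(4, 2)
  t1 <- random_parameters(a, seed = 4)
  t2 <- random_parameters(a, seed = 4)
  expect_identical(t1, t2)
  expect_length(t1, 24)
  expect_true(all(t1 >= 0 & t1 < 2 * pi))
})
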