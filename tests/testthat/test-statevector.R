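test_that("single-qubit rotations follow the half-angle convention", {
  # <Z> = cos(theta) after RY(theta)|0>
  for (theta in c(0, pi / 2, 2 * pi / 3, pi, -1.3, 2.7)) {
    s <- apply_gate(qcl_state(1), gate_ry(1, theta))
    expect_equal(z_expectation_exact(s, 1)$value, cos(theta), tolerance = 1e-12)
    expect_unit_norm(s)
  }
  # RZ only changes phases: probabilities of a superposition are unchanged
  s <- apply_gate(qcl_state(1), gate_ry(1, pi / 3))
  p_before <- Mod(s$amplitudes)^2
  s <- apply_gate(s, gate_rz(1, 1.1))
  expect_equal(Mod(s$amplitudes)^2, p_before, tolerance = 1e-12)
  # U3(theta, 0, 0) acts as RY(theta)
  s1 <- apply_gate(qcl_state(1), gate_u3(1, c(0.7, 0, 0)))
  s2 <- apply_gate(qcl_state(1), gate_ry(1, 0.7))
  expect_equal(s1$amplitudes, s2$amplitudes, tolerance = 1e-12)
})

test_that("CNOT implements the controlled flip and is an involution", {
  # truth table over all two-qubit basis states (qubit 1 = control)
  prep <- function(bits) {
    s <- qcl_state(2)
    for (q in which(bits == 1L)) s <- apply_gate(s, gate_ry(q, pi))
    s
  }
  for (b1 in 0:1) for (b2 in 0:1) {
    s <- apply_gate(prep(c(b1, b2)), gate_cnot(1, 2))
    expected_index <- b1 + 2 * xor(b1, b2) + 1  # little-endian basis index
    expect_equal(which.max(Mod(s$amplitudes)^2), expected_index)
  }
  # involution on an arbitrary entangled state
  s <- qcl_state(3)
  for (q in 1:3) s <- apply_gate(s, gate_ry(q, 0.3 * q))
  s1 <- apply_gate(s, gate_cnot(2, 3))
  s2 <- apply_gate(s1, gate_cnot(2, 3))
  expect_equal(s2$amplitudes, s$amplitudes, tolerance = 1e-12)
})

test_that("GHZ-like state has zero Z expectation on every qubit", {
  s <- apply_gate(qcl_state(4), gate_ry(1, pi / 2))
  for (q in 1:3) s <- apply_gate(s, gate_cnot(q, q + 1))
  expect_equal(Mod(s$amplitudes[1])^2, 0.5, tolerance = 1e-12)
  expect_equal(Mod(s$amplitudes[16])^2, 0.5, tolerance = 1e-12)
  for (q in 1:4) {
    expect_equal(z_expectation_exact(s, q)$value, 0, tolerance = 1e-12)
  }
})

test_that("random gate sequences preserve the norm and are invertible", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      n <- sample(2:5, 1)
      gates <- list()
      for (g in 1:15) {
        kind <- sample(c("ry", "rz", "u3", "cnot"), 1)
        q <- sample(n, 1)
        gates[[g]] <- switch(kind,
          ry = gate_ry(q, stats::runif(1, -pi, pi)),
          rz = gate_rz(q, stats::runif(1, -pi, pi)),
          u3 = gate_u3(q, stats::runif(3, -pi, pi)),
          cnot = {
            others <- setdiff(seq_len(n), q)
            gate_cnot(others[sample.int(length(others), 1)], q)
          })
      }
      s <- qcl_state(n)
      for (g in gates) s <- apply_gate(s, g)
      expect_unit_norm(s)
      # inverse pass: reversed order, negated angles (U3 swaps phi/lambda)
      for (g in rev(gates)) {
        inv <- switch(g$kind,
          RY = gate_ry(g$target, -g$angles),
          RZ = gate_rz(g$target, -g$angles),
          U3 = gate_u3(g$target, -g$angles[c(1, 3, 2)]),
          CNOT = g)
        s <- apply_gate(s, inv)
      }
      ref <- qcl_state(n)
      expect_equal(s$amplitudes, ref$amplitudes, tolerance = 1e-10)
    }
  })
})

test_that("sampled expectation follows the binomial estimator contract", {
  # degenerate probabilities give exact values at any shot count
  withr::with_seed(1, {
    expect_identical(z_expectation_sampled(qcl_state(2), 1, 50)$value, 1)
    flipped <- apply_gate(qcl_state(1), gate_ry(1, pi))
    expect_identical(z_expectation_sampled(flipped, 1, 50)$value, -1)
  })
  # value lies on the grid (2 n0 - shots) / shots and matches n_zero
  est <- withr::with_seed(2, z_expectation_sampled(state_with_p0(0.3), 1, 97))
  expect_equal(est$value, (2 * est$n_zero - 97) / 97)
  expect_true(est$n_zero >= 0 && est$n_zero <= 97)
  # reproducible under a fixed seed
  e1 <- withr::with_seed(7, z_expectation_sampled(state_with_p0(0.5), 1, 100))
  e2 <- withr::with_seed(7, z_expectation_sampled(state_with_p0(0.5), 1, 100))
  expect_identical(e1$value, e2$value)
  # unbiased: mean over repetitions within 4 standard errors of the mean
  p <- 0.5; shots <- 10000; reps <- 300
  vals <- withr::with_seed(8, replicate(reps, {
    z_expectation_sampled(state_with_p0(p), 1, shots)$value
  }))
  se_mean <- 2 * sqrt(p * (1 - p) / shots) / sqrt(reps)
  expect_lt(abs(mean(vals) - (2 * p - 1)), 4 * se_mean)
  # sampled and exact readout agree as shots grow: one 10^6-shot draw
  one <- withr::with_seed(9, z_expectation_sampled(state_with_p0(0.5), 1,
                                                   1e6))
  expect_lt(abs(one$value - 0), 5e-3)
})

test_that("simulator inputs are validated", {
  expect_error(qcl_state(0), "1..12")
  expect_error(apply_gate(qcl_state(2), gate_ry(3, 0.1)), "target")
  expect_error(apply_gate(qcl_state(2), gate_ry(1, NaN)), "finite")
  expect_error(apply_gate(qcl_state(2), gate_cnot(2, 2)), "differ")
  expect_error(z_expectation_exact(qcl_state(2), 5), "1..2")
  expect_error(z_expectation_sampled(qcl_state(1), 1, 0), "positive")
  expect_error(z_expectation_sampled(qcl_state(1), 1, -10), "positive")
})
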