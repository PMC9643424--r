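# Small fixtures shared across test files; everything is generated in code.

# compact synthetic dataset for fast training tests
tiny_dataset <- function(n = 30, seed = 42, noise_sd = 0.05) {
  generate_qspr(qspr_generator_spec(n_samples = n, seed = seed,
                                    noise_sd = noise_sd))
}

# single-qubit circuit with one trainable RY: readout expectation is
# cos(theta), the closed form used by the gradient oracles
ry_probe_circuit <- function() {
  qcl_circuit(1L, list(gate_ry(1L, 0, trainable = TRUE)), readout_qubit = 1L)
}

# identity encoder on one qubit (x = 0)
ry_probe_encoding <- function() encoding_spec(1L, 1L)

# a state with P(qubit = 0) = p, via RY(theta), cos(theta) = 2p - 1
state_with_p0 <- function(p) {
  apply_gate(qcl_state(1L), gate_ry(1L, acos(2 * p - 1)))
}

expect_unit_norm <- function(state, tol = 1e-10) {
  expect_lt(abs(sqrt(sum(Mod(state$amplitudes)^2)) - 1), tol)
}
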