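# Exact statevector simulator for few-qubit circuits.
#
# Amplitude ordering is little-endian: bit (q - 1) of the 0-based basis-state
# index holds the value of qubit q (qubits are numbered 1..n_qubits, qubit 1
# is the top wire of a circuit diagram). |0...0> is index 0.

#' Create a computational-basis statevector
#'
#' Allocates the state \eqn{|0\dots0\rangle} on `n_qubits` qubits as a dense
#' complex amplitude vector of length \eqn{2^{n}}.
#'
#' @param n_qubits Number of qubits (positive integer, at most 12).
#' @return An object of class `qcl_state`: a list with elements `amplitudes`
#'   (complex vector of length `2^n_qubits`, unit L2 norm) and `n_qubits`.
#' @examples
#' s <- qcl_state(2)
#' s$amplitudes  # (1+0i, 0, 0, 0)
#' @export
qcl_state <- function(n_qubits) {
  stopifnot(is.numeric(n_qubits), length(n_qubits) == 1L)
  n_qubits <- as.integer(n_qubits)
  if (is.na(n_qubits) || n_qubits < 1L || n_qubits > 12L) {
    stop("`n_qubits` must be an integer in 1..12", call. = FALSE)
  }
  amp <- complex(2L^n_qubits)
  amp[1L] <- 1 + 0i
  structure(list(amplitudes = amp, n_qubits = n_qubits), class = "qcl_state")
}

#' @export
print.qcl_state <- function(x, ...) {
  cat(sprintf("<qcl_state: %d qubit(s), %d amplitudes>\n",
              x$n_qubits, length(x$amplitudes)))
  invisible(x)
}

# memoized index tables: at <= 12 qubits these are tiny and reused millions
# of times in training loops
.qclr_cache <- new.env(parent = emptyenv())

# qubit-q "bit = 1" logical mask over basis indices 0..(2^n - 1)
.qubit_mask <- function(n_qubits, qubit) {
  key <- paste0("m", n_qubits, "_", qubit)
  m <- .qclr_cache[[key]]
  if (is.null(m)) {
    idx <- seq_len(2L^n_qubits) - 1L
    m <- bitwAnd(idx %/% 2L^(qubit - 1L), 1L) == 1L
    .qclr_cache[[key]] <- m
  }
  m
}

# paired 1-based positions (bit q = 0, bit q = 1) for a single-qubit gate
.idx_1q <- function(n_qubits, qubit) {
  key <- paste0("g", n_qubits, "_", qubit)
  p <- .qclr_cache[[key]]
  if (is.null(p)) {
    i1 <- which(.qubit_mask(n_qubits, qubit))
    p <- list(i0 = i1 - 2L^(qubit - 1L), i1 = i1)
    .qclr_cache[[key]] <- p
  }
  p
}

.idx_cnot <- function(n_qubits, control, target) {
  key <- paste0("c", n_qubits, "_", control, "_", target)
  p <- .qclr_cache[[key]]
  if (is.null(p)) {
    i1 <- which(.qubit_mask(n_qubits, control) & .qubit_mask(n_qubits, target))
    p <- list(i0 = i1 - 2L^(target - 1L), i1 = i1)
    .qclr_cache[[key]] <- p
  }
  p
}

.check_qubit <- function(qubit, n_qubits, what = "qubit") {
  if (!is.numeric(qubit) || length(qubit) != 1L || is.na(qubit) ||
      qubit != as.integer(qubit) || qubit < 1L || qubit > n_qubits) {
    stop(sprintf("%s index must be an integer in 1..%d", what, n_qubits),
         call. = FALSE)
  }
  as.integer(qubit)
}

# 2x2 unitaries; half-angle convention so that <Z> = cos(theta) after
# RY(theta)|0>.  RZ(a) = diag(exp(-ia/2), exp(ia/2)).
# U3(theta, phi, lambda) = RZ(phi) RY(theta) RZ(lambda) (global phase dropped).
# returned as length-4 complex vectors in column-major order
.mat_ry <- function(theta) {
  c <- cos(theta / 2); s <- sin(theta / 2)
  complex(real = c(c, s, -s, c))
}

.mat_rz <- function(theta) {
  c(exp(-1i * theta / 2), 0i, 0i, exp(1i * theta / 2))
}

.mat_u3 <- function(theta, phi, lambda) {
  c <- cos(theta / 2); s <- sin(theta / 2)
  c(exp(-1i * (phi + lambda) / 2) * c,
    exp( 1i * (phi - lambda) / 2) * s,
   -exp(-1i * (phi - lambda) / 2) * s,
    exp( 1i * (phi + lambda) / 2) * c)
}

.gate_matrix <- function(gate) {
  switch(gate$kind,
    RY = .mat_ry(gate$angles[1L]),
    RZ = .mat_rz(gate$angles[1L]),
    U3 = .mat_u3(gate$angles[1L], gate$angles[2L], gate$angles[3L]),
    stop("no matrix for gate kind ", gate$kind, call. = FALSE)
  )
}

# apply a 2x2 unitary `m` to qubit q of raw amplitude vector `amp`
.apply_1q <- function(amp, n_qubits, qubit, m) {
  p <- .idx_1q(n_qubits, qubit)
  a0 <- amp[p$i0]; a1 <- amp[p$i1]
  amp[p$i0] <- m[1L] * a0 + m[3L] * a1
  amp[p$i1] <- m[2L] * a0 + m[4L] * a1
  amp
}

.apply_cnot <- function(amp, n_qubits, control, target) {
  p <- .idx_cnot(n_qubits, control, target)
  tmp <- amp[p$i0]
  amp[p$i0] <- amp[p$i1]
  amp[p$i1] <- tmp
  amp
}

# gate dispatch on a raw complex vector; hot path for circuit execution
.apply_gate_raw <- function(amp, n_qubits, gate) {
  if (gate$kind == "CNOT") {
    .apply_cnot(amp, n_qubits, gate$control, gate$target)
  } else {
    .apply_1q(amp, n_qubits, gate$target, .gate_matrix(gate))
  }
}

#' Apply a single gate to a statevector
#'
#' Evolves the state by the gate's unitary. Conventions:
#' \eqn{R_Y(\theta) = e^{-i\theta Y/2}}, \eqn{R_Z(\theta) = e^{-i\theta Z/2}},
#' \eqn{U_3(\theta,\phi,\lambda) = R_Z(\phi)R_Y(\theta)R_Z(\lambda)} up to
#' global phase, and CNOT the controlled bit flip. Norm is preserved.
#'
#' @param state A [qcl_state()].
#' @param gate A gate built by [gate_ry()], [gate_rz()], [gate_u3()] or
#'   [gate_cnot()].
#' @return The evolved `qcl_state`.
#' @examples
#' s <- apply_gate(qcl_state(1), gate_ry(1, pi))
#' z_expectation_exact(s, 1)$value  # -1
#' @export
apply_gate <- function(state, gate) {
  stopifnot(inherits(state, "qcl_state"), inherits(gate, "qcl_gate"))
  validate_gate(gate, state$n_qubits)
  state$amplitudes <- .apply_gate_raw(state$amplitudes, state$n_qubits, gate)
  state
}

#' Exact Pauli-Z expectation on one qubit
#'
#' Computes \eqn{\langle Z_q\rangle = P(q = 0) - P(q = 1)} directly from the
#' amplitudes, with no sampling noise.
#'
#' @param state A [qcl_state()].
#' @param qubit Qubit index (1-based).
#' @return A `qcl_expectation`: list with `value` in \[-1, 1\], and
#'   `shots = "exact"`.
#' @examples
#' z_expectation_exact(qcl_state(3), 2)$value  # +1
#' @export
z_expectation_exact <- function(state, qubit) {
  stopifnot(inherits(state, "qcl_state"))
  qubit <- .check_qubit(qubit, state$n_qubits)
  p <- Mod(state$amplitudes)^2
  value <- sum(p[!.qubit_mask(state$n_qubits, qubit)]) -
    sum(p[.qubit_mask(state$n_qubits, qubit)])
  structure(list(value = min(1, max(-1, value)), shots = "exact",
                 n_zero = NULL),
            class = "qcl_expectation")
}

#' Finite-shot Pauli-Z expectation on one qubit
#'
#' Simulates `shots` projective measurements of the qubit: the number of
#' \eqn{|0\rangle} outcomes is drawn from a binomial with success probability
#' \eqn{P(q = 0)}, and the estimate is \eqn{(2 n_0 - \mathrm{shots}) /
#' \mathrm{shots}}. Uses R's random number generator; seed with
#' [set.seed()] (higher-level training functions take a `seed` argument).
#'
#' @inheritParams z_expectation_exact
#' @param shots Positive integer number of measurements.
#' @return A `qcl_expectation`: list with `value`, `shots`, and `n_zero`.
#' @examples
#' set.seed(1)
#' z_expectation_sampled(qcl_state(1), 1, shots = 100)$value  # +1, p0 = 1
#' @export
z_expectation_sampled <- function(state, qubit, shots) {
  stopifnot(inherits(state, "qcl_state"))
  qubit <- .check_qubit(qubit, state$n_qubits)
  if (!is.numeric(shots) || length(shots) != 1L || is.na(shots) || shots < 1) {
    stop("`shots` must be a positive integer", call. = FALSE)
  }
  shots <- as.integer(shots)
  p0 <- sum(Mod(state$amplitudes[!.qubit_mask(state$n_qubits, qubit)])^2)
  p0 <- min(1, max(0, p0))
  n_zero <- stats::rbinom(1L, shots, p0)
  structure(list(value = (2 * n_zero - shots) / shots, shots = shots,
                 n_zero = n_zero),
            class = "qcl_expectation")
}

#' @export
print.qcl_expectation <- function(x, ...) {
  cat(sprintf("<Z expectation: %.6f (%s)>\n", x$value,
              if (identical(x$shots, "exact")) "exact"
              else paste0(x$shots, " shots")))
  invisible(x)
}

# raw Z expectation helpers used by the training hot path
.z_exact_raw <- function(amp, n_qubits, qubit) {
  p <- Mod(amp)^2
  on <- .qubit_mask(n_qubits, qubit)
  sum(p[!on]) - sum(p[on])
}

.z_sampled_raw <- function(amp, n_qubits, qubit, shots) {
  p0 <- sum(Mod(amp[!.qubit_mask(n_qubits, qubit)])^2)
  p0 <- min(1, max(0, p0))
  (2 * stats::rbinom(1L, shots, p0) - shots) / shots
}
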