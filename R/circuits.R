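# Parameterized circuits: ordered gate lists with trainable-parameter slots
# and a designated readout qubit.

#' Construct a parameterized circuit
#'
#' A circuit is an ordered gate list plus bookkeeping: the trainable slots
#' (in canonical order: gate order, then angle order within a gate) and the
#' readout qubit whose Pauli-Z expectation is the model output.
#'
#' @param n_qubits Number of qubits.
#' @param gates List of `qcl_gate` objects, applied left to right.
#' @param readout_qubit Qubit measured for the prediction (1-based), or `NA`
#'   for circuits with no readout of their own (e.g. the encoder).
#' @return A `qcl_circuit`: list with `n_qubits`, `gates`, `trainable_slots`
#'   (data frame with columns `gate`, `angle`), `readout_qubit`.
#' @seealso [build_encoder()], [build_original_ansatz()], [build_mera_ansatz()]
#' @export
qcl_circuit <- function(n_qubits, gates, readout_qubit = NA_integer_) {
  n_qubits <- as.integer(n_qubits)
  stopifnot(n_qubits >= 1L, is.list(gates))
  for (g in gates) validate_gate(g, n_qubits)
  if (!is.na(readout_qubit)) {
    readout_qubit <- .check_qubit(readout_qubit, n_qubits, "readout")
  }
  slots <- .trainable_slots(gates)
  structure(list(n_qubits = n_qubits, gates = gates,
                 trainable_slots = slots,
                 readout_qubit = as.integer(readout_qubit)),
            class = "qcl_circuit")
}

.trainable_slots <- function(gates) {
  gi <- integer(); ai <- integer()
  for (i in seq_along(gates)) {
    tr <- which(gates[[i]]$trainable)
    if (length(tr)) {
      gi <- c(gi, rep.int(i, length(tr)))
      ai <- c(ai, tr)
    }
  }
  data.frame(gate = gi, angle = ai)
}

#' Number of trainable parameters of a circuit
#' @param circuit A [qcl_circuit()].
#' @return Integer count of trainable angle slots.
#' @export
n_trainable <- function(circuit) {
  stopifnot(inherits(circuit, "qcl_circuit"))
  nrow(circuit$trainable_slots)
}

#' @export
print.qcl_circuit <- function(x, ...) {
  cat(sprintf("<qcl_circuit: %d qubits, %d gates, %d trainable, readout q%s>\n",
              x$n_qubits, length(x$gates), n_trainable(x),
              ifelse(is.na(x$readout_qubit), "?", x$readout_qubit)))
  invisible(x)
}

#' Run a circuit on a statevector
#'
#' Applies all gates in order. All trainable angles must already hold
#' numeric values (see [bind_parameters()]).
#'
#' @param circuit A [qcl_circuit()].
#' @param state Initial [qcl_state()]; defaults to \eqn{|0\dots0\rangle}.
#' @return The final `qcl_state`.
#' @export
run_circuit <- function(circuit, state = NULL) {
  stopifnot(inherits(circuit, "qcl_circuit"))
  if (is.null(state)) state <- qcl_state(circuit$n_qubits)
  stopifnot(inherits(state, "qcl_state"),
            state$n_qubits == circuit$n_qubits)
  amp <- state$amplitudes
  for (g in circuit$gates) amp <- .apply_gate_raw(amp, circuit$n_qubits, g)
  state$amplitudes <- amp
  state
}

# CNOT entangling chain; `linear` is 1->2, 2->3, ..., `ring` closes n->1
.entangling_chain <- function(n_qubits, topology = c("linear", "ring")) {
  topology <- match.arg(topology)
  if (n_qubits < 2L) return(list())
  gates <- lapply(seq_len(n_qubits - 1L),
                  function(q) gate_cnot(q, q + 1L))
  if (topology == "ring" && n_qubits > 2L) {
    gates <- c(gates, list(gate_cnot(n_qubits, 1L)))
  }
  gates
}

#' Encoding specification
#'
#' Describes the fixed angle-encoding circuit: one qubit per retained
#' feature (principal component), with the rotation/CNOT block repeated.
#'
#' @param n_qubits Number of qubits = number of encoded features (default 4,
#'   one per retained principal component).
#' @param repetitions Number of rotation + CNOT-chain repetitions (default 2).
#' @param entangler CNOT chain topology, `"linear"` or `"ring"`.
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(n_qubits = 4L, repetitions = 2L,
                          entangler = c("linear", "ring")) {
  entangler <- match.arg(entangler)
  n_qubits <- as.integer(n_qubits); repetitions <- as.integer(repetitions)
  stopifnot(n_qubits >= 1L, repetitions >= 1L)
  structure(list(n_qubits = n_qubits, repetitions = repetitions,
                 entangler = entangler),
            class = "encoding_spec")
}

#' Build the angle-encoding circuit for one sample
#'
#' Embeds a scaled feature vector as rotation angles: per repetition,
#' \eqn{R_Y(x_i)} then \eqn{R_Z(x_i)} on each qubit \eqn{i}, followed by a
#' CNOT entangling chain. The scaled value is used directly as the Bloch
#' angle, so all entries must lie in \eqn{[-\pi, \pi]} (the range produced
#' by [transform_x()]); values outside signal missing preprocessing and are
#' an error. The encoder has no trainable parameters.
#'
#' @param x_scaled Numeric vector of length `spec$n_qubits`, entries in
#'   \eqn{[-\pi, \pi]}.
#' @param spec An [encoding_spec()].
#' @return A `qcl_circuit` with zero trainable slots.
#' @examples
#' enc <- build_encoder(rep(0, 4), encoding_spec(4, 2))
#' n_trainable(enc)  # 0
#' @export
build_encoder <- function(x_scaled, spec = encoding_spec(length(x_scaled))) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (length(x_scaled) != spec$n_qubits) {
    stop("`x_scaled` must have one entry per qubit", call. = FALSE)
  }
  if (any(!is.finite(x_scaled)) || any(abs(x_scaled) > pi + 1e-9)) {
    stop("encoded features must lie in [-pi, pi]; apply min-max scaling first",
         call. = FALSE)
  }
  gates <- list()
  for (rep in seq_len(spec$repetitions)) {
    for (q in seq_len(spec$n_qubits)) {
      gates <- c(gates, list(gate_ry(q, x_scaled[q]), gate_rz(q, x_scaled[q])))
    }
    gates <- c(gates, .entangling_chain(spec$n_qubits, spec$entangler))
  }
  qcl_circuit(spec$n_qubits, gates, readout_qubit = NA_integer_)
}

#' Build the layered hardware-efficient ansatz
#'
#' The "original" variational circuit: `L` layers, each a CNOT entangling
#' chain followed by one generic rotation \eqn{U_3} (three trainable angles)
#' on every qubit, so the trainable-parameter count is \eqn{3 n L} (12 per
#' layer on 4 qubits). The readout qubit is the last wire.
#'
#' @param n_qubits Number of qubits.
#' @param L Number of layers (\eqn{\ge 1}).
#' @param entangler CNOT chain topology.
#' @return A `qcl_circuit` with `3 * n_qubits * L` trainable slots and
#'   `readout_qubit = n_qubits`. Trainable angles are initialized to 0.
#' @examples
#' n_trainable(build_original_ansatz(4, 8))  # 96
#' @export
build_original_ansatz <- function(n_qubits, L,
                                  entangler = c("linear", "ring")) {
  entangler <- match.arg(entangler)
  n_qubits <- as.integer(n_qubits); L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("`L` must be >= 1", call. = FALSE)
  stopifnot(n_qubits >= 2L)
  gates <- list()
  for (layer in seq_len(L)) {
    gates <- c(gates, .entangling_chain(n_qubits, entangler))
    for (q in seq_len(n_qubits)) {
      gates <- c(gates, list(gate_u3(q, trainable = TRUE)))
    }
  }
  qcl_circuit(n_qubits, gates, readout_qubit = n_qubits)
}

#' Build the four-qubit MERA ansatz
#'
#' Multi-scale entanglement renormalization ansatz on 4 qubits: four
#' two-qubit blocks — a disentangler on (q2, q3), isometries on (q1, q2) and
#' (q3, q4), and a top block on (q2, q3) — each block one \eqn{U_3} per wire
#' followed by a CNOT. That gives 8 \eqn{U_3} gates = 24 trainable
#' parameters, the same count as the layered ansatz at L = 2. The readout is
#' the third qubit.
#'
#' @param n_qubits Must be 4 (the only published size).
#' @return A `qcl_circuit` with 24 trainable slots and `readout_qubit = 3`.
#' @examples
#' n_trainable(build_mera_ansatz())  # 24
#' @export
build_mera_ansatz <- function(n_qubits = 4L) {
  if (!identical(as.integer(n_qubits), 4L)) {
    stop("the MERA ansatz is defined for 4 qubits only", call. = FALSE)
  }
  block <- function(a, b) {
    list(gate_u3(a, trainable = TRUE), gate_u3(b, trainable = TRUE),
         gate_cnot(a, b))
  }
  gates <- c(block(2L, 3L),   # disentangler
             block(1L, 2L),   # isometry, upper half
             block(3L, 4L),   # isometry, lower half
             block(2L, 3L))   # top block feeding the readout wire
  qcl_circuit(4L, gates, readout_qubit = 3L)
}

#' Bind trainable parameters into a circuit
#'
#' Sets the trainable angles from a parameter vector, in the canonical slot
#' order (gate order, then angle order within a gate).
#'
#' @param circuit A [qcl_circuit()].
#' @param theta Numeric vector of length `n_trainable(circuit)`.
#' @return The circuit with angles set (slots stay trainable).
#' @export
bind_parameters <- function(circuit, theta) {
  stopifnot(inherits(circuit, "qcl_circuit"))
  slots <- circuit$trainable_slots
  if (length(theta) != nrow(slots)) {
    stop(sprintf("`theta` must have length %d, got %d",
                 nrow(slots), length(theta)), call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  for (k in seq_len(nrow(slots))) {
    circuit$gates[[slots$gate[k]]]$angles[slots$angle[k]] <- theta[k]
  }
  circuit
}

#' Extract the current trainable parameter vector
#' @param circuit A [qcl_circuit()].
#' @return Numeric vector in canonical slot order.
#' @export
circuit_parameters <- function(circuit) {
  stopifnot(inherits(circuit, "qcl_circuit"))
  slots <- circuit$trainable_slots
  vapply(seq_len(nrow(slots)), function(k) {
    circuit$gates[[slots$gate[k]]]$angles[slots$angle[k]]
  }, numeric(1))
}

#' Random initial parameters for an ansatz
#'
#' Draws i.i.d. angles uniformly on \eqn{[0, 2\pi)} — full period coverage,
#' matching random circuit initialization.
#'
#' @param circuit A [qcl_circuit()].
#' @param seed Optional integer seed (applied locally; the global RNG state
#'   is restored afterwards).
#' @return Numeric vector of length `n_trainable(circuit)`.
#' @export
random_parameters <- function(circuit, seed = NULL) {
  n <- n_trainable(circuit)
  if (is.null(seed)) {
    stats::runif(n, 0, 2 * pi)
  } else {
    withr::with_seed(seed, stats::runif(n, 0, 2 * pi))
  }
}

#' Serialize a circuit to / from JSON
#'
#' Round-trippable JSON document holding the gate list, trainable flags and
#' readout qubit, for reproducibility and command-line round-trips.
#'
#' @param circuit A [qcl_circuit()].
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `circuit_to_json()`: a JSON string (invisibly, when written to
#'   `path`); `circuit_from_json()`: a `qcl_circuit`.
#' @export
circuit_to_json <- function(circuit, path = NULL) {
  stopifnot(inherits(circuit, "qcl_circuit"))
  doc <- list(
    n_qubits = circuit$n_qubits,
    readout_qubit = if (is.na(circuit$readout_qubit)) NULL
                    else circuit$readout_qubit,
    gates = lapply(circuit$gates, function(g) {
      list(kind = g$kind, target = g$target,
           control = if (is.na(g$control)) NULL else g$control,
           angles = as.list(g$angles), trainable = as.list(g$trainable))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname circuit_to_json
#' @param json JSON string or path to a JSON file produced by
#'   [circuit_to_json()].
#' @export
circuit_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  gates <- lapply(doc$gates, function(g) {
    .new_gate(g$kind, g$target,
              control = if (is.null(g$control)) NA_integer_ else g$control,
              angles = unlist(g$angles),
              trainable = as.logical(unlist(g$trainable)))
  })
  readout <- if (is.null(doc$readout_qubit)) NA_integer_ else doc$readout_qubit
  qcl_circuit(doc$n_qubits, gates, readout_qubit = readout)
}
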