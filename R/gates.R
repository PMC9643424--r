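# Gate values are plain lists tagged "qcl_gate": kind, target, control,
# angles (radians), trainable (logical per angle).

.new_gate <- function(kind, target, control = NA_integer_, angles = numeric(),
                      trainable = logical(length(angles))) {
  structure(list(kind = kind, target = as.integer(target),
                 control = as.integer(control), angles = as.numeric(angles),
                 trainable = as.logical(trainable)),
            class = "qcl_gate")
}

#' Gate constructors
#'
#' Build single gates for [apply_gate()] and [qcl_circuit()]. `RY` and `RZ`
#' carry one angle, `U3` three (\eqn{\theta,\phi,\lambda}), `CNOT` none.
#' Angles are in radians. `trainable` marks which angles are free model
#' parameters (bound later via [bind_parameters()]).
#'
#' @param target Target qubit index (1-based).
#' @param control Control qubit index for `CNOT` (must differ from `target`).
#' @param angle,angles Rotation angle(s) in radians; must be finite.
#' @param trainable Logical, recycled to the number of angles.
#' @return A `qcl_gate` object.
#' @examples
#' gate_u3(2, c(0.1, 0.2, 0.3), trainable = TRUE)
#' @name gates
NULL

#' @rdname gates
#' @export
gate_ry <- function(target, angle, trainable = FALSE) {
  .new_gate("RY", target, angles = angle, trainable = trainable)
}

#' @rdname gates
#' @export
gate_rz <- function(target, angle, trainable = FALSE) {
  .new_gate("RZ", target, angles = angle, trainable = trainable)
}

#' @rdname gates
#' @export
gate_u3 <- function(target, angles = c(0, 0, 0), trainable = FALSE) {
  .new_gate("U3", target, angles = angles,
            trainable = rep_len(trainable, 3L))
}

#' @rdname gates
#' @export
gate_cnot <- function(control, target) {
  .new_gate("CNOT", target, control = control)
}

#' @export
print.qcl_gate <- function(x, ...) {
  ang <- if (length(x$angles)) {
    paste0("(", paste(sprintf("%.4g", x$angles), collapse = ", "), ")")
  } else ""
  wires <- if (x$kind == "CNOT") {
    sprintf("%d -> %d", x$control, x$target)
  } else sprintf("q%d", x$target)
  cat(sprintf("%s%s on %s\n", x$kind, ang, wires))
  invisible(x)
}

validate_gate <- function(gate, n_qubits) {
  n_angles <- switch(gate$kind, RY = 1L, RZ = 1L, U3 = 3L, CNOT = 0L,
                     stop("unknown gate kind: ", gate$kind, call. = FALSE))
  if (length(gate$angles) != n_angles) {
    stop(sprintf("%s gate requires exactly %d angle(s)", gate$kind, n_angles),
         call. = FALSE)
  }
  if (n_angles > 0 && any(!is.finite(gate$angles))) {
    stop("gate angles must be finite", call. = FALSE)
  }
  .check_qubit(gate$target, n_qubits, "target")
  if (gate$kind == "CNOT") {
    .check_qubit(gate$control, n_qubits, "control")
    if (gate$control == gate$target) {
      stop("CNOT control and target must differ", call. = FALSE)
    }
  }
  invisible(gate)
}
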