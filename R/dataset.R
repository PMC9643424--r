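# QSPR dataset container and CSV I/O.

#' Construct a QSPR dataset
#'
#' Bundles a numeric descriptor matrix with a numeric target property
#' (e.g. glass transition temperature) and provenance metadata.
#'
#' @param X Numeric matrix or data frame, `n` samples x `d` descriptors,
#'   no missing values, `n >= 2`, `d >= 1`.
#' @param y Numeric target vector of length `n`, no missing values.
#' @param names Optional descriptor labels (defaults to `colnames(X)`).
#' @param meta Optional list of provenance fields (source, seed, generator
#'   spec, ...).
#' @return A `qspr_dataset` object.
#' @export
qspr_dataset <- function(X, y, names = NULL, meta = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(X) < 1L) stop("need at least 1 descriptor", call. = FALSE)
  if (length(y) != nrow(X)) stop("X and y sizes disagree", call. = FALSE)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("missing or non-finite values are not allowed", call. = FALSE)
  }
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- sprintf("desc%02d", seq_len(ncol(X)))
  }
  colnames(X) <- names
  structure(list(X = X, y = y, names = names, meta = meta),
            class = "qspr_dataset")
}

#' @export
print.qspr_dataset <- function(x, ...) {
  cat(sprintf("<qspr_dataset: %d samples x %d descriptors>\n",
              nrow(x$X), ncol(x$X)))
  if (!is.null(x$meta$source)) cat("  source:", x$meta$source, "\n")
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' @export
as.data.frame.qspr_dataset <- function(x, ..., target = "property") {
  df <- as.data.frame(x$X)
  df[[target]] <- x$y
  df
}

#' Read / write QSPR datasets as CSV
#'
#' `write_qspr_csv()` writes one sample per line with a header row (the
#' target in a named column) and, when the dataset carries generator
#' metadata, a JSON sidecar `<path>.json` with the generating spec and seed.
#' `read_qspr_csv()` reads the same layout back.
#'
#' @param dataset A [qspr_dataset()].
#' @param path CSV file path.
#' @param target Name of the target column (default `"property"`).
#' @return `write_qspr_csv()` returns `path` invisibly; `read_qspr_csv()` a
#'   `qspr_dataset`.
#' @export
write_qspr_csv <- function(dataset, path, target = "property") {
  stopifnot(inherits(dataset, "qspr_dataset"))
  utils::write.csv(as.data.frame(dataset, target = target), path,
                   row.names = FALSE)
  if (length(dataset$meta)) {
    jsonlite::write_json(dataset$meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_qspr_csv
#' @export
read_qspr_csv <- function(path, target = "property") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!target %in% names(df)) {
    stop(sprintf("target column '%s' not found in %s", target, path),
         call. = FALSE)
  }
  y <- df[[target]]
  X <- as.matrix(df[setdiff(names(df), target)])
  meta <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- c(meta, jsonlite::fromJSON(sidecar, simplifyVector = TRUE))
  }
  qspr_dataset(X, y, meta = meta)
}
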