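#' Class codebook for a categorical field
#'
#' A codebook binds human-readable class labels to the contiguous integer
#' codes `0..n-1` used in rasters and sample tables, optionally together
#' with marginal class proportions. Primary and auxiliary (legacy) fields
#' carry independent codebooks, which need not have the same length.
#'
#' @param labels character vector of unique class names, in code order.
#' @param proportions optional numeric vector of marginal class
#'   proportions; must be non-negative and sum to 1 (tolerance 1e-9).
#' @return An object of class `"codebook"`: a list with `labels`, `codes`
#'   (integers `0..n-1`) and `proportions` (possibly `NULL`).
#' @examples
#' cb <- codebook(c("S1", "S2", "S3"), proportions = c(0.2, 0.5, 0.3))
#' cb$codes
#' @export
codebook <- function(labels, proportions = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("codebook labels must be unique")
  }
  if (length(labels) < 1L) {
    stop("codebook needs at least one class")
  }
  if (!is.null(proportions)) {
    proportions <- as.numeric(proportions)
    if (length(proportions) != length(labels)) {
      stop("proportions must have one entry per label")
    }
    if (any(proportions < 0)) {
      stop("proportions must be non-negative")
    }
    if (abs(sum(proportions) - 1) > 1e-9) {
      stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
    }
  }
  structure(
    list(
      labels = labels,
      codes = seq_along(labels) - 1L,
      proportions = proportions
    ),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat("codebook with", length(x$labels), "classes\n")
  df <- data.frame(code = x$codes, label = x$labels)
  if (!is.null(x$proportions)) df$proportion <- x$proportions
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
length.codebook <- function(x) length(x$labels)

n_classes <- function(cb) length(cb$labels)

validate_codes <- function(codes, cb, what = "class codes") {
  codes <- codes[!is.na(codes)]
  if (length(codes) && (min(codes) < 0L || max(codes) >= n_classes(cb))) {
    bad <- unique(codes[codes < 0L | codes >= n_classes(cb)])
    stop(what, " outside codebook range 0..", n_classes(cb) - 1L,
         ": ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read or write a codebook as JSON
#'
#' The JSON layout maps label to code, with an optional `proportions`
#' array, e.g. `{"labels": {"S1": 0, "S2": 1}, "proportions": [0.4, 0.6]}`.
#'
#' @param path file path.
#' @param cb a [codebook()].
#' @return `read_codebook_json` returns a `"codebook"`;
#'   `write_codebook_json` returns `path` invisibly.
#' @export
read_codebook_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  codes <- unlist(obj$labels)
  labels <- names(codes)[order(codes)]
  if (!identical(sort(as.integer(codes)), seq_along(codes) - 1L)) {
    stop("codebook JSON codes must be contiguous integers from 0")
  }
  codebook(labels, proportions = obj$proportions)
}

#' @rdname read_codebook_json
#' @export
write_codebook_json <- function(cb, path) {
  obj <- list(labels = stats::setNames(as.list(cb$codes), cb$labels))
  if (!is.null(cb$proportions)) obj$proportions <- cb$proportions
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
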