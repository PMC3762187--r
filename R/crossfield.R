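#' Estimate the cross-field transition probability matrix (CTPM)
#'
#' Counts point-to-point class-pair frequencies `f_ik` from primary
#' sample classes to the colocated auxiliary (legacy map) classes and
#' normalizes each row: `b_ik = f_ik / sum_j f_ij`. Rows and columns may
#' differ in number and meaning since the two fields carry independent
#' codebooks. Primary classes with no colocated pairs get a uniform row
#' `1 / n_aux` and are flagged, so simulation can proceed for classes
#' absent from the conditioning data.
#'
#' @param pairs a [colocate()] result (non-empty).
#' @param n_primary,n_aux class counts of the primary and auxiliary
#'   codebooks; inferred from the observed codes when missing.
#' @return An object of class `"ctpm"`: list with `b` (row-stochastic
#'   `n_primary x n_aux` matrix), `counts` (integer frequencies `f_ik`)
#'   and `uniform_rows` (codes of flagged zero-count rows).
#' @export
estimate_ctpm <- function(pairs, n_primary = NULL, n_aux = NULL) {
  if (!nrow(pairs)) stop("colocated pairs must be non-empty")
  if (is.null(n_primary)) n_primary <- max(pairs$primary) + 1L
  if (is.null(n_aux)) n_aux <- max(pairs$aux) + 1L
  if (max(pairs$primary) >= n_primary || max(pairs$aux) >= n_aux ||
      min(pairs$primary) < 0L || min(pairs$aux) < 0L) {
    stop("pair codes outside declared codebook sizes")
  }
  counts <- matrix(0L, nrow = n_primary, ncol = n_aux)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$primary[k] + 1L
    j <- pairs$aux[k] + 1L
    counts[i, j] <- counts[i, j] + 1L
  }
  tot <- rowSums(counts)
  b <- matrix(0, nrow = n_primary, ncol = n_aux)
  uniform_rows <- integer(0)
  for (i in seq_len(n_primary)) {
    if (tot[i] > 0) {
      b[i, ] <- counts[i, ] / tot[i]
    } else {
      b[i, ] <- 1 / n_aux
      uniform_rows <- c(uniform_rows, i - 1L)
    }
  }
  if (length(uniform_rows)) {
    message("CTPM row(s) ", paste(uniform_rows, collapse = ", "),
            " had no pairs; filled uniform")
  }
  structure(list(b = b, counts = counts, uniform_rows = uniform_rows),
            class = "ctpm")
}

#' @export
print.ctpm <- function(x, ...) {
  cat("ctpm:", nrow(x$b), "primary x", ncol(x$b), "auxiliary classes, ",
      sum(x$counts), "pairs\n")
  print(round(x$b, 4))
  invisible(x)
}

#' Flag uninformative auxiliary classes
#'
#' An auxiliary class carries no information about the primary variable
#' when its CTPM column is constant across primary classes and equal to
#' the auxiliary class proportion; its likelihood term then cancels from
#' the numerator and denominator of the cosimulation model.
#'
#' @param ctpm a `"ctpm"`.
#' @param aux_proportions marginal proportions of the auxiliary classes.
#' @param tol absolute tolerance on the probability comparison.
#' @return Logical vector, one flag per auxiliary class.
#' @export
is_uninformative <- function(ctpm, aux_proportions, tol = 1e-6) {
  if (length(aux_proportions) != ncol(ctpm$b)) {
    stop("aux_proportions must have one entry per auxiliary class")
  }
  vapply(seq_len(ncol(ctpm$b)), function(k) {
    all(abs(ctpm$b[, k] - aux_proportions[k]) <= tol)
  }, logical(1))
}

#' CTPM CSV export / import
#'
#' Writes the probability matrix with labeled rows (primary classes) and
#' columns (auxiliary classes).
#'
#' @param ctpm a `"ctpm"`.
#' @param path file path.
#' @param row_labels,col_labels optional class labels.
#' @return `read_ctpm_csv` returns a `"ctpm"` (with `counts` unknown,
#'   set to `NA`).
#' @export
write_ctpm_csv <- function(ctpm, path, row_labels = NULL, col_labels = NULL) {
  b <- ctpm$b
  rownames(b) <- row_labels %||% paste0("P", seq_len(nrow(b)) - 1L)
  colnames(b) <- col_labels %||% paste0("A", seq_len(ncol(b)) - 1L)
  utils::write.csv(b, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_ctpm_csv
#' @export
read_ctpm_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  b <- as.matrix(df)
  structure(list(b = unname(b) * 1.0,
                 counts = matrix(NA_integer_, nrow(b), ncol(b)),
                 uniform_rows = integer(0),
                 row_labels = rownames(b), col_labels = colnames(b)),
            class = "ctpm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
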