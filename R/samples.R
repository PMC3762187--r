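#' Sparse point samples of a categorical variable
#'
#' @param x,y numeric map coordinates.
#' @param class_code integer class codes, valid in `codebook` when given.
#' @param codebook optional [codebook()] for the primary variable.
#' @return A data.frame of class `"point_samples"` with columns `x`, `y`,
#'   `class_code`.
#' @export
point_samples <- function(x, y, class_code, codebook = NULL) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   class_code = as.integer(class_code))
  if (anyNA(df)) stop("point samples must not contain NA")
  if (anyDuplicated(df[, c("x", "y")])) {
    stop("duplicate sample coordinates are not allowed")
  }
  if (!is.null(codebook)) validate_codes(df$class_code, codebook, "sample codes")
  structure(df, class = c("point_samples", "data.frame"), codebook = codebook)
}

#' Read / write samples as CSV with header `x,y,class`
#'
#' @param path file path.
#' @param codebook optional [codebook()] for validation.
#' @return `read_samples` returns a [point_samples()] object.
#' @export
read_samples <- function(path, codebook = NULL) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "class")
  if (!all(need %in% names(df))) {
    stop("samples CSV must have header x,y,class; got: ",
         paste(names(df), collapse = ","))
  }
  point_samples(df$x, df$y, df$class, codebook = codebook)
}

#' @rdname read_samples
#' @param samples a [point_samples()] object.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(
    data.frame(x = samples$x, y = samples$y, class = samples$class_code),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Colocate point samples with an auxiliary raster
#'
#' Maps each sample to the class code of the raster cell containing it
#' (half-open cell membership, see [cell_index()]). Samples falling on
#' nodata cells are dropped with a message reporting the count; samples
#' outside the raster extent are an error.
#'
#' @param samples a [point_samples()] of the primary variable.
#' @param raster a [categorical_raster()] auxiliary (e.g. legacy) map.
#' @return An object of class `"colocated_pairs"`: a data.frame with
#'   columns `primary` and `aux` (class codes), and attribute `n_dropped`.
#' @export
colocate <- function(samples, raster) {
  idx <- cell_index(raster, samples$x, samples$y)
  outside <- is.na(idx$row) | is.na(idx$col)
  if (any(outside)) {
    bad <- utils::head(which(outside), 5L)
    stop("samples outside raster extent at (",
         paste(sprintf("%g,%g", samples$x[bad], samples$y[bad]),
               collapse = "; "), ")",
         if (sum(outside) > 5L) paste0(" and ", sum(outside) - 5L, " more"))
  }
  aux <- raster$values[cbind(idx$row, idx$col)]
  keep <- !is.na(aux)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " sample(s) on nodata cells dropped during colocation")
  }
  if (!any(keep)) stop("no samples remain after dropping nodata colocations")
  structure(
    data.frame(primary = samples$class_code[keep], aux = as.integer(aux[keep])),
    class = c("colocated_pairs", "data.frame"),
    n_dropped = n_dropped
  )
}
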