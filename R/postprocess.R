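#' Per-class occurrence probabilities across realizations
#'
#' Stacks realizations into an occurrence cube: at each cell, the
#' relative frequency of every class across the realizations. Cells that
#' are nodata in all realizations stay `NA`.
#'
#' @param realizations non-empty list of [categorical_raster()]s with
#'   identical geometry and codebooks.
#' @return An object of class `"occurrence_cube"`: list with `freq`
#'   (array `n_classes x n_rows x n_cols`, cell sums equal 1),
#'   `n_realizations`, and the shared `geometry`/`codebook`.
#' @export
occurrence <- function(realizations) {
  if (!length(realizations)) stop("need at least one realization")
  ref <- realizations[[1]]
  for (r in realizations[-1]) {
    if (r$n_rows != ref$n_rows || r$n_cols != ref$n_cols ||
        r$cell_size != ref$cell_size || !all(r$origin == ref$origin)) {
      stop("realization geometry mismatch")
    }
    if (!identical(r$codebook$labels, ref$codebook$labels)) {
      stop("realization codebook mismatch")
    }
  }
  n <- n_classes(ref$codebook)
  counts <- array(0L, dim = c(n, ref$n_rows, ref$n_cols))
  informed <- matrix(0L, ref$n_rows, ref$n_cols)
  for (r in realizations) {
    v <- r$values
    ok <- !is.na(v)
    informed <- informed + ok
    for (c in seq_len(n) - 1L) {
      counts[c + 1L, , ] <- counts[c + 1L, , ] + (!is.na(v) & v == c)
    }
  }
  freq <- array(NA_real_, dim = dim(counts))
  for (c in seq_len(n)) {
    freq[c, , ] <- ifelse(informed > 0L, counts[c, , ] / informed, NA_real_)
  }
  structure(
    list(freq = freq, n_realizations = length(realizations),
         n_rows = ref$n_rows, n_cols = ref$n_cols,
         cell_size = ref$cell_size, origin = ref$origin,
         codebook = ref$codebook, nodata = ref$nodata),
    class = "occurrence_cube"
  )
}

#' Optimal prediction and maximum occurrence probability maps
#'
#' Per cell, the class of maximal occurrence probability and that
#' probability. Ties are broken by the lowest class code; the number of
#' tied cells is reported.
#'
#' @param cube an [occurrence()] result.
#' @return List with `prediction` (a [categorical_raster()]), `max_prob`
#'   (numeric matrix) and `n_ties` (count of cells whose maximum was not
#'   unique).
#' @export
optimal_prediction <- function(cube) {
  n <- dim(cube$freq)[1]
  pred <- matrix(NA_integer_, cube$n_rows, cube$n_cols)
  maxp <- matrix(NA_real_, cube$n_rows, cube$n_cols)
  n_ties <- 0L
  flat <- matrix(cube$freq, nrow = n)  # n x (n_rows*n_cols)
  ok <- !is.na(flat[1, ])
  if (any(ok)) {
    m <- flat[, ok, drop = FALSE]
    best <- apply(m, 2L, which.max)  # first maximum = lowest class code
    bp <- m[cbind(best, seq_along(best))]
    tie <- colSums(abs(m - rep(bp, each = n)) < 1e-12) > 1L
    n_ties <- sum(tie)
    pred[ok] <- as.integer(best - 1L)
    maxp[ok] <- bp
  }
  if (n_ties > 0L) {
    message(n_ties, " cell(s) had tied maximum occurrence probabilities; ",
            "lowest class code kept")
  }
  list(
    prediction = categorical_raster(pred, cell_size = cube$cell_size,
                                    origin = cube$origin,
                                    codebook = cube$codebook,
                                    nodata = cube$nodata),
    max_prob = maxp,
    n_ties = n_ties
  )
}

#' Percentage of correctly classified cells (PCC)
#'
#' `100 * matching / compared` over all cells that are non-nodata in both
#' rasters, excluding cells that contain an excluded sample (conditioning
#' data must not inflate the score).
#'
#' @param prediction,reference [categorical_raster()]s with identical
#'   geometry.
#' @param exclude optional [point_samples()]; cells containing any of
#'   these points are left out of the comparison.
#' @return Percentage in `[0, 100]`.
#' @export
pcc <- function(prediction, reference, exclude = NULL) {
  if (prediction$n_rows != reference$n_rows ||
      prediction$n_cols != reference$n_cols) {
    stop("prediction and reference geometry mismatch")
  }
  keep <- !is.na(prediction$values) & !is.na(reference$values)
  if (!is.null(exclude) && nrow(exclude)) {
    idx <- cell_index(prediction, exclude$x, exclude$y)
    inside <- !is.na(idx$row)
    keep[cbind(idx$row[inside], idx$col[inside])] <- FALSE
  }
  n_cmp <- sum(keep)
  if (n_cmp == 0L) stop("no cells left to compare")
  100 * sum(prediction$values[keep] == reference$values[keep]) / n_cmp
}

#' Write post-processing artifacts to a directory
#'
#' Writes per-class occurrence probability grids (`prob_<class>.asc`,
#' float), the optimal prediction (`optimal_prediction.asc`, integer),
#' the maximum-probability grid (`max_prob.asc`, float) and a JSON
#' summary (n_realizations, tie count, and PCC when a reference is
#' given).
#'
#' @param cube an [occurrence()] result.
#' @param out_dir output directory (created if needed).
#' @param reference optional reference [categorical_raster()] for PCC.
#' @param exclude optional samples excluded from the PCC.
#' @return The summary list, invisibly.
#' @export
write_postprocess <- function(cube, out_dir, reference = NULL,
                              exclude = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- optimal_prediction(cube)
  for (c in seq_len(dim(cube$freq)[1])) {
    write_float_grid(cube$freq[c, , ], cube,
                     file.path(out_dir, sprintf("prob_%s.asc",
                                                cube$codebook$labels[c])))
  }
  write_raster(opt$prediction, file.path(out_dir, "optimal_prediction.asc"))
  write_float_grid(opt$max_prob, cube, file.path(out_dir, "max_prob.asc"))
  summary <- list(n_realizations = cube$n_realizations, n_ties = opt$n_ties)
  if (!is.null(reference)) {
    summary$pcc_optimal <- pcc(opt$prediction, reference, exclude = exclude)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

write_float_grid <- function(values, geom, path) {
  v <- values
  v[is.na(v)] <- geom$nodata
  header <- c(
    paste("ncols", geom$n_cols),
    paste("nrows", geom$n_rows),
    paste("xllcorner", format(geom$origin[1], scientific = FALSE)),
    paste("yllcorner", format(geom$origin[2], scientific = FALSE)),
    paste("cellsize", format(geom$cell_size, scientific = FALSE)),
    paste("NODATA_value", geom$nodata)
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}
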