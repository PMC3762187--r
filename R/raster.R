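#' Categorical raster grid
#'
#' A 2-D grid of integer class codes with map geometry. Row 1 is the top
#' row of the map (Esri ASCII grid reading order); map coordinates are
#' continuous with cell `(r, c)` covering the half-open box
#' `[x0 + (c-1) s, x0 + c s) x [y0 + (n_rows - r) s, y0 + (n_rows - r + 1) s)`,
#' where `s` is the cell size and `(x0, y0)` the lower-left corner of the
#' grid. Nodata cells are stored as `NA` internally and written out with
#' the configurable nodata sentinel (default -9999).
#'
#' @param values integer matrix of class codes (`NA` = nodata).
#' @param cell_size positive cell edge length in map units.
#' @param origin numeric `(x, y)` of the lower-left grid corner.
#' @param codebook a [codebook()]; inferred from the distinct values
#'   present when `NULL`.
#' @param nodata integer sentinel used on file output.
#' @return An object of class `"categorical_raster"`.
#' @export
categorical_raster <- function(values, cell_size = 1, origin = c(0, 0),
                               codebook = NULL, nodata = -9999L) {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (is.null(codebook)) {
    mx <- suppressWarnings(max(values, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 0L
    codebook <- codebook(paste0("C", 0:max(mx, 0L)))
  }
  validate_codes(as.vector(values), codebook, "raster values")
  structure(
    list(
      values = values,
      n_rows = nrow(values),
      n_cols = ncol(values),
      cell_size = as.numeric(cell_size),
      origin = as.numeric(origin[1:2]),
      codebook = codebook,
      nodata = as.integer(nodata)
    ),
    class = "categorical_raster"
  )
}

#' @export
print.categorical_raster <- function(x, ...) {
  cat("categorical_raster:", x$n_rows, "x", x$n_cols,
      "cells of size", x$cell_size, "\n")
  cat("origin (lower-left): (", x$origin[1], ",", x$origin[2], ")  classes:",
      length(x$codebook), " nodata cells:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Map coordinates of cell centers
#'
#' @param raster a [categorical_raster()].
#' @param rows,cols 1-based row/column indices (row 1 = top).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centers <- function(raster, rows, cols) {
  s <- raster$cell_size
  data.frame(
    x = raster$origin[1] + (cols - 0.5) * s,
    y = raster$origin[2] + (raster$n_rows - rows + 0.5) * s
  )
}

#' Cell indices containing map coordinates
#'
#' Membership follows the half-open cell boxes: a point on a shared
#' interior edge belongs to the cell whose closed (lower/left in map
#' coordinates) boundary it lies on.
#'
#' @inheritParams cell_centers
#' @param x,y numeric map coordinates.
#' @return data.frame with 1-based `row`, `col`; `NA` outside the extent.
#' @export
cell_index <- function(raster, x, y) {
  s <- raster$cell_size
  cx <- floor((x - raster$origin[1]) / s)
  cy <- floor((y - raster$origin[2]) / s)
  col <- ifelse(cx >= 0 & cx < raster$n_cols, cx + 1L, NA_integer_)
  row <- ifelse(cy >= 0 & cy < raster$n_rows, raster$n_rows - cy, NA_integer_)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Class proportions of a raster
#'
#' Relative frequency of each codebook class over non-nodata cells.
#'
#' @param raster a [categorical_raster()].
#' @return numeric vector of length `n_classes`, summing to 1.
#' @export
raster_proportions <- function(raster) {
  v <- raster$values[!is.na(raster$values)]
  if (!length(v)) stop("raster has no informed cells")
  tab <- tabulate(v + 1L, nbins = n_classes(raster$codebook))
  tab / sum(tab)
}

# ---- file formats ------------------------------------------------------

#' Read a categorical raster from a text file
#'
#' Supports the Esri ASCII grid format (6-line header `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) and a headerless
#' CSV matrix fallback (rows in map top-to-bottom order, nodata written as
#' the sentinel value).
#'
#' @param path file path.
#' @param format `"ascii_grid"` or `"csv"`; guessed from the file
#'   extension (`.asc` vs anything else) when missing.
#' @param codebook optional [codebook()]; inferred from distinct values
#'   otherwise.
#' @param cell_size,origin,nodata geometry for the CSV dialect, which
#'   carries no header (ignored for ASCII grids).
#' @return A [categorical_raster()]. Round-trips bit-exactly with
#'   [write_raster()].
#' @export
read_raster <- function(path, format = c("ascii_grid", "csv"),
                        codebook = NULL, cell_size = 1, origin = c(0, 0),
                        nodata = -9999L) {
  if (missing(format)) {
    format <- if (grepl("\\.asc$", path, ignore.case = TRUE)) "ascii_grid" else "csv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "ascii_grid") {
    read_ascii_grid(path, codebook = codebook)
  } else {
    read_csv_matrix(path, codebook = codebook, cell_size = cell_size,
                    origin = origin, nodata = nodata)
  }
}

#' @rdname read_raster
#' @param raster a [categorical_raster()] to write.
#' @export
write_raster <- function(raster, path, format = c("ascii_grid", "csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.asc$", path, ignore.case = TRUE)) "ascii_grid" else "csv"
  }
  format <- match.arg(format)
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  lines <- apply(v, 1L, paste, collapse = if (format == "csv") "," else " ")
  if (format == "ascii_grid") {
    header <- c(
      paste("ncols", raster$n_cols),
      paste("nrows", raster$n_rows),
      paste("xllcorner", format(raster$origin[1], scientific = FALSE)),
      paste("yllcorner", format(raster$origin[2], scientific = FALSE)),
      paste("cellsize", format(raster$cell_size, scientific = FALSE)),
      paste("NODATA_value", raster$nodata)
    )
    lines <- c(header, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

read_ascii_grid <- function(path, codebook = NULL) {
  lines <- readLines(path, warn = FALSE)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  hdr <- list()
  for (i in seq_len(6L)) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L || !tolower(parts[1]) %in% keys) {
      stop("malformed ASCII grid header at line ", i, " of ", path)
    }
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("non-numeric header value at line ", i, " of ", path)
    hdr[[tolower(parts[1])]] <- val
  }
  for (k in keys) if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows) {
    stop("expected ", n_rows, " data rows, found ", length(body), " in ", path)
  }
  vals <- parse_matrix_rows(body, n_cols, split = "[[:space:]]+",
                            path = path, offset = 6L)
  vals[vals == hdr$nodata_value] <- NA_integer_
  categorical_raster(vals, cell_size = hdr$cellsize,
                     origin = c(hdr$xllcorner, hdr$yllcorner),
                     codebook = codebook, nodata = as.integer(hdr$nodata_value))
}

read_csv_matrix <- function(path, codebook = NULL, cell_size = 1,
                            origin = c(0, 0), nodata = -9999L) {
  body <- readLines(path, warn = FALSE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty CSV matrix: ", path)
  n_cols <- length(strsplit(body[1], ",", fixed = TRUE)[[1]])
  vals <- parse_matrix_rows(body, n_cols, split = ",", path = path, offset = 0L)
  vals[vals == nodata] <- NA_integer_
  categorical_raster(vals, cell_size = cell_size, origin = origin,
                     codebook = codebook, nodata = nodata)
}

parse_matrix_rows <- function(body, n_cols, split, path, offset) {
  vals <- matrix(NA_integer_, nrow = length(body), ncol = n_cols)
  for (i in seq_along(body)) {
    cells <- strsplit(trimws(body[i]), split)[[1]]
    if (length(cells) != n_cols) {
      stop("ragged row at line ", i + offset, " of ", path, ": expected ",
           n_cols, " values, found ", length(cells))
    }
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num) || any(num != floor(num))) {
      stop("non-integer cell at line ", i + offset, " of ", path)
    }
    vals[i, ] <- as.integer(num)
  }
  vals
}
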