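#' Construct a neighborhood by hand
#'
#' A neighborhood holds up to four nearest informed locations, one per
#' quadrant sector, around a cell being simulated, plus the index of the
#' designated first neighbor — the location the spatial Markov chain is
#' taken to arrive from, whose term enters the model in the transposed
#' direction.
#'
#' @param class_code integer class codes of the neighbors.
#' @param lag positive lag distances to the neighbors (same units as the
#'   transiogram model).
#' @param quadrant optional sector indices 0 = E, 1 = N, 2 = W, 3 = S.
#' @param designated_first 1-based index of the designated first
#'   neighbor; defaults to the nearest entry.
#' @return An object of class `"neighborhood"`.
#' @export
neighborhood <- function(class_code, lag, quadrant = NULL,
                         designated_first = NULL) {
  class_code <- as.integer(class_code)
  lag <- as.numeric(lag)
  if (length(class_code) != length(lag)) stop("class_code and lag lengths differ")
  if (length(class_code) > 4L) stop("at most one neighbor per quadrant (4)")
  if (length(lag) && any(lag <= 0)) stop("lag distances must be > 0")
  if (!is.null(quadrant) && anyDuplicated(quadrant)) {
    stop("at most one neighbor per quadrant")
  }
  if (is.null(designated_first)) {
    designated_first <- if (length(lag)) which.min(lag) else NA_integer_
  }
  if (length(class_code) &&
      (designated_first < 1L || designated_first > length(class_code))) {
    stop("designated_first out of range")
  }
  structure(
    list(class_code = class_code, lag = lag, quadrant = quadrant,
         designated_first = as.integer(designated_first)),
    class = "neighborhood"
  )
}

#' Quadrant nearest-neighbor search
#'
#' Finds, in each of the four quadrant sectors around a cell (boundaries
#' at 45, 135, 225 and 315 degrees, so the cardinal directions are sector
#' centers), the informed location with the smallest Euclidean distance
#' within the search radius. A location exactly on a sector boundary is
#' assigned to the counter-clockwise sector; distance ties are broken by
#' the smallest `(row, col)` pair. The designated first neighbor is the
#' globally nearest entry.
#'
#' @param cell integer `(row, col)`, 1-based, row 1 = top.
#' @param informed integer matrix of the same shape as the grid with
#'   class codes at informed cells (samples plus previously simulated)
#'   and `NA` elsewhere.
#' @param radius search radius in cell units.
#' @param cell_size multiplier converting cell units to the lag units of
#'   the transiogram model.
#' @return A [neighborhood()] (possibly empty) with extra fields `row`,
#'   `col` (1-based).
#' @export
find_neighbors <- function(cell, informed, radius, cell_size = 1) {
  if (radius <= 0) stop("radius must be > 0")
  g <- informed
  g[is.na(g)] <- -1L
  storage.mode(g) <- "integer"
  res <- find_neighbors_cpp(g, cell[1] - 1L, cell[2] - 1L, radius)
  nb <- neighborhood(
    class_code = unname(res[, "class"]),
    lag = cell_size * sqrt(unname(res[, "d2"])),
    quadrant = if (nrow(res)) unname(res[, "quadrant"]) else NULL,
    designated_first = if (nrow(res)) which(res[, "first"] == 1L) else NULL
  )
  nb$row <- unname(res[, "row"]) + 1L
  nb$col <- unname(res[, "col"]) + 1L
  nb
}

#' Local conditional distribution of the simplified MCRF model
#'
#' Computes `p(i0) proportional to p_{i1,i0}(h10) prod_{g>=2} p_{i0,ig}(h0g)`
#' over the candidate classes, normalized — the simplified Markov chain
#' random field solution under conditional independence of the quadrant
#' neighbors. With a single neighbor the result is the transiogram row
#' from the designated first neighbor; with an empty neighborhood the
#' spatial chain is assumed to arrive from outside the search range and
#' the marginals are returned.
#'
#' @param neigh a [neighborhood()].
#' @param model a `"transiogram_model"` covering all classes present.
#' @return Numeric probability vector over the primary classes (sums to
#'   1), with attribute `fallback` (0 = none; see Details of
#'   [sequential_simulate()] for the fallback chain).
#' @export
local_mcrf <- function(neigh, model) {
  local_comcrf(neigh, integer(0), model, list())
}

#' Local conditional distribution of the colocated Co-MCRF model
#'
#' As [local_mcrf()], with the numerator of each candidate class `i0`
#' additionally multiplied by the cross-field likelihood
#' `prod_l b_{i0, r0^(l)}` of the colocated auxiliary classes. An
#' auxiliary whose CTPM column is constant across primary classes cancels
#' and leaves the MCSS distribution unchanged.
#'
#' @inheritParams local_mcrf
#' @param aux_codes integer vector, one colocated auxiliary class code
#'   per CTPM (`NA` skips that auxiliary, e.g. over nodata).
#' @param ctpms list of `"ctpm"` objects (or bare matrices), one per
#'   auxiliary variable.
#' @return Numeric probability vector with attribute `fallback`.
#' @export
local_comcrf <- function(neigh, aux_codes, model, ctpms) {
  if (length(aux_codes) != length(ctpms)) {
    stop("one auxiliary code per CTPM required")
  }
  mats <- lapply(ctpms, function(b) if (inherits(b, "ctpm")) b$b else as.matrix(b))
  for (b in mats) {
    if (nrow(b) != model$n_classes) {
      stop("CTPM rows must match the number of primary classes")
    }
  }
  if (length(neigh$class_code) &&
      (min(neigh$class_code) < 0L ||
       max(neigh$class_code) >= model$n_classes)) {
    stop("neighbor codes outside the model's class range")
  }
  ac <- as.integer(aux_codes)
  ac[is.na(ac)] <- -1L
  res <- local_dist_cpp(neigh$class_code, neigh$lag,
                        if (length(neigh$class_code)) neigh$designated_first - 1L else -1L,
                        model$anchors, as.numeric(model$matrices),
                        model$marginals, mats, ac)
  structure(res$p, fallback = res$fallback)
}

#' Random-path sequential (co)simulation of a categorical field
#'
#' Generates one realization of the primary categorical field on the
#' template grid: sample cells are fixed to their classes, the remaining
#' cells are visited in a seeded uniformly random permutation, and each
#' visited cell draws its class by inverse CDF (codebook order, one
#' uniform draw) from the local conditional distribution given the
#' quadrant nearest neighbors among previously informed cells
#' ([local_comcrf()] when auxiliary data are present — Co-MCSS — and
#' [local_mcrf()] otherwise — MCSS). Drawn cells immediately join the
#' informed set.
#'
#' @details
#' A single RNG stream is used per realization: the path permutation is
#' drawn first, then one uniform per visited cell. If every candidate
#' class has zero numerator at a cell, the distribution falls back, in
#' order, to (1) the CTPM likelihood times the marginals, (2) the
#' marginals, (3) uniform; fallback counts are reported in the result
#' metadata.
#'
#' @param grid a [categorical_raster()] template carrying geometry and
#'   the primary codebook; its cell values are ignored and the output is
#'   fully informed.
#' @param samples [point_samples()] of the primary variable, inside the
#'   grid extent.
#' @param model a `"transiogram_model"` for the primary classes.
#' @param aux `NULL` for MCSS, or auxiliary conditioning for Co-MCSS: a
#'   `list(raster =, ctpm =)` or a list of such pairs. Auxiliary rasters
#'   must share the template geometry.
#' @param radius search radius in map units (the common choice is 30
#'   cells, i.e. `30 * cell_size`).
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   realizations.
#' @return A [categorical_raster()] realization with attribute
#'   `simulation` (seed, radius, method, fallback counts).
#' @export
sequential_simulate <- function(grid, samples, model, aux = NULL,
                                radius = 30 * grid$cell_size, seed = 1L) {
  n <- n_classes(grid$codebook)
  if (model$n_classes != n) {
    stop("transiogram model classes (", model$n_classes,
         ") inconsistent with grid codebook (", n, ")")
  }
  validate_codes(samples$class_code, grid$codebook, "sample codes")
  aux <- normalize_aux(aux, grid, n)

  idx <- cell_index(grid, samples$x, samples$y)
  if (anyNA(idx$row)) stop("samples outside the simulation grid extent")
  init <- grid$values
  init[] <- -1L  # template values are ignored; output is fully informed
  lin <- cbind(idx$row, idx$col)
  prev <- init[lin]
  conflict <- prev >= 0L & prev != samples$class_code
  if (any(conflict)) {
    stop("conflicting sample classes share a grid cell at rows ",
         paste(utils::head(idx$row[conflict], 3L), collapse = ", "))
  }
  init[lin] <- samples$class_code
  storage.mode(init) <- "integer"

  free <- which(init < 0L)
  set.seed(seed)
  path_lin <- free[sample.int(length(free))]
  path <- cbind((path_lin - 1L) %% grid$n_rows,
                (path_lin - 1L) %/% grid$n_rows)
  storage.mode(path) <- "integer"

  res <- mcrf_simulate_cpp(init, path, model$anchors,
                           as.numeric(model$matrices), model$marginals,
                           radius / grid$cell_size, grid$cell_size,
                           aux$grids, aux$ctpms)
  out <- categorical_raster(res$grid, cell_size = grid$cell_size,
                            origin = grid$origin, codebook = grid$codebook,
                            nodata = grid$nodata)
  attr(out, "simulation") <- list(
    seed = seed, radius = radius,
    method = if (length(aux$ctpms)) "comcss" else "mcss",
    n_fallback_ctpm = res$n_fallback_ctpm,
    n_fallback_marginal = res$n_fallback_marginal
  )
  out
}

normalize_aux <- function(aux, grid, n_primary) {
  if (is.null(aux) || !length(aux)) {
    return(list(grids = list(), ctpms = list()))
  }
  if (!is.null(names(aux)) && all(c("raster", "ctpm") %in% names(aux))) {
    aux <- list(aux)
  }
  grids <- list()
  ctpms <- list()
  for (a in aux) {
    r <- a$raster
    b <- if (inherits(a$ctpm, "ctpm")) a$ctpm$b else as.matrix(a$ctpm)
    if (r$n_rows != grid$n_rows || r$n_cols != grid$n_cols ||
        r$cell_size != grid$cell_size || !all(r$origin == grid$origin)) {
      stop("auxiliary raster geometry differs from the simulation grid")
    }
    if (nrow(b) != n_primary) {
      stop("CTPM rows (", nrow(b), ") inconsistent with primary classes (",
           n_primary, ")")
    }
    if (max(r$values, na.rm = TRUE) >= ncol(b)) {
      stop("auxiliary raster codes exceed CTPM columns")
    }
    g <- r$values
    g[is.na(g)] <- -1L
    storage.mode(g) <- "integer"
    grids <- c(grids, list(g))
    ctpms <- c(ctpms, list(b))
  }
  list(grids = grids, ctpms = ctpms)
}

#' Generate multiple realizations
#'
#' Runs [sequential_simulate()] `n_realizations` times; realization `r`
#' uses seed `seed + r`, so runs can be reproduced or extended
#' independently.
#'
#' @inheritParams sequential_simulate
#' @param n_realizations number of realizations (>= 1).
#' @return List of [categorical_raster()] realizations.
#' @export
simulate_realizations <- function(n_realizations, grid, samples, model,
                                  aux = NULL, radius = 30 * grid$cell_size,
                                  seed = 1L) {
  if (n_realizations < 1L) stop("n_realizations must be >= 1")
  lapply(seq_len(n_realizations), function(r) {
    sequential_simulate(grid, samples, model, aux = aux, radius = radius,
                        seed = seed + r)
  })
}
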