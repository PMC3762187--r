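#' Construct an experimental transiogram object
#'
#' Usually produced by [estimate_transiograms()]; the constructor is
#' exported so that transiogram matrices obtained elsewhere (e.g. matrix
#' powers of a known Markov chain) can be wrapped directly.
#'
#' @param lag_centers increasing positive lag distances, one per bin.
#' @param matrices numeric array `(n, n, n_bins)`; each slice holds the
#'   transition probabilities `p_ij(h)` at that lag. Rows with no pairs
#'   may be `NA` (marked empty).
#' @param pair_counts integer matrix `(n_bins, n)` of ordered-pair counts
#'   per lag and head class; defaults to 1 for every non-`NA` row.
#' @return An object of class `"experimental_transiogram"`.
#' @export
experimental_transiogram <- function(lag_centers, matrices,
                                     pair_counts = NULL) {
  lag_centers <- as.numeric(lag_centers)
  if (any(diff(lag_centers) <= 0) || any(lag_centers <= 0)) {
    stop("lag_centers must be positive and strictly increasing")
  }
  if (length(dim(matrices)) != 3L || dim(matrices)[1] != dim(matrices)[2] ||
      dim(matrices)[3] != length(lag_centers)) {
    stop("matrices must be an (n, n, n_bins) array")
  }
  n <- dim(matrices)[1]
  if (is.null(pair_counts)) {
    pair_counts <- t(apply(matrices, 3L, function(m) {
      as.integer(!is.na(m[, 1]))
    }))
    dim(pair_counts) <- c(length(lag_centers), n)
  }
  for (l in seq_along(lag_centers)) {
    for (i in seq_len(n)) {
      row <- matrices[i, , l]
      if (pair_counts[l, i] > 0L) {
        if (anyNA(row) || any(row < 0) || abs(sum(row) - 1) > 1e-9) {
          stop("row ", i, " of lag bin ", l, " is not a probability vector")
        }
      }
    }
  }
  structure(
    list(lag_centers = lag_centers, matrices = matrices,
         pair_counts = pair_counts, n_classes = n),
    class = "experimental_transiogram"
  )
}

#' Estimate experimental auto-/cross-transiograms from point samples
#'
#' Counts class transitions over every ordered sample pair with Euclidean
#' separation `d <= max_lag` (both orderings of each pair, omnidirectional
#' mode) into lag bins `floor(d / bin_width)` and normalizes each bin row
#' by its total. Rows with zero pairs are marked empty (`NA`). The lag
#' attached to each bin is the mean pair distance within it (the nominal
#' bin center `(k + 0.5) bin_width` is used only for bins without pairs),
#' which keeps the estimate anchored at the distances actually observed.
#'
#' @param samples a [point_samples()] object (>= 2 samples).
#' @param bin_width positive lag bin width (map units); a sensible default
#'   is the raster cell size.
#' @param max_lag maximum lag distance considered, `>= bin_width`.
#' @param n_classes number of primary classes; taken from the samples'
#'   codebook, else `max(code) + 1`.
#' @param mode only `"omnidirectional"` is supported (anisotropy is out of
#'   scope).
#' @return An `"experimental_transiogram"` with only non-empty bins kept.
#' @export
estimate_transiograms <- function(samples, bin_width, max_lag,
                                  n_classes = NULL,
                                  mode = "omnidirectional") {
  mode <- match.arg(mode, "omnidirectional")
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (max_lag < bin_width) stop("max_lag must be >= bin_width")
  if (is.null(n_classes)) {
    cb <- attr(samples, "codebook")
    n_classes <- if (!is.null(cb)) n_classes(cb) else max(samples$class_code) + 1L
  }
  ord <- order(samples$x, samples$y)
  res <- transio_count_cpp(samples$x[ord], samples$y[ord],
                           samples$class_code[ord], n_classes,
                           bin_width, max_lag)
  if (sum(res$n_pairs) == 0) {
    stop("no sample pairs within max_lag = ", max_lag,
         "; increase max_lag or check coordinates")
  }
  keep <- which(res$n_pairs > 0)
  n_bins <- length(keep)
  centers <- res$dist_sum[keep] / res$n_pairs[keep]
  mats <- array(NA_real_, dim = c(n_classes, n_classes, n_bins))
  pc <- matrix(0L, nrow = n_bins, ncol = n_classes)
  for (l in seq_len(n_bins)) {
    cnt <- res$counts[, , keep[l], drop = TRUE]
    dim(cnt) <- c(n_classes, n_classes)
    tot <- rowSums(cnt)
    pc[l, ] <- as.integer(tot)
    for (i in seq_len(n_classes)) {
      if (tot[i] > 0) mats[i, , l] <- cnt[i, ] / tot[i]
    }
  }
  experimental_transiogram(centers, mats, pc)
}

#' Build a continuous transiogram model by linear interpolation
#'
#' Anchors the interpolation grid at lag 0 with the identity matrix (a
#' class transitions to itself over zero distance), places the
#' experimental matrices at their bin lags, and fills marked-empty rows
#' with the marginal proportions. Beyond the last anchor the model
#' returns the theoretical sill: every row equals the marginals, the
#' stationary large-lag limit of a transiogram.
#'
#' @param exp an [experimental_transiogram()].
#' @param marginals numeric vector of marginal class proportions (sums to
#'   1); typically the sample class proportions.
#' @return An object of class `"transiogram_model"` with fields `anchors`
#'   (lag 0 first), `matrices`, `marginals` and `max_lag` (the last
#'   anchor, beyond which sills are returned).
#' @export
build_model <- function(exp, marginals) {
  n <- exp$n_classes
  marginals <- as.numeric(marginals)
  if (length(marginals) != n) stop("marginals must have one entry per class")
  if (any(marginals < 0) || abs(sum(marginals) - 1) > 1e-9) {
    stop("marginals must be non-negative and sum to 1")
  }
  mats <- exp$matrices
  n_filled <- 0L
  for (l in seq_along(exp$lag_centers)) {
    for (i in seq_len(n)) {
      if (exp$pair_counts[l, i] == 0L) {
        mats[i, , l] <- marginals
        n_filled <- n_filled + 1L
      }
    }
  }
  if (n_filled > 0L) {
    warning(n_filled, " empty transiogram row(s) filled with marginals")
  }
  anchors <- c(0, exp$lag_centers)
  arr <- array(0, dim = c(n, n, length(anchors)))
  arr[, , 1] <- diag(n)
  arr[, , -1] <- mats
  structure(
    list(anchors = anchors, matrices = arr, marginals = marginals,
         n_classes = n, max_lag = anchors[length(anchors)]),
    class = "transiogram_model"
  )
}

#' Construct a transiogram model directly from known matrices
#'
#' Bypasses estimation, e.g. to build a model from the matrix powers of a
#' known one-dimensional Markov chain or from imported JSON.
#'
#' @inheritParams experimental_transiogram
#' @param marginals marginal class proportions (sums to 1).
#' @return A `"transiogram_model"`.
#' @export
transiogram_model <- function(lag_centers, matrices, marginals) {
  build_model(experimental_transiogram(lag_centers, matrices), marginals)
}

#' Evaluate a transiogram model
#'
#' Piecewise-linear interpolation between the bracketing anchors, with
#' the identity at lag 0 and the marginal sill beyond the last anchor.
#' Each interpolated row is renormalized to sum exactly to 1.
#'
#' @param model a `"transiogram_model"`.
#' @param h non-negative lag distance (scalar).
#' @param i,j optional class codes; when given, the single probability
#'   `p_ij(h)` is returned instead of the full matrix.
#' @return An `n x n` row-stochastic matrix, or a scalar when `i` and `j`
#'   are supplied.
#' @export
transio_eval <- function(model, h, i = NULL, j = NULL) {
  if (h < 0) stop("lag distance must be >= 0")
  n <- model$n_classes
  anchors <- model$anchors
  K <- length(anchors)
  if (h > anchors[K]) {
    M <- matrix(model$marginals, nrow = n, ncol = n, byrow = TRUE)
  } else {
    k <- findInterval(h, anchors, rightmost.closed = FALSE)
    k <- max(1L, min(k, K - 1L))
    w <- (h - anchors[k]) / (anchors[k + 1L] - anchors[k])
    M <- (1 - w) * model$matrices[, , k] + w * model$matrices[, , k + 1L]
  }
  M <- M / rowSums(M)
  if (!is.null(i) && !is.null(j)) {
    if (i < 0 || i >= n || j < 0 || j >= n) {
      stop("class codes must be in 0..", n - 1L)
    }
    return(M[i + 1L, j + 1L])
  }
  M
}

#' @export
print.transiogram_model <- function(x, ...) {
  cat("transiogram_model:", x$n_classes, "classes,",
      length(x$anchors) - 1L, "lag anchors up to", format(x$max_lag), "\n")
  invisible(x)
}

#' Transiogram model JSON export / import
#'
#' The layout is `{lag_centers, matrices, marginals}` with the lag-0
#' identity anchor included in `lag_centers`/`matrices`.
#'
#' @param model a `"transiogram_model"`.
#' @param path file path.
#' @return `read_transiogram_json` returns a `"transiogram_model"`.
#' @export
write_transiogram_json <- function(model, path) {
  obj <- list(
    lag_centers = model$anchors,
    matrices = lapply(seq_along(model$anchors),
                      function(k) model$matrices[, , k]),
    marginals = model$marginals
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transiogram_json
#' @export
read_transiogram_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  anchors <- as.numeric(obj$lag_centers)
  n <- length(obj$marginals)
  arr <- array(0, dim = c(n, n, length(anchors)))
  if (is.array(obj$matrices) && length(dim(obj$matrices)) == 3L) {
    # jsonlite simplifies a list of equal-shape matrices to (K, n, n)
    for (k in seq_along(anchors)) arr[, , k] <- obj$matrices[k, , ]
  } else {
    for (k in seq_along(anchors)) arr[, , k] <- obj$matrices[[k]]
  }
  structure(
    list(anchors = anchors, matrices = arr,
         marginals = as.numeric(obj$marginals), n_classes = n,
         max_lag = anchors[length(anchors)]),
    class = "transiogram_model"
  )
}

#' Diagnostic transiogram plot
#'
#' Draws the `p_ij(h)` curves of a model on the current graphics device,
#' one panel per head class, with the marginal sills as dotted lines.
#'
#' @param x a `"transiogram_model"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.transiogram_model <- function(x, ...) {
  n <- x$n_classes
  hs <- seq(0, x$max_lag * 1.2, length.out = 101L)
  vals <- vapply(hs, function(h) transio_eval(x, h), matrix(0, n, n))
  op <- graphics::par(mfrow = c(1, n), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    graphics::matplot(hs, t(vals[i, , ]), type = "l", lty = 1,
                      xlab = "lag h", ylab = sprintf("p_%d,j(h)", i - 1L),
                      ylim = c(0, 1), ...)
    graphics::abline(h = x$marginals, lty = 3, col = "grey50")
  }
  invisible(x)
}
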