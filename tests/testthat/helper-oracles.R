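# Shared fixtures and independent oracles used across the test files.

# Build a transiogram model directly from matrices at given lags.
make_model <- function(lags, mats, marginals) {
  arr <- array(unlist(mats), dim = c(nrow(mats[[1]]), ncol(mats[[1]]),
                                     length(mats)))
  transiogram_model(lags, arr, marginals)
}

# Random row-stochastic matrix.
rand_stochastic <- function(n) {
  m <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  m / rowSums(m)
}

# Random row-stochastic CTPM (possibly non-square).
rand_stochastic_ctpm <- function(n_primary, n_aux) {
  m <- matrix(stats::runif(n_primary * n_aux, 0.05, 1), n_primary, n_aux)
  m / rowSums(m)
}

# Random transiogram model with L lag anchors.
rand_model <- function(n, L = 3L) {
  lags <- sort(stats::runif(L, 0.5, 10))
  mats <- replicate(L, rand_stochastic(n), simplify = FALSE)
  marg <- stats::runif(n, 0.1, 1)
  make_model(lags, mats, marg / sum(marg))
}

# Independent piecewise-linear transiogram lookup (mirrors the documented
# interpolation contract, written separately from the package code path).
oracle_eval <- function(model, i, j, h) {
  a <- model$anchors
  K <- length(a)
  if (h > a[K]) return(model$marginals[j + 1L])
  k <- max(1L, min(findInterval(h, a), K - 1L))
  w <- (h - a[k]) / (a[k + 1L] - a[k])
  (1 - w) * model$matrices[i + 1L, j + 1L, k] +
    w * model$matrices[i + 1L, j + 1L, k + 1L]
}

# Brute-force local conditional distribution: direct evaluation of the
# product formula over every candidate state.
oracle_local <- function(classes, lags, first, model, aux_codes = integer(0),
                         ctpms = list()) {
  n <- model$n_classes
  num <- numeric(n)
  for (f in seq_len(n) - 1L) {
    if (length(classes) == 0L) {
      v <- model$marginals[f + 1L]
    } else {
      v <- oracle_eval(model, classes[first], f, lags[first])
      for (g in seq_along(classes)) {
        if (g == first) next
        v <- v * oracle_eval(model, f, classes[g], lags[g])
      }
    }
    if (length(ctpms)) {
      for (l in seq_along(ctpms)) {
        b <- if (inherits(ctpms[[l]], "ctpm")) ctpms[[l]]$b else ctpms[[l]]
        v <- v * b[f + 1L, aux_codes[l] + 1L]
      }
    }
    num[f + 1L] <- v
  }
  num / sum(num)
}

# Simulate a 1-D first-order Markov chain of class codes 0..n-1.
sim_markov_chain <- function(P, n, init = 0L) {
  out <- integer(n)
  out[1] <- init
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(n - 1L)
  for (t in 2:n) {
    out[t] <- findInterval(u[t - 1L], cum[out[t - 1L] + 1L, ],
                           left.open = TRUE)
  }
  out
}

# Random raster fixture.
rand_raster <- function(n_rows, n_cols, n_classes, p_nodata = 0,
                        cell_size = 1, origin = c(0, 0)) {
  v <- matrix(sample.int(n_classes, n_rows * n_cols, replace = TRUE) - 1L,
              n_rows, n_cols)
  if (p_nodata > 0) {
    v[stats::runif(length(v)) < p_nodata] <- NA_integer_
  }
  categorical_raster(v, cell_size = cell_size, origin = origin,
                     codebook = codebook(paste0("C", seq_len(n_classes))))
}
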