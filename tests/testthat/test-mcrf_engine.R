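informed_grid <- function(n_rows, n_cols, cells, codes) {
  g <- matrix(NA_integer_, n_rows, n_cols)
  g[cells] <- as.integer(codes)
  g
}

test_that("quadrant search keeps the nearest informed cell per sector", {
  g <- informed_grid(9, 9, rbind(c(3, 5), c(5, 7), c(7, 5), c(5, 3)),
                     0:3)  # N, E, S, W of center (5,5) at distance 2
  nb <- find_neighbors(c(5, 5), g, radius = 5)
  expect_equal(length(nb$class_code), 4L)
  expect_setequal(nb$quadrant, 0:3)
  expect_equal(nb$lag, rep(2, 4))

  # two informed cells in the same (east) sector: only the closer is kept
  g2 <- informed_grid(9, 9, rbind(c(5, 8), c(5, 7)), c(0L, 1L))
  nb2 <- find_neighbors(c(5, 5), g2, radius = 5)
  expect_equal(length(nb2$class_code), 1L)
  expect_equal(nb2$class_code, 1L)
  expect_equal(nb2$lag, 2)

  # beyond the radius nothing is found
  expect_equal(length(find_neighbors(c(5, 5), g2, radius = 1)$class_code), 0L)
})

test_that("sector boundaries assign to the counter-clockwise sector", {
  # enumerate the four diagonal directions (points exactly on the 45-degree
  # boundaries) and check each lands in the documented CCW sector
  center <- c(5, 5)
  cases <- list(
    list(cell = c(4, 6), sector = 1L),  # NE diagonal -> N
    list(cell = c(4, 4), sector = 2L),  # NW diagonal -> W
    list(cell = c(6, 4), sector = 3L),  # SW diagonal -> S
    list(cell = c(6, 6), sector = 0L)   # SE diagonal -> E
  )
  for (cs in cases) {
    g <- informed_grid(9, 9, rbind(cs$cell), 0L)
    nb <- find_neighbors(center, g, radius = 5)
    expect_equal(nb$quadrant, cs$sector)
  }
})

test_that("distance ties break to the smallest (row, col)", {
  # two cells in the east sector at equal distance sqrt(5)
  g <- informed_grid(9, 9, rbind(c(4, 7), c(6, 7)), c(0L, 1L))
  nb <- find_neighbors(c(5, 5), g, radius = 5)
  expect_equal(nb$class_code, 0L)
  expect_equal(nb$row, 4L)
})

test_that("the designated first neighbor is the globally nearest", {
  g <- informed_grid(9, 9, rbind(c(5, 7), c(2, 5)), c(0L, 1L))
  nb <- find_neighbors(c(5, 5), g, radius = 5)
  expect_equal(nb$designated_first, which(nb$lag == 2))
})

test_that("single-neighbor and empty neighborhoods reduce as the model says", {
  M <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  m <- make_model(1, list(M), c(0.5, 0.5))
  # one neighbor: posterior equals the (transposed-direction) prior row
  p <- local_mcrf(neighborhood(0L, 1), m)
  expect_equal(as.numeric(p), c(0.7, 0.3))
  # empty neighborhood: the chain arrives from outside the search range
  m4 <- make_model(1, list(diag(4) * 0.4 + 0.15), rep(0.25, 4))
  expect_equal(as.numeric(local_mcrf(neighborhood(integer(0), numeric(0)), m4)),
               rep(0.25, 4))
})

test_that("two-neighbor posterior matches the hand-evaluated product", {
  # first neighbor A at h10 = 1 with p_AA = 0.7; second neighbor B at
  # h02 = 2 with p_AB(2) = 0.4, p_BB(2) = 0.6:
  # p(A) = 0.7 * 0.4 / 0.46, p(B) = 0.3 * 0.6 / 0.46
  M1 <- matrix(c(0.7, 0.3, 0.35, 0.65), 2, 2, byrow = TRUE)
  M2 <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE)
  m <- make_model(c(1, 2), list(M1, M2), c(0.5, 0.5))
  p <- local_mcrf(neighborhood(c(0L, 1L), c(1, 2), designated_first = 1L), m)
  expect_equal(as.numeric(p), c(0.28, 0.18) / 0.46, tolerance = 1e-12)

  # adding a colocated auxiliary with b_A = 0.9, b_B = 0.2:
  # p(A) = 0.252 / 0.288 = 0.875
  b <- matrix(c(0.9, 0.2), ncol = 1)
  pc <- local_comcrf(neighborhood(c(0L, 1L), c(1, 2), designated_first = 1L),
                     0L, m, list(b))
  expect_equal(as.numeric(pc), c(0.875, 0.125), tolerance = 1e-12)
})

test_that("degenerate and uninformative CTPM columns behave as limits", {
  set.seed(21)
  m <- rand_model(3, L = 2)
  nb <- neighborhood(c(0L, 2L), c(1.2, 3.4), designated_first = 1L)
  # unit-vector column forces the corresponding class
  b_unit <- matrix(0, 3, 2)
  b_unit[2, 1] <- 1
  b_unit[, 2] <- c(0.2, 0.3, 0.5)
  p <- local_comcrf(nb, 0L, m, list(b_unit))
  expect_equal(as.numeric(p), c(0, 1, 0))
  # constant column cancels: identical to the MCSS distribution
  b_const <- matrix(c(0.4, 0.4, 0.4, 0.6, 0.6, 0.6), 3, 2)
  expect_equal(as.numeric(local_comcrf(nb, 0L, m, list(b_const))),
               as.numeric(local_mcrf(nb, m)), tolerance = 1e-12)
})

test_that("engine distributions equal brute-force evaluation of the product formula", {
  set.seed(1234)
  for (case in 1:200) {
    n <- sample(2:3, 1)
    m <- rand_model(n, L = sample(2:4, 1))
    k <- sample(0:4, 1)
    cls <- if (k) sample(0:(n - 1), k, TRUE) else integer(0)
    lags <- if (k) stats::runif(k, 0.2, 14) else numeric(0)
    first <- if (k) sample(k, 1) else 1L
    use_aux <- stats::runif(1) < 0.5
    ctpms <- list()
    aux <- integer(0)
    if (use_aux) {
      na <- sample(2:4, 1)
      ctpms <- list(rand_stochastic_ctpm(n, na))
      aux <- sample(0:(na - 1), 1)
    }
    nb <- neighborhood(cls, lags, designated_first = if (k) first else NULL)
    got <- as.numeric(local_comcrf(nb, aux, m, ctpms))
    want <- oracle_local(cls, lags, first, m, aux, ctpms)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_lt(abs(sum(got) - 1), 1e-9)
  }
})

test_that("with detailed balance the neighbor-prior and marginal-prior forms agree", {
  # build a reversible model: p_i * p_ij(h) = p_j * p_ji(h) at every anchor
  set.seed(77)
  marg <- c(0.6, 0.4)
  P <- matrix(c(0.85, 0.15, 0.225, 0.775), 2, 2, byrow = TRUE)  # reversible wrt marg
  expect_equal(marg[1] * P[1, 2], marg[2] * P[2, 1])
  P2 <- P %*% P
  m <- make_model(c(1, 2), list(P, P2), marg)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    cls <- sample(0:1, k, TRUE)
    lags <- sample(c(0.5, 1, 1.7, 2), k, TRUE)
    first <- sample(k, 1)
    got <- as.numeric(local_mcrf(neighborhood(cls, lags,
                                              designated_first = first), m))
    # stationary special case: marginal prior times untransposed products
    num <- vapply(0:1, function(f) {
      v <- marg[f + 1]
      for (g in seq_len(k)) v <- v * oracle_eval(m, f, cls[g], lags[g])
      v
    }, 0)
    expect_lt(max(abs(got - num / sum(num))), 1e-9)
  }
})

test_that("sequential simulation is seed-deterministic and honors sample cells", {
  set.seed(31)
  m <- rand_model(3, L = 3)
  tmpl <- categorical_raster(matrix(0L, 12, 12),
                             codebook = codebook(c("A", "B", "C")))
  ctr <- cell_centers(tmpl, rows = c(2, 6, 11), cols = c(2, 7, 4))
  s <- point_samples(ctr$x, ctr$y, c(0L, 1L, 2L))
  r1 <- sequential_simulate(tmpl, s, m, radius = 6, seed = 5)
  r2 <- sequential_simulate(tmpl, s, m, radius = 6, seed = 5)
  r3 <- sequential_simulate(tmpl, s, m, radius = 6, seed = 6)
  expect_identical(r1$values, r2$values)
  expect_false(identical(r1$values, r3$values))
  expect_false(anyNA(r1$values))
  expect_equal(r1$values[cbind(c(2, 6, 11), c(2, 7, 4))], c(0L, 1L, 2L))
})

test_that("unit-vector CTPM columns reproduce the legacy map exactly", {
  set.seed(8)
  legacy <- rand_raster(15, 15, 3)
  # relabeling 0->1, 1->2, 2->0 expressed as a CTPM with unit columns
  b <- matrix(0, 3, 3)
  b[2, 1] <- 1; b[3, 2] <- 1; b[1, 3] <- 1
  relabeled <- matrix(c(1L, 2L, 0L)[legacy$values + 1L], 15, 15)
  tmpl <- categorical_raster(matrix(0L, 15, 15),
                             codebook = codebook(c("U0", "U1", "U2")))
  ctr <- cell_centers(tmpl, rows = c(1, 8), cols = c(1, 8))
  s <- point_samples(ctr$x, ctr$y, relabeled[cbind(c(1, 8), c(1, 8))])
  m <- rand_model(3, L = 2)
  for (seed in 1:3) {
    r <- sequential_simulate(tmpl, s, m, aux = list(raster = legacy, ctpm = b),
                             radius = 5, seed = seed)
    expect_identical(r$values, relabeled)
  }
})

test_that("inconsistent codebooks are rejected before simulating", {
  m <- rand_model(2, L = 2)
  tmpl <- categorical_raster(matrix(0L, 5, 5),
                             codebook = codebook(c("A", "B", "C")))
  s <- point_samples(0.5, 0.5, 0L)
  expect_error(sequential_simulate(tmpl, s, m, radius = 3, seed = 1),
               "inconsistent")
  legacy <- categorical_raster(matrix(0L, 4, 4), codebook = codebook("L"))
  m3 <- rand_model(3, L = 2)
  expect_error(sequential_simulate(tmpl, s, m3,
                                   aux = list(raster = legacy,
                                              ctpm = matrix(1, 3, 1)),
                                   radius = 3, seed = 1),
               "geometry")
})
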