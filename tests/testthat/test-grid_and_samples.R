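test_that("ASCII grid and CSV rasters round-trip bit-exactly", {
  r <- categorical_raster(matrix(c(0L, 1L, 1L, 0L), 2, 2),
                          cell_size = 20, origin = c(100, 200))
  expect_equal(r$n_rows, 2L)
  expect_equal(length(r$codebook), 2L)

  withr::with_tempdir({
    write_raster(r, "a.asc")
    back <- read_raster("a.asc")
    expect_identical(back$values, r$values)
    expect_equal(back$cell_size, 20)
    expect_equal(back$origin, c(100, 200))

    set.seed(42)
    for (rep in 1:3) {
      big <- rand_raster(175, 128, 7, p_nodata = 0.02)
      write_raster(big, "big.asc")
      expect_identical(read_raster("big.asc")$values, big$values)
      write_raster(big, "big.csv", format = "csv")
      expect_identical(read_raster("big.csv", format = "csv")$values,
                       big$values)
    }
  })
})

test_that("nodata cells are excluded from class proportions", {
  v <- matrix(c(0L, 0L, 1L, NA), 2, 2)
  r <- categorical_raster(v, codebook = codebook(c("A", "B")))
  expect_equal(raster_proportions(r), c(2 / 3, 1 / 3))
  expect_equal(sum(raster_proportions(r)), 1)
  withr::with_tempdir({
    write_raster(r, "nd.asc")
    expect_true(any(grepl("-9999", readLines("nd.asc"))))
    expect_identical(read_raster("nd.asc")$values, v)
  })
})

test_that("malformed raster files fail with the offending line number", {
  withr::with_tempdir({
    writeLines(c("ncols 2", "garbage", "xllcorner 0", "yllcorner 0",
                 "cellsize 1", "NODATA_value -9999", "0 1", "1 0"), "bad.asc")
    expect_error(read_raster("bad.asc"), "line 2")
    writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
                 "cellsize 1", "NODATA_value -9999", "0 1 1", "1 0"),
               "ragged.asc")
    expect_error(read_raster("ragged.asc"), "line 7")
    writeLines(c("0,1", "1,x"), "bad.csv")
    expect_error(read_raster("bad.csv", format = "csv"), "line 2")
    writeLines(c("0,1", "1,0.5"), "frac.csv")
    expect_error(read_raster("frac.csv", format = "csv"), "non-integer")
  })
})

test_that("samples CSV round-trips and validates its header", {
  s <- point_samples(c(0.5, 1.5), c(0.5, 0.5), c(0L, 1L))
  withr::with_tempdir({
    write_samples(s, "s.csv")
    back <- read_samples("s.csv")
    expect_equal(back$x, s$x)
    expect_equal(back$class_code, s$class_code)
    writeLines(c("a,b,c", "1,2,3"), "bad.csv")
    expect_error(read_samples("bad.csv"), "x,y,class")
  })
  expect_error(point_samples(c(1, 1), c(2, 2), c(0, 0)), "duplicate")
})

test_that("colocation maps samples to the containing cell", {
  v <- matrix(c(0L, 1L, 2L, 3L), 2, 2)  # (1,1)=0 (1,2)=2 / (2,1)=1 (2,2)=3
  r <- categorical_raster(v, codebook = codebook(paste0("L", 0:3)))
  # cell centers
  s <- point_samples(c(0.5, 1.5), c(1.5, 0.5), c(0L, 0L))
  pr <- colocate(s, r)
  expect_equal(pr$aux, c(v[1, 1], v[2, 2]))

  # a point exactly on the interior edges: half-open boxes, so it belongs
  # to the cell whose closed lower/left boundary it lies on — enumerate
  # both candidate cells on each axis and check the documented winner
  edge <- point_samples(1, 1, 0L)
  idx <- cell_index(r, edge$x, edge$y)
  expect_equal(idx$col, 2L)  # x = 1 starts the right column's interval
  expect_equal(idx$row, 1L)  # y = 1 starts the top row's interval
  expect_equal(colocate(edge, r)$aux, v[1, 2])
})

test_that("colocation drops nodata cells with a count and rejects outside points", {
  v <- matrix(c(0L, 0L, NA, 1L, 1L, 0L), 2, 3)
  r <- categorical_raster(v, codebook = codebook(c("A", "B")))
  ctr <- cell_centers(r, rows = c(1, 2, 1, 2, 1), cols = c(1, 1, 2, 2, 3))
  s <- point_samples(ctr$x, ctr$y, rep(0L, 5))
  expect_message(pr <- colocate(s, r), "1 sample")
  expect_equal(nrow(pr), 4L)
  expect_equal(attr(pr, "n_dropped"), 1L)

  out <- point_samples(10, 10, 0L)
  expect_error(colocate(out, r), "outside")
})

test_that("colocation is unchanged by a raster write/read round-trip", {
  set.seed(7)
  r <- rand_raster(10, 12, 3)
  ctr <- cell_centers(r, rows = sample(10, 20, TRUE), cols = sample(12, 20, TRUE))
  keep <- !duplicated(ctr)
  s <- point_samples(ctr$x[keep], ctr$y[keep], sample(0:2, sum(keep), TRUE))
  withr::with_tempdir({
    write_raster(r, "r.asc")
    r2 <- read_raster("r.asc")
    expect_equal(colocate(s, r)$aux, colocate(s, r2)$aux)
  })
})
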