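test_that("legacy map generation is deterministic and honors proportions", {
  r1 <- generate_legacy(40, 40, 2, c(0.5, 0.5), mean_patch_size = 50,
                        seed = 3)
  r2 <- generate_legacy(40, 40, 2, c(0.5, 0.5), mean_patch_size = 50,
                        seed = 3)
  expect_identical(r1$values, r2$values)
  expect_false(anyNA(r1$values))

  big <- generate_legacy(100, 100, 2, c(0.5, 0.5), mean_patch_size = 80,
                         seed = 9)
  expect_lt(max(abs(raster_proportions(big) - 0.5)), 0.05)

  # one class: constant raster
  one <- generate_legacy(10, 10, 1, 1, mean_patch_size = 10, seed = 1)
  expect_true(all(one$values == 0L))

  # unreachable proportions: one patch cannot hold two classes
  expect_error(generate_legacy(10, 10, 2, c(0.5, 0.5),
                               mean_patch_size = 100, seed = 1),
               "patches")
})

test_that("an empty scenario is the identity and merges are pure relabels", {
  set.seed(14)
  legacy <- rand_raster(20, 20, 3)
  ident <- update_scenario(0:2)
  out <- apply_scenario(legacy, ident, seed = 1)
  expect_identical(out$values, legacy$values)

  # merge class 2 into class 0 only
  merged <- apply_scenario(legacy, update_scenario(c(0L, 1L, 0L)), seed = 1)
  expect_identical(merged$values,
                   matrix(c(0L, 1L, 0L)[legacy$values + 1L], 20, 20))
})

test_that("patch swaps relabel the requested fraction inside the region", {
  set.seed(6)
  legacy <- rand_raster(30, 30, 2)
  region <- swap_region("rect", xmin = 5, xmax = 20, ymin = 5, ymax = 20)
  # exhaustive swap: no from-class cells remain in the region
  sc <- update_scenario(0:1, patch_swaps = list(
    list(region = region, from_class = 0L, to_class = 1L, fraction = 1)))
  out <- apply_scenario(legacy, sc, seed = 2)
  # region mask in matrix orientation (row 1 = top): center of cell (r, c)
  # is at x = c - 0.5, y = 30 - r + 0.5
  inreg <- outer(1:30, 1:30, function(r, c) {
    x <- c - 0.5; y <- 30 - r + 0.5
    x >= 5 & x <= 20 & y >= 5 & y <= 20
  })
  expect_false(any(out$values[inreg] == 0L))
  expect_identical(out$values[!inreg], legacy$values[!inreg])

  # partial swap hits the rounded target count
  sc2 <- update_scenario(0:1, patch_swaps = list(
    list(region = region, from_class = 0L, to_class = 1L, fraction = 0.4)))
  out2 <- apply_scenario(legacy, sc2, seed = 2)
  eligible <- sum(legacy$values[inreg] == 0L)
  changed <- sum(out2$values != legacy$values)
  expect_equal(changed, round(0.4 * eligible))

  # a swap with no eligible cells warns and is a no-op
  sc3 <- update_scenario(0:1, patch_swaps = list(
    list(region = swap_region("rect", xmin = 0, xmax = 2, ymin = 0, ymax = 2),
         from_class = 0L, to_class = 1L, fraction = 1, legacy_from = 99L)))
  expect_warning(out3 <- apply_scenario(legacy, sc3, seed = 2), "no eligible")
  expect_identical(out3$values, legacy$values)
})

test_that("pseudo-only sampling agrees with the legacy map everywhere", {
  legacy <- generate_legacy(30, 30, 3, c(0.3, 0.4, 0.3),
                            mean_patch_size = 60, seed = 5)
  sc <- update_scenario(0:2)  # no changes at all
  ref <- apply_scenario(legacy, sc, seed = 1)
  s <- draw_samples(ref, legacy, sampling_plan(60, 0, seed = 4), sc)
  pr <- colocate(s, legacy)
  expect_true(all(pr$primary == pr$aux))
  expect_equal(attr(s, "n_survey"), 0L)
})

test_that("the canonical scenario has the stated size and sample count", {
  sc <- generate_scenario(seed = 2)
  expect_equal(sc$legacy$n_rows * sc$legacy$n_cols, 22400L)
  expect_equal(nrow(sc$samples), 646L)
  # samples occupy distinct cells
  idx <- cell_index(sc$reference, sc$samples$x, sc$samples$y)
  expect_false(anyDuplicated(idx) > 0)
  # requesting more samples than cells is an error
  expect_error(draw_samples(sc$reference, sc$legacy,
                            sampling_plan(1e6, 0.1, 1), sc$scenario),
               "more samples")
})

test_that("untouched classes give exactly unit CTPM rows", {
  sc <- generate_scenario(n_rows = 80, n_cols = 60, n_samples = 300,
                          seed = 13)
  ct <- estimate_ctpm(colocate(sc$samples, sc$legacy), n_primary = 5L,
                      n_aux = 7L)
  # SU2 (code 0) <- legacy S2 (code 1) and SU4 (code 2) <- S4 (code 3)
  # are untouched by every merge and swap
  expect_identical(ct$b[1, 2], 1.0)
  expect_identical(ct$b[3, 4], 1.0)
})

test_that("a merges-only scenario is reproduced exactly by cosimulation", {
  legacy <- generate_legacy(30, 30, 4, c(0.3, 0.3, 0.2, 0.2),
                            mean_patch_size = 45, seed = 20)
  sc <- update_scenario(c(0L, 1L, 0L, 2L))  # classes 0 and 2 merge
  ref <- apply_scenario(legacy, sc, seed = 1)
  s <- draw_samples(ref, legacy, sampling_plan(80, 0, seed = 21), sc)
  ex <- estimate_transiograms(s, bin_width = 1, max_lag = 15, n_classes = 3)
  marg <- tabulate(s$class_code + 1L, 3)
  model <- suppressWarnings(build_model(ex, marg / sum(marg)))
  ct <- estimate_ctpm(colocate(s, legacy), 3L, 4L)
  tmpl <- categorical_raster(matrix(0L, 30, 30), codebook = ref$codebook)
  for (seed in 1:2) {
    r <- sequential_simulate(tmpl, s, model,
                             aux = list(raster = legacy, ctpm = ct),
                             radius = 10, seed = seed)
    expect_identical(r$values, ref$values)
  }
})
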