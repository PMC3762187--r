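with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a patchy categorical legacy map
#'
#' Builds a contiguous-patch categorical map by seeded region growth:
#' patch seeds are placed uniformly at random, classes are allocated to
#' seeds in proportion to the targets (largest-remainder rounding, every
#' positive-proportion class gets at least one seed), and patches grow by
#' randomized dilation — each round, every unassigned cell adjacent to an
#' assigned cell copies the class of a uniformly chosen assigned
#' 4-neighbor. The generator is independent of the simulation engine so
#' it can serve as an unbiased end-to-end fixture.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_classes number of classes.
#' @param target_proportions class proportions (sum to 1); realized
#'   proportions match within about 0.05 for reasonably large grids.
#' @param mean_patch_size mean patch area in cells (>= 1); the number of
#'   patch seeds is `round(n_cells / mean_patch_size)`.
#' @param seed integer RNG seed; the same seed gives the same map.
#' @param labels optional class labels.
#' @param cell_size,origin map geometry.
#' @return A [categorical_raster()].
#' @export
generate_legacy <- function(n_rows, n_cols, n_classes,
                            target_proportions = rep(1 / n_classes, n_classes),
                            mean_patch_size = 100, seed = 1L,
                            labels = paste0("S", seq_len(n_classes)),
                            cell_size = 1, origin = c(0, 0)) {
  if (mean_patch_size < 1) stop("mean_patch_size must be >= 1")
  if (abs(sum(target_proportions) - 1) > 1e-9) {
    stop("target_proportions must sum to 1")
  }
  n_cells <- n_rows * n_cols
  K <- max(1L, round(n_cells / mean_patch_size))
  positive <- which(target_proportions > 0)
  if (K < length(positive)) {
    stop("cannot realize ", length(positive), " classes with only ", K,
         " patches; decrease mean_patch_size")
  }
  with_preserved_seed(seed, {
    # largest-remainder allocation of patch seeds to classes
    quota <- rep(0L, n_classes)
    quota[positive] <- 1L
    rest <- K - length(positive)
    raw <- target_proportions * rest
    quota <- quota + floor(raw)
    leftover <- rest - sum(floor(raw))
    if (leftover > 0) {
      extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(leftover)]
      quota[extra] <- quota[extra] + 1L
    }
    seed_classes <- sample(rep(seq_len(n_classes) - 1L, quota))
    seed_cells <- sample.int(n_cells, K)
    vals <- matrix(NA_integer_, n_rows, n_cols)
    vals[seed_cells] <- seed_classes
    vals <- grow_regions(vals)
    categorical_raster(vals, cell_size = cell_size, origin = origin,
                       codebook = codebook(labels))
  })
}

# randomized multi-source dilation until every cell is assigned;
# mask (if given) restricts growth to TRUE cells
grow_regions <- function(vals, mask = NULL, max_cells = Inf) {
  nr <- nrow(vals)
  nc <- ncol(vals)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  n_assigned <- sum(!is.na(vals) & mask)
  repeat {
    todo <- is.na(vals) & mask
    if (!any(todo) || n_assigned >= max_cells) break
    # classes of the 4 neighbors (NA outside / unassigned)
    up <- rbind(vals[-1, , drop = FALSE], NA_integer_)
    dn <- rbind(NA_integer_, vals[-nr, , drop = FALSE])
    lf <- cbind(vals[, -1, drop = FALSE], NA_integer_)
    rt <- cbind(NA_integer_, vals[, -nc, drop = FALSE])
    cand <- rbind(up[todo], dn[todo], lf[todo], rt[todo])
    avail <- !is.na(cand)
    k <- colSums(avail)
    frontier <- which(todo)[k > 0L]
    if (!length(frontier)) break  # disconnected remainder
    cand <- cand[, k > 0L, drop = FALSE]
    avail <- avail[, k > 0L, drop = FALSE]
    k <- k[k > 0L]
    if (n_assigned + length(frontier) > max_cells) {
      keep <- sample.int(length(frontier), max_cells - n_assigned)
      frontier <- frontier[keep]
      cand <- cand[, keep, drop = FALSE]
      avail <- avail[, keep, drop = FALSE]
      k <- k[keep]
    }
    pick <- floor(stats::runif(length(k)) * k) + 1L
    chosen <- integer(length(k))
    # class code 0 is valid; track assignment separately
    assigned <- logical(length(k))
    cnt <- integer(length(k))
    for (d in 1:4) {
      cnt <- cnt + avail[d, ]
      hit <- avail[d, ] & cnt == pick & !assigned
      chosen[hit] <- cand[d, hit]
      assigned[hit] <- TRUE
    }
    vals[frontier] <- chosen
    n_assigned <- n_assigned + length(frontier)
  }
  vals
}

#' Describe a map update scenario
#'
#' A scenario is a total merge mapping from legacy classes to updated
#' classes (many-to-one allowed, e.g. taxonomy joins) followed by
#' localized patch swaps: inside a region, a stated fraction of the
#' cells of one updated class is relabeled to another as contiguous
#' sub-patches.
#'
#' @param merges integer vector, one updated class code per legacy class
#'   code (position `k` maps legacy code `k - 1`).
#' @param patch_swaps list of swaps, each a list with `region` (see
#'   [swap_region()]), `from_class`, `to_class` (updated codes),
#'   `fraction` in `(0, 1]` of eligible cells, and optionally
#'   `legacy_from` (legacy codes): when given, only cells originating
#'   from those legacy classes are eligible, so a swap can express
#'   "part of legacy class X became Y" even when several legacy classes
#'   merged into `from_class`.
#' @param new_labels labels of the updated classes.
#' @return An object of class `"update_scenario"`.
#' @export
update_scenario <- function(merges, patch_swaps = list(),
                            new_labels = NULL) {
  merges <- as.integer(merges)
  n_new <- max(merges) + 1L
  if (!setequal(unique(merges), seq_len(n_new) - 1L)) {
    stop("merge targets must cover contiguous updated codes 0..", n_new - 1L)
  }
  if (is.null(new_labels)) new_labels <- paste0("U", seq_len(n_new) - 1L)
  if (length(new_labels) != n_new) stop("one label per updated class needed")
  for (s in patch_swaps) {
    if (!all(c("region", "from_class", "to_class", "fraction") %in% names(s))) {
      stop("each swap needs region, from_class, to_class, fraction")
    }
    if (s$fraction <= 0 || s$fraction > 1) stop("swap fraction must be in (0, 1]")
  }
  structure(list(merges = merges, patch_swaps = patch_swaps,
                 new_labels = new_labels, n_new = n_new),
            class = "update_scenario")
}

#' Rectangular or disc swap region
#'
#' @param type `"rect"` or `"disc"`.
#' @param xmin,xmax,ymin,ymax rectangle bounds (map units, rect only).
#' @param x,y,r disc center and radius (disc only).
#' @return A region description usable in [update_scenario()] swaps.
#' @export
swap_region <- function(type = c("rect", "disc"), xmin = NULL, xmax = NULL,
                        ymin = NULL, ymax = NULL, x = NULL, y = NULL,
                        r = NULL) {
  type <- match.arg(type)
  if (type == "rect") {
    list(type = "rect", xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  } else {
    list(type = "disc", x = x, y = y, r = r)
  }
}

region_mask <- function(region, raster) {
  ctr <- cell_centers(raster,
                      rows = rep(seq_len(raster$n_rows), raster$n_cols),
                      cols = rep(seq_len(raster$n_cols),
                                 each = raster$n_rows))
  m <- if (region$type == "rect") {
    ctr$x >= region$xmin & ctr$x <= region$xmax &
      ctr$y >= region$ymin & ctr$y <= region$ymax
  } else {
    (ctr$x - region$x)^2 + (ctr$y - region$y)^2 <= region$r^2
  }
  matrix(m, raster$n_rows, raster$n_cols)
}

#' Apply an update scenario to a legacy map
#'
#' Applies the class merges everywhere, then each patch swap: within its
#' region, contiguous sub-patches of the `from_class` covering the stated
#' fraction of eligible cells are relabeled to `to_class`. Patches are
#' grown by randomized dilation from random eligible seeds. A swap whose
#' class is absent from its region warns and is a no-op.
#'
#' @param legacy a [categorical_raster()].
#' @param scenario an [update_scenario()].
#' @param seed integer RNG seed for the sub-patch growth.
#' @return The reference [categorical_raster()] with the updated
#'   codebook.
#' @export
apply_scenario <- function(legacy, scenario, seed = 1L) {
  if (length(scenario$merges) < n_classes(legacy$codebook)) {
    stop("merge mapping must cover every legacy class")
  }
  vals <- matrix(scenario$merges[legacy$values + 1L],
                 legacy$n_rows, legacy$n_cols)
  out <- categorical_raster(vals, cell_size = legacy$cell_size,
                            origin = legacy$origin,
                            codebook = codebook(scenario$new_labels),
                            nodata = legacy$nodata)
  with_preserved_seed(seed, {
    for (s in scenario$patch_swaps) {
      mask <- region_mask(s$region, out)
      eligible <- mask & !is.na(out$values) & out$values == s$from_class
      if (!is.null(s$legacy_from)) {
        eligible <- eligible & legacy$values %in% s$legacy_from
      }
      n_eligible <- sum(eligible)
      if (n_eligible == 0L) {
        warning("swap from class ", s$from_class,
                " has no eligible cells in its region; skipped")
        next
      }
      n_target <- max(1L, round(s$fraction * n_eligible))
      swapped <- matrix(NA_integer_, out$n_rows, out$n_cols)
      n_done <- 0L
      while (n_done < n_target) {
        open <- which(eligible & is.na(swapped))
        if (!length(open)) break
        swapped[open[sample.int(length(open), 1L)]] <- 1L
        swapped <- grow_regions(swapped, mask = eligible,
                                max_cells = n_target)
        n_done <- sum(!is.na(swapped) & eligible)
      }
      out$values[eligible & !is.na(swapped)] <- s$to_class
    }
    out
  })
}

#' Sampling plan for survey plus pseudo-samples
#'
#' @param n_total total number of samples (>= number of classes).
#' @param survey_fraction_in_changed_areas share of `n_total` placed
#'   uniformly in changed cells (update survey data); the remainder is
#'   placed uniformly in unchanged cells as pseudo-samples carrying the
#'   legacy (= reference) class.
#' @param seed integer RNG seed.
#' @return An object of class `"sampling_plan"`.
#' @export
sampling_plan <- function(n_total, survey_fraction_in_changed_areas = 0.15,
                          seed = 1L) {
  if (survey_fraction_in_changed_areas < 0 ||
      survey_fraction_in_changed_areas > 1) {
    stop("survey_fraction_in_changed_areas must be in [0, 1]")
  }
  structure(list(n_total = as.integer(n_total),
                 survey_fraction = survey_fraction_in_changed_areas,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Draw a mixed survey / pseudo-sample set
#'
#' Samples distinct cells of the reference map at cell centers: the
#' planned share in changed cells (cells where the reference differs from
#' the merge-relabeled legacy — pure taxonomy merges are not changes),
#' the rest in unchanged cells. All classes are read from the reference,
#' so pseudo-samples automatically agree with the (merged) legacy map.
#'
#' @param reference the reference [categorical_raster()].
#' @param legacy the legacy [categorical_raster()] (same geometry).
#' @param plan a [sampling_plan()].
#' @param scenario the [update_scenario()] defining the merges (needed to
#'   identify changed cells).
#' @return A [point_samples()] object with attribute `n_survey` (number
#'   of samples that fell in changed cells).
#' @export
draw_samples <- function(reference, legacy, plan, scenario) {
  if (reference$n_rows != legacy$n_rows ||
      reference$n_cols != legacy$n_cols) {
    stop("reference and legacy geometry mismatch")
  }
  n_cells <- reference$n_rows * reference$n_cols
  if (plan$n_total > n_cells) {
    stop("requested more samples (", plan$n_total, ") than cells (",
         n_cells, ")")
  }
  merged <- matrix(scenario$merges[legacy$values + 1L],
                   legacy$n_rows, legacy$n_cols)
  changed <- which(reference$values != merged)
  unchanged <- which(reference$values == merged)
  with_preserved_seed(plan$seed, {
    n_survey <- min(round(plan$survey_fraction * plan$n_total),
                    length(changed))
    n_pseudo <- min(plan$n_total - n_survey, length(unchanged))
    cells <- c(
      if (n_survey > 0L) changed[sample.int(length(changed), n_survey)],
      unchanged[sample.int(length(unchanged), n_pseudo)]
    )
    rows <- (cells - 1L) %% reference$n_rows + 1L
    cols <- (cells - 1L) %/% reference$n_rows + 1L
    ctr <- cell_centers(reference, rows, cols)
    s <- point_samples(ctr$x, ctr$y, reference$values[cells],
                       codebook = reference$codebook)
    attr(s, "n_survey") <- n_survey
    s
  })
}

#' Generate the canonical end-to-end update scenario
#'
#' Builds a complete synthetic study: a 7-class patchy legacy map on a
#' 175 x 128 grid, an update scenario with two taxonomy merges (a minor
#' class joined into a major one, and another pair joined) plus two
#' localized class swaps in opposite map corners, the resulting 5-class
#' reference map, and a mixed survey/pseudo sample set of 646 points.
#' All sizes can be overridden; the defaults form the package's standard
#' evaluation configuration.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_samples total sample count.
#' @param survey_fraction share of samples placed in changed cells.
#' @param mean_patch_size mean legacy patch area in cells.
#' @param proportions legacy class proportions (7 classes).
#' @param swap_fraction fraction of eligible cells relabeled inside each
#'   swap region.
#' @param seed integer master seed; sub-stage seeds are derived from it.
#' @return List with `legacy`, `scenario`, `reference`, `samples`,
#'   `changed` (logical matrix of changed cells) and `merged_legacy`
#'   (legacy map relabeled to updated codes).
#' @export
generate_scenario <- function(n_rows = 175, n_cols = 128, n_samples = 646,
                              survey_fraction = 0.15,
                              mean_patch_size = 120,
                              proportions = c(0.08, 0.18, 0.21, 0.14,
                                              0.05, 0.16, 0.18),
                              swap_fraction = 0.6, seed = 1L) {
  legacy <- generate_legacy(n_rows, n_cols, n_classes = 7,
                            target_proportions = proportions,
                            mean_patch_size = mean_patch_size,
                            seed = seed)
  # legacy S1..S7 are codes 0..6; updated classes:
  # U0 = S2, U1 = S3 + S5, U2 = S4, U3 = S6 (+ part of S7),
  # U4 = S7 + S1 (+ part of S6)
  merges <- c(4L, 0L, 1L, 2L, 1L, 3L, 4L)
  scenario <- update_scenario(
    merges,
    patch_swaps = list(
      # part of legacy S7 becomes updated SU6 in the top-right corner
      list(region = swap_region("rect",
                                xmin = n_cols - 40, xmax = n_cols,
                                ymin = n_rows - 36, ymax = n_rows),
           from_class = 4L, to_class = 3L, fraction = swap_fraction,
           legacy_from = 6L),
      # part of legacy S6 becomes updated SU7 at the bottom middle east
      list(region = swap_region("rect",
                                xmin = 0.45 * n_cols, xmax = 0.9 * n_cols,
                                ymin = 0, ymax = 30),
           from_class = 3L, to_class = 4L, fraction = swap_fraction,
           legacy_from = 5L)
    ),
    new_labels = c("SU2", "SU3", "SU4", "SU6", "SU7")
  )
  reference <- apply_scenario(legacy, scenario, seed = seed + 1L)
  samples <- draw_samples(reference, legacy,
                          sampling_plan(n_samples, survey_fraction,
                                        seed = seed + 2L),
                          scenario)
  merged <- categorical_raster(
    matrix(scenario$merges[legacy$values + 1L], n_rows, n_cols),
    cell_size = legacy$cell_size, origin = legacy$origin,
    codebook = reference$codebook
  )
  list(legacy = legacy, scenario = scenario, reference = reference,
       samples = samples, changed = reference$values != merged$values,
       merged_legacy = merged)
}
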