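#' Validate a run configuration
#'
#' A run configuration is a plain list (typically read from YAML) with:
#' `out_dir`; `method` (`"mcss"` or `"comcss"`); `seed`;
#' `n_realizations` (>= 1); `radius` (map units); `bin_width` and
#' `max_lag` for transiogram estimation; and either `synth` (argument
#' list for [generate_scenario()]) or input paths `samples`, `legacy`
#' (required for comcss) and optional `reference`. Referenced files must
#' exist at validation time.
#'
#' @param config list or path to a YAML file.
#' @return The completed config list, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(method = "comcss", seed = 1L, n_realizations = 100L,
                   radius = NULL, bin_width = NULL, max_lag = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$out_dir)) stop("config needs out_dir")
  if (!config$method %in% c("mcss", "comcss")) {
    stop("method must be 'mcss' or 'comcss'")
  }
  if (config$n_realizations < 1L) stop("n_realizations must be >= 1")
  if (is.null(config$synth)) {
    if (is.null(config$samples)) stop("config needs samples or synth")
    if (!file.exists(config$samples)) {
      stop("samples file not found: ", config$samples)
    }
    if (config$method == "comcss") {
      if (is.null(config$legacy)) {
        stop("method 'comcss' requires a legacy map path")
      }
      if (!file.exists(config$legacy)) {
        stop("legacy file not found: ", config$legacy)
      }
    }
    if (!is.null(config$reference) && !file.exists(config$reference)) {
      stop("reference file not found: ", config$reference)
    }
  }
  config
}

#' Run the full map-update workflow
#'
#' Executes the staged workflow — synthetic scenario generation (or input
#' loading), transiogram estimation, CTPM estimation, sequential
#' (co)simulation, and post-processing — writing all artifacts plus a
#' run manifest (`run_manifest.json` with the parameter echo, per-stage
#' wall times and the PCC when a reference map is available) to
#' `out_dir`. Re-running the same config reproduces every artifact
#' bit-exactly.
#'
#' @param config list or YAML path; see [validate_run_config()].
#' @return The manifest list, invisibly.
#' @export
run_update <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  reference <- NULL
  legacy <- NULL
  if (!is.null(config$synth)) {
    sc <- t_stage("synth", {
      args <- config$synth
      if (is.null(args$seed)) args$seed <- config$seed
      sc <- do.call(generate_scenario, args)
      write_raster(sc$legacy, file.path(config$out_dir, "legacy.asc"))
      write_raster(sc$reference, file.path(config$out_dir, "reference.asc"))
      write_samples(sc$samples, file.path(config$out_dir, "samples.csv"))
      sc
    })
    samples <- sc$samples
    legacy <- sc$legacy
    reference <- sc$reference
    grid <- sc$reference
  } else {
    samples <- t_stage("load", {
      s <- read_samples(config$samples)
      if (!is.null(config$legacy)) legacy <<- read_raster(config$legacy)
      if (!is.null(config$reference)) {
        reference <<- read_raster(config$reference)
      }
      s
    })
    grid <- reference %||% legacy
    if (is.null(grid)) stop("need a legacy or reference raster to define the grid")
  }
  n_primary <- max(samples$class_code) + 1L
  template <- categorical_raster(
    matrix(0L, grid$n_rows, grid$n_cols),
    cell_size = grid$cell_size, origin = grid$origin,
    codebook = if (!is.null(reference)) reference$codebook else
      codebook(paste0("U", seq_len(n_primary) - 1L))
  )
  bin_width <- config$bin_width %||% grid$cell_size
  max_lag <- config$max_lag %||% (50 * grid$cell_size)
  radius <- config$radius %||% (30 * grid$cell_size)

  model <- t_stage("transiogram", {
    ex <- estimate_transiograms(samples, bin_width = bin_width,
                                max_lag = max_lag, n_classes = n_primary)
    marginals <- tabulate(samples$class_code + 1L, nbins = n_primary)
    m <- build_model(ex, marginals / sum(marginals))
    write_transiogram_json(m, file.path(config$out_dir, "transiograms.json"))
    m
  })

  aux <- NULL
  if (config$method == "comcss") {
    ctpm <- t_stage("ctpm", {
      ct <- estimate_ctpm(colocate(samples, legacy),
                          n_primary = n_primary,
                          n_aux = n_classes(legacy$codebook))
      write_ctpm_csv(ct, file.path(config$out_dir, "ctpm.csv"),
                     row_labels = template$codebook$labels,
                     col_labels = legacy$codebook$labels)
      ct
    })
    aux <- list(raster = legacy, ctpm = ctpm)
  }

  reals <- t_stage("simulate", {
    rs <- simulate_realizations(config$n_realizations, template, samples,
                                model, aux = aux, radius = radius,
                                seed = config$seed)
    for (r in seq_along(rs)) {
      write_raster(rs[[r]],
                   file.path(config$out_dir, sprintf("realization_%03d.asc", r)))
    }
    rs
  })

  summary <- t_stage("postprocess", {
    cube <- occurrence(reals)
    write_postprocess(cube, config$out_dir, reference = reference,
                      exclude = samples)
  })

  manifest$pcc_optimal <- summary$pcc_optimal
  manifest$version <- as.character(utils::packageVersion("mcrfupdate"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
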