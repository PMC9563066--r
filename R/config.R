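#' Default model parameters
#'
#' The package-wide defaults, with units. These are the operating conditions
#' every assay and configuration falls back to.
#'
#' @return A `data.frame` with columns `parameter`, `value`, `unit`.
#' @export
default_params <- function() {
  data.frame(
    parameter = c("dt", "block_area", "cells_per_block",
                  "ahl_diffusivity", "metabolite_diffusivity", "decay_k",
                  "secretion_rate_per_cell", "secretion_rate_per_block",
                  "threshold", "fitness_gain", "base_fitness",
                  "bandpass_window_low", "bandpass_window_high"),
    value = c(10, 10, 1e8,
              8e-10, 5e-10, 4.6e-4,
              1.6e-10, 1.6e-2,
              5, 0.05, 0.25,
              10, 200),
    unit = c("min", "mm^2", "cells/block",
             "m^2/s", "m^2/s", "1/min",
             "nM/cell/min", "nM/cell-block/min",
             "nM", "probability", "probability/step",
             "nM", "nM")
  )
}

config_known_keys <- c("grid", "model_kind", "n_strains", "dt_min", "n_steps",
                       "seed", "snapshot_every", "update_order", "strains",
                       "diffusion", "seeding")

strain_known_keys <- c("strain_id", "produced", "sensed",
                       "secretion_rate_nM_per_block_min", "threshold_nM",
                       "base_fitness", "fitness_gain", "model_kind")

#' Load a simulation configuration from a YAML file
#'
#' Configuration keys carry explicit unit suffixes (`dt_min`, `D_m2_per_s`,
#' `threshold_nM`, ...). Any unspecified field takes the package default (see
#' [default_params()]): an empty file yields the default two-strain
#' quorum-sensing consortium, 4 + 4 random seed blocks, 50 steps. Unknown keys
#' and parameter sets violating the diffusion stability criterion are rejected
#' with a descriptive error.
#'
#' @param path Path to a YAML file (may be empty).
#' @param quiet Suppress the startup log of resolved parameters and stability
#'   numbers.
#' @return A [simulation_config()].
#' @export
load_config <- function(path, quiet = TRUE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw, quiet = quiet)
}

# build a simulation_config from a nested list, applying defaults
build_config <- function(raw, quiet = TRUE) {
  unknown <- setdiff(names(raw), config_known_keys)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  gr <- raw$grid %||% list()
  unknown <- setdiff(names(gr), c("width", "height", "block_area_mm2", "cells_per_block"))
  if (length(unknown))
    stop(sprintf("unknown grid key(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  grid <- create_grid(gr$width %||% 21, gr$height %||% 21,
                      block_area = gr$block_area_mm2 %||% 10,
                      cells_per_block = gr$cells_per_block %||% 1e8)
  dt_min <- raw$dt_min %||% 10
  model_kind <- raw$model_kind %||% "QSMM"

  if (!is.null(raw$strains)) {
    strains <- lapply(raw$strains, function(s) {
      unknown <- setdiff(names(s), strain_known_keys)
      if (length(unknown))
        stop(sprintf("unknown strain key(s): %s", paste(unknown, collapse = ", ")),
             call. = FALSE)
      strain_spec(s$strain_id, s$produced, s$sensed,
                  secretion_rate = s$secretion_rate_nM_per_block_min %||% 1.6e-2,
                  threshold = s$threshold_nM %||% 5,
                  base_fitness = s$base_fitness %||%
                    (if ((s$model_kind %||% model_kind) == "MMM") 0 else 0.25),
                  fitness_gain = s$fitness_gain %||% 0.05,
                  model_kind = s$model_kind %||% model_kind)
    })
  } else {
    strains <- make_consortium(raw$n_strains %||% 2, model_kind = model_kind)$strains
  }
  ids <- vapply(strains, `[[`, "", "strain_id")

  diff_raw <- raw$diffusion %||% list()
  unknown <- setdiff(names(diff_raw), c("default", "per_molecule"))
  if (length(unknown))
    stop(sprintf("unknown diffusion key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  make_dp <- function(d, fallback_D) {
    unknown <- setdiff(names(d), c("D_m2_per_s", "decay_k_per_min", "boundary"))
    if (length(unknown))
      stop(sprintf("unknown diffusion parameter key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    diffusion_params(D_m2_per_s = d$D_m2_per_s %||% fallback_D,
                     dt_min = dt_min, dL_mm = grid$square_length,
                     decay_k_per_min = d$decay_k_per_min %||% 4.6e-4,
                     boundary = d$boundary %||% "zero_flux")
  }
  fallback_D <- if (model_kind == "MMM") 5e-10 else 8e-10
  diffusion <- list()
  mols <- unique(c(vapply(strains, `[[`, "", "produced"),
                   vapply(strains, `[[`, "", "sensed")))
  for (m in mols)
    diffusion[[m]] <- make_dp(diff_raw$per_molecule[[m]] %||% diff_raw$default %||% list(),
                              fallback_D)

  sd_raw <- raw$seeding %||% list(kind = "random", n_per_strain = 4, seed = 1)
  pattern <- switch(sd_raw$kind %||% "random",
    random = seed_random(ids, n_per_strain = sd_raw$n_per_strain %||% 4,
                         seed = sd_raw$seed %||% 1),
    parallel_lines = seed_parallel_lines(ids, length = sd_raw$length %||% 8,
                                         separation = sd_raw$separation %||% 4,
                                         row = sd_raw$row),
    single_file = seed_single_file(ids, n_per_strain = sd_raw$n_per_strain %||% 4,
                                   row = sd_raw$row),
    diagonal_corners = seed_diagonal_corners(ids,
                                             n_per_strain = sd_raw$n_per_strain %||% 4),
    concentric_circles = seed_concentric_circles(ids, radii = sd_raw$radii),
    custom = seed_custom(as.data.frame(sd_raw$positions)),
    stop(sprintf("unknown seeding kind '%s'", sd_raw$kind), call. = FALSE))

  cfg <- simulation_config(grid, strains, pattern,
                           n_steps = raw$n_steps %||% 50,
                           seed = raw[["seed"]] %||% 1L,
                           diffusion = diffusion, dt_min = dt_min,
                           snapshot_every = raw$snapshot_every %||% 0,
                           update_order = raw$update_order %||% "shuffled")
  if (!quiet) {
    message(sprintf("grid %dx%d, dt = %g min, %d steps, seed %d",
                    grid$width, grid$height, dt_min, cfg$n_steps, cfg$seed))
    for (m in cfg$molecules)
      message(sprintf("  molecule %s: s = %.4g (stable)", m, cfg$diffusion[[m]]$s))
  }
  cfg
}

#' Serialise a simulation configuration back to YAML
#'
#' Writes a fully resolved configuration; `load_config()` on the output
#' reproduces the configuration exactly (round trip).
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  pat <- config$pattern
  seeding <- c(list(kind = pat$kind),
               pat[setdiff(names(pat), c("kind", "strains"))])
  seeding <- seeding[!vapply(seeding, is.null, TRUE)]
  if (!is.null(seeding$positions)) seeding$positions <- as.list(seeding$positions)
  raw <- list(
    grid = list(width = config$grid$width, height = config$grid$height,
                block_area_mm2 = config$grid$block_area,
                cells_per_block = config$grid$cells_per_block),
    dt_min = config$dt_min,
    n_steps = config$n_steps,
    seed = config$seed,
    snapshot_every = config$snapshot_every,
    update_order = config$update_order,
    strains = lapply(config$strains, function(s) list(
      strain_id = s$strain_id, produced = s$produced, sensed = s$sensed,
      secretion_rate_nM_per_block_min = s$secretion_rate,
      threshold_nM = s$threshold, base_fitness = s$base_fitness,
      fitness_gain = s$fitness_gain, model_kind = s$model_kind)),
    diffusion = list(per_molecule = stats::setNames(lapply(config$molecules, function(m) {
      d <- config$diffusion[[m]]
      list(D_m2_per_s = d$D_m2_per_s, decay_k_per_min = d$decay_k_per_min,
           boundary = d$boundary)
    }), config$molecules)),
    seeding = seeding
  )
  raw$strains <- unname(raw$strains)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run manifest
#'
#' A reproducibility record: the fully resolved configuration, the root seed,
#' the package version and MD5 checksums of the run's output files. A manifest
#' plus the package version suffices to reproduce every output.
#'
#' @param config A [simulation_config()].
#' @param outputs Character vector of output file paths to checksum.
#' @param path Optional path; if given the manifest is written there as JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, outputs = character(0), path = NULL) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  save_config(config, cfg_file)
  man <- list(
    package = "quorumCA",
    version = as.character(utils::packageVersion("quorumCA")),
    seed = config$seed,
    config = yaml::read_yaml(cfg_file),
    checksums = as.list(tools::md5sum(outputs))
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(man))
  }
  man
}

`%||%` <- function(a, b) if (is.null(a)) b else a
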