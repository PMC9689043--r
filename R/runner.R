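#' End-to-end experiment configuration
#'
#' Bundles scenario, solver, acquisition and imaging settings. Two scales
#' are predefined: `"paper"` keeps the reference acquisition (50 x 10 mm
#' slab, 32 elements, 28 sweeps, 50 us window, 10 points per wavelength) and
#' `"desk"` is a reduced configuration (25 x 10 mm slab, 16 elements, 12
#' sweeps, 30 us, 8 ppw) that runs in minutes on one CPU while preserving
#' every mechanism — equations, material ranges and boundary conditions are
#' identical at both scales.
#'
#' @param variant `"A"`, `"B"`, `"NARROW"` or `"NONE"` (healthy control).
#' @param G muscle inhomogeneity level (0, 5 or 10 in the reference runs).
#' @param f0 center frequency (Hz); defaults to 4 MHz for `"NARROW"`, else
#'   2 MHz.
#' @param seeds integer seeds (length 2) for the LDZ and muscle textures.
#' @param scale `"desk"` (default) or `"paper"`.
#' @param ... overrides for any config field: `muscle_width`,
#'   `muscle_height`, `pml_width`, `ldz_length`, `ldz_height`, `n_elements`,
#'   `aperture_size`, `step`, `ppw`, `cfl`, `dt`, `t_end`, `order`,
#'   `interp`, `dynamic_range`, `focus_depth`, `c_ref`, `pml_order`,
#'   `pml_atten_db`.
#' @return An object of class `lus_experiment_config` (a named list).
#' @export
experiment_config <- function(variant = "A", G = 0, f0 = NULL,
                              seeds = c(101L, 202L),
                              scale = c("desk", "paper"), ...) {
  scale <- match.arg(scale)
  if (is.null(f0)) f0 <- if (identical(variant, "NARROW")) 4e6 else 2e6
  base <- list(
    variant = variant, G = G, f0 = f0, seeds = as.integer(seeds[1:2]),
    scale = scale,
    muscle_width = if (scale == "paper") 0.050 else 0.025,
    muscle_height = 0.010,
    pml_width = 0.005,
    ldz_length = NULL,      # variant default
    ldz_height = 0.005,
    n_elements = if (scale == "paper") 32L else 16L,
    aperture_size = 5L, step = 1L,
    ppw = if (scale == "paper") 10 else 8,
    cfl = 0.5,
    dt = 2e-8,
    t_end = if (scale == "paper") 50e-6 else 30e-6,
    pml_order = 3, pml_atten_db = 60,
    order = "log_first", interp = 4L, dynamic_range = 50,
    focus_depth = 0.010, c_ref = 1570)
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  structure(modifyList(base, over), class = "lus_experiment_config")
}

#' @export
print.lus_experiment_config <- function(x, ...) {
  cat(sprintf("<lus_experiment_config> variant %s, G = %g, f0 = %g MHz, %s scale\n",
              x$variant, x$G, x$f0 * 1e-6, x$scale))
  cat(sprintf("  slab %.0f x %.0f mm, %d elements, ppw %g, t_end %g us, seeds (%d, %d)\n",
              x$muscle_width * 1e3, x$muscle_height * 1e3, x$n_elements,
              x$ppw, x$t_end * 1e6, x$seeds[1], x$seeds[2]))
  invisible(x)
}

#' Write / read an experiment configuration file
#'
#' Flat key/value YAML; every field of [experiment_config()] round-trips.
#'
#' @param config a `lus_experiment_config`.
#' @param path file path.
#' @return `path` invisibly (write) or the config (read).
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "lus_experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 readers take "2.0e6" (no signed exponent) as a string
  num <- c("G", "f0", "muscle_width", "muscle_height", "pml_width",
           "ldz_length", "ldz_height", "ppw", "cfl", "dt", "t_end",
           "pml_order", "pml_atten_db", "dynamic_range", "focus_depth",
           "c_ref")
  for (k in intersect(num, names(raw)))
    if (!is.null(raw[[k]])) raw[[k]] <- as.numeric(raw[[k]])
  for (k in intersect(c("n_elements", "aperture_size", "step", "interp"),
                      names(raw)))
    raw[[k]] <- as.integer(raw[[k]])
  args <- raw[setdiff(names(raw), c("variant", "G", "f0", "seeds", "scale"))]
  args <- args[!vapply(args, is.null, TRUE)]
  do.call(experiment_config,
          c(list(variant = raw$variant, G = raw$G, f0 = raw$f0,
                 seeds = as.integer(unlist(raw$seeds)), scale = raw$scale),
            args))
}

config_geometry <- function(config) {
  scenario_geometry(config$variant,
                    muscle_width = config$muscle_width,
                    muscle_height = config$muscle_height,
                    pml_width = config$pml_width,
                    ldz_height = config$ldz_height,
                    ldz_length = config$ldz_length)
}

#' Report problem sizes for a configuration without solving
#'
#' @param config a [experiment_config()].
#' @return list: grid dimensions, internal time step and substep, sweep and
#'   trace counts, total cell updates.
#' @export
dry_run <- function(config) {
  geom <- config_geometry(config)
  grid <- phantom_grid(geom, G = config$G, f0 = config$f0, ppw = config$ppw)
  c_max <- if (geom$ldz_length > 0) max(LDZ_V_MID + LDZ_V_HALF, MUSCLE_V + config$G)
           else MUSCLE_V + config$G
  dt_max <- config$cfl / (c_max * sqrt(1 / grid$dx^2 + 1 / grid$dy^2))
  substep <- max(1L, as.integer(ceiling(config$dt / dt_max - 1e-12)))
  n_out <- as.integer(round(config$t_end / config$dt))
  plan <- sweep_plan(config$n_elements, config$aperture_size, config$step)
  n_sweeps <- length(plan$positions)
  steps <- (n_out - 1L) * substep
  list(grid_nx = grid$nx, grid_ny = grid$ny, dx = grid$dx,
       dt_internal = config$dt / substep, substep = substep,
       n_samples = n_out, internal_steps = steps,
       n_sweeps = n_sweeps, n_traces = n_sweeps * config$n_elements,
       cell_updates = as.numeric(grid$nx) * grid$ny * steps * n_sweeps)
}

#' Run one end-to-end experiment
#'
#' Phantom construction, full subaperture sweep acquisition, B-scan
#' composition and artifact metrics, with the generating configuration
#' embedded in every artifact for provenance. Stages are run in order;
#' a failure aborts with the stage name.
#'
#' @param config a [experiment_config()].
#' @param sweeps optional subset of sweep indices (default all).
#' @param verbose print per-sweep progress.
#' @return An object of class `lus_experiment`: `phantom`, `rf`
#'   (`lus_rfdata`), `image` ([compose_bscan()] result), `metrics`
#'   (named vector), `config`.
#' @export
run_experiment <- function(config, sweeps = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "lus_experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("experiment stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  phantom <- stage("phantom",
    build_phantom(config_geometry(config), G = config$G, seeds = config$seeds,
                  f0 = config$f0, ppw = config$ppw))
  arr <- array_spec(n_elements = config$n_elements,
                    aperture_width = config$muscle_width)
  plan <- sweep_plan(config$n_elements, config$aperture_size, config$step)
  scfg <- solver_config(dt = config$dt, t_end = config$t_end,
                        cfl_number = config$cfl, pml_order = config$pml_order,
                        pml_atten_db = config$pml_atten_db)
  rf <- stage("simulate",
    acquire_rf(phantom, arr, plan, pulse_spec(f0 = config$f0), scfg,
               focus_depth = config$focus_depth, c_ref = config$c_ref,
               sweeps = sweeps, verbose = verbose))
  image <- stage("image",
    compose_bscan(rf, order = config$order, interp = config$interp,
                  dynamic_range = config$dynamic_range,
                  focus_depth = config$focus_depth, c_ref = config$c_ref))
  metrics <- stage("metrics", metrics_report(image, phantom$geometry))
  structure(list(phantom = phantom, rf = rf, image = image,
                 metrics = metrics, config = config),
            class = "lus_experiment")
}

#' @export
print.lus_experiment <- function(x, ...) {
  print(x$config)
  cat("metrics:\n")
  print(round(x$metrics, 3))
  invisible(x)
}

#' Run the domain-by-inhomogeneity image suite
#'
#' The six-panel experiment: domain variants A (10 mm LDZ) and B (4 mm LDZ)
#' crossed with inhomogeneity levels G = 0, 5, 10, each imaged and scored.
#'
#' @param scale `"desk"` (default) or `"paper"`.
#' @param variants,G_levels factors of the suite.
#' @param seeds texture seeds shared across runs.
#' @param verbose print progress.
#' @param ... further [experiment_config()] overrides applied to every run.
#' @return list of `lus_experiment`, named like `"A_G0"`, plus an attribute
#'   `"summary"` data frame of metrics.
#' @export
fig_suite <- function(scale = c("desk", "paper"), variants = c("A", "B"),
                      G_levels = c(0, 5, 10), seeds = c(101L, 202L),
                      verbose = FALSE, ...) {
  scale <- match.arg(scale)
  runs <- list()
  for (G in G_levels) for (v in variants) {
    key <- sprintf("%s_G%g", v, G)
    if (verbose) message("running ", key)
    cfg <- experiment_config(variant = v, G = G, seeds = seeds,
                             scale = scale, ...)
    runs[[key]] <- run_experiment(cfg, verbose = verbose)
  }
  summ <- do.call(rbind, lapply(names(runs), function(k) {
    m <- runs[[k]]$metrics
    data.frame(run = k, metric = names(m), value = unname(m))
  }))
  attr(runs, "summary") <- summ
  runs
}
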