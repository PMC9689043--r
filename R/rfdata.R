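#' RF acquisition: run the full subaperture sweep against the solver
#'
#' For each sweep position, drives the 5-element subaperture with the
#' focal-delayed pulse and records the trace of every array element (the
#' spatial average of pressure over the element width at the array face).
#' Sweep solves are independent and executed sequentially; results do not
#' depend on execution order.
#'
#' @param phantom a [build_phantom()] result.
#' @param array a [array_spec()]; defaults to an array spanning the muscle
#'   slab with 32 elements (scaled variants may pass fewer).
#' @param plan a [sweep_plan()]; default (n_elements, 5, 1).
#' @param pulse a [pulse_spec()]; default center frequency from the phantom.
#' @param config a [solver_config()].
#' @param focus_depth,c_ref transmit focal law parameters.
#' @param sweeps optional subset of sweep indices to run (default all).
#' @param verbose print one progress line per sweep.
#' @return An object of class `lus_rfdata`: `rf` (sweep x element x sample
#'   array), `t`, `dt`, `array`, `plan`, `pulse`, and `meta` (variant, G,
#'   seeds, f0, solver diagnostics).
#' @export
acquire_rf <- function(phantom, array = NULL, plan = NULL, pulse = NULL,
                       config = solver_config(), focus_depth = 0.010,
                       c_ref = 1570, sweeps = NULL, verbose = FALSE) {
  stopifnot(inherits(phantom, "lus_phantom"))
  if (is.null(array))
    array <- array_spec(aperture_width = phantom$geometry$muscle_width)
  if (is.null(plan)) plan <- sweep_plan(array$n_elements)
  if (is.null(pulse)) pulse <- pulse_spec(f0 = phantom$f0)
  if (is.null(sweeps)) sweeps <- seq_along(plan$positions)

  cols <- element_columns(array, phantom$grid)
  receivers <- lapply(cols, function(cc) list(cells = cbind(cc, 1L)))
  n_samp <- round(config$t_end / config$dt)
  rf <- array(0, dim = c(length(sweeps), array$n_elements, n_samp))
  diag_last <- NULL
  for (k in seq_along(sweeps)) {
    s <- sweeps[k]
    drive <- element_drive(s, plan, array, pulse, focus_depth, c_ref)
    sources <- lapply(drive, function(d) {
      list(cells = cbind(cols[[d$element_index]], 1L),
           onset_delay = d$onset_delay, pulse = d$pulse)
    })
    tr <- run_forward(phantom, sources, config, receivers)
    rf[k, , ] <- t(tr$traces)
    diag_last <- tr$diagnostics
    if (verbose)
      message(sprintf("sweep %d/%d: Courant %.3f, max|p| %.3g",
                      s, length(plan$positions), diag_last$courant,
                      diag_last$max_abs_p))
  }
  structure(list(rf = rf, t = (seq_len(n_samp) - 1L) * config$dt,
                 dt = config$dt, array = array,
                 plan = subset_plan(plan, sweeps), pulse = pulse,
                 meta = list(variant = phantom$geometry$variant,
                             G = phantom$G, seeds = phantom$seeds,
                             f0 = phantom$f0, t_end = config$t_end,
                             sweeps = sweeps, diagnostics = diag_last)),
            class = "lus_rfdata")
}

subset_plan <- function(plan, sweeps) {
  plan$positions <- plan$positions[sweeps]
  plan
}

#' @export
print.lus_rfdata <- function(x, ...) {
  d <- dim(x$rf)
  cat(sprintf("<lus_rfdata> %d sweeps x %d elements x %d samples (dt = %.3g us)\n",
              d[1], d[2], d[3], x$dt * 1e6))
  cat(sprintf("  variant %s, G = %g, f0 = %.3g MHz, seeds (%d, %d)\n",
              x$meta$variant, x$meta$G, x$meta$f0 * 1e-6,
              x$meta$seeds[1], x$meta$seeds[2]))
  invisible(x)
}

#' Write / read an RF dataset container
#'
#' The container holds the 3D `rf` dataset (sweep x element x sample) with
#' acquisition attributes; a JSON sidecar carries the attributes for audit
#' without loading the array.
#'
#' @param rf a `lus_rfdata`.
#' @param path output path (`.rds`; `<path>.json` sidecar written beside it).
#' @return `path` invisibly (write) or the `lus_rfdata` (read).
#' @export
write_rfdata <- function(rf, path) {
  stopifnot(inherits(rf, "lus_rfdata"))
  saveRDS(rf, path)
  meta <- c(list(datasets = "rf", dims = dim(rf$rf), dt = rf$dt),
            rf$meta[c("variant", "G", "seeds", "f0", "t_end")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rfdata
#' @export
read_rfdata <- function(path) {
  rf <- readRDS(path)
  if (!inherits(rf, "lus_rfdata")) stop("not an RF dataset container")
  rf
}
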