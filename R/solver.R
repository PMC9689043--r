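#' Solver configuration
#'
#' The solver integrates the first-order pressure–velocity acoustic system
#' with a staggered-grid finite-difference scheme (2nd order in time, 4th
#' order in space away from boundaries). The internal time step is
#' CFL-limited and decoupled from the output sampling `dt`: the solver
#' sub-steps per output sample (chosen automatically so the Courant number
#' stays at or below `cfl_number`) and records every output interval without
#' interpolation.
#'
#' @param dt output sampling interval (s; default 0.02 us).
#' @param t_end recording window (s; default 50 us).
#' @param cfl_number Courant safety factor in (0, 1]; the 2D stability limit
#'   of the 4th-order stencil is `c_max dt_int sqrt(1/dx^2 + 1/dy^2) <= 6/7`,
#'   so keep `cfl_number` below about 0.85 (default 0.5).
#' @param pml_order polynomial grading order of the absorbing profile.
#' @param pml_atten_db target round-trip attenuation across the absorbing
#'   strip (dB).
#' @param check_every steps between numerical-health checks (finiteness of
#'   the field); a non-finite field aborts with the step index.
#' @param record_energy if `TRUE`, the total discrete acoustic energy is
#'   recorded at every output sample.
#' @return An object of class `lus_solver_config`.
#' @export
solver_config <- function(dt = 2e-8, t_end = 50e-6, cfl_number = 0.5,
                          pml_order = 3, pml_atten_db = 60,
                          check_every = 250L, record_energy = FALSE) {
  stopifnot(dt > 0, t_end >= dt, cfl_number > 0, cfl_number <= 1)
  structure(list(dt = dt, t_end = t_end, cfl_number = cfl_number,
                 pml_order = pml_order, pml_atten_db = pml_atten_db,
                 check_every = as.integer(check_every),
                 record_energy = isTRUE(record_energy)),
            class = "lus_solver_config")
}

#' Courant stability check
#'
#' @param material a phantom or any list with a `velocity` matrix.
#' @param grid the grid (defaults to `material$grid`).
#' @param dt_internal candidate internal time step (s).
#' @param cfl_number admissible Courant number.
#' @return list with `courant`, `pass`, and `margin = cfl_number - courant`.
#' @examples
#' m <- list(velocity = matrix(1570, 2, 2),
#'           grid = acoustic_grid(2, 2, 1e-4))
#' check_stability(m, dt_internal = 1e-8)$courant  # 0.222
#' @export
check_stability <- function(material, grid = material$grid, dt_internal,
                            cfl_number = 0.5) {
  c_max <- max(material$velocity)
  courant <- c_max * dt_internal * sqrt(1 / grid$dx^2 + 1 / grid$dy^2)
  list(courant = courant, pass = courant <= cfl_number,
       margin = cfl_number - courant)
}

# polynomial-graded damping sigma_x(x) for the lateral strips, sampled at
# cell centers (length nx) and x-faces (length nx + 1)
pml_sigma <- function(grid, pml_width, order, atten_db, c_ref) {
  n_pml <- round(pml_width / grid$dx)
  sig_c <- numeric(grid$nx)
  sig_f <- numeric(grid$nx + 1)
  if (n_pml > 0) {
    L <- n_pml * grid$dx
    sig_max <- (order + 1) * c_ref * (atten_db * log(10) / 20) / (2 * L)
    xl <- grid$x0 + n_pml * grid$dx          # inner edge of left strip
    xr <- grid$x0 + (grid$nx - n_pml) * grid$dx
    prof <- function(x) {
      d <- pmax(0, pmax(xl - x, x - xr)) / L
      sig_max * pmin(1, d)^order
    }
    sig_c <- prof(grid_x(grid))
    sig_f <- prof(grid$x0 + (0:grid$nx) * grid$dx)
  }
  list(centers = sig_c, faces = sig_f, n_cells = n_pml)
}

# normalize a source/receiver cell spec to 1-based flat indices
flat_cells <- function(cells, grid) {
  if (is.matrix(cells)) {
    stopifnot(ncol(cells) == 2)
    as.integer(cells[, 1] + grid$nx * (cells[, 2] - 1L))
  } else as.integer(cells)
}

#' Run the forward acoustic simulation
#'
#' Integrates the variable-density acoustic system through the material map
#' to `t_end`. Boundaries: pressure release (p = 0) at the top (the pleural
#' interface with the aerated lung, reflection coefficient -1), rigid walls
#' (zero normal velocity) at the array face and the outer sides, and
#' polynomial-graded split-field absorbing strips (PML) inside the lateral
#' margins. Sources are additive ("soft") pressure injections; each receiver
#' records the spatial average of pressure over its cells at every output
#' sample.
#'
#' @param material a [build_phantom()] result, or any list with `velocity`
#'   and `density` matrices and a `grid`.
#' @param sources list of source terms; each a list with `cells` (two-column
#'   integer matrix of `(i, j)` grid indices, or flat indices), and either a
#'   `pulse` ([pulse_spec()]) plus optional `onset_delay` (s), or a
#'   `waveform` function of time (s).
#' @param config a [solver_config()].
#' @param receivers list of receiver cell specs (same `cells` format).
#' @param pml_width width of each lateral absorbing strip (m); defaults to
#'   the phantom geometry's, or 0 for a raw material list.
#' @param top_release logical: pressure-release top boundary (default TRUE).
#' @return An object of class `lus_traces`: `traces` (samples x receivers
#'   matrix), `t` (sample times, s), `dt`, `energy` (if recorded),
#'   `diagnostics` (internal step, substep, Courant number, max |p|).
#' @export
run_forward <- function(material, sources, config = solver_config(),
                        receivers, pml_width = NULL, top_release = TRUE) {
  grid <- material$grid
  stopifnot(inherits(grid, "lus_grid"))
  if (is.null(pml_width))
    pml_width <- if (!is.null(material$geometry)) material$geometry$pml_width else 0

  c_max <- max(material$velocity)
  dt_max <- config$cfl_number / (c_max * sqrt(1 / grid$dx^2 + 1 / grid$dy^2))
  substep <- max(1L, as.integer(ceiling(config$dt / dt_max - 1e-12)))
  dt_int <- config$dt / substep
  st <- check_stability(material, grid, dt_int, config$cfl_number)
  if (!st$pass) stop("internal time step unstable (Courant ", st$courant, ")")

  n_out <- round(config$t_end / config$dt)
  nsteps <- (n_out - 1L) * substep

  sig <- pml_sigma(grid, pml_width, config$pml_order, config$pml_atten_db,
                   c_ref = c_max)

  t_int <- (seq_len(nsteps)) * dt_int
  src_cells <- lapply(sources, function(s) flat_cells(s$cells, grid))
  src_wave <- vapply(sources, function(s) {
    delay <- if (is.null(s$onset_delay)) 0 else s$onset_delay
    if (delay < 0) stop("source onset_delay must be >= 0")
    w <- if (!is.null(s$pulse)) pulse_waveform(t_int - delay, s$pulse)
         else s$waveform(t_int - delay)
    if (any(!is.finite(w))) stop("source waveform must be finite")
    w
  }, numeric(nsteps))
  if (nsteps == 1L) src_wave <- matrix(src_wave, nrow = 1L)
  rec_cells <- lapply(receivers, function(r) flat_cells(r$cells, grid))

  out <- fdtd_run_cpp(material$velocity, material$density,
                      grid$dx, grid$dy, dt_int, nsteps, substep,
                      src_cells, src_wave, rec_cells,
                      sig$centers, sig$faces,
                      top_release, config$record_energy, config$check_every)
  if (out$blowup_step >= 0)
    stop(sprintf("solver diverged: non-finite field at internal step %d (t = %.3g us)",
                 out$blowup_step, out$blowup_step * dt_int * 1e6))

  structure(list(traces = out$traces,
                 t = (seq_len(n_out) - 1L) * config$dt,
                 dt = config$dt,
                 energy = if (config$record_energy) out$energy else NULL,
                 diagnostics = list(dt_internal = dt_int, substep = substep,
                                    courant = st$courant,
                                    max_abs_p = out$max_abs_p,
                                    pml_cells = sig$n_cells)),
            class = "lus_traces")
}

#' @export
print.lus_traces <- function(x, ...) {
  cat(sprintf("<lus_traces> %d receivers x %d samples, dt = %.3g us, Courant %.3f\n",
              ncol(x$traces), nrow(x$traces), x$dt * 1e6,
              x$diagnostics$courant))
  invisible(x)
}

#' Measure the residual reflection from the lateral absorbing strip
#'
#' Quasi-1D numerical experiment: a plane pulse is launched in a homogeneous
#' medium toward one absorbing strip, and the spurious return is compared to
#' the direct (incident) pulse at a receiver between the source and the
#' strip, in dB. With the strip disabled (`pml_width = 0`) the outer rigid
#' wall sits at the interface and returns the pulse at about 0 dB.
#'
#' @param pml_width strip width (m; default 5 mm; 0 disables absorption).
#' @param pml_order,pml_atten_db absorbing profile parameters.
#' @param f0 pulse center frequency (Hz).
#' @param ppw grid points per wavelength.
#' @param c0,rho0 medium sound speed (m/s) and density (kg/m^3).
#' @return list with `reflection_db`, `incident`, `returned` amplitudes.
#' @export
measure_pml_reflection <- function(pml_width = 5e-3, pml_order = 3,
                                   pml_atten_db = 60, f0 = 2e6, ppw = 10,
                                   c0 = 1570, rho0 = 1090) {
  dx <- (c0 / f0) / ppw
  interior <- 0.030                       # m, strip interface 10 mm left of source
  strip <- max(pml_width, 1e-3)           # reserve wall offset even when disabled
  nx <- ceiling((interior + 2 * strip) / dx)
  ny <- 8L
  grid <- acoustic_grid(nx, ny, dx, dx, x0 = -(interior / 2 + strip))
  mat <- list(velocity = matrix(c0, nx, ny), density = matrix(rho0, nx, ny),
              grid = grid)
  x <- grid_x(grid)
  col_near <- which.min(abs(x - (-0.005)))   # source column, 10 mm from interface
  col_rec <- which.min(abs(x - 0))           # receiver, 5 mm right of source
  allj <- seq_len(ny)
  src <- list(list(cells = cbind(col_near, allj), pulse = pulse_spec(f0 = f0)))
  rec <- list(list(cells = cbind(col_rec, allj)))
  cfg <- solver_config(t_end = 24e-6, pml_order = pml_order,
                       pml_atten_db = pml_atten_db)
  tr <- run_forward(mat, src, cfg, rec,
                    pml_width = if (pml_width > 0) pml_width else 0,
                    top_release = FALSE)
  env <- envelope(tr$traces[, 1])
  tt <- tr$t
  direct <- max(env[tt < 9e-6])
  returned <- max(env[tt >= 10e-6])
  list(reflection_db = 20 * log10(returned / direct),
       incident = direct, returned = returned)
}
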