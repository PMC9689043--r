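#' Linear array specification
#'
#' A linear array of `n_elements` point-like rectangular elements centered
#' laterally on the slab, lying on the array face (depth 0). The reference
#' probe has 32 elements spanning the 50 mm slab, so the default pitch is
#' `width / n_elements` and the element width is 80% of the pitch (kerf 20%).
#'
#' @param n_elements element count (default 32).
#' @param pitch center-to-center spacing (m); default `aperture_width /
#'   n_elements`.
#' @param element_width active element width (m); default `0.8 * pitch`.
#' @param aperture_width lateral span available to the array (m).
#' @return An object of class `lus_array`; `element_x` holds element centers.
#' @export
array_spec <- function(n_elements = 32L, pitch = NULL, element_width = NULL,
                       aperture_width = 0.050) {
  n_elements <- as.integer(n_elements)
  stopifnot(n_elements >= 1L)
  if (is.null(pitch)) pitch <- aperture_width / n_elements
  if (is.null(element_width)) element_width <- 0.8 * pitch
  if (n_elements * pitch > aperture_width * (1 + 1e-9))
    stop("array wider than the available aperture")
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(n_elements = n_elements, pitch = pitch,
                 element_width = element_width, element_x = x, face_y = 0),
            class = "lus_array")
}

#' @export
print.lus_array <- function(x, ...) {
  cat(sprintf("<lus_array> %d elements, pitch %.3f mm, width %.3f mm\n",
              x$n_elements, x$pitch * 1e3, x$element_width * 1e3))
  invisible(x)
}

#' Excitation pulse specification
#'
#' A Gaussian-windowed tone burst: `sin(2 pi f0 (t - tc)) exp(-(t - tc)^2 /
#' (2 sigma^2))`, peak-normalized. The default envelope width `sigma = 1.5 /
#' f0` gives roughly a three-cycle pulse.
#'
#' @param f0 center frequency (Hz; 2 MHz default, 4 MHz for the narrow-LDZ
#'   variant).
#' @param envelope_sigma Gaussian envelope standard deviation (s).
#' @param duration total pulse duration (s); must cover at least 6 sigma.
#' @return An object of class `lus_pulse`.
#' @export
pulse_spec <- function(f0 = 2e6, envelope_sigma = 1.5 / f0,
                       duration = 6 * envelope_sigma) {
  if (!(envelope_sigma > 0)) stop("envelope_sigma must be positive")
  if (duration < 6 * envelope_sigma - 1e-15)
    stop("duration must cover at least 6 sigma")
  structure(list(f0 = f0, envelope_sigma = envelope_sigma,
                 duration = duration, t_center = duration / 2),
            class = "lus_pulse")
}

#' Sample the excitation pulse
#'
#' @param t time points (s), measured from pulse start.
#' @param spec a [pulse_spec()].
#' @return pressure samples, peak-normalized to `max |p| = 1` (normalization
#'   computed on a dense internal grid so it is independent of `t`).
#' @export
pulse_waveform <- function(t, spec) {
  stopifnot(inherits(spec, "lus_pulse"))
  raw <- function(tt) {
    u <- tt - spec$t_center
    out <- sin(2 * pi * spec$f0 * u) * exp(-u^2 / (2 * spec$envelope_sigma^2))
    out[tt < 0 | tt > spec$duration] <- 0
    out
  }
  tt <- seq(0, spec$duration, length.out = 4096)
  peak <- max(abs(raw(tt)))
  raw(t) / peak
}

#' Subaperture sweep plan
#'
#' Sliding windows of `aperture_size` contiguous elements advancing by
#' `step`; the reference acquisition uses (32, 5, 1), giving 28 lines.
#'
#' @param n_elements total element count.
#' @param aperture_size elements per transmit subaperture (default 5).
#' @param step window advance in elements (default 1).
#' @return An object of class `lus_sweep_plan`; `positions` is a list of
#'   integer element-index windows (1-based).
#' @examples
#' length(sweep_plan(32, 5, 1)$positions)  # 28
#' @export
sweep_plan <- function(n_elements, aperture_size = 5L, step = 1L) {
  n_elements <- as.integer(n_elements)
  aperture_size <- as.integer(aperture_size)
  step <- as.integer(step)
  if (aperture_size > n_elements) stop("aperture larger than the array")
  span <- n_elements - aperture_size
  if (span %% step != 0L)
    stop("sweep does not tile the array: (n_elements - aperture_size) must be a multiple of step")
  starts <- seq(1L, n_elements - aperture_size + 1L, by = step)
  positions <- lapply(starts, function(s) s:(s + aperture_size - 1L))
  structure(list(aperture_size = aperture_size, step = step,
                 n_elements = n_elements, positions = positions),
            class = "lus_sweep_plan")
}

#' @export
print.lus_sweep_plan <- function(x, ...) {
  cat(sprintf("<lus_sweep_plan> %d positions (%d elements, aperture %d, step %d)\n",
              length(x$positions), x$n_elements, x$aperture_size, x$step))
  invisible(x)
}

#' Transmit focal delay law
#'
#' Per-element delays making all subaperture pulses arrive simultaneously at
#' a focus point on the subaperture axis: `B_i = (max_j path_j - path_i) /
#' c_ref` with `path_i = sqrt(focus_depth^2 + (x_i - x_center)^2)`. The edge
#' elements (longest path) fire first (`B = 0`); the center element last.
#'
#' @param element_x lateral positions of the subaperture elements (m).
#' @param focus_depth transmit focus depth (m; default 10 mm).
#' @param c_ref sound speed used for the delay law (m/s; default 1570,
#'   nominal muscle).
#' @return numeric vector of onset delays (s), all `>= 0`.
#' @examples
#' focal_delays((-2:2) * 1.5e-3, 0.010, 1570)  # edge-to-center 0.28 us
#' @export
focal_delays <- function(element_x, focus_depth = 0.010, c_ref = 1570) {
  if (!(focus_depth > 0)) stop("focus_depth must be positive")
  xc <- mean(range(element_x))
  path <- sqrt(focus_depth^2 + (element_x - xc)^2)
  (max(path) - path) / c_ref
}

#' Assemble the per-element source terms for one sweep position
#'
#' Applies the gate/delay law: elements inside the sweep window are ON with
#' the shared pulse delayed by their focal delay; all others are OFF.
#'
#' @param sweep_index 1-based sweep position in `plan`.
#' @param plan a [sweep_plan()].
#' @param array a [array_spec()].
#' @param pulse a [pulse_spec()].
#' @param focus_depth,c_ref focal law parameters, see [focal_delays()].
#' @return list of source terms, one per driven element: each has
#'   `element_index`, `onset_delay` (s) and the shared `pulse` spec.
#' @export
element_drive <- function(sweep_index, plan, array, pulse,
                          focus_depth = 0.010, c_ref = 1570) {
  stopifnot(inherits(plan, "lus_sweep_plan"), inherits(array, "lus_array"))
  if (sweep_index < 1L || sweep_index > length(plan$positions))
    stop("sweep_index out of range")
  idx <- plan$positions[[sweep_index]]
  B <- focal_delays(array$element_x[idx], focus_depth, c_ref)
  lapply(seq_along(idx), function(k) {
    list(element_index = idx[k], onset_delay = B[k], pulse = pulse)
  })
}

# grid column indices covered by each element's active width
element_columns <- function(array, grid) {
  x <- grid_x(grid)
  lapply(array$element_x, function(xe) {
    cols <- which(abs(x - xe) <= array$element_width / 2 + 1e-12)
    if (length(cols) == 0L) cols <- which.min(abs(x - xe))
    cols
  })
}
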