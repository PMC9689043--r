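#' Spectral parameters for a bounded random tissue texture
#'
#' The inhomogeneous tissue textures are sums of `n_modes` random cosine
#' plane waves with wavenumber magnitudes drawn uniformly from
#' `[k_min, k_max]` (cycles/m), directions uniform on the circle, amplitudes
#' uniform on (0, 1] and phases uniform on [0, 2 pi). `anisotropy_ratio > 1`
#' stretches the texture horizontally (x-wavenumbers divided by the ratio),
#' emulating muscle fiber structure.
#'
#' @param n_modes number of cosine modes (default 400).
#' @param k_min,k_max wavenumber band in cycles per meter; `0 <= k_min < k_max`.
#' @param seed integer seed; regeneration with the same seed is bit-identical.
#' @param anisotropy_ratio x/y feature elongation factor (>= 1; default 1).
#' @return An object of class `lus_field_params`.
#' @seealso [generate_random_field()]
#' @export
field_spectrum_params <- function(n_modes = 400L, k_min = 0, k_max,
                                  seed = 1L, anisotropy_ratio = 1) {
  n_modes <- as.integer(n_modes)
  if (n_modes < 1L) stop("n_modes must be >= 1")
  if (!(k_min >= 0 && k_min < k_max)) stop("need 0 <= k_min < k_max")
  if (anisotropy_ratio < 1) stop("anisotropy_ratio must be >= 1")
  structure(list(n_modes = n_modes, k_min = k_min, k_max = k_max,
                 seed = as.integer(seed), anisotropy_ratio = anisotropy_ratio),
            class = "lus_field_params")
}

#' Default wavenumber band for tissue texture at a given center frequency
#'
#' Chosen so the texture correlation length is about half a wavelength at
#' `f0` in water-like tissue (c = 1500 m/s), i.e. `k_max = 2 f0 / c`.
#'
#' @param f0 center frequency (Hz).
#' @param c_ref reference sound speed (m/s, default 1500).
#' @return numeric `c(k_min, k_max)` in cycles/m.
#' @export
default_k_band <- function(f0, c_ref = 1500) c(0, 2 * f0 / c_ref)

#' Generate a bounded stochastic field on a grid
#'
#' Sum of seeded random cosine modes, rescaled so that the maximum absolute
#' value is exactly 1; every value lies in `[-1, 1]`. Deterministic given the
#' seed in `params`.
#'
#' @param grid a [acoustic_grid()].
#' @param params a [field_spectrum_params()].
#' @return An object of class `lus_field`: list with `values`
#'   (`nx` x `ny` matrix), `grid` and `params`.
#' @examples
#' g <- acoustic_grid(64, 64, 1e-4)
#' f <- generate_random_field(g, field_spectrum_params(k_max = 2000, seed = 7))
#' max(abs(f$values))  # exactly 1
#' @export
generate_random_field <- function(grid, params) {
  stopifnot(inherits(grid, "lus_grid"), inherits(params, "lus_field_params"))
  # effective x-wavenumber is k_x / anisotropy_ratio; Nyquist applies to what
  # is actually sampled on the grid
  k_nyq <- 1 / (2 * max(grid$dx, grid$dy))
  if (params$k_max > k_nyq) {
    stop(sprintf(
      "grid too coarse for requested spectrum: k_max = %.3g cycles/m exceeds Nyquist %.3g cycles/m",
      params$k_max, k_nyq))
  }
  x <- grid_x(grid); y <- grid_y(grid)
  vals <- with_seed(params$seed, {
    m <- params$n_modes
    kmag <- runif(m, params$k_min, params$k_max)
    theta <- runif(m, 0, 2 * pi)
    amp <- 1 - runif(m)           # uniform on (0, 1]
    phase <- runif(m, 0, 2 * pi)
    kx <- kmag * cos(theta) / params$anisotropy_ratio
    ky <- kmag * sin(theta)
    # outer accumulation: cos(2 pi (kx x + ky y) + phi) = cos(a + b) expanded
    # so each mode costs two outer products instead of an nx*ny*m array
    acc <- matrix(0, grid$nx, grid$ny)
    for (q in seq_len(m)) {
      ax <- 2 * pi * kx[q] * x + phase[q]
      by <- 2 * pi * ky[q] * y
      acc <- acc + amp[q] * (cos(ax) %o% cos(by) - sin(ax) %o% sin(by))
    }
    acc
  })
  peak <- max(abs(vals))
  if (peak > 0) vals <- vals / peak
  structure(list(values = vals, grid = grid, params = params),
            class = "lus_field")
}

#' @export
print.lus_field <- function(x, ...) {
  cat(sprintf("<lus_field> %d x %d, %d modes, k in [%g, %g] cycles/m, seed %d\n",
              x$grid$nx, x$grid$ny, x$params$n_modes, x$params$k_min,
              x$params$k_max, x$params$seed))
  invisible(x)
}

#' @export
plot.lus_field <- function(x, ...) {
  image(grid_x(x$grid) * 1e3, grid_y(x$grid) * 1e3, x$values,
        col = gray(seq(0, 1, length.out = 256)), zlim = c(-1, 1),
        xlab = "x (mm)", ylab = "depth (mm)", useRaster = TRUE, ...)
  invisible(x)
}
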