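#' Uniform 2D simulation grid
#'
#' Cell-centered uniform grid for material maps and the acoustic solver.
#' The coordinate convention is: origin at the center of the array face,
#' `x` lateral, `y` increasing into the tissue (depth). Cell `(i, j)` has its
#' center at `(x0 + (i - 1/2) dx, y0 + (j - 1/2) dy)`.
#'
#' @param nx,ny number of cells along x (lateral) and y (depth).
#' @param dx,dy cell size in meters; must be positive.
#' @param x0,y0 coordinates (m) of the lower-left corner of the grid.
#' @return An object of class `lus_grid`.
#' @examples
#' g <- acoustic_grid(nx = 100, ny = 50, dx = 1e-4, dy = 1e-4, x0 = -5e-3)
#' range(grid_x(g))
#' @export
acoustic_grid <- function(nx, ny, dx, dy = dx, x0 = 0, y0 = 0) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 1L, ny >= 1L)
  if (!(dx > 0) || !(dy > 0)) stop("grid spacing must be positive")
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy, x0 = x0, y0 = y0),
            class = "lus_grid")
}

#' @rdname acoustic_grid
#' @param grid a `lus_grid`.
#' @export
grid_x <- function(grid) grid$x0 + (seq_len(grid$nx) - 0.5) * grid$dx

#' @rdname acoustic_grid
#' @export
grid_y <- function(grid) grid$y0 + (seq_len(grid$ny) - 0.5) * grid$dy

#' @export
print.lus_grid <- function(x, ...) {
  cat(sprintf("<lus_grid> %d x %d cells, dx = %.3g mm, dy = %.3g mm\n",
              x$nx, x$ny, x$dx * 1e3, x$dy * 1e3))
  cat(sprintf("  x: [%.2f, %.2f] mm, y: [%.2f, %.2f] mm\n",
              x$x0 * 1e3, (x$x0 + x$nx * x$dx) * 1e3,
              x$y0 * 1e3, (x$y0 + x$ny * x$dy) * 1e3))
  invisible(x)
}

#' Check that a grid resolves the shortest propagating wavelength
#'
#' The shortest wavelength is `c_min / f_max`; the grid must sample it with
#' at least `ppw` points per wavelength in both directions.
#'
#' @param grid a [acoustic_grid()].
#' @param c_min slowest sound speed in the medium (m/s).
#' @param f_max maximum signal frequency (Hz).
#' @param ppw required points per wavelength (default 10).
#' @return `TRUE` invisibly; errors if under-resolved.
#' @export
check_grid_resolution <- function(grid, c_min, f_max, ppw = 10) {
  lambda <- c_min / f_max
  need <- lambda / ppw
  if (max(grid$dx, grid$dy) > need * (1 + 1e-9)) {
    stop(sprintf(
      "grid under-resolved: dx = %.3g m exceeds lambda/ppw = %.3g m (c_min = %g, f = %g, ppw = %g)",
      max(grid$dx, grid$dy), need, c_min, f_max, ppw))
  }
  invisible(TRUE)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
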