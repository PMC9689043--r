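#' Scenario geometry: muscle slab, absorbing strips and the LDZ ellipse
#'
#' The simulated scene is a rectangular muscle slab (default 50 x 10 mm) with
#' an absorbing strip (PML) on each lateral side and an elliptical lung
#' disease zone (LDZ) of fluid-infiltrated lung tissue embedded in the upper
#' band of the slab, touching the pleural (top) boundary. The LDZ length
#' depends on the variant: 10 mm (`"A"`), 4 mm (`"B"`), or 1 mm (`"NARROW"`,
#' the 4 MHz case). `"NONE"` is the healthy-lung control without an LDZ.
#'
#' @param variant one of `"A"`, `"B"`, `"NARROW"`, `"NONE"`.
#' @param muscle_width,muscle_height slab dimensions (m).
#' @param pml_width width of each lateral absorbing strip (m).
#' @param ldz_height,ldz_length ellipse full height and full length (m);
#'   defaults set by `variant`. The ellipse is centered laterally and its top
#'   touches the pleural boundary at depth `muscle_height`.
#' @param ldz_center_x lateral center of the ellipse (m, default 0).
#' @return An object of class `lus_geometry`.
#' @export
scenario_geometry <- function(variant = c("A", "B", "NARROW", "NONE"),
                              muscle_width = 0.050, muscle_height = 0.010,
                              pml_width = 0.005,
                              ldz_height = 0.005, ldz_length = NULL,
                              ldz_center_x = 0) {
  variant <- match.arg(variant)
  if (is.null(ldz_length)) {
    ldz_length <- switch(variant, A = 0.010, B = 0.004, NARROW = 0.001,
                         NONE = 0)
  }
  if (variant == "NONE") ldz_length <- 0
  geom <- structure(list(variant = variant,
                         muscle_width = muscle_width,
                         muscle_height = muscle_height,
                         pml_width = pml_width,
                         ldz_height = ldz_height,
                         ldz_length = ldz_length,
                         ldz_center_x = ldz_center_x),
                    class = "lus_geometry")
  if (ldz_length > 0) {
    if (ldz_height > muscle_height)
      stop("LDZ ellipse taller than the muscle slab")
    if (abs(ldz_center_x) + ldz_length / 2 > muscle_width / 2)
      stop("LDZ ellipse extends outside the muscle slab")
  }
  geom
}

#' @export
print.lus_geometry <- function(x, ...) {
  cat(sprintf("<lus_geometry> variant %s: muscle %.0f x %.0f mm, PML %.0f mm\n",
              x$variant, x$muscle_width * 1e3, x$muscle_height * 1e3,
              x$pml_width * 1e3))
  if (x$ldz_length > 0)
    cat(sprintf("  LDZ ellipse %.1f mm long x %.1f mm high at x = %.1f mm\n",
                x$ldz_length * 1e3, x$ldz_height * 1e3, x$ldz_center_x * 1e3))
  else cat("  no LDZ (healthy-lung control)\n")
  invisible(x)
}

# nominal material constants (m/s, kg/m^3)
LDZ_V_MID <- 1070; LDZ_V_HALF <- 430
LDZ_D_MID <- 715;  LDZ_D_HALF <- 285
MUSCLE_V <- 1570;  MUSCLE_D <- 1090

#' Material maps for the fluid-infiltrated lung disease zone
#'
#' Affine maps of a bounded texture field onto sound speed and density:
#' `v = 1070 + 430 f` (m/s) and `d = 715 + 285 f` (kg/m^3). At `f = +1` the
#' tissue is pure water (1500 m/s, 1000 kg/m^3); at `f = -1` it is lung with
#' about 60% air content (640 m/s, 430 kg/m^3).
#'
#' @param field a [generate_random_field()] result, or any array with values
#'   in `[-1, 1]`.
#' @return list with `velocity` and `density` arrays shaped like the field.
#' @export
ldz_material <- function(field) {
  f <- field_values(field)
  list(velocity = LDZ_V_MID + LDZ_V_HALF * f,
       density  = LDZ_D_MID + LDZ_D_HALF * f)
}

#' Material maps for the muscle slab
#'
#' `v = 1570 + G g` (m/s) and `d = 1090 + G g` (kg/m^3), where `G` (0, 5 or
#' 10 in the reference experiments) sets the inhomogeneity level and `g` is a
#' bounded texture field. The same numeric `G` perturbs both velocity and
#' density.
#'
#' @param field texture field with values in `[-1, 1]`.
#' @param G inhomogeneity level (>= 0).
#' @return list with `velocity` and `density` arrays.
#' @export
muscle_material <- function(field, G) {
  if (!(is.numeric(G) && length(G) == 1L && G >= 0)) stop("G must be >= 0")
  g <- field_values(field)
  list(velocity = MUSCLE_V + G * g,
       density  = MUSCLE_D + G * g)
}

field_values <- function(field) {
  f <- if (inherits(field, "lus_field")) field$values else field
  if (!is.numeric(f)) stop("field must be numeric")
  if (any(!is.finite(f)) || max(abs(f)) > 1 + 1e-12)
    stop("field values must lie in [-1, 1]")
  f
}

#' Build the full material map for a scenario
#'
#' Creates a grid covering the muscle slab plus lateral absorbing strips,
#' fills it with muscle material textured by field `g`, and overwrites the
#' LDZ ellipse cells with infiltrated-lung material textured by an
#' independent field `f`. Cells beyond the pleural boundary (depth >
#' `muscle_height`) are not part of the computational domain; the boundary
#' itself is handled by the solver as a pressure-release condition.
#'
#' @param geometry a [scenario_geometry()].
#' @param grid a [acoustic_grid()] covering `muscle_width + 2 pml_width`
#'   laterally and `muscle_height` in depth, or `NULL` to build one from
#'   `f0` and `ppw`.
#' @param G muscle inhomogeneity level (0, 5, 10 in the reference runs).
#' @param seeds integer vector of length 2: seeds for the LDZ field `f` and
#'   the muscle field `g` (kept independent so the two textures decorrelate).
#' @param f0 center frequency (Hz), used for the default spectrum band and,
#'   when `grid` is `NULL`, the grid spacing.
#' @param ppw points per wavelength for the auto-built grid (default 10).
#' @param field_params optional list with elements `ldz` and `muscle`, each a
#'   [field_spectrum_params()] override (seed is still taken from `seeds`).
#' @return An object of class `lus_phantom`: `velocity`, `density` (nx x ny
#'   matrices), logical `ldz_mask`, plus `grid`, `geometry`, `G`, `seeds`.
#' @examples
#' ph <- build_phantom(scenario_geometry("B"), G = 5, seeds = c(11, 12),
#'                     ppw = 4)  # coarse grid for speed
#' range(ph$velocity[ph$ldz_mask])
#' @export
build_phantom <- function(geometry, grid = NULL, G = 0, seeds = c(1L, 2L),
                          f0 = 2e6, ppw = 10, field_params = NULL) {
  stopifnot(inherits(geometry, "lus_geometry"), length(seeds) >= 2)
  if (is.null(grid)) grid <- phantom_grid(geometry, G = G, f0 = f0, ppw = ppw)
  x <- grid_x(grid); y <- grid_y(grid)
  half_w <- geometry$muscle_width / 2 + geometry$pml_width
  if (grid$x0 > -half_w + 1e-12 ||
      grid$x0 + grid$nx * grid$dx < half_w - 1e-12 ||
      grid$ny * grid$dy < geometry$muscle_height - 1e-12)
    stop("grid does not cover the muscle slab plus absorbing strips")

  band <- default_k_band(f0)
  p_mus <- field_spectrum_params(k_max = band[2], seed = seeds[2],
                                 anisotropy_ratio = 4)
  p_ldz <- field_spectrum_params(k_max = band[2], seed = seeds[1])
  if (!is.null(field_params$muscle)) {
    p_mus <- field_params$muscle; p_mus$seed <- as.integer(seeds[2])
  }
  if (!is.null(field_params$ldz)) {
    p_ldz <- field_params$ldz; p_ldz$seed <- as.integer(seeds[1])
  }

  g <- generate_random_field(grid, p_mus)
  mus <- muscle_material(g, G)
  velocity <- mus$velocity
  density <- mus$density

  # LDZ ellipse: semi-axes (length/2, height/2), top tangent to the pleural
  # boundary at depth muscle_height
  ldz_mask <- matrix(FALSE, grid$nx, grid$ny)
  if (geometry$ldz_length > 0) {
    a <- geometry$ldz_length / 2
    b <- geometry$ldz_height / 2
    cy <- geometry$muscle_height - b
    xs <- (x - geometry$ldz_center_x) / a
    ys <- (y - cy) / b
    ldz_mask <- outer(xs^2, ys^2, `+`) <= 1
    f <- generate_random_field(grid, p_ldz)
    ldz <- ldz_material(f)
    velocity[ldz_mask] <- ldz$velocity[ldz_mask]
    density[ldz_mask] <- ldz$density[ldz_mask]
  }

  structure(list(velocity = velocity, density = density, ldz_mask = ldz_mask,
                 grid = grid, geometry = geometry, G = G,
                 seeds = as.integer(seeds[1:2]), f0 = f0),
            class = "lus_phantom")
}

#' Default grid for a scenario
#'
#' Spacing resolves the shortest wavelength — `c_min / f0` with `c_min` the
#' smallest sound speed the material maps can produce (640 m/s inside an LDZ,
#' `1570 - G` otherwise) — with `ppw` points per wavelength.
#'
#' @inheritParams build_phantom
#' @return a [acoustic_grid()] centered on the array face.
#' @export
phantom_grid <- function(geometry, G = 0, f0 = 2e6, ppw = 10) {
  c_min <- if (geometry$ldz_length > 0) LDZ_V_MID - LDZ_V_HALF else MUSCLE_V - G
  dx <- (c_min / f0) / ppw
  half_w <- geometry$muscle_width / 2 + geometry$pml_width
  nx <- ceiling(2 * half_w / dx)
  ny <- ceiling(geometry$muscle_height / dx)
  # recenter so cells tile [-half_w, half_w] exactly with spacing dx
  acoustic_grid(nx, ny, dx, dx, x0 = -nx * dx / 2, y0 = 0)
}

#' @export
print.lus_phantom <- function(x, ...) {
  print(x$geometry)
  cat(sprintf("  grid %d x %d (dx = %.3g mm), G = %g, seeds (f, g) = (%d, %d)\n",
              x$grid$nx, x$grid$ny, x$grid$dx * 1e3, x$G,
              x$seeds[1], x$seeds[2]))
  cat(sprintf("  velocity [%.0f, %.0f] m/s, density [%.0f, %.0f] kg/m3, LDZ cells: %d\n",
              min(x$velocity), max(x$velocity), min(x$density), max(x$density),
              sum(x$ldz_mask)))
  invisible(x)
}

#' @export
plot.lus_phantom <- function(x, what = c("velocity", "density"), ...) {
  what <- match.arg(what)
  image(grid_x(x$grid) * 1e3, grid_y(x$grid) * 1e3, x[[what]],
        col = gray(seq(0, 1, length.out = 256)),
        xlab = "x (mm)", ylab = "depth (mm)", useRaster = TRUE, ...)
  title(sprintf("%s (variant %s, G = %g)", what, x$geometry$variant, x$G))
  invisible(x)
}

#' Write / read a material map container
#'
#' Serializes the named datasets (`velocity`, `density`, `ldz_mask`) as an
#' RDS payload with a JSON metadata sidecar carrying the grid and scenario
#' attributes, so a map can be rebuilt or audited without loading the array.
#'
#' @param phantom a `lus_phantom`.
#' @param path output path (an `.rds` file; `<path>.json` is written beside it).
#' @return `path` invisibly (write) or the `lus_phantom` (read).
#' @export
write_material_map <- function(phantom, path) {
  stopifnot(inherits(phantom, "lus_phantom"))
  saveRDS(phantom, path)
  meta <- list(datasets = c("velocity", "density", "ldz_mask"),
               nx = phantom$grid$nx, ny = phantom$grid$ny,
               dx = phantom$grid$dx, dy = phantom$grid$dy,
               x0 = phantom$grid$x0, y0 = phantom$grid$y0,
               variant = phantom$geometry$variant, G = phantom$G,
               seeds = phantom$seeds, f0 = phantom$f0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_material_map
#' @export
read_material_map <- function(path) {
  ph <- readRDS(path)
  if (!inherits(ph, "lus_phantom")) stop("not a material map container")
  ph
}
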