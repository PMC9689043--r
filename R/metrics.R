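#' Detect the echo train in an envelope trace
#'
#' Local maxima of an envelope-detected trace above `threshold` times the
#' global maximum, separated by at least `min_separation`. In a
#' healthy-lung run the train is the initial pulse followed by reverberation
#' echoes spaced by the round trip `2 L / c` between the array face and the
#' pleura (12.74 us for a 10 mm slab at 1570 m/s).
#'
#' @param trace envelope-detected trace (non-negative vector).
#' @param dt sample interval (s).
#' @param threshold detection threshold as a fraction of the global maximum
#'   (default 0.1).
#' @param min_separation minimum spacing between detected peaks (s).
#' @return An object of class `lus_echo_train`: `arrival_times` (s, strictly
#'   increasing) and `amplitudes`; possibly empty.
#' @export
detect_echoes <- function(trace, dt, threshold = 0.1,
                          min_separation = 3e-6) {
  stopifnot(all(is.finite(trace)))
  n <- length(trace)
  peak <- max(trace)
  out <- list(arrival_times = numeric(0), amplitudes = numeric(0))
  if (peak > 0 && n >= 3) {
    is_max <- trace[2:(n - 1)] >= trace[1:(n - 2)] &
      trace[2:(n - 1)] >= trace[3:n] &
      trace[2:(n - 1)] >= threshold * peak
    cand <- which(is_max) + 1L
    # greedy by amplitude under the separation constraint
    cand <- cand[order(trace[cand], decreasing = TRUE)]
    keep <- integer(0)
    gap <- max(1L, round(min_separation / dt))
    for (i in cand) if (all(abs(i - keep) >= gap)) keep <- c(keep, i)
    keep <- sort(keep)
    out <- list(arrival_times = (keep - 1L) * dt, amplitudes = trace[keep])
  }
  structure(out, class = "lus_echo_train")
}

#' @export
print.lus_echo_train <- function(x, ...) {
  cat(sprintf("<lus_echo_train> %d peaks", length(x$arrival_times)))
  if (length(x$arrival_times))
    cat(": t (us) =", paste(sprintf("%.2f", x$arrival_times * 1e6),
                            collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Locate the pleural line depth in a B-scan
#'
#' The pleural line is the first strong horizontal band: the depth of the
#' largest laterally-averaged linear intensity beyond `min_depth` (which
#' excludes the transmit pulse residue near depth 0).
#'
#' @param image a [compose_bscan()] result.
#' @param min_depth shallowest admissible depth (m; default 4 mm).
#' @return pleural depth (m).
#' @export
pleural_depth <- function(image, min_depth = 4e-3) {
  stopifnot(inherits(image, "lus_bscan"))
  lin <- 10^(image$intensity / 20)
  prof <- rowMeans(lin)
  ok <- image$depth_axis >= min_depth
  image$depth_axis[ok][which.max(prof[ok])]
}

#' B-line intensity score of a B-scan image
#'
#' Mean linear intensity below the pleural line, averaged over image columns
#' above the LDZ (inside its lateral extent) versus columns away from it;
#' `ratio = inside / outside`. A healthy-lung image scores about 1; vertical
#' B-line artifacts rising from an LDZ push the ratio well above 1.
#'
#' Because the face/pleura cavity reverberates almost losslessly, the
#' horizontal A-line bands recur at round-trip multiples in **all** columns
#' and would dominate a plain below-pleura average; the score therefore
#' excludes depth rows within `band_exclusion` of each horizontal band
#' detected in the reference (outside) columns, so it measures the
#' inter-band region where the vertical artifact is unambiguous. Likewise
#' the vertical artifact bleeds laterally past the LDZ edge by roughly the
#' receive subaperture half-width, so a `guard` band on each side of the LDZ
#' extent is excluded from the outside reference.
#'
#' @param image a [compose_bscan()] result.
#' @param ldz_extent lateral interval `c(x_min, x_max)` (m) of the LDZ.
#' @param pleura pleural depth (m); located with [pleural_depth()] if `NULL`.
#' @param margin depth margin below the pleural band to skip (m, default
#'   1.5 mm) so the band itself is not scored.
#' @param guard lateral guard band (m) excluded on each side of the LDZ
#'   extent from the outside reference (default 3 mm, about the half-width
#'   of a 5-element subaperture at the reference pitch).
#' @param band_exclusion depth half-width (m) excluded around each detected
#'   A-line band (default 2 mm, about half the pulse's depth footprint);
#'   set to 0 to score every row below the pleura.
#' @return An object of class `lus_bline_score`: `inside_mean` and
#'   `outside_mean` (dB), `ratio` (linear), plus the column masks.
#' @export
bline_score <- function(image, ldz_extent, pleura = NULL, margin = 1.5e-3,
                        guard = 3e-3, band_exclusion = 2e-3) {
  stopifnot(inherits(image, "lus_bscan"), length(ldz_extent) == 2)
  if (is.null(pleura)) pleura <- pleural_depth(image)
  below <- image$depth_axis > pleura + margin
  if (!any(below)) stop("no image rows below the pleural depth")
  lat <- image$lateral_axis
  inside <- lat >= ldz_extent[1] & lat <= ldz_extent[2]
  outside <- lat < ldz_extent[1] - guard | lat > ldz_extent[2] + guard
  if (!any(outside)) stop("LDZ extent covers all columns: no reference region")
  if (!any(inside)) stop("no image columns inside the LDZ extent")
  if (band_exclusion > 0) {
    bands <- aline_bands(image, columns = outside, threshold = 0.3)
    rows <- below
    for (b in bands$arrival_times)
      rows <- rows & abs(image$depth_axis - b) > band_exclusion
    if (sum(rows) >= 5) below <- rows  # keep plain average if too few rows
  }
  lin <- 10^(image$intensity[below, , drop = FALSE] / 20)
  col_mean <- colMeans(lin)
  inside_mean <- mean(col_mean[inside])
  outside_mean <- mean(col_mean[outside])
  structure(list(inside_mean = 20 * log10(inside_mean),
                 outside_mean = 20 * log10(outside_mean),
                 ratio = inside_mean / outside_mean,
                 pleura = pleura, col_mean = col_mean,
                 inside = inside, outside = outside),
            class = "lus_bline_score")
}

#' @export
print.lus_bline_score <- function(x, ...) {
  cat(sprintf("<lus_bline_score> inside %.1f dB, outside %.1f dB, ratio %.2f (pleura %.1f mm)\n",
              x$inside_mean, x$outside_mean, x$ratio, x$pleura * 1e3))
  invisible(x)
}

#' Lateral width of the vertical (B-line) artifact
#'
#' Width (m) of the image columns whose below-pleura mean linear intensity
#' exceeds the midpoint between the inside and outside means of a
#' [bline_score()]. Wider LDZs produce wider vertical artifacts.
#'
#' @param image a [compose_bscan()] result.
#' @param score a [bline_score()] of the same image.
#' @return width in meters.
#' @export
bline_width <- function(image, score) {
  stopifnot(inherits(score, "lus_bline_score"))
  mid <- (10^(score$inside_mean / 20) + 10^(score$outside_mean / 20)) / 2
  lat <- image$lateral_axis
  dlat <- if (length(lat) > 1) median(diff(lat)) else 0
  sum(score$col_mean > mid) * dlat
}

#' A-line band detection outside the LDZ columns
#'
#' Averages the linear intensity over the given columns and detects the
#' horizontal-band peaks along depth; used to verify that reverberation
#' A-lines persist at round-trip multiples even in LDZ runs.
#'
#' @param image a [compose_bscan()] result.
#' @param columns logical or integer selection of lateral columns (default
#'   all).
#' @param threshold,min_separation passed to [detect_echoes()] (separation
#'   here in meters of depth).
#' @return a `lus_echo_train` whose `arrival_times` field holds **depths**
#'   (m).
#' @export
aline_bands <- function(image, columns = NULL, threshold = 0.1,
                        min_separation = 3e-3) {
  stopifnot(inherits(image, "lus_bscan"))
  lin <- 10^(image$intensity / 20)
  if (!is.null(columns)) lin <- lin[, columns, drop = FALSE]
  prof <- rowMeans(lin)
  keep <- image$depth_axis >= 0
  dz <- median(diff(image$depth_axis))
  tr <- detect_echoes(prof[keep], dz, threshold, min_separation)
  tr$arrival_times <- tr$arrival_times + min(image$depth_axis[keep])
  tr
}

#' Flat metrics report for one run
#'
#' @param image a [compose_bscan()] result.
#' @param geometry the [scenario_geometry()] of the run (for the LDZ extent).
#' @return named numeric vector: pleural depth, B-line ratio and width
#'   (when an LDZ exists), and the first A-line band spacing.
#' @export
metrics_report <- function(image, geometry) {
  pl <- pleural_depth(image)
  out <- c(pleural_depth_mm = pl * 1e3)
  bands <- aline_bands(image)
  if (length(bands$arrival_times) >= 2)
    out <- c(out, band_spacing_mm = median(diff(bands$arrival_times)) * 1e3)
  out <- c(out, n_bands = length(bands$arrival_times))
  if (geometry$ldz_length > 0) {
    ext <- geometry$ldz_center_x + c(-0.5, 0.5) * geometry$ldz_length
    sc <- tryCatch(bline_score(image, ext, pleura = pl),
                   error = function(e) NULL)  # e.g. no reference columns
    if (!is.null(sc))
      out <- c(out, bline_ratio = sc$ratio,
               bline_width_mm = bline_width(image, sc) * 1e3)
  }
  out
}
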