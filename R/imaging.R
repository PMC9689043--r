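#' Sign-preserving logarithmic amplification
#'
#' `y = sign(x) log10(1 + |x| / x_ref)`. The reference level defaults to the
#' dataset peak divided by 1000, so roughly 60 dB of input range is mapped
#' into the compressed scale. An all-zero input returns zeros (identity).
#'
#' @param x numeric vector, matrix or array of RF samples.
#' @param x_ref reference amplitude; default `max(abs(x)) / 1e3`.
#' @return compressed samples, same shape as `x`.
#' @export
log_amplify <- function(x, x_ref = NULL) {
  if (any(!is.finite(x))) stop("RF samples must be finite")
  if (is.null(x_ref)) x_ref <- max(abs(x)) / 1e3
  if (x_ref <= 0) return(x)  # all-zero dataset guard
  sign(x) * log10(1 + abs(x) / x_ref)
}

#' Signal envelope via the analytic signal
#'
#' Magnitude of the analytic signal, whose imaginary part is the Hilbert
#' transform of the trace (computed in the frequency domain).
#'
#' @param x uniformly sampled real trace (vector) or a matrix of column
#'   traces.
#' @return non-negative envelope, same shape; pointwise `>= |x|`.
#' @export
envelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, envelope))
  n <- length(x)
  if (n < 2) return(abs(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Receive delay-and-sum focusing of subaperture traces
#'
#' Shifts each trace earlier by its receive delay (the same focal geometry
#' as transmit: focus at 10 mm, reference speed 1570 m/s, unless other
#' delays are supplied) and sums. Delays are rounded to whole samples;
#' samples shifted past the end are zero-filled.
#'
#' @param traces samples x elements matrix (columns aligned to a common
#'   t = 0).
#' @param delays per-element receive delays (s), one per column.
#' @param dt sample interval (s).
#' @return single summed RF line (numeric vector).
#' @export
beamform_line <- function(traces, delays, dt) {
  traces <- as.matrix(traces)
  stopifnot(length(delays) == ncol(traces))
  n <- nrow(traces)
  shifts <- as.integer(round(delays / dt))
  if (any(shifts >= n)) {
    warning("receive delay exceeds trace length; truncating with zero fill")
    shifts <- pmin(shifts, n - 1L)
  }
  line <- numeric(n)
  for (k in seq_len(ncol(traces))) {
    s <- shifts[k]
    if (s == 0L) line <- line + traces[, k]
    else line <- line + c(traces[(s + 1L):n, k], numeric(s))
  }
  line
}

#' Compose a B-scan image from an RF dataset
#'
#' One image line per sweep position, built from the 5 traces of the
#' transmitting subaperture. The default processing chain applies the
#' logarithmic amplifier to each RF trace first, then Hilbert-envelope
#' detection, then receive delay-and-sum focusing (`order = "log_first"`);
#' `order = "conventional"` beamforms the RF coherently, then detects the
#' envelope, then log-compresses. Lines are laterally interpolated
#' (endpoint-preserving linear interpolation by `interp` so 28 lines become
#' `4*28 - 3 = 109` columns at the default factor), normalized to a 0 dB
#' peak and clipped at `-dynamic_range`.
#'
#' @param rf a `lus_rfdata` acquisition (see [acquire_rf()]).
#' @param order processing order, `"log_first"` (default) or
#'   `"conventional"`.
#' @param interp integer lateral interpolation factor (default 4).
#' @param dynamic_range display range in dB (default 50).
#' @param focus_depth,c_ref receive focal law parameters.
#' @return An object of class `lus_bscan`: `intensity` (depth x lateral dB
#'   matrix in `[-dynamic_range, 0]`), `depth_axis` (m, `c_ref t / 2`
#'   measured from the pulse center), `lateral_axis` (m), `dynamic_range`.
#' @export
compose_bscan <- function(rf, order = c("log_first", "conventional"),
                          interp = 4L, dynamic_range = 50,
                          focus_depth = 0.010, c_ref = 1570) {
  order <- match.arg(order)
  stopifnot(inherits(rf, "lus_rfdata"))
  n_sweep <- dim(rf$rf)[1]
  if (any(!is.finite(rf$rf))) stop("incomplete dataset: non-finite traces")
  x_ref <- max(abs(rf$rf)) / 1e3
  arr <- rf$array
  lines <- matrix(0, dim(rf$rf)[3], n_sweep)
  for (s in seq_len(n_sweep)) {
    idx <- rf$plan$positions[[s]]
    tr <- t(rf$rf[s, idx, , drop = TRUE])      # samples x aperture
    B <- focal_delays(arr$element_x[idx], focus_depth, c_ref)
    # an echo from the focus reaches element i at (const - B_i): the center
    # element, with the shortest return path, receives last in B terms, so
    # the aligning receive advance is max(B) - B_i
    recv <- max(B) - B
    if (order == "log_first") {
      tr <- log_amplify(tr, x_ref = x_ref)
      tr <- envelope(tr)
      lines[, s] <- beamform_line(tr, recv, rf$dt)
    } else {
      line <- beamform_line(tr, recv, rf$dt)
      lines[, s] <- log_amplify(envelope(line),
                                x_ref = max(abs(rf$rf)) * 5 / 1e3)
    }
  }

  lateral <- vapply(rf$plan$positions,
                    function(ix) mean(arr$element_x[ix]), 0)
  interp <- as.integer(interp)
  if (interp > 1L && n_sweep > 1L) {
    lat_out <- seq(lateral[1], lateral[n_sweep],
                   length.out = interp * (n_sweep - 1L) + 1L)
    lines <- t(apply(lines, 1, function(row)
      approx(lateral, row, xout = lat_out)$y))
    lateral <- lat_out
  }

  peak <- max(abs(lines))
  if (peak <= 0) {
    db <- matrix(-dynamic_range, nrow(lines), ncol(lines))
  } else {
    db <- 20 * log10(pmax(abs(lines) / peak, 10^(-dynamic_range / 20)))
  }
  depth <- c_ref * (rf$t - rf$pulse$t_center) / 2
  structure(list(intensity = db, depth_axis = depth, lateral_axis = lateral,
                 dynamic_range = dynamic_range, order = order,
                 interp = interp, c_ref = c_ref, meta = rf$meta),
            class = "lus_bscan")
}

#' @export
print.lus_bscan <- function(x, ...) {
  cat(sprintf("<lus_bscan> %d depth x %d lateral samples, %g dB range (%s order)\n",
              nrow(x$intensity), length(x$lateral_axis), x$dynamic_range,
              x$order))
  invisible(x)
}

#' @export
plot.lus_bscan <- function(x, ...) {
  keep <- x$depth_axis >= 0
  image(x$lateral_axis * 1e3, x$depth_axis[keep] * 1e3,
        t(x$intensity[keep, , drop = FALSE]),
        col = gray(seq(0, 1, length.out = 256)),
        zlim = c(-x$dynamic_range, 0),
        xlab = "lateral (mm)", ylab = "depth (mm)", ylim = rev(range(
          x$depth_axis[keep] * 1e3)), useRaster = TRUE, ...)
  invisible(x)
}

#' Export a B-scan as 8-bit grayscale PNG (plus a lossless dump)
#'
#' @param bscan a `lus_bscan`.
#' @param path output PNG path; `<path>.rds` holds the lossless array with
#'   axis metadata.
#' @return `path` invisibly.
#' @export
write_bscan_png <- function(bscan, path) {
  stopifnot(inherits(bscan, "lus_bscan"))
  keep <- bscan$depth_axis >= 0
  img <- bscan$intensity[keep, , drop = FALSE]
  gray01 <- (img + bscan$dynamic_range) / bscan$dynamic_range
  png::writePNG(pmin(pmax(gray01, 0), 1), path)
  saveRDS(bscan, paste0(path, ".rds"))
  invisible(path)
}
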