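# build a synthetic RF dataset without running the solver
synthetic_rfdata <- function(n_sweep = 28L, n_elem = 32L, n_samp = 500L,
                             dt = 2e-8, fill = NULL) {
  arr <- array_spec(n_elem, aperture_width = 0.050)
  plan <- sweep_plan(n_elem, 5L, 1L)
  stopifnot(length(plan$positions) == n_sweep)
  rf <- array(0, dim = c(n_sweep, n_elem, n_samp))
  if (!is.null(fill)) rf <- fill(rf)
  structure(list(rf = rf, t = (seq_len(n_samp) - 1) * dt, dt = dt,
                 array = arr, plan = plan, pulse = pulse_spec(2e6),
                 meta = list(variant = "SYNTH", G = 0, seeds = c(0L, 0L),
                             f0 = 2e6, t_end = n_samp * dt)),
            class = "lus_rfdata")
}

test_that("log amplifier is odd, monotone and fixed at zero", {
  expect_identical(log_amplify(0, x_ref = 1), 0)
  x <- seq(-3, 3, by = 0.01)
  y <- log_amplify(x, x_ref = 0.5)
  expect_equal(y, -rev(y))                       # sign symmetry
  expect_true(all(diff(y) > 0))                  # monotone
  set.seed(1)
  r <- sort(runif(100, -10, 10))
  expect_true(all(diff(log_amplify(r, x_ref = 2)) >= 0))
  expect_identical(log_amplify(numeric(5)), numeric(5))  # all-zero guard
  expect_error(log_amplify(c(1, NA)), "finite")
})

test_that("envelope recovers amplitude of tones and pulses", {
  t <- seq(0, 50e-6, by = 2e-8)
  tone <- cos(2 * pi * 2e6 * t)
  env <- envelope(tone)
  core <- seq(100, length(t) - 100)
  expect_true(all(abs(env[core] - 1) < 0.02))
  expect_true(all(env >= abs(tone) - 1e-9))
  # Gaussian-windowed burst: envelope matches the window
  spec <- pulse_spec(2e6)
  tp <- seq(0, spec$duration, by = 2e-8)
  w <- pulse_waveform(tp, spec)
  gauss <- exp(-(tp - spec$t_center)^2 / (2 * spec$envelope_sigma^2))
  core <- which(gauss > 0.1)
  scale <- max(envelope(w))
  expect_lt(max(abs(envelope(w)[core] / scale - gauss[core] / max(gauss))),
            0.05)
})

test_that("delay-and-sum focusing gains on coherent echoes", {
  n <- 400; dt <- 2e-8
  expect_equal(beamform_line(matrix(rep(sin(1:n), 5), n, 5), numeric(5), dt),
               5 * sin(1:n))
  # point echo at the focus: traces delayed by the focal law realign
  spec <- pulse_spec(2e6)
  B <- focal_delays((-2:2) * 1.5e-3, 0.010, 1570)
  recv <- max(B) - B                   # echo reaches element i at const - B_i
  tt <- (seq_len(n) - 1) * dt
  traces <- vapply(recv, function(b) pulse_waveform(tt - 3e-6 - b, spec),
                   numeric(n))
  line <- beamform_line(traces, recv, dt)
  expect_gte(max(abs(line)), 5 * 0.9 * max(abs(traces)))
  # random-phase traces add incoherently (~ sqrt(5), not 5)
  set.seed(42)
  amps <- replicate(40, {
    ph <- runif(5, 0, 2 * pi)
    tr <- vapply(ph, function(p) sin(2 * pi * 2e6 * tt + p), numeric(n))
    max(abs(beamform_line(tr, numeric(5), dt)))
  })
  expect_lt(mean(amps), 3.5)
  expect_gt(mean(amps), 1.2)
  expect_warning(beamform_line(matrix(1, 10, 2), c(0, 1), dt), "zero fill")
})

test_that("B-scan composition interpolates laterally and maps depth", {
  spec <- pulse_spec(2e6)
  echo_at <- spec$t_center + 2 * 0.010 / 1570    # pleural echo round trip
  rf <- synthetic_rfdata(n_samp = 900L, fill = function(a) {
    tt <- (seq_len(dim(a)[3]) - 1) * 2e-8
    w <- pulse_waveform(tt - echo_at + spec$t_center, spec)
    for (s in seq_len(dim(a)[1])) for (e in seq_len(dim(a)[2])) a[s, e, ] <- w
    a
  })
  img <- compose_bscan(rf, interp = 4L)
  expect_identical(ncol(img$intensity), 4L * 28L - 3L)
  expect_true(all(img$intensity <= 0 & img$intensity >= -img$dynamic_range))
  # the echo band sits at the slab thickness
  expect_lt(abs(pleural_depth(img) - 0.010) / 0.010, 0.05)
  # determinism
  expect_identical(img$intensity, compose_bscan(rf, interp = 4L)$intensity)
})

test_that("degenerate and convexity properties of composition", {
  rf0 <- synthetic_rfdata(n_samp = 200L)
  img0 <- compose_bscan(rf0)
  expect_true(all(img0$intensity == -img0$dynamic_range))  # uniform floor
  # linear lateral interpolation never escapes neighboring line values
  set.seed(7)
  rf <- synthetic_rfdata(n_samp = 120L,
                         fill = function(a) array(runif(length(a)), dim(a)))
  lo <- compose_bscan(rf, interp = 1L)
  hi <- compose_bscan(rf, interp = 4L)
  lin_lo <- 10^(lo$intensity / 20); lin_hi <- 10^(hi$intensity / 20)
  for (k in seq_len(ncol(lin_lo) - 1)) {
    seg <- lin_hi[, (4 * (k - 1) + 1):(4 * k + 1)]
    lo_pair <- pmin(lin_lo[, k], lin_lo[, k + 1])
    hi_pair <- pmax(lin_lo[, k], lin_lo[, k + 1])
    expect_true(all(seg >= lo_pair * (1 - 1e-6) & seg <= hi_pair * (1 + 1e-6)))
  }
  # both processing orders accept the same dataset
  expect_s3_class(compose_bscan(rf, order = "conventional"), "lus_bscan")
})
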