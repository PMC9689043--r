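# shared fixtures built in code

# homogeneous material block
homog_material <- function(nx, ny, dx, c0 = 1570, rho0 = 1090, x0 = 0) {
  list(velocity = matrix(c0, nx, ny), density = matrix(rho0, nx, ny),
       grid = acoustic_grid(nx, ny, dx, dx, x0 = x0))
}

# arrival time of the strongest event via envelope cross-correlation with
# the source-pulse envelope (robust to carrier-phase dispersion)
arrival_time <- function(trace, dt, pulse) {
  env <- envelope(trace)
  tt <- seq(0, pulse$duration, by = dt)
  senv <- envelope(pulse_waveform(tt, pulse))
  senv <- c(senv, numeric(length(env) - length(senv)))
  cc <- stats::ccf(env, senv, lag.max = length(env) - 1, plot = FALSE)
  cc$lag[which.max(cc$acf)] * dt
}

# signed correlation between two gated events, aligning envelope peaks and
# searching sub-cycle lags for the strongest carrier alignment
signed_echo_corr <- function(trace, t, gate_ref, gate_echo, dt, f0) {
  i1 <- which(t >= gate_ref[1] & t < gate_ref[2])
  i2 <- which(t >= gate_echo[1] & t < gate_echo[2])
  env <- envelope(trace)
  p1 <- i1[which.max(env[i1])]
  p2 <- i2[which.max(env[i2])]
  n <- round(2.5 / f0 / dt)
  best <- 0
  for (L in -round(0.45 / f0 / dt):round(0.45 / f0 / dt)) {
    a <- trace[(p1 - n):(p1 + n)]
    b <- trace[(p2 - n + L):(p2 + n + L)]
    cc <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    if (abs(cc) > abs(best)) best <- cc
  }
  best
}

# tiny end-to-end configuration (healthy slab, 6 elements, seconds to run)
toy_config <- function(...) {
  experiment_config(variant = "NONE", G = 0, scale = "desk",
                    muscle_width = 8e-3, muscle_height = 6e-3,
                    pml_width = 2e-3, n_elements = 6L, ppw = 6,
                    t_end = 12e-6, ...)
}

# desk-scale acceptance runs are expensive; compute once per test session
desk_cache <- new.env(parent = emptyenv())
desk_run <- function(key) {
  if (!is.null(desk_cache[[key]])) return(desk_cache[[key]])
  cfg <- switch(key,
    A0 = experiment_config(variant = "A", G = 0, scale = "desk"),
    B0 = experiment_config(variant = "B", G = 0, scale = "desk"),
    control = experiment_config(variant = "NONE", G = 0, scale = "desk"))
  desk_cache[[key]] <- run_experiment(cfg)
  desk_cache[[key]]
}
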