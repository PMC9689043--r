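test_that("Courant number predicate matches the closed form", {
  m <- homog_material(2, 2, 1e-4)
  st <- check_stability(m, dt_internal = 1e-8, cfl_number = 0.5)
  expect_equal(st$courant, 1570 * 1e-8 * sqrt(2) / 1e-4, tolerance = 1e-12)
  expect_true(st$pass)
  expect_true(check_stability(m, dt_internal = 0)$pass)  # degenerate
})

test_that("empirical stability bound brackets the 4th-order limit", {
  nx <- 50L; ny <- 50L; dx <- 1e-4; c0 <- 1570
  v <- matrix(c0, nx, ny); d <- matrix(1090, nx, ny)
  lim <- (6 / 7) / (c0 * sqrt(2) / dx)
  run_at <- function(f) {
    sw <- matrix(c(rep(1, 20), numeric(1980)), 2000, 1)
    lusim:::fdtd_run_cpp(v, d, dx, dx, f * lim, 2000L, 10L, list(1275L), sw,
                         list(1275L), numeric(nx), numeric(nx + 1),
                         FALSE, FALSE, 50L)
  }
  expect_identical(run_at(0.95)$blowup_step, -1L)
  expect_gt(run_at(1.05)$blowup_step, 0L)
})

test_that("homogeneous travel time matches distance over sound speed", {
  c0 <- 1570; f0 <- 2e6; dx <- (c0 / f0) / 14
  nx <- ceiling(0.036 / dx); ny <- ceiling(0.016 / dx)
  m <- homog_material(nx, ny, dx, x0 = -nx * dx / 2)
  x <- grid_x(m$grid)
  pu <- pulse_spec(f0)
  tr <- run_forward(m,
                    list(list(cells = cbind(which.min(abs(x + 0.005)), 1L),
                              pulse = pu)),
                    solver_config(t_end = 9.5e-6),
                    list(list(cells = cbind(which.min(abs(x - 0.005)), 1L))),
                    pml_width = 0, top_release = FALSE)
  arr <- arrival_time(tr$traces[, 1], tr$dt, pu)
  expect_lt(abs(arr - 0.010 / c0) / (0.010 / c0), 0.02)
})

test_that("first-arrival time converges under grid refinement", {
  c0 <- 1570; f0 <- 2e6
  arr <- vapply(c(10, 20), function(ppw) {
    dx <- (c0 / f0) / ppw
    nx <- ceiling(0.030 / dx); ny <- ceiling(0.012 / dx)
    m <- homog_material(nx, ny, dx, x0 = -nx * dx / 2)
    x <- grid_x(m$grid)
    pu <- pulse_spec(f0)
    tr <- run_forward(m,
                      list(list(cells = cbind(which.min(abs(x + 0.004)), 1L),
                                pulse = pu)),
                      solver_config(t_end = 8.5e-6),
                      list(list(cells = cbind(which.min(abs(x - 0.004)), 1L))),
                      pml_width = 0, top_release = FALSE)
    arrival_time(tr$traces[, 1], tr$dt, pu)
  }, 0)
  expect_lt(abs(arr[2] - arr[1]) / arr[2], 0.005)
})

test_that("two-layer normal-incidence reflection matches impedance theory", {
  c1 <- 1570; r1 <- 1090; c2 <- 1500; r2 <- 1000
  R_theory <- (c2 * r2 - c1 * r1) / (c2 * r2 + c1 * r1)
  f0 <- 2e6; dx <- (c1 / f0) / 12
  W <- 0.040; pml <- 5e-3
  nx <- ceiling((W + 2 * pml) / dx); ny <- 8L
  g <- acoustic_grid(nx, ny, dx, dx, x0 = -(W / 2 + pml))
  x <- grid_x(g)
  v <- matrix(c1, nx, ny); d <- matrix(r1, nx, ny)
  v[x >= 0, ] <- c2; d[x >= 0, ] <- r2
  m <- list(velocity = v, density = d, grid = g)
  allj <- seq_len(ny)
  tr <- run_forward(m,
                    list(list(cells = cbind(which.min(abs(x + 0.015)), allj),
                              pulse = pulse_spec(f0))),
                    solver_config(t_end = 22e-6),
                    list(list(cells = cbind(which.min(abs(x + 0.010)), allj))),
                    pml_width = pml, top_release = FALSE)
  env <- envelope(tr$traces[, 1]); tt <- tr$t
  ratio <- max(env[tt > 13e-6 & tt < 21e-6]) / max(env[tt < 9e-6])
  expect_lt(abs(ratio - abs(R_theory)) / abs(R_theory), 0.02)
})

test_that("pressure-release top inverts the echo; rigid face does not", {
  c0 <- 1570; f0 <- 2e6; dx <- (c0 / f0) / 20
  ny <- ceiling(0.016 / dx); nx <- 8L
  m <- homog_material(nx, ny, dx)
  y <- grid_y(m$grid)
  js <- which.min(abs(y - 0.005))
  tr <- run_forward(m,
                    list(list(cells = cbind(1:nx, js), pulse = pulse_spec(f0))),
                    solver_config(t_end = 20e-6),
                    list(list(cells = cbind(1:nx, js))),
                    pml_width = 0, top_release = TRUE)
  w <- tr$traces[, 1]
  # source pulse centered 2.25 us; rigid-face echo (10 mm path) at 8.6 us;
  # release-top echo (22 mm path) at 16.3 us
  expect_gt(signed_echo_corr(w, tr$t, c(0, 5.5e-6), c(6.5e-6, 12e-6),
                             tr$dt, f0), 0.9)
  expect_lt(signed_echo_corr(w, tr$t, c(0, 5.5e-6), c(13.5e-6, 19.5e-6),
                             tr$dt, f0), -0.9)
})

test_that("traces are linear in the source and zero without one", {
  m <- homog_material(80, 60, 1e-4)
  src <- function(a) list(list(cells = cbind(40L, 1L),
                               waveform = function(t)
                                 a * pulse_waveform(t, pulse_spec(2e6))))
  rec <- list(list(cells = cbind(60L, 1L)))
  cfg <- solver_config(t_end = 6e-6)
  t1 <- run_forward(m, src(1), cfg, rec, pml_width = 0)$traces
  t3 <- run_forward(m, src(3), cfg, rec, pml_width = 0)$traces
  expect_equal(t3, 3 * t1, tolerance = 1e-12)
  t0 <- run_forward(m, src(0), cfg, rec, pml_width = 0)$traces
  expect_true(all(t0 == 0))
})

test_that("point-source/point-receiver reciprocity holds in a uniform medium", {
  m <- homog_material(160, 120, 7.85e-5)
  cfg <- solver_config(t_end = 12e-6)
  run <- function(s, r)
    run_forward(m, list(list(cells = cbind(s[1], s[2]),
                             pulse = pulse_spec(2e6))),
                cfg, list(list(cells = cbind(r[1], r[2]))),
                pml_width = 0, top_release = FALSE)$traces[, 1]
  t1 <- run(c(40L, 30L), c(120L, 90L))
  t2 <- run(c(120L, 90L), c(40L, 30L))
  expect_lt(max(abs(t1 - t2)) / max(abs(t1)), 1e-10)
})

test_that("repeated solves are bit-identical", {
  m <- homog_material(60, 40, 1e-4)
  cfg <- solver_config(t_end = 4e-6)
  args <- list(m, list(list(cells = cbind(30L, 1L), pulse = pulse_spec(2e6))),
               cfg, list(list(cells = cbind(45L, 1L))))
  a <- do.call(run_forward, c(args, pml_width = 0))
  b <- do.call(run_forward, c(args, pml_width = 0))
  expect_identical(a$traces, b$traces)
})

test_that("absorbing strips attenuate and hard walls reflect", {
  pml <- measure_pml_reflection()
  expect_lt(pml$reflection_db, -30)
  wall <- measure_pml_reflection(pml_width = 0)
  expect_gt(wall$reflection_db, -3)
  weak <- measure_pml_reflection(pml_atten_db = 20)
  expect_gt(weak$reflection_db, pml$reflection_db)  # stronger profile absorbs more
  wide <- measure_pml_reflection(pml_width = 10e-3)
  expect_lt(wide$reflection_db, pml$reflection_db + 1)  # never worse
})

test_that("discrete acoustic energy decays once the source is off", {
  m <- homog_material(160, 120, 7.85e-5)
  cfg <- solver_config(t_end = 30e-6, record_energy = TRUE)
  tr <- run_forward(m, list(list(cells = cbind(80L, 60L),
                                 pulse = pulse_spec(2e6))),
                    cfg, list(list(cells = cbind(80L, 60L))),
                    pml_width = 5e-3, top_release = FALSE)
  e <- tr$energy
  after <- tr$t > 5e-6                   # pulse ends at 4.5 us
  expect_lt(max(diff(e[after])), 5e-3 * max(e))  # no spurious growth
  expect_lt(e[length(e)], 0.15 * max(e))         # strips drained the field
})

test_that("a diverging run aborts with the step index", {
  # dx chosen so a single sub-step lands the Courant number at 0.94 --
  # inside the user-allowed cfl_number but above the scheme's 6/7 limit
  m <- homog_material(60, 60, 4.7e-5)
  expect_error(run_forward(m, list(list(cells = cbind(30L, 1L),
                                        pulse = pulse_spec(2e6))),
                           solver_config(t_end = 50e-6, cfl_number = 0.95),
                           list(list(cells = cbind(30L, 1L))),
                           pml_width = 0),
               "diverged.*step")
})
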