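test_that("random fields are bounded, peak-normalized and seeded", {
  g <- acoustic_grid(60, 40, 1e-4)
  for (seed in c(1L, 42L, 99L)) {
    f <- generate_random_field(g, field_spectrum_params(k_max = 2000,
                                                        seed = seed))
    expect_equal(max(abs(f$values)), 1)
    expect_true(all(f$values >= -1 & f$values <= 1))
  }
  p <- field_spectrum_params(k_max = 2000, seed = 7L)
  expect_identical(generate_random_field(g, p)$values,
                   generate_random_field(g, p)$values)
  p2 <- field_spectrum_params(k_max = 2000, seed = 8L)
  expect_false(identical(generate_random_field(g, p)$values,
                         generate_random_field(g, p2)$values))
})

test_that("material bounds hold over many texture seeds", {
  g <- acoustic_grid(40, 30, 1e-4)
  for (seed in seq_len(200)) {
    f <- generate_random_field(g, field_spectrum_params(n_modes = 50,
                                                        k_max = 2000,
                                                        seed = seed))
    ldz <- ldz_material(f)
    expect_true(all(ldz$velocity >= 640 & ldz$velocity <= 1500))
    expect_true(all(ldz$density >= 430 & ldz$density <= 1000))
  }
})

test_that("spectrum parameters are validated", {
  g <- acoustic_grid(30, 30, 1e-3)  # Nyquist 500 cycles/m
  expect_error(generate_random_field(g, field_spectrum_params(k_max = 2000,
                                                              seed = 1)),
               "Nyquist")
  expect_error(field_spectrum_params(n_modes = 0, k_max = 100))
  expect_error(field_spectrum_params(k_min = 200, k_max = 100))
})

test_that("infiltrated-lung material maps hit the published endpoints", {
  ex <- ldz_material(matrix(0, 2, 2))
  expect_equal(unique(as.vector(ex$velocity)), 1070)
  expect_equal(unique(as.vector(ex$density)), 715)
  hi <- ldz_material(matrix(1, 2, 2))
  expect_equal(unique(as.vector(hi$velocity)), 1500)
  expect_equal(unique(as.vector(hi$density)), 1000)
  lo <- ldz_material(matrix(-1, 2, 2))
  expect_equal(unique(as.vector(lo$velocity)), 640)
  expect_equal(unique(as.vector(lo$density)), 430)
  expect_error(ldz_material(matrix(1.5, 2, 2)), "\\[-1, 1\\]")
})

test_that("muscle material maps follow the G-scaled law", {
  g0 <- muscle_material(matrix(runif(16, -1, 1), 4, 4), G = 0)
  expect_true(all(g0$velocity == 1570) && all(g0$density == 1090))
  expect_equal(unique(as.vector(muscle_material(matrix(1, 2, 2), 10)$velocity)),
               1580)
  expect_equal(unique(as.vector(muscle_material(matrix(1, 2, 2), 10)$density)),
               1100)
  hi <- muscle_material(matrix(-1, 2, 2), 5)
  expect_equal(unique(as.vector(hi$velocity)), 1565)
  expect_equal(unique(as.vector(hi$density)), 1085)
  expect_error(muscle_material(matrix(0, 2, 2), G = -1))
})

test_that("G-monotonicity: peak muscle deviation equals G exactly", {
  g <- acoustic_grid(80, 50, 1e-4)
  f <- generate_random_field(g, field_spectrum_params(k_max = 2000, seed = 3))
  for (G in c(0, 5, 10)) {
    m <- muscle_material(f, G)
    expect_equal(max(abs(m$velocity - 1570)), G)
    expect_equal(max(abs(m$density - 1090)), G)
  }
})

test_that("phantom assembly fills muscle and LDZ with the right textures", {
  ph <- build_phantom(scenario_geometry("A"), G = 0, seeds = c(5L, 6L),
                      ppw = 5)
  expect_true(all(ph$velocity[!ph$ldz_mask] == 1570))
  expect_true(all(ph$density[!ph$ldz_mask] == 1090))
  v_ldz <- ph$velocity[ph$ldz_mask]
  expect_true(all(v_ldz >= 640 & v_ldz <= 1500))
  expect_lt(min(v_ldz), 800)     # texture spans a wide part of its range
  expect_gt(max(v_ldz), 1400)
  # ellipse touches the pleural boundary and is centered
  y_top <- max(grid_y(ph$grid)[colSums(ph$ldz_mask) > 0])
  expect_gt(y_top, 0.010 - 2 * ph$grid$dy)
})

test_that("degenerate geometry reduces to a pure muscle slab", {
  ph <- build_phantom(scenario_geometry("NONE"), G = 5, seeds = c(1L, 2L),
                      ppw = 5)
  expect_equal(sum(ph$ldz_mask), 0L)
  expect_true(all(abs(ph$velocity - 1570) <= 5))
  # an ellipse pushed outside the slab is rejected at construction
  expect_error(scenario_geometry("A", ldz_center_x = 0.030), "outside")
})

test_that("rasterized LDZ area matches the analytic ellipse area", {
  geom <- scenario_geometry("A")   # 10 x 5 mm ellipse
  grid <- acoustic_grid(600, 100, 1e-4, 1e-4, x0 = -0.030)
  ph <- build_phantom(geom, grid = grid, G = 0, seeds = c(1L, 2L))
  area <- sum(ph$ldz_mask) * grid$dx * grid$dy
  analytic <- pi * 5e-3 * 2.5e-3
  expect_lt(abs(area - analytic) / analytic, 0.03)
})

test_that("phantoms regenerate bit-identically from config and seeds", {
  a <- build_phantom(scenario_geometry("B"), G = 5, seeds = c(9L, 10L),
                     ppw = 5)
  b <- build_phantom(scenario_geometry("B"), G = 5, seeds = c(9L, 10L),
                     ppw = 5)
  expect_identical(a$velocity, b$velocity)
  expect_identical(a$density, b$density)
  expect_identical(a$ldz_mask, b$ldz_mask)
})

test_that("material map container round-trips", {
  ph <- build_phantom(scenario_geometry("B"), G = 5, seeds = c(3L, 4L),
                      ppw = 4)
  path <- tempfile(fileext = ".rds")
  write_material_map(ph, path)
  back <- read_material_map(path)
  expect_identical(back$velocity, ph$velocity)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$variant, "B")
  unlink(c(path, paste0(path, ".json")))
})
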