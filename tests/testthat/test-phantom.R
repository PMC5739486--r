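test_that("phantom specs validate their fields with informative errors", {
  expect_error(phantom_spec(grid_n = 4), "grid_n")
  expect_error(phantom_spec(fov_mm = -1), "fov_mm")
  expect_error(phantom_spec(background_mu = -0.1), "background_mu")
  expect_error(phantom_spec(ellipses = data.frame(cx_mm = 0)), "lacks column")
  bad <- data.frame(cx_mm = 0, cy_mm = 0, a_mm = -1, b_mm = 1,
                    angle_deg = 0, delta_mu = 0.1)
  expect_error(phantom_spec(ellipses = bad), "axes must be positive")
})

test_that("rasterized disk matches its analytic area and value", {
  # [DERIVED] pixel-centre membership count of a disk approximates pi r^2
  spec <- phantom_catalog("disk", grid_n = 256L, fov_mm = 200)
  ph <- generate_phantom(spec)
  px <- ph$pixel_size_mm
  n_inside <- sum(ph$values > 0)
  area_analytic <- pi * 50^2 / px^2
  expect_lt(abs(n_inside - area_analytic) / area_analytic, 0.01)
  expect_setequal(unique(as.vector(ph$values)), c(0, 0.02))
  # centre pixel carries the disk value
  expect_equal(ph$values[128, 128], 0.02)
})

test_that("overlapping negative ellipses never drive attenuation below zero", {
  ell <- data.frame(cx_mm = c(0, 0), cy_mm = c(0, 0), a_mm = c(40, 20),
                    b_mm = c(40, 20), angle_deg = c(0, 0),
                    delta_mu = c(0.01, -0.05))
  ph <- generate_phantom(phantom_spec(grid_n = 64L, fov_mm = 100,
                                      ellipses = ell))
  expect_true(all(ph$values >= 0))
  expect_equal(ph$values[32, 32], 0)   # 0.01 - 0.05 clipped
})

test_that("random phantoms are reproducible from (spec, seed) and distinct across seeds", {
  spec <- random_phantom_spec(grid_n = 64L)
  a <- generate_phantom(spec, seed = 7L)
  b <- generate_phantom(spec, seed = 7L)
  c <- generate_phantom(spec, seed = 8L)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_true(all(a$values >= 0))
})

test_that("random family always contains the body disk and dense inserts", {
  spec <- random_phantom_spec(grid_n = 64L)
  for (s in 1:5) {
    ph <- generate_phantom(spec, seed = s)
    # centre is inside the body disk
    expect_gte(ph$values[32, 32], spec$random$body_mu - 0.012 - 1e-12)
    # at least one pixel reaches bone-level attenuation
    expect_gt(max(ph$values), spec$random$body_mu + spec$random$bone_delta[1] - 1e-9)
  }
})

test_that("ellipse rotation enters the membership test", {
  e <- data.frame(cx_mm = 0, cy_mm = 0, a_mm = 40, b_mm = 10,
                  angle_deg = 0, delta_mu = 0.01)
  flat <- generate_phantom(phantom_spec(grid_n = 64L, fov_mm = 100,
                                        ellipses = e))
  e$angle_deg <- 90
  tall <- generate_phantom(phantom_spec(grid_n = 64L, fov_mm = 100,
                                        ellipses = e))
  # a 90-degree rotation transposes the raster of a centred ellipse
  expect_equal(tall$values, t(flat$values))
  expect_false(identical(flat$values, tall$values))
})

test_that("phantom specs survive a JSON round trip", {
  spec <- phantom_catalog("two_disk", grid_n = 64L)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  phantom_spec_to_json(spec, path)
  back <- phantom_spec_from_json(path)
  expect_equal(back$grid_n, spec$grid_n)
  expect_equal(back$fov_mm, spec$fov_mm)
  expect_equal(as.data.frame(back$ellipses), as.data.frame(spec$ellipses))
  expect_identical(generate_phantom(back)$values,
                   generate_phantom(spec)$values)
})
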