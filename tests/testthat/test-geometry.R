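test_that("proportionality factors reproduce the published machine values", {
  geo <- linac_geometry(d_epi = 1000)
  expect_equal(signif(proportionality_factor(geo, "X"), 4), 2.368)
  expect_equal(signif(proportionality_factor(geo, "X", d_epi = 1050), 5),
               2.2556)
  expect_equal(signif(proportionality_factor(geo, "Y"), 4), 0.9141)
  expect_equal(signif(proportionality_factor(geo, "Y", d_epi = 1050), 4),
               0.8706)
})

test_that("ion-chamber lever arms and jaw-plane projection match the quoted values", {
  geo <- linac_geometry(d_epi = 1000)
  expect_equal(signif(ic_lever_arm(geo, "Y"), 3), 1.74)
  expect_equal(signif(ic_lever_arm(geo, "X"), 3), 2.18)
  expect_equal(jaw_plane_shift(1, 406), 0.406)
  expect_equal(jaw_plane_shift(1, 319), 0.319)
  expect_equal(jaw_plane_shift(0, 406), 0)
})

test_that("degenerate geometries are rejected", {
  expect_error(linac_geometry(d_epi = 1000, d_jaw_x = 490, d_mlc = 490),
               "degenerate")
  expect_error(linac_geometry(d_epi = 1000, d_ic = 300),
               "chamber")
  expect_error(linac_geometry(d_epi = 1000, d_mlc = 1200), "detector")
  expect_error(linac_geometry(d_epi = -5), "positive")
})

test_that("offset_from_separation is the plain product", {
  expect_equal(offset_from_separation(0, 2.368), 0)
  expect_equal(offset_from_separation(0.1, 2.368), 0.2368)
})

test_that("projection geometry closes the round trip to 1e-9 mm", {
  set.seed(42)
  for (i in 1:20) {
    geo <- linac_geometry(d_epi = runif(1, 900, 1600),
                          d_jaw_x = runif(1, 350, 450),
                          d_jaw_y = runif(1, 280, 340),
                          d_mlc = runif(1, 460, 520))
    s <- runif(1, -0.5, 0.5)
    for (ax in c("X", "Y")) {
      d_jaw <- if (ax == "X") geo$d_jaw_x else geo$d_jaw_y
      sep <- project_center(s, geo$d_mlc, geo$d_epi) -
        project_center(s, d_jaw, geo$d_epi)
      a <- proportionality_factor(geo, ax)
      expect_equal(offset_from_separation(sep, a), s, tolerance = 1e-9)
    }
  }
})

test_that("project_center agrees with the independent ray-trace oracle", {
  for (s in c(-0.3, 0, 0.1, 0.5)) {
    for (d_col in c(319, 406, 490)) {
      h <- 50 * d_col / 1000  # symmetric aperture centred on the axis
      oracle <- ray_trace_center(s, c(-h, h), d_col, 1000)
      expect_equal(project_center(s, d_col, 1000), oracle,
                   tolerance = 1e-6)
    }
  }
})

test_that("dimensionless factors are invariant to a global scale of distances", {
  geo1 <- linac_geometry(d_epi = 1000)
  geo2 <- linac_geometry(d_epi = 2000, d_jaw_x = 812, d_jaw_y = 638,
                         d_mlc = 980, d_ic = 1500, sad = 2000)
  for (ax in c("X", "Y")) {
    expect_equal(proportionality_factor(geo1, ax),
                 proportionality_factor(geo2, ax))
    expect_equal(ic_lever_arm(geo1, ax), ic_lever_arm(geo2, ax))
  }
})

test_that("a 1 mm SID calibration error moves a 0.5 mm offset by well under 0.002 mm", {
  # the separation is measured in detector mm; only the factor a uses the
  # (possibly miscalibrated) SID
  geo <- linac_geometry(d_epi = 1000)
  s <- 0.5
  for (ax in c("X", "Y")) {
    d_jaw <- if (ax == "X") geo$d_jaw_x else geo$d_jaw_y
    sep <- project_center(s, geo$d_mlc, 1000) -
      project_center(s, d_jaw, 1000)
    for (de in c(999, 1001)) {
      rec <- sep * proportionality_factor(geo, ax, d_epi = de)
      expect_lt(abs(rec - s), 0.002)
    }
  }
})

test_that("geometry YAML config loads with unit conversion and validates keys", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units: cm", "d_epi: 100", "d_jaw_x: 40.6", "d_jaw_y: 31.9",
               "d_mlc: 49", "d_ic: 75", "sad: 100"), p)
  geo <- read_geometry_config(p)
  expect_equal(geo$d_epi, 1000)
  expect_equal(geo$d_jaw_y, 319)
  expect_equal(signif(proportionality_factor(geo, "X"), 4), 2.368)

  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units: mm", "d_epi: 1000"), p2)
  expect_error(read_geometry_config(p2), "missing keys")
})

test_that("implausibly large offsets warn but are not errors", {
  expect_warning(offset_vector(4, 4), "implausible")
  expect_silent(offset_vector(0.1, -0.4))
  expect_error(offset_vector(Inf, 0), "finite")
})
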