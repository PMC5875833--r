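test_that("upsampling reaches the common 0.0392 mm effective pitch for both panels", {
  set.seed(1)
  mk <- function(pitch) {
    px <- matrix(runif(40 * 40, 10, 100), 40, 40)
    px[15:25, 15:25] <- 1000
    epid_image(px, pitch, 1000, 90, "JAW")
  }
  pp <- preprocess(mk(0.784))
  expect_equal(pp$factor, 20L)
  expect_equal(pp$effective_pitch, 0.0392)
  pp2 <- preprocess(mk(0.392))
  expect_equal(pp2$factor, 10L)
  expect_equal(pp2$effective_pitch, 0.0392)
})

test_that("normalization maps the image onto [0, 1] and rejects flat images", {
  set.seed(2)
  px <- matrix(runif(30 * 30, 50, 400), 30, 30)
  img <- epid_image(px, 0.784, 1000, 90, "JAW")
  # factor 1: no resampling, so the output is exactly the scaled image
  pp <- preprocess(img, analysis_params(median_kernel = 1,
                                        target_effective_pitch = 0.784))
  expect_equal(pp$factor, 1L)
  expect_equal(min(pp$pixels), 0)
  expect_equal(max(pp$pixels), 1)
  flat <- epid_image(matrix(7, 20, 20), 0.784, 1000, 90, "JAW")
  expect_error(preprocess(flat), "degenerate image")
})

test_that("the 3x3 median filter matches a brute-force median on random images", {
  set.seed(3)
  x <- matrix(rnorm(15 * 12), 15, 12)
  got <- focalspot:::median_filter2d(x, 3L)
  ref <- matrix(NA_real_, 15, 12)
  for (r in 1:15) for (cl in 1:12) {
    rr <- pmin(pmax(r + (-1:1), 1), 15)
    cc <- pmin(pmax(cl + (-1:1), 1), 12)
    ref[r, cl] <- median(as.vector(x[rr, cc]))
  }
  expect_equal(got, ref)
})

test_that("a binary rectangle yields the enumerated centre exactly", {
  m <- matrix(0, 512, 512)
  m[151:350, 101:355] <- 1  # columns 100..354 zero-based
  fc <- find_field_center(m, effective_pitch = 0.0392)
  expect_equal(fc$u, ((100 + 354) / 2 + 0.5 - 256) * 0.0392, tolerance = 1e-12)
  expect_equal(fc$v, ((150 + 349) / 2 + 0.5 - 256) * 0.0392, tolerance = 1e-12)
  # centred rectangle maps to the origin by symmetry
  m2 <- matrix(0, 400, 400)
  m2[101:300, 151:250] <- 1
  fc2 <- find_field_center(m2, effective_pitch = 0.05)
  expect_equal(fc2$u, 0, tolerance = 1e-12)
  expect_equal(fc2$v, 0, tolerance = 1e-12)
})

test_that("degenerate masks raise no-field and field-clipped errors", {
  expect_error(find_field_center(matrix(0, 50, 50), effective_pitch = 0.1),
               "no field")
  tiny <- matrix(0, 100, 100); tiny[50:51, 50] <- 1  # < 1% of frame
  expect_error(find_field_center(tiny, effective_pitch = 0.1), "no field")
  clip <- matrix(0, 50, 50); clip[1:30, 10:40] <- 1
  expect_error(find_field_center(clip, effective_pitch = 0.1), "clipped")
})

test_that("an erf-penumbra field with a known centre is recovered within 0.01 mm", {
  # both Y banks displaced by the same amount move the projected centre to
  # m * d_epi / d_jaw_y = 0.25 mm without involving the source offset
  m_bank <- 0.25 * 319 / 1000
  cfg <- test_cfg(miscalibration = c(Y1 = m_bank, Y2 = m_bank))
  img <- render_image(cfg, "JAW", 90)
  fc <- find_field_center(preprocess(img))
  expect_lt(abs(fc$u - 0.25), 0.01)
  expect_lt(abs(fc$v), 0.01)
})

test_that("find_field_center is translation-equivariant on the upsampled grid", {
  cfg <- test_cfg()
  pp <- preprocess(render_image(cfg, "MLC", 90))
  base <- find_field_center(pp)
  for (k in c(3L, 40L)) {
    shifted <- pp
    n <- ncol(pp$pixels)
    shifted$pixels <- pp$pixels[, c((n - k + 1):n, 1:(n - k))]
    fc <- find_field_center(shifted)
    expect_equal(fc$u - base$u, k * pp$effective_pitch, tolerance = 1e-9)
    expect_equal(fc$v, base$v, tolerance = 1e-9)
  }
})

test_that("pair averaging cancels aperture miscalibration", {
  expect_equal(
    pair_centroid(structure(list(u = 0.1, v = 0, source_tag = "a"),
                            class = "field_center"),
                  structure(list(u = -0.1, v = 0, source_tag = "b"),
                            class = "field_center"))$u, 0)
  expect_equal(
    pair_centroid(structure(list(u = 0.08, v = -0.02, source_tag = "a"),
                            class = "field_center"),
                  structure(list(u = 0.06, v = -0.04, source_tag = "b"),
                            class = "field_center"))[c("u", "v")],
    list(u = 0.07, v = -0.03))
  # zero focal offset + one shifted jaw bank: the pair centroid stays at 0
  cfg <- test_cfg(miscalibration = c(Y1 = 0.5))
  c90 <- find_field_center(preprocess(render_image(cfg, "JAW", 90)))
  c270 <- find_field_center(preprocess(render_image(cfg, "JAW", 270)))
  pc <- pair_centroid(c90, c270)
  expect_lt(abs(pc$u), 0.01)
  expect_lt(abs(pc$v), 0.01)
  expect_gt(abs(c90$u), 0.5)  # each single image is strongly displaced
})

test_that("centroid separation inverts the proportionality factor on simulation", {
  expect_equal(centroid_separation(
    structure(list(u = 0, v = 0), class = "field_center"),
    structure(list(u = 0.10, v = 0), class = "field_center"))[["u"]], 0.10)
  cfg <- test_cfg(inplane = 0.2)  # inplane is the X-jaw direction
  m <- measure_sim(cfg)
  expect_lt(abs(m$separation[["v"]] - 0.2 / 2.3683), 0.01)
})

test_that("the recovered offset is robust to the binarization threshold", {
  cfg <- test_cfg(crossplane = 0.3, inplane = -0.2)
  set <- render_measurement_set(cfg)
  offs <- lapply(c(0.45, 0.5, 0.55), function(thr) {
    measure_focal_spot(set, cfg$geometry,
                       params = analysis_params(threshold = thr))$offset
  })
  for (i in c(1, 3)) {
    expect_lt(max(abs(offs[[i]] - offs[[2]])), 0.01)
  }
})

test_that("a lateral detector shift common to all four images leaves the offset unchanged", {
  cfg <- test_cfg(crossplane = 0.15, inplane = -0.25)
  set <- render_measurement_set(cfg)
  roll <- function(img, k) {
    n <- ncol(img$pixels)
    img$pixels <- img$pixels[, c((n - k + 1):n, 1:(n - k))]
    img
  }
  shifted <- measurement_set(roll(set$jaw_90, 5L), roll(set$jaw_270, 5L),
                             roll(set$mlc_90, 5L), roll(set$mlc_270, 5L))
  m0 <- measure_focal_spot(set, cfg$geometry)
  m1 <- measure_focal_spot(shifted, cfg$geometry)
  expect_equal(as.numeric(m1$offset), as.numeric(m0$offset),
               tolerance = 1e-6)
})
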