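sample_image <- function(pitch = 0.392, angle = 90, system = "JAW",
                         nr = 32L, nc = 48L, seed = 5L) {
  set.seed(seed)
  px <- matrix(sample.int(60000L, nr * nc, replace = TRUE), nr, nc)
  epid_image(px, pixel_pitch = pitch, sid = 1000, collimator_angle = angle,
             defining_system = system)
}

test_that("epid_image enforces its invariants", {
  expect_error(epid_image(matrix(-1, 2, 2), 0.392, 1000, 90, "JAW"),
               "non-negative")
  expect_error(epid_image(matrix(1, 2, 2), 0.392, 1000, 45, "JAW"),
               "90 or 270")
  expect_warning(epid_image(matrix(1, 2, 2), 0.5, 1000, 90, "JAW"),
                 "standard panel pitches")
})

test_that("measurement_set checks slots, pitch and SID consistency", {
  j90 <- sample_image(angle = 90, system = "JAW")
  j270 <- sample_image(angle = 270, system = "JAW")
  m90 <- sample_image(angle = 90, system = "MLC")
  m270 <- sample_image(angle = 270, system = "MLC")
  expect_s3_class(measurement_set(j90, j270, m90, m270), "measurement_set")
  expect_error(measurement_set(j90, j270, m270, m90), "expected MLC at 90")
  bad <- sample_image(angle = 270, system = "MLC")
  bad$sid <- 1001
  expect_error(measurement_set(j90, j270, m90, bad), "SID")
})

test_that("raw TIFF + sidecar round-trips pixels bit-exactly with metadata", {
  img <- sample_image()
  p <- withr::local_tempfile(fileext = ".tif")
  write_raw_with_sidecar(img, p)
  back <- read_raw_with_sidecar(p)
  expect_identical(back$pixels, img$pixels * 1)
  expect_equal(back$pixel_pitch, img$pixel_pitch, tolerance = 1e-6)
  expect_equal(back$sid, img$sid, tolerance = 1e-6)
  expect_equal(back$collimator_angle, img$collimator_angle)
  expect_equal(back$defining_system, img$defining_system)
})

test_that("a sidecar missing required keys is rejected by name", {
  img <- sample_image()
  p <- withr::local_tempfile(fileext = ".tif")
  write_raw_with_sidecar(img, p)
  sc <- paste0(tools::file_path_sans_ext(p), ".yaml")
  meta <- yaml::read_yaml(sc)
  meta$defining_system <- NULL
  yaml::write_yaml(meta, sc)
  expect_error(read_raw_with_sidecar(p), "defining_system")
})

test_that("DICOM RT Image write-then-read is an identity on pixels and metadata", {
  for (pitch in c(0.392, 0.784)) {
    img <- sample_image(pitch = pitch, angle = 270, system = "MLC")
    p <- withr::local_tempfile(fileext = ".dcm")
    write_dicom_rt_image(img, p)
    back <- read_dicom_rt_image(p)
    expect_identical(back$pixels, img$pixels * 1)
    expect_equal(back$pixel_pitch, pitch, tolerance = 1e-6)
    expect_equal(back$sid, 1000, tolerance = 1e-6)
    expect_equal(back$collimator_angle, 270)
    expect_equal(back$defining_system, "MLC")
  }
})

test_that("missing SID and unsupported collimator angles are rejected", {
  img <- sample_image()
  p <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_rt_image(img, p)
  bytes <- readBin(p, raw(), file.size(p))
  # strip the RTImageSID element (3002,0026): rebuild without it
  strip_tag <- function(bytes, group, element) {
    hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                    endian = "little")
    hits <- which(bytes == hdr[1])
    for (i in hits) {
      if (i + 3 <= length(bytes) && identical(bytes[i:(i + 3)], hdr)) {
        len <- readBin(bytes[(i + 6):(i + 7)], "integer", size = 2L,
                       signed = FALSE, endian = "little")
        return(bytes[-(i:(i + 7 + len))])
      }
    }
    bytes
  }
  p2 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(strip_tag(bytes, 0x3002, 0x0026), p2)
  expect_error(read_dicom_rt_image(p2), "RTImageSID")

  img0 <- sample_image()
  img0$collimator_angle <- 90
  p3 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_rt_image(img0, p3)
  b <- readBin(p3, raw(), file.size(p3))
  # rewrite the beam-limiting-device angle to 0 (same DS payload length)
  hdr <- writeBin(as.integer(c(0x300A, 0x0120)), raw(), size = 2L,
                  endian = "little")
  for (i in which(b == hdr[1])) {
    if (i + 3 <= length(b) && identical(b[i:(i + 3)], hdr)) {
      b[(i + 8):(i + 9)] <- charToRaw("0 ")
      break
    }
  }
  p4 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(b, p4)
  expect_error(read_dicom_rt_image(p4), "not supported")
})

test_that("files we write are readable by an independent DICOM implementation", {
  img <- sample_image(pitch = 0.784, angle = 90, system = "JAW",
                      nr = 16L, nc = 20L)
  p <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_rt_image(img, p)
  script <- paste(
    "import pydicom, sys",
    "d = pydicom.dcmread(sys.argv[1])",
    "px = d.pixel_array",
    "print(d.Rows, d.Columns, d.ImagePlanePixelSpacing[0], d.RTImageSID,",
    "      d.BeamLimitingDeviceAngle, int(px.sum()), sep=',')",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(p)),
                 stdout = TRUE, stderr = FALSE)
  vals <- strsplit(out[[1]], ",")[[1]]
  expect_equal(as.numeric(vals[1:2]), c(16, 20))
  expect_equal(as.numeric(vals[3]), 0.784)
  expect_equal(as.numeric(vals[4]), 1000)
  expect_equal(as.numeric(vals[5]), 90)
  expect_equal(as.numeric(vals[6]), sum(img$pixels))
})
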