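#' EPID portal image
#'
#' A single integrated portal image with the acquisition metadata the
#' focal-spot analysis needs. Pixels are stored row-major in the detector
#' frame: rows run along the inplane (gun-target) direction, columns along
#' the crossplane direction.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param pixel_pitch Detector pixel pitch, mm. The supported flat panels
#'   use 0.784 mm (aS500-class, and lower-resolution acquisition modes) or
#'   0.392 mm (aS1000/IDU); other pitches are accepted with a warning.
#' @param sid Source-to-imager distance, mm.
#' @param collimator_angle 90 or 270 (degrees).
#' @param defining_system `"JAW"` or `"MLC"`: which collimator shaped the field.
#' @param source_tag Free-text provenance (typically the file of origin).
#' @return An `epid_image` object.
#' @export
epid_image <- function(pixels, pixel_pitch, sid, collimator_angle,
                       defining_system, source_tag = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixels must be finite and non-negative", call. = FALSE)
  }
  if (!isTRUE(all.equal(pixel_pitch, 0.784, tolerance = 1e-6)) &&
      !isTRUE(all.equal(pixel_pitch, 0.392, tolerance = 1e-6))) {
    warning("pixel pitch ", pixel_pitch,
            " mm is not one of the standard panel pitches (0.784, 0.392)",
            call. = FALSE)
  }
  if (!collimator_angle %in% c(90, 270)) {
    stop("collimator_angle must be 90 or 270", call. = FALSE)
  }
  defining_system <- match.arg(toupper(defining_system), c("JAW", "MLC"))
  structure(
    list(pixels = pixels, pixel_pitch = pixel_pitch, sid = sid,
         collimator_angle = collimator_angle,
         defining_system = defining_system, source_tag = source_tag),
    class = "epid_image")
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf(
    "<epid_image> %dx%d px @ %.3f mm | SID %.0f mm | %s field, collimator %d deg\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_pitch, x$sid,
    x$defining_system, x$collimator_angle))
  invisible(x)
}

#' The four-image measurement set
#'
#' One focal-spot measurement uses four integrated images: the jaw-defined
#' and MLC-defined 10x10 fields, each at collimator 90 and 270 degrees.
#' All four must share pixel pitch and SID (0.1 mm tolerance on SID).
#'
#' @param jaw_90,jaw_270,mlc_90,mlc_270 [epid_image()] objects in their slots.
#' @return A `measurement_set`.
#' @export
measurement_set <- function(jaw_90, jaw_270, mlc_90, mlc_270) {
  imgs <- list(jaw_90 = jaw_90, jaw_270 = jaw_270,
               mlc_90 = mlc_90, mlc_270 = mlc_270)
  for (nm in names(imgs)) {
    img <- imgs[[nm]]
    if (!inherits(img, "epid_image")) {
      stop("'", nm, "' is not an epid_image", call. = FALSE)
    }
    want_sys <- if (grepl("^jaw", nm)) "JAW" else "MLC"
    want_ang <- if (grepl("90$", nm)) 90 else 270
    if (img$defining_system != want_sys || img$collimator_angle != want_ang) {
      stop("image in slot '", nm, "' has defining system ",
           img$defining_system, " at ", img$collimator_angle,
           " deg; expected ", want_sys, " at ", want_ang, " deg",
           call. = FALSE)
    }
  }
  pitches <- vapply(imgs, function(i) i$pixel_pitch, numeric(1))
  sids <- vapply(imgs, function(i) i$sid, numeric(1))
  if (diff(range(pitches)) > 1e-9) {
    stop("all four images must share the same pixel pitch", call. = FALSE)
  }
  if (diff(range(sids)) > 0.1) {
    stop("all four images must share the same SID (0.1 mm tolerance)",
         call. = FALSE)
  }
  structure(imgs, class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> 4 images, %.3f mm pitch, SID %.0f mm\n",
              x$jaw_90$pixel_pitch, x$jaw_90$sid))
  invisible(x)
}
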