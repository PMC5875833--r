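#' Read a raw 16-bit portal image with a YAML sidecar
#'
#' The raw fixture dialect: pixel data as a 16-bit grayscale TIFF, with the
#' acquisition metadata in a YAML sidecar holding `pixel_pitch_mm`,
#' `sid_mm`, `collimator_angle_deg` and `defining_system`.
#'
#' @param image_path Path to a 16-bit grayscale TIFF.
#' @param sidecar_path Path to the YAML sidecar; defaults to the image path
#'   with its extension replaced by `.yaml`.
#' @return An [epid_image()]. Intensities are kept on the stored integer
#'   scale (0..65535); the analysis normalizes per image, so the scale is
#'   immaterial.
#' @export
read_raw_with_sidecar <- function(image_path,
                                  sidecar_path = paste0(
                                    tools::file_path_sans_ext(image_path),
                                    ".yaml")) {
  px <- tiff::readTIFF(image_path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grayscale channels
  px <- round(px * 65535)
  meta <- yaml::read_yaml(sidecar_path)
  need <- c("pixel_pitch_mm", "sid_mm", "collimator_angle_deg",
            "defining_system")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("sidecar ", sidecar_path, " missing keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  epid_image(px, pixel_pitch = meta$pixel_pitch_mm, sid = meta$sid_mm,
             collimator_angle = meta$collimator_angle_deg,
             defining_system = meta$defining_system,
             source_tag = basename(image_path))
}

#' Write an EPID image as 16-bit TIFF plus YAML sidecar
#'
#' @param image An [epid_image()].
#' @param image_path Destination TIFF path; the sidecar is written next to
#'   it with extension `.yaml`.
#' @return `image_path`, invisibly.
#' @export
write_raw_with_sidecar <- function(image, image_path) {
  stopifnot(inherits(image, "epid_image"))
  px <- image$pixels
  if (max(px) > 65535 || any(px != round(px))) {
    px <- round(65535 * (px - min(px)) / max(max(px) - min(px), .Machine$double.eps))
  }
  tiff::writeTIFF(px / 65535, image_path, bits.per.sample = 16L)
  meta <- list(pixel_pitch_mm = image$pixel_pitch, sid_mm = image$sid,
               collimator_angle_deg = image$collimator_angle,
               defining_system = image$defining_system)
  yaml::write_yaml(meta, paste0(tools::file_path_sans_ext(image_path), ".yaml"))
  invisible(image_path)
}
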