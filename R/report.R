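#' Write a focal-spot measurement report as JSON
#'
#' The report carries everything a QA record needs: per-image field centres
#' in the detector frame, the per-axis centroid separations and projection
#' factors, the resulting offset, the geometry used, software version and a
#' timestamp. Values are stored at full precision.
#'
#' @param result A `focal_spot_measurement` from [measure_focal_spot()].
#' @param path Destination JSON path.
#' @param ic Optional named list merged under `"ion_chamber"` (e.g. offsets
#'   from [ic_offset()]).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, ic = NULL) {
  stopifnot(inherits(result, "focal_spot_measurement"))
  rep <- list(
    report_type = "focal_spot_offset",
    software = paste0("focalspot ",
                      as.character(utils::packageVersion("focalspot"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    offset_mm = list(crossplane = result$offset[["crossplane"]],
                     inplane = result$offset[["inplane"]]),
    separation_mm = as.list(result$separation),
    factors = as.list(result$factors),
    jaw_axis_per_detector_axis = as.list(result$jaw_axis),
    axis_mapping = result$axis_mapping,
    sid_mm = result$sid,
    pixel_pitch_mm = result$pixel_pitch,
    field_centers = result$centers,
    geometry_mm = unclass(result$geometry),
    params = unclass(result$params))
  if (!is.null(ic)) rep$ion_chamber <- ic
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a JSON measurement report
#'
#' @param path Path written by [write_report()].
#' @return A named list; `field_centers` is returned as a tibble.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rep$report_type, "focal_spot_offset")) {
    stop(path, " is not a focal-spot offset report", call. = FALSE)
  }
  rep$field_centers <- tibble::as_tibble(rep$field_centers)
  rep
}
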