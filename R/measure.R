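#' Measure the focal-spot offset from a four-image set
#'
#' Runs the full analysis: preprocess each of the four images, locate the
#' field centres, average the collimator-opposed pairs, form the MLC-minus-
#' jaw centroid separation per detector axis, and scale each separation by
#' its projection factor to the physical focal-spot offset. The factor for
#' an axis uses the distance of the jaw pair that defines the field edges
#' along that axis, with the measurement's own SID as the detector distance.
#'
#' The default axis mapping pairs the X jaws with the inplane (row)
#' direction and the Y jaws with the crossplane (column) direction;
#' `axis_mapping = "xjaw_crossplane"` swaps it for head configurations
#' where the X jaws shape the crossplane edges in the detector frame.
#'
#' @param set A [measurement_set()].
#' @param geometry A [linac_geometry()]; its `d_epi` is replaced by the
#'   set's SID.
#' @param params An [analysis_params()].
#' @param axis_mapping `"xjaw_inplane"` (default) or `"xjaw_crossplane"`.
#' @return A `focal_spot_measurement` holding the [offset_vector()], the
#'   per-image field centres, the separations and factors used, and the
#'   inputs — see [tidy.focal_spot_measurement()] and
#'   [glance.focal_spot_measurement()].
#' @examples
#' \donttest{
#' cfg <- sim_config(true_offset = offset_vector(0.1, -0.2),
#'                   grid = c(160, 160))
#' set <- render_measurement_set(cfg)
#' m <- measure_focal_spot(set, cfg$geometry)
#' m$offset
#' }
#' @export
measure_focal_spot <- function(set, geometry, params = analysis_params(),
                               axis_mapping = c("xjaw_inplane",
                                                "xjaw_crossplane")) {
  stopifnot(inherits(set, "measurement_set"),
            inherits(geometry, "linac_geometry"))
  axis_mapping <- match.arg(axis_mapping)
  sid <- set$jaw_90$sid

  centers <- lapply(names(set), function(nm) {
    img <- set[[nm]]
    pp <- preprocess(img, params)
    find_field_center(pp, params = params,
                      source_tag = if (nzchar(img$source_tag)) img$source_tag else nm)
  })
  names(centers) <- names(set)

  jaw_cent <- pair_centroid(centers$jaw_90, centers$jaw_270)
  mlc_cent <- pair_centroid(centers$mlc_90, centers$mlc_270)
  sep <- centroid_separation(jaw_cent, mlc_cent)

  # columns (u) are crossplane, rows (v) inplane; the jaw pair bounding each
  # direction supplies d_jaw for that axis' factor
  jaw_u <- if (axis_mapping == "xjaw_inplane") "Y" else "X"
  jaw_v <- if (axis_mapping == "xjaw_inplane") "X" else "Y"
  a_u <- proportionality_factor(geometry, jaw_u, d_epi = sid)
  a_v <- proportionality_factor(geometry, jaw_v, d_epi = sid)

  offset <- offset_vector(
    crossplane = offset_from_separation(sep[["u"]], a_u),
    inplane = offset_from_separation(sep[["v"]], a_v))

  structure(list(
    offset = offset,
    centers = tibble::tibble(
      image = names(centers),
      defining_system = vapply(set, function(i) i$defining_system, ""),
      collimator_angle = vapply(set, function(i) i$collimator_angle, 0),
      u_mm = vapply(centers, function(ct) ct$u, 0),
      v_mm = vapply(centers, function(ct) ct$v, 0)),
    separation = sep,
    factors = c(u = a_u, v = a_v),
    jaw_axis = c(u = jaw_u, v = jaw_v),
    axis_mapping = axis_mapping,
    sid = sid,
    pixel_pitch = set$jaw_90$pixel_pitch,
    geometry = geometry,
    params = params),
    class = "focal_spot_measurement")
}

#' @export
print.focal_spot_measurement <- function(x, ...) {
  cat("Focal-spot offset measurement (EPID, jaw-vs-MLC centroids)\n")
  cat(sprintf("  SID %.0f mm, pitch %.3f mm\n", x$sid, x$pixel_pitch))
  cat(sprintf("  centroid separation: u %+0.4f mm (a=%.4f), v %+0.4f mm (a=%.4f)\n",
              x$separation[["u"]], x$factors[["u"]],
              x$separation[["v"]], x$factors[["v"]]))
  print(x$offset)
  invisible(x)
}

#' Tidy a focal-spot measurement into one row per reported direction
#'
#' @param x A `focal_spot_measurement`.
#' @param ... Unused.
#' @return A tibble with columns `direction`, `detector_axis`, `jaw_axis`,
#'   `separation_mm`, `factor_a`, `offset_mm`.
#' @exportS3Method generics::tidy
#' @export
tidy.focal_spot_measurement <- function(x, ...) {
  tibble::tibble(
    direction = c("crossplane", "inplane"),
    detector_axis = c("u", "v"),
    jaw_axis = c(x$jaw_axis[["u"]], x$jaw_axis[["v"]]),
    separation_mm = c(x$separation[["u"]], x$separation[["v"]]),
    factor_a = c(x$factors[["u"]], x$factors[["v"]]),
    offset_mm = c(x$offset[["crossplane"]], x$offset[["inplane"]]))
}

#' One-row summary of a focal-spot measurement
#'
#' @param x A `focal_spot_measurement`.
#' @param ... Unused.
#' @return A tibble with `crossplane_mm`, `inplane_mm`, `magnitude_mm`,
#'   `sid_mm`, `pixel_pitch_mm`.
#' @exportS3Method generics::glance
#' @export
glance.focal_spot_measurement <- function(x, ...) {
  tibble::tibble(
    crossplane_mm = x$offset[["crossplane"]],
    inplane_mm = x$offset[["inplane"]],
    magnitude_mm = sqrt(sum(x$offset^2)),
    sid_mm = x$sid,
    pixel_pitch_mm = x$pixel_pitch)
}

#' Plot the field centres and resulting offset
#'
#' Shows the four per-image field centres, the two pair centroids and the
#' derived focal-spot offset in the detector frame (mm). The separation
#' between pair centroids is typically a fraction of the pixel size; note
#' the axis scale.
#'
#' @param object A `focal_spot_measurement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.focal_spot_measurement <- function(object, ...) {
  cent <- object$centers
  pairs <- dplyr::summarise(
    dplyr::group_by(cent, .data$defining_system),
    u_mm = mean(.data$u_mm), v_mm = mean(.data$v_mm), .groups = "drop")
  ggplot2::ggplot(cent, ggplot2::aes(x = .data$u_mm, y = .data$v_mm)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$defining_system,
                                     shape = factor(.data$collimator_angle)),
                        size = 3) +
    ggplot2::geom_point(data = pairs,
                        ggplot2::aes(colour = .data$defining_system),
                        shape = 4, size = 5, stroke = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "u, crossplane (mm)", y = "v, inplane (mm)",
      colour = "defining system", shape = "collimator (deg)",
      title = "Field centres at the detector plane",
      subtitle = sprintf("offset: crossplane %+0.3f mm, inplane %+0.3f mm",
                         object$offset[["crossplane"]],
                         object$offset[["inplane"]])) +
    ggplot2::theme_minimal()
}
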