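#' Linac projection geometry
#'
#' Bundles the source-to-plane distances that define how collimator apertures
#' project onto the portal imager. All distances are measured from the x-ray
#' focal spot along the beam axis, in millimetres.
#'
#' The method rests on the jaws and the MLC sitting at different distances
#' from the source: a lateral focal-spot offset displaces the projected
#' centres of jaw-defined and MLC-defined fields by different amounts, and
#' the difference is what the detector sees.
#'
#' @param d_epi Source-to-detector (EPID) distance, mm.
#' @param d_jaw_x Source-to-X-jaw distance, mm (default 406).
#' @param d_jaw_y Source-to-Y-jaw distance, mm (default 319).
#' @param d_mlc Source-to-MLC distance, mm (default 490).
#' @param d_ic Source-to-ionization-chamber distance, mm (default 750).
#' @param sad Source-to-isocenter distance, mm (default 1000).
#' @return An object of class `linac_geometry` (a named list of distances).
#' @examples
#' geo <- linac_geometry(d_epi = 1000)
#' proportionality_factor(geo, "X")
#' @export
linac_geometry <- function(d_epi = 1000, d_jaw_x = 406, d_jaw_y = 319,
                           d_mlc = 490, d_ic = 750, sad = 1000) {
  g <- list(d_epi = d_epi, d_jaw_x = d_jaw_x, d_jaw_y = d_jaw_y,
            d_mlc = d_mlc, d_ic = d_ic, sad = sad)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("geometry distance '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (any(c(g$d_jaw_x, g$d_jaw_y, g$d_mlc, g$d_ic) >= g$d_epi)) {
    stop("collimator and chamber planes must lie above the detector ",
         "(d_jaw_x, d_jaw_y, d_mlc, d_ic < d_epi)", call. = FALSE)
  }
  if (g$d_mlc == g$d_jaw_x || g$d_mlc == g$d_jaw_y) {
    stop("degenerate geometry: d_mlc must differ from both jaw distances",
         call. = FALSE)
  }
  if (g$d_ic <= g$d_jaw_x || g$d_ic <= g$d_jaw_y) {
    stop("chamber must sit below both jaw planes (d_ic > d_jaw_x, d_jaw_y)",
         call. = FALSE)
  }
  structure(g, class = "linac_geometry")
}

#' @export
print.linac_geometry <- function(x, ...) {
  cat("<linac_geometry> (mm)\n")
  cat(sprintf("  d_epi  %8.1f   d_jaw_x %7.1f   d_jaw_y %7.1f\n",
              x$d_epi, x$d_jaw_x, x$d_jaw_y))
  cat(sprintf("  d_mlc  %8.1f   d_ic    %7.1f   sad     %7.1f\n",
              x$d_mlc, x$d_ic, x$sad))
  invisible(x)
}

d_jaw_for_axis <- function(geometry, jaw_axis) {
  jaw_axis <- match.arg(toupper(jaw_axis), c("X", "Y"))
  if (jaw_axis == "X") geometry$d_jaw_x else geometry$d_jaw_y
}

#' Proportionality factor from centroid separation to focal-spot offset
#'
#' The jaw-defined and MLC-defined field centres, each averaged over
#' collimator angles 90 and 270 degrees, differ at the detector plane by a
#' distance proportional to the focal-spot offset. This factor `a`
#' converts that separation to the physical offset:
#' `a = 1 / ((d_epi - d_jaw)/d_jaw - (d_epi - d_mlc)/d_mlc)`.
#'
#' @param geometry A [linac_geometry()].
#' @param jaw_axis `"X"` or `"Y"`: which jaw pair defines the axis.
#' @param d_epi Optional override of the source-imager distance, mm
#'   (e.g. a per-acquisition SID).
#' @return Dimensionless factor (positive when the jaws sit above the MLC).
#' @examples
#' proportionality_factor(linac_geometry(d_epi = 1000), "X")  # 2.368
#' @export
proportionality_factor <- function(geometry, jaw_axis, d_epi = NULL) {
  stopifnot(inherits(geometry, "linac_geometry"))
  d_jaw <- d_jaw_for_axis(geometry, jaw_axis)
  de <- if (is.null(d_epi)) geometry$d_epi else d_epi
  denom <- (de - d_jaw) / d_jaw - (de - geometry$d_mlc) / geometry$d_mlc
  if (abs(denom) < 1e-12) {
    stop("degenerate geometry: jaw and MLC magnifications coincide",
         call. = FALSE)
  }
  1 / denom
}

#' Focal-spot offset from a measured centroid separation
#'
#' @param separation Separation between the MLC and jaw pair centroids at
#'   the detector plane (MLC minus jaw), mm.
#' @param a Proportionality factor from [proportionality_factor()].
#' @return Offset component in mm.
#' @export
offset_from_separation <- function(separation, a) {
  stopifnot(is.finite(a), a != 0)
  a * separation
}

#' Detector-plane displacement of a projected field centre
#'
#' For an aperture centred on the collimator rotation axis at plane `d_col`
#' and a point source displaced laterally by `source_offset`, similar
#' triangles give the displacement of the projected field centre at the
#' detector: `-source_offset * (d_epi - d_col) / d_col`.
#'
#' @param source_offset Lateral focal-spot offset, mm.
#' @param d_col Source-to-collimator-plane distance, mm.
#' @param d_epi Source-to-detector distance, mm.
#' @return Displacement at the detector plane, mm (sign opposite the source).
#' @export
project_center <- function(source_offset, d_col, d_epi) {
  stopifnot(d_col > 0, d_col < d_epi)
  -source_offset * (d_epi - d_col) / d_col
}

#' Ion-chamber lever arm
#'
#' Converts a physical jaw-plane shift equivalent to the observed charge
#' change into a focal-spot offset for a chamber mounted on the collimator
#' at distance `d_ic`: `d_ic / (d_ic - d_jaw)`.
#'
#' @inheritParams proportionality_factor
#' @return Dimensionless lever arm.
#' @examples
#' ic_lever_arm(linac_geometry(d_epi = 1000), "Y")  # 1.74
#' @export
ic_lever_arm <- function(geometry, jaw_axis) {
  stopifnot(inherits(geometry, "linac_geometry"))
  d_jaw <- d_jaw_for_axis(geometry, jaw_axis)
  if (geometry$d_ic <= d_jaw) {
    stop("degenerate geometry: chamber must sit below the jaw plane",
         call. = FALSE)
  }
  geometry$d_ic / (geometry$d_ic - d_jaw)
}

#' Jaw shift at the physical jaw plane for a shift stated at isocenter
#'
#' Jaw positions are calibrated at isocenter level; the physical blades sit
#' much closer to the source, so a 1 mm shift at isocenter moves the X and Y
#' blades by `d_jaw / sad` mm (0.406 and 0.319 mm for the usual distances).
#'
#' @param shift_at_iso Shift at isocenter level, mm.
#' @param d_jaw Source-to-jaw distance, mm.
#' @param sad Source-to-isocenter distance, mm.
#' @return Shift at the physical jaw plane, mm.
#' @export
jaw_plane_shift <- function(shift_at_iso, d_jaw, sad = 1000) {
  stopifnot(sad > 0)
  shift_at_iso * d_jaw / sad
}

#' Read a geometry configuration from YAML
#'
#' The file holds the source-to-plane distances with a `units` key (`mm` or
#' `cm`); values in cm are converted on load. Recognised keys: `units`,
#' `d_epi`, `d_jaw_x`, `d_jaw_y`, `d_mlc`, `d_ic`, `sad`.
#'
#' @param path Path to a YAML file.
#' @return A [linac_geometry()].
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  units <- cfg$units %||% "mm"
  if (!units %in% c("mm", "cm")) {
    stop("geometry config: units must be 'mm' or 'cm'", call. = FALSE)
  }
  scale <- if (units == "cm") 10 else 1
  keys <- c("d_epi", "d_jaw_x", "d_jaw_y", "d_mlc", "d_ic", "sad")
  missing <- setdiff(c("d_epi", "d_jaw_x", "d_jaw_y", "d_mlc"), names(cfg))
  if (length(missing)) {
    stop("geometry config missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  args <- lapply(intersect(keys, names(cfg)), function(k) cfg[[k]] * scale)
  names(args) <- intersect(keys, names(cfg))
  do.call(linac_geometry, args)
}

#' Construct a focal-spot offset vector
#'
#' The reported quantity: the lateral focal-spot offset from the collimator
#' rotation axis, split into the crossplane (transverse) and inplane
#' (gun-target) directions. Offsets with magnitude above 5 mm are physically
#' implausible for a steered beam and raise a warning.
#'
#' @param crossplane,inplane Signed components, mm.
#' @return An `offset_vector` (named numeric of length 2).
#' @export
offset_vector <- function(crossplane, inplane) {
  v <- c(crossplane = as.numeric(crossplane), inplane = as.numeric(inplane))
  if (any(!is.finite(v))) stop("offset components must be finite", call. = FALSE)
  if (sqrt(sum(v^2)) >= 5) {
    warning("focal-spot offset magnitude >= 5 mm is implausible; ",
            "check inputs", call. = FALSE)
  }
  structure(v, class = "offset_vector")
}

#' @export
print.offset_vector <- function(x, ...) {
  cat(sprintf("focal-spot offset: crossplane %+0.3f mm, inplane %+0.3f mm\n",
              x[["crossplane"]], x[["inplane"]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
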