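#' Configuration of the synthetic portal-image simulator
#'
#' The simulator is a point-source forward model of the measurement: two
#' rectangular apertures (jaws and MLC) at their physical planes, projected
#' through a source displaced laterally by the ground-truth offset onto a
#' pixelated detector, with error-function penumbra and multiplicative
#' Gaussian noise. Per-bank aperture miscalibration emulates imperfect
#' collimator calibration, which the 90/270 averaging must cancel.
#'
#' @param geometry A [linac_geometry()]; its `d_epi` is the simulated SID.
#' @param true_offset An [offset_vector()] — the ground truth.
#' @param field_size_at_iso Square field side at isocenter, mm (default 100,
#'   the standard 10x10 QA field).
#' @param penumbra_sigma Penumbra width (Gaussian sigma) at the detector,
#'   mm (default 1.0, typical of a 6 MV beam).
#' @param miscalibration Named numeric: per-bank aperture position errors at
#'   the collimator plane, mm, names among `X1`, `X2`, `Y1`, `Y2`,
#'   `MLC_A`, `MLC_B` (defaults 0). MLC banks A/B are the leaf ends, which
#'   bound the same detector direction as the X jaws; leaf sides are taken
#'   as exactly calibrated.
#' @param noise Relative (multiplicative) Gaussian noise sigma (default
#'   0.005).
#' @param pixel_pitch Detector pixel pitch, mm (default 0.784).
#' @param grid Detector size as `c(rows, cols)` (default the clinical
#'   `c(384, 512)` raster).
#' @param seed Integer RNG seed for the noise (default 1).
#' @param axis_mapping As in [measure_focal_spot()]: which jaw pair bounds
#'   which detector direction.
#' @return A `sim_config` list.
#' @export
sim_config <- function(geometry = linac_geometry(d_epi = 1000),
                       true_offset = offset_vector(0, 0),
                       field_size_at_iso = 100,
                       penumbra_sigma = 1.0,
                       miscalibration = c(X1 = 0, X2 = 0, Y1 = 0, Y2 = 0,
                                          MLC_A = 0, MLC_B = 0),
                       noise = 0.005,
                       pixel_pitch = 0.784,
                       grid = c(384L, 512L),
                       seed = 1L,
                       axis_mapping = c("xjaw_inplane", "xjaw_crossplane")) {
  stopifnot(inherits(geometry, "linac_geometry"),
            inherits(true_offset, "offset_vector"),
            field_size_at_iso > 0, penumbra_sigma >= 0, noise >= 0,
            pixel_pitch > 0, length(grid) == 2L)
  mis <- c(X1 = 0, X2 = 0, Y1 = 0, Y2 = 0, MLC_A = 0, MLC_B = 0)
  if (length(miscalibration)) {
    bad <- setdiff(names(miscalibration), names(mis))
    if (length(bad)) stop("unknown miscalibration banks: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    mis[names(miscalibration)] <- miscalibration
  }
  structure(list(geometry = geometry, true_offset = true_offset,
                 field_size_at_iso = field_size_at_iso,
                 penumbra_sigma = penumbra_sigma, miscalibration = mis,
                 noise = noise, pixel_pitch = pixel_pitch,
                 grid = as.integer(grid), seed = as.integer(seed),
                 axis_mapping = match.arg(axis_mapping)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Aperture edge positions in the detector frame for one detector direction.
# e: edge positions at the collimator plane in the collimator frame;
# the 270-degree head position flips the collimator frame 180 degrees,
# negating the aperture coordinates while the source offset stays put.
project_edges <- function(edges_col, d_col, d_epi, source_offset, angle) {
  sgn <- if (angle == 90) 1 else -1
  sort(sgn * edges_col * d_epi / d_col -
         source_offset * (d_epi - d_col) / d_col)
}

sim_axis_spec <- function(cfg, defining_system) {
  g <- cfg$geometry
  xj_v <- cfg$axis_mapping == "xjaw_inplane"
  half_at <- function(d) cfg$field_size_at_iso / 2 * d / g$sad
  m <- cfg$miscalibration
  if (defining_system == "JAW") {
    d_u <- if (xj_v) g$d_jaw_y else g$d_jaw_x
    d_v <- if (xj_v) g$d_jaw_x else g$d_jaw_y
    mis_u <- if (xj_v) c(m[["Y1"]], m[["Y2"]]) else c(m[["X1"]], m[["X2"]])
    mis_v <- if (xj_v) c(m[["X1"]], m[["X2"]]) else c(m[["Y1"]], m[["Y2"]])
  } else {
    d_u <- d_v <- g$d_mlc
    mis_u <- if (xj_v) c(0, 0) else c(m[["MLC_A"]], m[["MLC_B"]])
    mis_v <- if (xj_v) c(m[["MLC_A"]], m[["MLC_B"]]) else c(0, 0)
  }
  list(
    u = list(d = d_u, edges = c(-half_at(d_u) + mis_u[1],
                                half_at(d_u) + mis_u[2])),
    v = list(d = d_v, edges = c(-half_at(d_v) + mis_v[1],
                                half_at(d_v) + mis_v[2])))
}

#' Render one synthetic portal image
#'
#' @param cfg A [sim_config()].
#' @param defining_system `"JAW"` or `"MLC"`.
#' @param collimator_angle 90 or 270.
#' @param seed Seed for the noise draw; defaults to the config seed (give
#'   each image of a set its own).
#' @return An [epid_image()] with intensities on a 0..1-ish continuous
#'   scale (quantized only when written to file).
#' @export
render_image <- function(cfg, defining_system, collimator_angle,
                         seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  defining_system <- match.arg(toupper(defining_system), c("JAW", "MLC"))
  stopifnot(collimator_angle %in% c(90, 270))
  g <- cfg$geometry
  nr <- cfg$grid[1L]; nc <- cfg$grid[2L]
  ax <- sim_axis_spec(cfg, defining_system)
  s_u <- cfg$true_offset[["crossplane"]]
  s_v <- cfg$true_offset[["inplane"]]
  eu <- project_edges(ax$u$edges, ax$u$d, g$d_epi, s_u, collimator_angle)
  ev <- project_edges(ax$v$edges, ax$v$d, g$d_epi, s_v, collimator_angle)

  u <- (seq_len(nc) - 0.5 - nc / 2) * cfg$pixel_pitch
  v <- (seq_len(nr) - 0.5 - nr / 2) * cfg$pixel_pitch
  if (eu[1] < min(u) || eu[2] > max(u) || ev[1] < min(v) || ev[2] > max(v)) {
    stop("field out of frame: projected aperture exceeds the detector",
         call. = FALSE)
  }
  sig <- max(cfg$penumbra_sigma, 1e-9)
  fu <- stats::pnorm((u - eu[1]) / sig) * stats::pnorm((eu[2] - u) / sig)
  fv <- stats::pnorm((v - ev[1]) / sig) * stats::pnorm((ev[2] - v) / sig)
  img <- outer(fv, fu)
  if (cfg$noise > 0) {
    img <- with_seed(seed,
      img * (1 + cfg$noise * matrix(stats::rnorm(nr * nc), nr, nc)))
  }
  img[img < 0] <- 0
  epid_image(img, pixel_pitch = cfg$pixel_pitch, sid = g$d_epi,
             collimator_angle = collimator_angle,
             defining_system = defining_system,
             source_tag = sprintf("sim_%s_%d", tolower(defining_system),
                                  collimator_angle))
}

#' Render the four-image measurement set, optionally writing it to disk
#'
#' @param cfg A [sim_config()].
#' @param out_dir If given, the four images are written there together with
#'   a `manifest.json` recording the ground truth, seed and geometry (the
#'   truth never enters the image files themselves).
#' @param format `"dicom"` or `"raw"` (16-bit TIFF + YAML sidecar).
#' @return A [measurement_set()], invisibly carrying the file paths in an
#'   attribute `paths` when written.
#' @export
render_measurement_set <- function(cfg, out_dir = NULL,
                                   format = c("dicom", "raw")) {
  stopifnot(inherits(cfg, "sim_config"))
  format <- match.arg(format)
  slots <- list(jaw_90 = c("JAW", 90), jaw_270 = c("JAW", 270),
                mlc_90 = c("MLC", 90), mlc_270 = c("MLC", 270))
  imgs <- lapply(seq_along(slots), function(k) {
    render_image(cfg, slots[[k]][1], as.numeric(slots[[k]][2]),
                 seed = cfg$seed + k - 1L)
  })
  names(imgs) <- names(slots)
  set <- measurement_set(imgs$jaw_90, imgs$jaw_270, imgs$mlc_90, imgs$mlc_270)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "dicom") ".dcm" else ".tif"
    paths <- character(0)
    for (nm in names(set)) {
      p <- file.path(out_dir, paste0(nm, ext))
      if (format == "dicom") write_dicom_rt_image(set[[nm]], p)
      else write_raw_with_sidecar(set[[nm]], p)
      paths[nm] <- p
    }
    manifest <- list(
      true_offset = list(crossplane = cfg$true_offset[["crossplane"]],
                         inplane = cfg$true_offset[["inplane"]]),
      seed = cfg$seed, noise = cfg$noise,
      field_size_at_iso = cfg$field_size_at_iso,
      penumbra_sigma = cfg$penumbra_sigma,
      miscalibration = as.list(cfg$miscalibration),
      pixel_pitch = cfg$pixel_pitch,
      axis_mapping = cfg$axis_mapping,
      geometry = unclass(cfg$geometry),
      files = as.list(paths), format = format)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(set, "paths") <- paths
  }
  invisible(set)
}

#' Read a simulated measurement set back from disk
#'
#' @param dir Directory written by [render_measurement_set()].
#' @return A [measurement_set()]; the manifest (with ground truth) is
#'   attached as attribute `manifest`.
#' @export
read_measurement_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(p) {
    if (manifest$format == "dicom") read_dicom_rt_image(p)
    else read_raw_with_sidecar(p)
  }
  imgs <- lapply(manifest$files, function(p) {
    rd(if (file.exists(p)) p else file.path(dir, basename(p)))
  })
  set <- measurement_set(imgs$jaw_90, imgs$jaw_270, imgs$mlc_90,
                         imgs$mlc_270)
  attr(set, "manifest") <- manifest
  set
}

#' Simulate the ion-chamber measurement for one jaw axis
#'
#' Generates the half-blocked-field chamber data: a sensitivity scan
#' (charge vs jaw shift stated at isocenter, linear with slope
#' `sensitivity`) and the paired charge readings at collimator 90/270
#' implied by the configured true offset through the inverse of the
#' lever-arm chain. The X jaw probes the inplane direction, the Y jaw
#' crossplane.
#'
#' @param cfg A [sim_config()].
#' @param jaw_axis `"X"` or `"Y"`.
#' @param sensitivity Chamber sensitivity, nC per mm of jaw shift at
#'   isocenter (default -2: retracting the blocking jaw admits more of the
#'   source).
#' @param q_base Charge with the jaw exactly half-blocking, nC (default 50).
#' @param scan_shifts Jaw shifts at isocenter for the scan, mm.
#' @param scan_noise Gaussian sigma on scan charges, nC (default 0).
#' @return A list with `scan` (an [ic_scan()]) and `reading` (an
#'   [ic_reading()]).
#' @export
simulate_ic <- function(cfg, jaw_axis, sensitivity = -2, q_base = 50,
                        scan_shifts = seq(-1.5, 1.5, by = 0.5),
                        scan_noise = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  jaw_axis <- match.arg(toupper(jaw_axis), c("X", "Y"))
  g <- cfg$geometry
  d_jaw <- d_jaw_for_axis(g, jaw_axis)
  xj_in <- cfg$axis_mapping == "xjaw_inplane"
  comp <- if ((jaw_axis == "X") == xj_in) "inplane" else "crossplane"
  s <- cfg$true_offset[[comp]]
  lever <- ic_lever_arm(g, jaw_axis)
  z_iso <- s * g$sad / (lever * d_jaw)  # inverse of the estimation chain
  q <- q_base + sensitivity * scan_shifts
  if (scan_noise > 0) {
    q <- with_seed(cfg$seed, q + stats::rnorm(length(q), sd = scan_noise))
  }
  list(scan = ic_scan(tibble::tibble(shift_mm = scan_shifts, charge_nC = q),
                      jaw_axis = jaw_axis),
       reading = ic_reading(q_90 = q_base + sensitivity * z_iso,
                            q_270 = q_base - sensitivity * z_iso,
                            jaw_axis = jaw_axis))
}
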