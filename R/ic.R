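#' Ion-chamber sensitivity scan
#'
#' Charge collected by the half-blocked chamber as a function of the
#' blocking jaw's position (stated at isocenter level). Used to calibrate
#' the chamber's sensitivity to an effective source shift.
#'
#' @param points A data frame with columns `shift_mm` (jaw shift at
#'   isocenter) and `charge_nC` (collected charge per fixed MU).
#' @param jaw_axis `"X"` or `"Y"`.
#' @return An `ic_scan` (a tibble with attribute `jaw_axis`).
#' @export
ic_scan <- function(points, jaw_axis) {
  jaw_axis <- match.arg(toupper(jaw_axis), c("X", "Y"))
  points <- tibble::as_tibble(points)
  if (!all(c("shift_mm", "charge_nC") %in% names(points))) {
    stop("scan needs columns shift_mm and charge_nC", call. = FALSE)
  }
  if (nrow(points) < 3L) {
    stop("insufficient points: a sensitivity scan needs at least 3",
         call. = FALSE)
  }
  if (diff(range(points$shift_mm)) < 1) {
    stop("scan shifts must span at least 1 mm", call. = FALSE)
  }
  if (any(points$charge_nC <= 0)) {
    stop("scan charges must be positive", call. = FALSE)
  }
  structure(points, jaw_axis = jaw_axis, class = c("ic_scan", class(points)))
}

#' Read a sensitivity scan from CSV
#'
#' @param path CSV with columns `shift_mm`, `charge_nC`.
#' @param jaw_axis `"X"` or `"Y"`.
#' @return An [ic_scan()].
#' @export
read_ic_scan <- function(path, jaw_axis) {
  ic_scan(utils::read.csv(path), jaw_axis)
}

#' Paired chamber readings at opposed collimator angles
#'
#' @param q_90,q_270 Collected charges (nC) at collimator 90 and 270
#'   degrees with the half-blocked field.
#' @param jaw_axis `"X"` or `"Y"`: which jaw half-blocks the field.
#' @return An `ic_reading`.
#' @export
ic_reading <- function(q_90, q_270, jaw_axis) {
  jaw_axis <- match.arg(toupper(jaw_axis), c("X", "Y"))
  if (q_90 <= 0 || q_270 <= 0) stop("charges must be positive", call. = FALSE)
  structure(list(q_90 = q_90, q_270 = q_270, jaw_axis = jaw_axis),
            class = "ic_reading")
}

#' Chamber sensitivity to jaw position
#'
#' Ordinary least-squares slope of charge against jaw shift. The physical
#' assumption is first-order linearity of the half-blocked signal in the
#' blocking-edge position; a poor linear fit (R-squared below 0.95) raises
#' a warning.
#'
#' @param scan An [ic_scan()].
#' @return A list with `sensitivity` (nC per mm at isocenter level),
#'   `r_squared`, `max_residual` and the underlying `fit` (an `lm`).
#' @export
ic_sensitivity <- function(scan) {
  stopifnot(inherits(scan, "ic_scan"))
  if (stats::var(scan$shift_mm) == 0) {
    stop("zero-variance shifts: cannot fit a slope", call. = FALSE)
  }
  fit <- stats::lm(charge_nC ~ shift_mm, data = scan)
  ss_tot <- sum((scan$charge_nC - mean(scan$charge_nC))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  if (is.finite(r2) && r2 < 0.95) {
    warning("sensitivity scan R-squared ", signif(r2, 3),
            " < 0.95: linearity assumption questionable", call. = FALSE)
  }
  list(sensitivity = unname(stats::coef(fit)[["shift_mm"]]),
       r_squared = r2,
       max_residual = max(abs(stats::residuals(fit))),
       fit = fit)
}

#' Focal-spot offset from paired chamber readings
#'
#' The estimation chain: half the charge difference between the opposed
#' collimator angles, divided by the sensitivity, is the equivalent jaw
#' shift at isocenter; scaled to the physical jaw plane by `d_jaw/sad`;
#' multiplied by the chamber lever arm `d_ic/(d_ic - d_jaw)` to give the
#' focal-spot offset along the direction the jaw probes (X jaw: inplane,
#' Y jaw: crossplane, under the default mapping).
#'
#' @param reading An [ic_reading()].
#' @param sensitivity nC per mm at isocenter, from [ic_sensitivity()]
#'   (either the list or the bare number).
#' @param geometry A [linac_geometry()].
#' @return Offset component, mm, on the same sign convention as the EPID
#'   method.
#' @export
ic_offset <- function(reading, sensitivity, geometry) {
  stopifnot(inherits(reading, "ic_reading"),
            inherits(geometry, "linac_geometry"))
  if (is.list(sensitivity)) sensitivity <- sensitivity$sensitivity
  if (!is.finite(sensitivity) || sensitivity == 0) {
    stop("zero sensitivity: cannot convert charge to shift", call. = FALSE)
  }
  z_iso <- (reading$q_90 - reading$q_270) / 2 / sensitivity
  d_jaw <- d_jaw_for_axis(geometry, reading$jaw_axis)
  z_phys <- jaw_plane_shift(z_iso, d_jaw, geometry$sad)
  ic_lever_arm(geometry, reading$jaw_axis) * z_phys
}

#' Compare EPID-derived and chamber-derived offsets
#'
#' @param pairs A data frame with columns `epid_mm` and `ic_mm`, one row per
#'   (linac, direction) measurement.
#' @return A one-row tibble: `mean_diff_mm`, `sd_diff_mm` (sample SD, n-1),
#'   `max_abs_diff_mm`, `n`. Differences are chamber minus EPID.
#' @export
compare_methods <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("epid_mm", "ic_mm") %in% names(pairs))) {
    stop("pairs needs columns epid_mm and ic_mm", call. = FALSE)
  }
  if (nrow(pairs) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- pairs$ic_mm - pairs$epid_mm
  tibble::tibble(mean_diff_mm = mean(d),
                 sd_diff_mm = stats::sd(d),
                 max_abs_diff_mm = max(abs(d)),
                 n = length(d))
}
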