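#' Locate the centre of a radiation field in a preprocessed image
#'
#' Binarizes the unit-scaled image at the half-value threshold, keeps the
#' largest connected above-threshold region, and takes the field centre as
#' the average midpoint between opposing 50% edges: for every row inside
#' the central band of the field's vertical extent, each edge position is
#' the half-value crossing, linearly interpolated between the outermost
#' above-threshold pixel and its below-threshold neighbour; the row centre
#' is the midpoint of the two crossings, averaged over rows (and
#' symmetrically for the other axis). Positions are reported in mm in a
#' detector frame centred on the pixel grid, columns (`u`, crossplane)
#' increasing rightward and rows (`v`, inplane) increasing downward.
#'
#' @param processed Output of [preprocess()], or a plain unit-scaled matrix.
#' @param effective_pitch Pixel size of `processed`, mm (taken from the
#'   preprocess output when one is supplied).
#' @param params An [analysis_params()].
#' @param source_tag Provenance string attached to the result.
#' @return A `field_center`: list with `u`, `v` (mm) and `source_tag`.
#' @export
find_field_center <- function(processed, effective_pitch = NULL,
                              params = analysis_params(),
                              source_tag = "") {
  if (is.list(processed) && !is.null(processed$pixels)) {
    effective_pitch <- effective_pitch %||% processed$effective_pitch
    processed <- processed$pixels
  }
  stopifnot(is.matrix(processed), is.numeric(effective_pitch))
  nr <- nrow(processed); nc <- ncol(processed)
  bin <- processed >= params$threshold
  labels <- EBImage::bwlabel(bin)
  nlab <- max(labels)
  if (nlab == 0L) stop("no field found: no above-threshold region", call. = FALSE)
  sizes <- tabulate(labels[labels > 0L], nbins = nlab)
  frac <- sizes / (nr * nc)
  ok <- which(frac >= 0.01 & frac <= 0.90)
  if (length(ok) == 0L) {
    stop("no field found: no connected region covers 1-90% of the frame",
         call. = FALSE)
  }
  lab <- ok[which.max(sizes[ok])]
  mask <- labels == lab
  if (any(mask[1L, ]) || any(mask[nr, ]) || any(mask[, 1L]) || any(mask[, nc])) {
    stop("field clipped: region touches the frame border", call. = FALSE)
  }

  rows_any <- which(rowSums(mask) > 0L)
  cols_any <- which(colSums(mask) > 0L)
  band_idx <- function(idx, frac_band) {
    lo <- idx[1L]; hi <- idx[length(idx)]
    c0 <- (lo + hi) / 2; half <- (hi - lo) * frac_band / 2
    idx[idx >= c0 - half & idx <= c0 + half]
  }
  b <- params$edge_band_fraction
  thr <- params$threshold
  # 50% edge with sub-pixel refinement: the extreme above-threshold pixels
  # bracket the crossing; linear interpolation against the neighbouring
  # below-threshold sample places the half-value point between them. On a
  # hard binary edge this lands exactly halfway between the two pixels, so
  # the midpoint of a binary rectangle is unchanged.
  cross_lo <- function(profile, i) {
    if (i <= 1L || profile[i - 1L] >= thr || profile[i] == profile[i - 1L])
      return(i)
    (i - 1L) + (thr - profile[i - 1L]) / (profile[i] - profile[i - 1L])
  }
  cross_hi <- function(profile, i) {
    if (i >= length(profile) || profile[i + 1L] >= thr ||
        profile[i] == profile[i + 1L])
      return(i)
    i + (profile[i] - thr) / (profile[i] - profile[i + 1L])
  }
  # u (column) centre from rows in the central band of the vertical extent
  rband <- band_idx(rows_any, b)
  u_idx <- vapply(rband, function(r) {
    cc <- which(mask[r, ])
    prof <- processed[r, ]
    (cross_lo(prof, cc[1L]) + cross_hi(prof, cc[length(cc)])) / 2
  }, numeric(1))
  cband <- band_idx(cols_any, b)
  v_idx <- vapply(cband, function(cl) {
    rr <- which(mask[, cl])
    prof <- processed[, cl]
    (cross_lo(prof, rr[1L]) + cross_hi(prof, rr[length(rr)])) / 2
  }, numeric(1))

  structure(list(
    u = (mean(u_idx) - 0.5 - nc / 2) * effective_pitch,
    v = (mean(v_idx) - 0.5 - nr / 2) * effective_pitch,
    source_tag = source_tag), class = "field_center")
}

#' @export
print.field_center <- function(x, ...) {
  cat(sprintf("field centre: u %+0.4f mm, v %+0.4f mm  [%s]\n",
              x$u, x$v, x$source_tag))
  invisible(x)
}

#' Average the field centres of a collimator-opposed pair
#'
#' Averaging the 90- and 270-degree centres of fields shaped by the same
#' collimator cancels aperture miscalibration (which flips sign with the
#' 180-degree rotation) and leaves the focal-spot projection, which does
#' not rotate with the collimator.
#'
#' @param center_90,center_270 `field_center` objects from the same
#'   defining system at the two collimator angles.
#' @return A `field_center` at the component-wise mean.
#' @export
pair_centroid <- function(center_90, center_270) {
  stopifnot(inherits(center_90, "field_center"),
            inherits(center_270, "field_center"))
  structure(list(u = (center_90$u + center_270$u) / 2,
                 v = (center_90$v + center_270$v) / 2,
                 source_tag = paste(center_90$source_tag,
                                    center_270$source_tag, sep = "+")),
            class = "field_center")
}

#' Separation between the MLC and jaw pair centroids
#'
#' @param jaw_centroid,mlc_centroid Pair centroids from [pair_centroid()].
#' @return Named numeric: `u` and `v` separations (MLC minus jaw), mm.
#' @export
centroid_separation <- function(jaw_centroid, mlc_centroid) {
  c(u = mlc_centroid$u - jaw_centroid$u,
    v = mlc_centroid$v - jaw_centroid$v)
}
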