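# Minimal DICOM RT Image codec: Explicit VR Little Endian, the attributes
# the focal-spot analysis needs. Written in-package because no R DICOM
# reader is available; round-tripped in tests and cross-checked against an
# independent DICOM implementation.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_VR_LE <- "1.2.840.10008.1.2"
UID_RT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.1"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.9.7434.1"

dcm_pad <- function(x) if (nchar(x) %% 2L == 1L) paste0(x, " ") else x

dcm_element <- function(group, element, vr, value) {
  hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% c("UI", "SH", "CS", "DS", "IS", "LO", "DA", "TM")) {
    s <- dcm_pad(paste(value, collapse = "\\"))
    body <- charToRaw(s)
    if (vr == "UI" && length(body) && body[length(body)] == charToRaw(" ")) {
      body[length(body)] <- as.raw(0L)  # UIDs pad with NUL, not space
    }
    len <- writeBin(as.integer(length(body)), raw(), size = 2L,
                    endian = "little")
    c(hdr, charToRaw(vr), len, body)
  } else if (vr == "US") {
    body <- writeBin(as.integer(value), raw(), size = 2L, endian = "little")
    len <- writeBin(as.integer(length(body)), raw(), size = 2L,
                    endian = "little")
    c(hdr, charToRaw(vr), len, body)
  } else if (vr %in% c("OB", "OW", "UL4")) {
    body <- value  # raw vector, caller-encoded
    if (vr == "UL4") vr <- "UL"
    c(hdr, charToRaw(vr),
      if (vr %in% c("OB", "OW")) {
        c(as.raw(c(0, 0)),
          writeBin(as.integer(length(body)), raw(), size = 4L,
                   endian = "little"))
      } else {
        writeBin(as.integer(length(body)), raw(), size = 2L,
                 endian = "little")
      },
      body)
  } else if (vr == "UL") {
    body <- writeBin(as.integer(value), raw(), size = 4L, endian = "little")
    len <- writeBin(as.integer(length(body)), raw(), size = 2L,
                    endian = "little")
    c(hdr, charToRaw(vr), len, body)
  } else {
    stop("unsupported VR ", vr)
  }
}

dcm_new_uid <- function() {
  paste0(UID_IMPL_CLASS, ".",
         format(as.integer(Sys.time()) %% 1e8, scientific = FALSE), ".",
         sample.int(1e6, 1))
}

#' Write an EPID image as a DICOM RT Image file
#'
#' Writes an Explicit VR Little Endian RT Image with the acquisition
#' attributes this package reads back: image-plane pixel spacing, RT image
#' SID, beam-limiting-device angle, rescale slope/intercept, and the
#' defining collimator system in the RT Image Label. Pixels are stored as
#' unsigned 16-bit; images not already on an integer 0..65535 scale are
#' min-max scaled into it.
#'
#' @param image An [epid_image()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_dicom_rt_image <- function(image, path) {
  stopifnot(inherits(image, "epid_image"))
  px <- image$pixels
  if (max(px) > 65535 || min(px) < 0 || any(px != round(px))) {
    px <- round(65535 * (px - min(px)) /
                  max(max(px) - min(px), .Machine$double.eps))
  }
  v <- as.integer(as.vector(t(px)))  # DICOM is row-major
  pix_raw <- writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2L,
                      endian = "little")

  sop_uid <- dcm_new_uid()
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", UID_RT_IMAGE_STORAGE),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dcm_element(0x0002, 0x0012, "UI", UID_IMPL_CLASS))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)

  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RT_IMAGE_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "RTIMAGE"),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(px)),
    dcm_element(0x0028, 0x0011, "US", ncol(px)),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x0028, 0x1052, "DS", "0"),
    dcm_element(0x0028, 0x1053, "DS", "1"),
    dcm_element(0x3002, 0x0002, "SH", image$defining_system),
    dcm_element(0x3002, 0x0011, "DS",
                c(format(image$pixel_pitch), format(image$pixel_pitch))),
    dcm_element(0x3002, 0x0022, "DS", "1000"),
    dcm_element(0x3002, 0x0026, "DS", format(image$sid)),
    dcm_element(0x300A, 0x0120, "DS", format(image$collimator_angle)),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# Parse a DICOM byte stream into a named list keyed "gggg,eeee" (hex).
dcm_parse <- function(bytes) {
  n <- length(bytes)
  pos <- 1L
  if (n < 132L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic)", call. = FALSE)
  }
  pos <- 133L
  elems <- list()
  explicit <- TRUE  # file meta is always explicit
  ts_checked <- FALSE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    grp <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2L,
                   signed = FALSE, endian = "little")
    el <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                  signed = FALSE, endian = "little")
    if (!ts_checked && grp != 0x0002) {
      # leaving file meta: switch syntax per (0002,0010)
      ts <- elems[["0002,0010"]]$string %||% UID_EXPLICIT_VR_LE
      explicit <- !identical(ts, UID_IMPLICIT_VR_LE)
      ts_checked <- TRUE
    }
    if (explicit || grp == 0x0002) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                       endian = "little")
        body_at <- pos + 12L
      } else {
        len <- readBin(bytes[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                       signed = FALSE, endian = "little")
        body_at <- pos + 8L
      }
    } else {
      vr <- ""
      len <- readBin(bytes[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                     endian = "little")
      body_at <- pos + 8L
    }
    if (len < 0L || body_at + len - 1L > n) {
      stop("corrupt DICOM element at byte ", pos, call. = FALSE)
    }
    body <- if (len > 0L) bytes[body_at:(body_at + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", grp, el)
    elems[[key]] <- list(
      vr = vr, raw = body,
      string = if (len > 0L && (vr == "" || !vr %in% long_vrs)) {
        b <- body
        while (length(b) && b[length(b)] %in% as.raw(c(0L, 32L))) {
          b <- b[-length(b)]
        }
        rawToChar(b)
      } else NULL)
    pos <- body_at + len
  }
  elems
}

dcm_numeric <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  if (identical(e$vr, "US")) {
    readBin(e$raw, "integer", n = length(e$raw) / 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else {
    as.numeric(strsplit(e$string, "\\\\")[[1]])
  }
}

#' Read a DICOM RT Image into an [epid_image()]
#'
#' Supports Explicit and Implicit VR Little Endian with 16-bit unsigned
#' pixels. Pixel values are rescaled by slope/intercept when present; the
#' pixel pitch comes from the image-plane pixel spacing (stated at the
#' receptor plane in RT Image objects), the SID from the RT Image SID, the
#' collimator angle from the beam-limiting-device angle (must round to 90
#' or 270 within 2 degrees), and the defining system from the RT Image
#' Label when it reads JAW or MLC.
#'
#' @param path Path to a DICOM RT Image file.
#' @param defining_system Override/fallback for the defining collimator
#'   system when the file does not carry one.
#' @return An [epid_image()].
#' @export
read_dicom_rt_image <- function(path, defining_system = NULL) {
  elems <- dcm_parse(readBin(path, raw(), file.size(path)))
  need <- c(`0028,0010` = "Rows", `0028,0011` = "Columns",
            `3002,0011` = "ImagePlanePixelSpacing",
            `3002,0026` = "RTImageSID",
            `300a,0120` = "BeamLimitingDeviceAngle",
            `7fe0,0010` = "PixelData")
  for (k in names(need)) {
    if (is.null(elems[[k]])) {
      stop("DICOM file is missing attribute ", need[[k]], " (", k, ")",
           call. = FALSE)
    }
  }
  rows <- dcm_numeric(elems, "0028,0010")
  cols <- dcm_numeric(elems, "0028,0011")
  spacing <- dcm_numeric(elems, "3002,0011")
  sid <- dcm_numeric(elems, "3002,0026")
  ang <- dcm_numeric(elems, "300a,0120") %% 360
  slope <- dcm_numeric(elems, "0028,1053") %||% 1
  intercept <- dcm_numeric(elems, "0028,1052") %||% 0

  near <- c(90, 270)[which.min(abs(ang - c(90, 270)))]
  if (abs(ang - near) > 2) {
    stop("collimator angle ", ang, " deg not supported: the method needs ",
         "90 or 270 (within 2 deg)", call. = FALSE)
  }
  label <- elems[["3002,0002"]]$string
  sys <- if (!is.null(label) && toupper(label) %in% c("JAW", "MLC")) {
    toupper(label)
  } else if (!is.null(defining_system)) {
    defining_system
  } else {
    stop("defining collimator system not recorded in the file; pass ",
         "defining_system = 'JAW' or 'MLC'", call. = FALSE)
  }
  v <- readBin(elems[["7fe0,0010"]]$raw, "integer", n = rows * cols,
               size = 2L, signed = FALSE, endian = "little")
  px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE) * slope + intercept
  epid_image(px, pixel_pitch = spacing[1], sid = sid,
             collimator_angle = near, defining_system = sys,
             source_tag = basename(path))
}
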