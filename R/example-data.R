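#' Example reproducibility series from a four-linac study
#'
#' Weekly 6 MV focal-spot offset measurements (three repeats per machine)
#' collected with the EPID method on four clinical Varian linacs — two
#' 6EX, one 21iX and one TrueBeam. Useful as a worked example for
#' [repro_stats()] and as a realistic scale reference: three of the four
#' machines sit below 0.1 mm in both directions, while linac 3 carries a
#' genuine ~0.43 mm inplane misalignment.
#'
#' @return A tibble with columns `linac`, `repeat_no`, `crossplane_mm`,
#'   `inplane_mm`.
#' @export
fs_repro_example <- function() {
  tibble::tibble(
    linac = rep(paste0("linac", 1:4), each = 3L),
    repeat_no = rep(1:3, times = 4L),
    crossplane_mm = c(-0.002, -0.008, -0.006,
                      0.069, 0.087, 0.081,
                      -0.027, -0.026, -0.032,
                      0.081, 0.082, 0.085),
    inplane_mm = c(0.099, 0.084, 0.098,
                   0.021, 0.058, 0.097,
                   -0.445, -0.419, -0.433,
                   -0.020, -0.018, -0.046))
}

#' Example EPID-vs-chamber method comparison from the same study
#'
#' Per-linac, per-direction focal-spot offsets measured independently with
#' the EPID method and the half-blocked-field ionization-chamber method on
#' the four machines of [fs_repro_example()]. Input for
#' [compare_methods()].
#'
#' @return A tibble with columns `linac`, `direction`, `ic_mm`, `epid_mm`.
#' @export
fs_validation_example <- function() {
  tibble::tibble(
    linac = rep(paste0("linac", 1:4), each = 2L),
    direction = rep(c("crossplane", "inplane"), times = 4L),
    ic_mm = c(-0.005, 0.094, 0.097, 0.055, -0.036, -0.458, 0.106, -0.024),
    epid_mm = c(-0.005, 0.094, 0.079, 0.059, -0.029, -0.433, 0.083, -0.028))
}
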