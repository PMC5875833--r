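#' Reproducibility statistics for repeated focal-spot measurements
#'
#' Summarises a series of repeated measurements (same linac, same energy):
#' mean and sample standard deviation (n-1 denominator) per reported
#' direction, optionally per grouping column (e.g. linac).
#'
#' @param repeats A data frame with columns `crossplane_mm` and
#'   `inplane_mm`, one row per repeat; any other columns named in `by`
#'   group the summary.
#' @param by Optional character vector of grouping columns.
#' @return A tibble in long form: one row per (group, direction) with
#'   `n`, `mean_mm`, `sd_mm`, and the rounded 3-decimal report values
#'   `mean_report`, `sd_report` (half-away-from-zero rounding, as printed
#'   in QA tables; full precision is retained in `mean_mm`/`sd_mm`).
#' @export
repro_stats <- function(repeats, by = NULL) {
  repeats <- tibble::as_tibble(repeats)
  if (!all(c("crossplane_mm", "inplane_mm") %in% names(repeats))) {
    stop("repeats needs columns crossplane_mm and inplane_mm", call. = FALSE)
  }
  long <- tidyr::pivot_longer(repeats,
                              cols = c("crossplane_mm", "inplane_mm"),
                              names_to = "direction", values_to = "offset_mm")
  long$direction <- sub("_mm$", "", long$direction)
  grouped <- dplyr::group_by(long,
                             dplyr::across(dplyr::all_of(c(by, "direction"))))
  out <- dplyr::summarise(grouped,
                          n = dplyr::n(),
                          mean_mm = mean(.data$offset_mm),
                          sd_mm = stats::sd(.data$offset_mm),
                          .groups = "drop")
  if (any(out$n < 2L)) {
    stop("too few repeats: need at least 2 per group for an SD",
         call. = FALSE)
  }
  out$mean_report <- round_half_away(out$mean_mm, 3L)
  out$sd_report <- round_half_away(out$sd_mm, 3L)
  out
}

# round half away from zero (the convention of printed QA tables; R's
# round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
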