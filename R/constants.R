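#' Exposure-assessment constants
#'
#' Bundle of the fixed reference values used throughout the pipeline: the
#' instrument limit of detection (LOD), the ceiling value (CV) that must
#' never be exceeded, the 8-h occupational exposure limit (OEL), and the
#' reference shift length used as the TWA denominator.
#'
#' The expert-campaign instruments (OdaLog, Draeger) resolve down to
#' 0.1 ppm, while the self-assessed-collection detectors (BW MicroClipX3)
#' have an LOD of 1.6 ppm; pass `lod_ppm` accordingly. CV (10 ppm) and OEL
#' (5 ppm) are regulatory constants for H2S and are fixed.
#'
#' @param lod_ppm limit of detection in ppm (default 1.6, the
#'   electrochemical alarm-detector floor; use 0.1 for the
#'   expert-campaign instruments).
#' @param twa_reference_min reference shift length in minutes for the
#'   time-weighted average denominator (default 480 = 8 h).
#' @return an object of class `h2s_constants`.
#' @export
#' @examples
#' h2s_constants()              # alarm-detector defaults
#' h2s_constants(lod_ppm = 0.1) # expert-campaign instruments
h2s_constants <- function(lod_ppm = 1.6, twa_reference_min = 480) {
  stopifnot(is.numeric(lod_ppm), length(lod_ppm) == 1, lod_ppm > 0,
            is.numeric(twa_reference_min), twa_reference_min > 0)
  structure(
    list(lod_ppm = lod_ppm,
         cv_ppm = 10.0,
         oel_ppm = 5.0,
         twa_reference_min = twa_reference_min),
    class = "h2s_constants"
  )
}

#' @export
print.h2s_constants <- function(x, ...) {
  cat("H2S exposure constants\n")
  cat(sprintf("  LOD: %.1f ppm | CV: %.0f ppm | OEL: %.0f ppm | TWA ref: %d min\n",
              x$lod_ppm, x$cv_ppm, x$oel_ppm, as.integer(x$twa_reference_min)))
  invisible(x)
}

# Concentrations live on a 0.1-ppm grid; all band comparisons are done on
# the integer deci-ppm scale to make edge membership float-safe.
dppm <- function(ppm) as.integer(round(ppm * 10))

# Band lower edges in deci-ppm. A peak "crosses" every band whose lower
# edge it reaches: B01 >= 0.1, B1 >= 1.1, B5 >= 5.1, B10 > 10.0 ppm.
.band_edges_dppm <- c(b01 = 1L, b1 = 11L, b5 = 51L, b10 = 101L)

#' Round half away from zero
#'
#' Reporting convention used for printed tables (index to 1 decimal,
#' percentages and ratios to integers). Base `round()` rounds half to
#' even, which does not reproduce printed values such as 51 902 from
#' 51 901.67.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(18.5)   # 19, not 18
#' round_half_up(2.725, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
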