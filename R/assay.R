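#' Percent wound closure
#'
#' Percent change in wound area between time 0 and the endpoint:
#' 100 x (W0 - Wt) / W0. Negative when the gap widened.
#'
#' @param w0 Wound width/area at 0 h (> 0).
#' @param wt Wound width/area at the endpoint (>= 0).
#'
#' @return Percent closure (vectorized); scale-invariant in the
#'   measurement units.
#' @export
wound_closure_pct <- function(w0, wt) {
  if (any(is.na(w0)) || any(w0 <= 0))
    stop("w0 must be positive", call. = FALSE)
  if (any(is.na(wt)) || any(wt < 0))
    stop("wt must be non-negative", call. = FALSE)
  100 * (w0 - wt) / w0
}

#' Percent protein remaining after protease activation
#'
#' Band-intensity ratio after vs before activation: (after x 100) /
#' before.
#'
#' @param before Band intensity before activation (> 0).
#' @param after Band intensity after activation (>= 0).
#'
#' @return Percent remaining (vectorized).
#' @export
protein_remaining_pct <- function(before, after) {
  if (any(is.na(before)) || any(before <= 0))
    stop("before must be positive", call. = FALSE)
  if (any(is.na(after)) || any(after < 0))
    stop("after must be non-negative", call. = FALSE)
  100 * after / before
}

#' Total protein relative to non-variant reference cells
#'
#' Normalizes a sample's percent protein remaining to the mean of the
#' non-variant reference measurements: (sample remaining x 100) / mean of
#' reference values.
#'
#' @param sample_remaining Percent remaining of the sample.
#' @param nonvariant_remaining Numeric vector of percent-remaining values
#'   of the non-variant reference cells (non-empty, positive mean).
#'
#' @return Percent of the reference mean.
#' @export
total_protein_pct <- function(sample_remaining, nonvariant_remaining) {
  if (length(nonvariant_remaining) == 0L)
    stop("empty non-variant reference set", call. = FALSE)
  m <- mean(nonvariant_remaining)
  if (!is.finite(m) || m == 0)
    stop("reference mean must be nonzero", call. = FALSE)
  100 * sample_remaining / m
}

#' Background-corrected total fluorescence
#'
#' ImageJ-style correction: integrated density minus (selected area x
#' mean background fluorescence). May be negative for low-signal
#' biopsies; negative values are retained and flagged with a warning
#' rather than clipped.
#'
#' @param integrated_density Integrated fluorescence density.
#' @param area Selected biopsy area (>= 0).
#' @param mean_background Mean fluorescence of the background readings.
#'
#' @return Corrected total fluorescence (vectorized).
#' @export
corrected_total_fluorescence <- function(integrated_density, area,
                                         mean_background) {
  if (any(is.na(area)) || any(area < 0))
    stop("area must be non-negative", call. = FALSE)
  ctf <- integrated_density - area * mean_background
  if (any(ctf < 0))
    warning("negative corrected fluorescence: signal below background",
            call. = FALSE)
  ctf
}
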