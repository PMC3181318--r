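# Fingerprint (band-table) metrics: relative intensities, Shannon diversity,
# presence-absence band turnover.  A band table emulates a set of DGGE lanes:
# rows are site-date samples, columns are matched bands, values are
# non-negative fluorescence intensities.

#' Relative band intensities of one lane
#'
#' The relative contribution of each band to the total intensity of the lane.
#'
#' @param row Numeric vector of non-negative band intensities.
#' @return Vector of proportions summing to 1; zeros are preserved.
#' @export
relative_intensities <- function(row) {
  row <- as.numeric(row)
  if (any(row < 0)) stop("negative band intensity", call. = FALSE)
  total <- sum(row)
  if (total <= 0) stop("empty lane: all band intensities are zero",
                       call. = FALSE)
  row / total
}

#' Shannon diversity of a lane
#'
#' `H' = -sum(p * log(p))` over the positive relative intensities, with
#' `0 * log(0)` taken as 0.  The natural logarithm is the default; `base`
#' makes the choice explicit since fingerprint studies vary.
#'
#' @param proportions Relative intensities (must sum to 1).
#' @param base Logarithm base (default `exp(1)`).
#' @return H' (dimensionless), between 0 and `log(number of positive bands)`.
#' @export
shannon_index <- function(proportions, base = exp(1)) {
  p <- as.numeric(proportions)
  if (any(p < 0)) stop("negative proportion", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("proportions must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Presence-absence band turnover between two lanes
#'
#' Compares the banding pattern of a site against the pattern of its
#' transition's head site.  A band is *present* when its intensity exceeds
#' `presence_threshold`.  `n_changed` counts bands present in exactly one of
#' the two lanes (gains plus losses); `n_shared` counts bands present in
#' both.  The measure is symmetric in its two arguments.
#'
#' @param head_row,site_row Intensity vectors over the same band index space
#'   (same length; if both are named, the same names).
#' @param presence_threshold Intensity above which a band counts as present
#'   (default 0: any positive intensity).
#' @return Named integer vector `c(n_shared, n_changed)`.
#' @export
band_turnover <- function(head_row, site_row, presence_threshold = 0) {
  if (length(head_row) != length(site_row)) {
    stop("lanes cover different band spaces", call. = FALSE)
  }
  if (!is.null(names(head_row)) && !is.null(names(site_row)) &&
      !identical(names(head_row), names(site_row))) {
    stop("lanes cover different band spaces (names differ)", call. = FALSE)
  }
  a <- as.numeric(head_row) > presence_threshold
  b <- as.numeric(site_row) > presence_threshold
  c(n_shared = sum(a & b), n_changed = sum(xor(a, b)))
}
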