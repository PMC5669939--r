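#' Nanoplasmonic aggregation index (AI)
#'
#' Ratio of the localized surface plasmon resonance absorbances at 519 and
#' 650 nm, `AI = A519 / A650`, of a gold-nanoparticle/EV mixture; an EV
#' purity/concentration readout. Off-grid wavelengths are linearly
#' interpolated (spectra are normally acquired at 1 nm steps over
#' 400-900 nm, so interpolation error is negligible).
#'
#' @param wavelength numeric, strictly ascending wavelengths (nm); must
#'   cover 519 and 650 nm. May also be a two-column data.frame/matrix
#'   `(wavelength_nm, absorbance)`, in which case `absorbance` is ignored.
#' @param absorbance numeric, non-negative absorbances (a.u.).
#' @return the dimensionless aggregation index.
#' @export
aggregationIndex <- function(wavelength, absorbance = NULL) {
  if (is.null(absorbance)) {
    stopifnot(ncol(wavelength) >= 2L)
    absorbance <- wavelength[[2L]]
    wavelength <- wavelength[[1L]]
  }
  if (length(wavelength) != length(absorbance) || length(wavelength) < 2L)
    stop("wavelength and absorbance must be equal-length vectors (>= 2)")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly ascending")
  if (any(absorbance < 0)) stop("negative absorbance")
  if (min(wavelength) > 519 || max(wavelength) < 650)
    stop("spectrum must cover 519 and 650 nm")
  a519 <- stats::approx(wavelength, absorbance, xout = 519)$y
  a650 <- stats::approx(wavelength, absorbance, xout = 650)$y
  if (a650 == 0) stop("A650 is zero; aggregation index undefined")
  a519 / a650
}

#' Count-weighted mean particle diameter
#'
#' `sum(d_i * n_i) / sum(n_i)` over histogram bins with diameter at or above
#' `minDiameter`; objects below 30 nm (the default) are excluded from the
#' size analysis, matching AFM practice for small-EV preparations.
#'
#' @param diameter numeric bin diameters (nm, > 0). May also be a two-column
#'   data.frame/matrix `(diameter_nm, count)`.
#' @param count particle counts per bin (>= 0).
#' @param minDiameter exclusion threshold in nm (inclusive: `>=` kept).
#' @return weighted mean diameter in nm.
#' @export
weightedMeanDiameter <- function(diameter, count = NULL, minDiameter = 30) {
  if (is.null(count)) {
    stopifnot(ncol(diameter) >= 2L)
    count <- diameter[[2L]]
    diameter <- diameter[[1L]]
  }
  if (length(diameter) != length(count))
    stop("diameter and count must have equal length")
  if (any(diameter <= 0)) stop("diameters must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  keep <- diameter >= minDiameter & count > 0
  if (!any(keep))
    stop("no bins with diameter >= ", minDiameter, " nm and count > 0")
  sum(diameter[keep] * count[keep]) / sum(count[keep])
}

#' Read a UV-Vis spectrum TSV
#'
#' Two columns: `wavelength_nm`, `absorbance`.
#'
#' @param path TSV path.
#' @return data.frame with the two columns.
#' @export
readSpectrumTsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  need <- c("wavelength_nm", "absorbance")
  if (!all(need %in% colnames(df)))
    stop("spectrum TSV needs columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Read a particle size histogram TSV
#'
#' Two columns: `diameter_nm`, `count`.
#'
#' @param path TSV path.
#' @return data.frame with the two columns.
#' @export
readSizeHistogramTsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  need <- c("diameter_nm", "count")
  if (!all(need %in% colnames(df)))
    stop("size histogram TSV needs columns: ", paste(need, collapse = ", "))
  df[need]
}
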