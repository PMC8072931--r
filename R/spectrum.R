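#' Construct an absorbance spectrum
#'
#' @param wavelength Wavelength grid in nm, strictly increasing.
#' @param absorbance Absorbance values (AU), same length.
#' @param path Optical path length in cm (> 0).
#' @return A data frame of class `spectrum` with columns `wavelength` and
#'   `absorbance` and a `path_cm` attribute.
#' @export
new_spectrum <- function(wavelength, absorbance, path = 1) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance must have equal length")
  if (anyNA(wavelength) || is.unsorted(wavelength, strictly = TRUE))
    stop("wavelength grid must be strictly increasing (and unique)")
  if (!is.numeric(path) || length(path) != 1L || path <= 0)
    stop("path length must be a single positive number (cm)")
  structure(data.frame(wavelength = wavelength, absorbance = absorbance),
            path_cm = path, class = c("spectrum", "data.frame"))
}

path_cm <- function(s) {
  p <- attr(s, "path_cm")
  if (is.null(p)) 1 else p
}

#' Correct a spectrum for titrant dilution
#'
#' Differential titrations dilute the absorbing complex as titrant is added;
#' multiplying the recorded absorbances by `(V0 + V_added) / V0` puts all
#' spectra back on the initial-volume concentration scale, the convention in
#' which a two-species equilibrium shows a volume-independent isosbestic
#' point.
#'
#' @param raw A `spectrum`.
#' @param V0 Initial cell volume (any volume unit, > 0).
#' @param V_added Cumulative added titrant volume, same unit (>= 0).
#' @return The corrected `spectrum` (wavelengths unchanged).
#' @export
correct_dilution <- function(raw, V0, V_added) {
  if (!is.numeric(V0) || V0 <= 0) stop("V0 must be positive")
  if (!is.numeric(V_added) || V_added < 0) stop("V_added must be >= 0")
  out <- raw
  out$absorbance <- raw$absorbance * (V0 + V_added) / V0
  out
}

#' Protein concentration from A280
#'
#' Beer-Lambert quantitation of protein stock solutions from the absorbance
#' at 280 nm: `C = A / (epsilon * l)`. The molar absorptivities used in this
#' problem domain are 38940 M^-1 cm^-1 for hen egg-white lysozyme and
#' 8640 M^-1 cm^-1 for ribonuclease A.
#'
#' @param A Absorbance (AU, >= 0).
#' @param epsilon Molar absorptivity at 280 nm (M^-1 cm^-1, > 0).
#' @param path Path length in cm (> 0).
#' @return Molar concentration (M).
#' @export
#' @examples
#' concentration_from_a280(0.38940, 38940)  # 1e-5 M HEWL
concentration_from_a280 <- function(A, epsilon, path = 1) {
  if (!is.numeric(epsilon) || any(epsilon <= 0))
    stop("epsilon must be positive")
  if (!is.numeric(path) || any(path <= 0)) stop("path must be positive")
  if (any(A < 0)) stop("absorbance must be >= 0")
  A / (epsilon * path)
}

#' Difference between two spectra
#'
#' Interpolates both spectra onto their common wavelength range (the grid of
#' `s1` restricted to the overlap; `s2` linearly interpolated) and returns
#' the per-wavelength difference `s2 - s1` together with the location and
#' size of the largest absolute change. Used as a qualitative stability
#' probe, e.g. for the growth of a new band when a labile ligand exchanges
#' in buffer.
#'
#' @param s1,s2 `spectrum` objects with overlapping wavelength ranges.
#' @return A list with `wavelength`, `difference`, `max_abs_difference` and
#'   `lambda_max` (nm of the largest absolute difference).
#' @export
diff_spectra <- function(s1, s2) {
  lo <- max(min(s1$wavelength), min(s2$wavelength))
  hi <- min(max(s1$wavelength), max(s2$wavelength))
  if (lo > hi) stop("spectra have disjoint wavelength ranges")
  grid <- s1$wavelength[s1$wavelength >= lo & s1$wavelength <= hi]
  a1 <- stats::approx(s1$wavelength, s1$absorbance, xout = grid)$y
  a2 <- stats::approx(s2$wavelength, s2$absorbance, xout = grid)$y
  d <- a2 - a1
  i <- which.max(abs(d))
  list(wavelength = grid, difference = d,
       max_abs_difference = abs(d[i]), lambda_max = grid[i])
}

spectrum_at <- function(s, lambda) {
  if (lambda < min(s$wavelength) || lambda > max(s$wavelength))
    stop("analysis wavelength ", lambda, " nm outside the spectrum range")
  stats::approx(s$wavelength, s$absorbance, xout = lambda)$y
}
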