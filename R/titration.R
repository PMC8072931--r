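#' Construct a titration series
#'
#' Bundles the per-addition spectra of a differential UV-Vis titration with
#' the analytical (total) concentrations of complex and protein at each
#' point. Point 1 must be the protein-free spectrum of the complex alone: it
#' defines the free-complex molar absorptivity. Concentrations and spectra
#' must be expressed in a mutually consistent convention - either the actual
#' in-cell totals with raw spectra, or the initial-volume scale with
#' dilution-corrected spectra (see [correct_dilution()]).
#'
#' @param spectra List of [new_spectrum()] objects, one per titration point.
#' @param C_PtL Numeric vector of total complex concentrations (M).
#' @param C_protein Numeric vector of total protein concentrations (M);
#'   first element must be 0 and the vector non-decreasing.
#' @param volume_added Cumulative added titrant volume per point (L);
#'   defaults to zeros (unknown).
#' @param V0 Initial cell volume (L).
#' @param lambda_star Optional analysis wavelength (nm). When `NULL` the
#'   wavelength of maximum absolute change between the first and last
#'   spectrum is used at analysis time.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra, C_PtL, C_protein,
                             volume_added = NULL, V0 = NA_real_,
                             lambda_star = NULL) {
  n <- length(spectra)
  if (length(C_PtL) != n || length(C_protein) != n)
    stop("spectra, C_PtL and C_protein must have the same length")
  if (any(C_PtL < 0) || any(C_protein < 0))
    stop("concentrations must be >= 0")
  if (C_protein[1] != 0)
    stop("the first titration point must be protein-free (C_protein = 0)")
  if (is.unsorted(C_protein))
    stop("C_protein must be non-decreasing across points")
  if (is.null(volume_added)) volume_added <- numeric(n)
  structure(list(spectra = spectra, C_PtL = as.numeric(C_PtL),
                 C_protein = as.numeric(C_protein),
                 volume_added = as.numeric(volume_added),
                 V0 = V0, lambda_star = lambda_star),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series> ", length(x$spectra), " points, C_PtL ",
      format(x$C_PtL[1], digits = 4), " M, C_protein up to ",
      format(max(x$C_protein), digits = 4), " M\n", sep = "")
  if (!is.null(x$lambda_star))
    cat("  analysis wavelength: ", x$lambda_star, " nm\n", sep = "")
  invisible(x)
}

#' Analysis wavelength of a titration series
#'
#' The default analysis wavelength is the wavelength at which the absorbance
#' change between the first (protein-free) and last spectrum is largest in
#' magnitude.
#'
#' @param series A `titration_series`.
#' @return Wavelength in nm.
#' @export
default_lambda_star <- function(series) {
  if (!is.null(series$lambda_star)) return(series$lambda_star)
  n <- length(series$spectra)
  diff_spectra(series$spectra[[1]], series$spectra[[n]])$lambda_max
}

#' Build the binding isotherm from a titration series
#'
#' Evaluates each spectrum at the analysis wavelength (linear interpolation
#' if the wavelength is not a grid point), estimates the free-complex molar
#' absorptivity from the protein-free first point when not supplied, and
#' returns the differential signal `dA = A - eps_PtL * C_PtL * l`,
#' normalized to a 1 cm path.
#'
#' @param series A [titration_series()].
#' @param epsilon_PtL Free-complex molar absorptivity at the analysis
#'   wavelength (M^-1 cm^-1). Default: estimated from point 1 as
#'   `A(lambda*) / (l * C_PtL)`.
#' @param lambda_star Analysis wavelength (nm); default per
#'   [default_lambda_star()].
#' @return A data frame of class `binding_isotherm` with columns `C_PtL`,
#'   `C_protein`, `dA`, and attributes `lambda_star`, `epsilon_PtL`.
#' @export
build_isotherm <- function(series, epsilon_PtL = NULL, lambda_star = NULL) {
  if (length(series$spectra) < 4L)
    stop("need at least 4 titration points for the downstream regressions")
  lam <- if (is.null(lambda_star)) default_lambda_star(series) else lambda_star
  A <- vapply(series$spectra, function(s) spectrum_at(s, lam) / path_cm(s),
              numeric(1))
  if (is.null(epsilon_PtL)) {
    if (series$C_PtL[1] <= 0)
      stop("cannot estimate epsilon_PtL: first point has C_PtL = 0")
    epsilon_PtL <- A[1] / series$C_PtL[1]
  }
  dA <- A - epsilon_PtL * series$C_PtL
  structure(data.frame(C_PtL = series$C_PtL, C_protein = series$C_protein,
                       dA = dA),
            lambda_star = lam, epsilon_PtL = epsilon_PtL,
            class = c("binding_isotherm", "data.frame"))
}

#' Solve the 1:1 / n-equivalent-site binding equilibrium
#'
#' For the equilibrium `protein + PtL <-> protein-PtL` generalized to `n`
#' independent equivalent sites per protein, the bound concentration `x`
#' satisfies the mass-action quadratic
#' `K x^2 - (K (C_PtL + n C_protein) + 1) x + K n C_protein C_PtL = 0`.
#' The smaller root is the physical one; it is computed in the numerically
#' stable form `2c / (b + sqrt(b^2 - 4ac))`, which is exact down to K = 0
#' (no binding) and up to the stoichiometric limit
#' `min(C_PtL, n C_protein)` as K grows.
#'
#' @param C_PtL Total complex concentration (M), vectorized.
#' @param C_protein Total protein concentration (M), vectorized.
#' @param K Binding constant (M^-1, >= 0).
#' @param n Equivalent sites per protein (> 0), default 1.
#' @return Bound complex concentration (M).
#' @export
#' @examples
#' solve_equilibrium(1e-5, 1e-4, K = 1e4)
solve_equilibrium <- function(C_PtL, C_protein, K, n = 1) {
  if (any(K < 0)) stop("K must be >= 0")
  if (any(n <= 0)) stop("n must be > 0")
  if (any(C_PtL < 0) || any(C_protein < 0))
    stop("concentrations must be >= 0")
  S <- n * C_protein
  b <- K * (C_PtL + S) + 1
  cc <- K * S * C_PtL
  disc <- b^2 - 4 * K * cc
  disc[disc < 0] <- 0  # guard rounding; true discriminant is >= 1
  2 * cc / (b + sqrt(disc))
}
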