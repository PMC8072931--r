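gauss_band <- function(lambda, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(lambda - center)^2 / (2 * s^2))
}

#' Simulate a differential UV-Vis titration
#'
#' Forward model for a two-species Beer-Lambert titration with 1:1 (or
#' n-equivalent-site) binding. The free complex absorbs as a Gaussian band;
#' the bound adduct is the same band shifted by `bound_shift_nm` and scaled
#' so that the absorptivity change at the free band maximum equals
#' `delta_eps`. Because both basis spectra are Gaussians of equal width
#' there is a single wavelength where they cross - a well-defined isosbestic
#' point, as expected for a simple two-species equilibrium (it is reported
#' in the `truth` attribute). The protein contributes no absorbance,
#' emulating the differential (double-cell) titration design.
#'
#' Each addition dilutes the complex and adds protein from the stock; the
#' generator solves the exact mass-action equilibrium at the *actual*
#' in-cell totals and stores spectra uncorrected, with those totals, so the
#' forward model used here is exactly the model the estimators invert.
#' Apply [correct_dilution()] to reproduce the instrument-convention
#' (initial-volume scale) spectra, in which the isosbestic absorbance is
#' constant.
#'
#' @param K Binding constant (M^-1).
#' @param n Equivalent sites per protein.
#' @param delta_eps Absorptivity change at the free band maximum
#'   (M^-1 cm^-1, signed; negative = hypochromism).
#' @param eps_max Free-complex absorptivity at the band maximum
#'   (M^-1 cm^-1); must exceed `|delta_eps|` for a physical bound spectrum.
#' @param lambda0 Free band maximum (nm).
#' @param band_fwhm Band full width at half maximum (nm).
#' @param bound_shift_nm Red-shift of the bound band (nm, non-zero).
#' @param C_PtL0 Initial complex concentration in the cell (M). Default
#'   1.304e-4 M: 150 uL of a 1e-3 M stock in 1.15 mL.
#' @param protein_stock Protein titrant concentration (M), default 2e-3.
#' @param additions Number of titrant additions (default 15).
#' @param add_volume Volume per addition (L), default 8.2e-6 (one turn of
#'   the micrometric screw syringe).
#' @param V0 Initial cell volume (L), default 1.15e-3.
#' @param sigma_A Additive Gaussian absorbance noise (AU), default 0.002.
#' @param seed Optional RNG seed; a fixed seed makes the series
#'   reproducible byte-for-byte.
#' @param wavelengths Wavelength grid (nm).
#' @param path Path length (cm).
#' @return A [titration_series()] with a `truth` attribute: the generating
#'   parameters, the isosbestic wavelength, and the free/bound absorptivity
#'   curves on the wavelength grid.
#' @export
simulate_titration <- function(K = 1e4, n = 1, delta_eps = -5000,
                               eps_max = 12000, lambda0 = 378,
                               band_fwhm = 60, bound_shift_nm = 10,
                               C_PtL0 = 1.304e-4, protein_stock = 2e-3,
                               additions = 15, add_volume = 8.2e-6,
                               V0 = 1.15e-3, sigma_A = 0.002, seed = NULL,
                               wavelengths = seq(300, 500, by = 1),
                               path = 1) {
  if (eps_max + delta_eps <= 0)
    stop("eps_max + delta_eps must be positive (bound species absorbs)")
  if (bound_shift_nm == 0) stop("bound_shift_nm must be non-zero")
  if (sigma_A < 0) stop("sigma_A must be >= 0")
  if (K * protein_stock < 0.1)
    warning("unsaturated scenario: K * protein_stock = ",
            formatC(K * protein_stock, digits = 3),
            " < 0.1; K will be poorly determined")
  if (!is.null(seed)) set.seed(seed)
  s <- band_fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-bound_shift_nm^2 / (2 * s^2))
  scale_bound <- (eps_max + delta_eps) / (eps_max * g)
  eps_free <- eps_max * gauss_band(wavelengths, lambda0, band_fwhm)
  eps_bound <- scale_bound * eps_max *
    gauss_band(wavelengths, lambda0 + bound_shift_nm, band_fwhm)
  lambda_iso <- lambda0 +
    (bound_shift_nm^2 - 2 * s^2 * log(scale_bound)) / (2 * bound_shift_nm)
  V <- (0:additions) * add_volume
  C_L <- C_PtL0 * V0 / (V0 + V)
  C_P <- protein_stock * V / (V0 + V)
  spectra <- lapply(seq_along(V), function(i) {
    x <- solve_equilibrium(C_L[i], C_P[i], K, n)
    A <- path * (eps_free * (C_L[i] - x) + eps_bound * x)
    if (sigma_A > 0) A <- A + stats::rnorm(length(A), 0, sigma_A)
    new_spectrum(wavelengths, A, path = path)
  })
  out <- titration_series(spectra, C_L, C_P, volume_added = V, V0 = V0)
  attr(out, "truth") <- list(K = K, n = n, delta_eps = delta_eps,
                             eps_max = eps_max, lambda0 = lambda0,
                             bound_shift_nm = bound_shift_nm,
                             lambda_iso = lambda_iso,
                             eps_free = eps_free, eps_bound = eps_bound,
                             wavelengths = wavelengths, sigma_A = sigma_A)
  out
}

#' Simulate a DSC thermogram
#'
#' Sum of two-state excess heat capacity components ([two_state_cp()]) on a
#' uniform temperature grid, plus Gaussian noise scaled to the peak height.
#' A single population reproduces a clean two-state endotherm; several
#' populations a few kelvin apart emulate the shouldered thermograms of
#' heterogeneous protein-complex mixtures that a single two-state fit must
#' reject.
#'
#' @param T_d Denaturation temperature (K) of the single population.
#' @param dH Denaturation enthalpy (kJ/mol) of the single population.
#' @param dCp Heat-capacity increment (kJ mol^-1 K^-1).
#' @param sigma_frac Noise SD as a fraction of peak height (default 0.01).
#' @param T_range_C Scanned range, degrees Celsius (default 20-95, the
#'   instrument window).
#' @param step Grid step in K (default 0.1, must be <= 0.2).
#' @param seed Optional RNG seed.
#' @param populations Optional data frame with columns `weight`, `T_d`,
#'   `dH` (and optionally `dCp`); weights must sum to 1. Overrides
#'   `T_d`/`dH`.
#' @param protein_M,scan_rate Metadata copied onto the thermogram
#'   (defaults 2e-4 M, 0.5 K/min).
#' @return A [thermogram()].
#' @export
simulate_dsc <- function(T_d = 350, dH = 450, dCp = 0, sigma_frac = 0.01,
                         T_range_C = c(20, 95), step = 0.1, seed = NULL,
                         populations = NULL, protein_M = 2e-4,
                         scan_rate = 0.5) {
  if (step > 0.2) stop("grid step must be <= 0.2 K")
  if (T_range_C[1] < 15 || T_range_C[2] > 100)
    stop("T_range_C must lie within 15-100 degC")
  if (sigma_frac < 0) stop("sigma_frac must be >= 0")
  if (is.null(populations))
    populations <- data.frame(weight = 1, T_d = T_d, dH = dH)
  if (is.null(populations$dCp)) populations$dCp <- dCp
  if (abs(sum(populations$weight) - 1) > 1e-8)
    stop("population weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  TK <- seq(T_range_C[1] + 273.15, T_range_C[2] + 273.15, by = step)
  cp <- rowSums(vapply(seq_len(nrow(populations)), function(i) {
    populations$weight[i] *
      two_state_cp(TK, populations$dH[i], populations$T_d[i],
                   populations$dCp[i])
  }, numeric(length(TK))))
  if (sigma_frac > 0)
    cp <- cp + stats::rnorm(length(cp), 0, sigma_frac * max(cp))
  thermogram(TK, cp, unit = "K", protein_M = protein_M,
             scan_rate = scan_rate)
}

#' Simulate a positive-mode ESI charge envelope
#'
#' For each species and each charge state in `z_range`, places a Gaussian
#' peak at `mz_from_mass(M, z)` with intensity proportional to the species
#' abundance times a Gaussian charge-state envelope, on a uniform m/z grid
#' clipped to the acquisition window. Noise is multiplicative,
#' `N(1, sigma_rel)` per grid point.
#'
#' @param masses Neutral masses (Da, > 0).
#' @param abundances Relative abundances, same length (default equal).
#' @param z_range Charge states (default 6:15).
#' @param envelope_center_z Centre of the charge-state envelope.
#' @param envelope_width SD of the charge-state envelope (in charge units).
#' @param peak_fwhm_mz Peak full width at half maximum (m/z).
#' @param sigma_rel Relative intensity noise (default 0.02).
#' @param seed Optional RNG seed.
#' @param mz_window Acquisition window (default c(1000, 2600)).
#' @param mz_step Grid step (default 0.25).
#' @return A data frame with columns `mz`, `intensity`.
#' @export
simulate_esi_spectrum <- function(masses, abundances = NULL,
                                  z_range = 6:15, envelope_center_z = 10,
                                  envelope_width = 2, peak_fwhm_mz = 1,
                                  sigma_rel = 0.02, seed = NULL,
                                  mz_window = c(1000, 2600),
                                  mz_step = 0.25) {
  if (any(masses <= 0)) stop("masses must be positive")
  if (is.null(abundances)) abundances <- rep(1, length(masses))
  if (length(abundances) != length(masses))
    stop("masses and abundances must have equal length")
  if (sigma_rel < 0) stop("sigma_rel must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mz <- seq(mz_window[1], mz_window[2], by = mz_step)
  intensity <- numeric(length(mz))
  any_in <- FALSE
  for (i in seq_along(masses)) {
    if (abundances[i] <= 0) next
    for (z in z_range) {
      center <- mz_from_mass(masses[i], z)
      if (center < mz_window[1] || center > mz_window[2]) next
      any_in <- TRUE
      w <- abundances[i] *
        exp(-(z - envelope_center_z)^2 / (2 * envelope_width^2))
      intensity <- intensity + w * gauss_band(mz, center, peak_fwhm_mz)
    }
  }
  if (!any_in && any(abundances > 0))
    warning("all predicted peaks fall outside the acquisition window")
  if (sigma_rel > 0)
    intensity <- pmax(0, intensity *
                        stats::rnorm(length(intensity), 1, sigma_rel))
  data.frame(mz = mz, intensity = intensity)
}
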