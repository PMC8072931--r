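read_csv_checked <- function(path, required) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot read ", path, ": ",
                                          conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))
      if (length(bad) > 0L)
        stop("non-numeric value in column ", sQuote(col), " at data row ",
             bad[1], " of ", path)
      df[[col]] <- suppress
    }
  }
  df
}

#' Read a titration CSV
#'
#' Long-format titration file with columns `addition_index`,
#' `volume_added_uL`, `wavelength_nm`, `absorbance`; the accompanying
#' configuration supplies the analytical setup. Analytical totals per point
#' are computed from the volumes: by default the actual (diluted) in-cell
#' totals with spectra kept as recorded; with
#' `dilution_correct = TRUE` the spectra are rescaled to the initial-volume
#' convention ([correct_dilution()]) and the totals put on the same scale
#' (constant `C_PtL`, `C_protein = stock * V / V0`).
#'
#' @param path CSV file path.
#' @param config List with `C_PtL_initial_M`, `protein_stock_M`, `V0_mL`,
#'   `path_cm`, and optionally `lambda_star_nm`. May also be a path to a
#'   JSON file with those fields.
#' @param dilution_correct Apply the initial-volume convention
#'   (default `FALSE`).
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path, config, dilution_correct = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("C_PtL_initial_M", "protein_stock_M", "V0_mL", "path_cm")
  if (!all(need %in% names(config)))
    stop("config lacks field(s): ",
         paste(setdiff(need, names(config)), collapse = ", "))
  df <- read_csv_checked(path, c("addition_index", "volume_added_uL",
                                 "wavelength_nm", "absorbance"))
  V0 <- config$V0_mL * 1e-3
  idx <- sort(unique(df$addition_index))
  spectra <- list(); V <- numeric(length(idx))
  for (j in seq_along(idx)) {
    sub <- df[df$addition_index == idx[j], , drop = FALSE]
    sub <- sub[order(sub$wavelength_nm), , drop = FALSE]
    if (anyDuplicated(sub$wavelength_nm))
      stop("duplicate wavelength at addition_index ", idx[j])
    vu <- unique(sub$volume_added_uL)
    if (length(vu) != 1L)
      stop("inconsistent volume_added_uL at addition_index ", idx[j])
    V[j] <- vu * 1e-6
    spectra[[j]] <- new_spectrum(sub$wavelength_nm, sub$absorbance,
                                 path = config$path_cm)
  }
  C_L <- config$C_PtL_initial_M * V0 / (V0 + V)
  C_P <- config$protein_stock_M * V / (V0 + V)
  if (dilution_correct) {
    spectra <- lapply(seq_along(spectra), function(j)
      correct_dilution(spectra[[j]], V0, V[j]))
    C_L <- rep(config$C_PtL_initial_M, length(V))
    C_P <- config$protein_stock_M * V / V0
  }
  titration_series(spectra, C_L, C_P, volume_added = V, V0 = V0,
                   lambda_star = config$lambda_star_nm)
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()] (long format; raw spectra as stored).
#'
#' @param series A [titration_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(seq_along(series$spectra), function(j) {
    s <- series$spectra[[j]]
    data.frame(addition_index = j - 1L,
               volume_added_uL = series$volume_added[j] * 1e6,
               wavelength_nm = s$wavelength,
               absorbance = s$absorbance)
  }))
  utils::write.csv(format(rows, digits = 12, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DSC thermogram CSV
#'
#' Columns `temperature_C` and `cp_exc_kJ_mol_K` (excess molar heat
#' capacity), or `temperature_C` and `power_uW` (raw differential power),
#' in which case `config` must supply `protein_M`, `cell_volume_mL` and
#' `scan_rate_K_min` and the conversion
#' `Cp_exc = power / (scan_rate * moles)` is applied.
#'
#' @param path CSV path.
#' @param config Optional list for the raw-power conversion.
#' @return A [thermogram()] (kelvin grid).
#' @export
read_thermogram_csv <- function(path, config = NULL) {
  df <- read_csv_checked(path, "temperature_C")
  if ("cp_exc_kJ_mol_K" %in% names(df)) {
    df <- read_csv_checked(path, c("temperature_C", "cp_exc_kJ_mol_K"))
    cp <- df$cp_exc_kJ_mol_K
  } else if ("power_uW" %in% names(df)) {
    df <- read_csv_checked(path, c("temperature_C", "power_uW"))
    need <- c("protein_M", "cell_volume_mL", "scan_rate_K_min")
    if (is.null(config) || !all(need %in% names(config)))
      stop("raw power input requires config fields: ",
           paste(need, collapse = ", "))
    moles <- config$protein_M * config$cell_volume_mL * 1e-3
    rate_K_s <- config$scan_rate_K_min / 60
    cp <- df$power_uW * 1e-6 / (rate_K_s * moles) / 1000  # -> kJ/(mol K)
  } else {
    stop("file ", path,
         " lacks required column(s): cp_exc_kJ_mol_K (or power_uW)")
  }
  thermogram(df$temperature_C, cp, unit = "C",
             protein_M = if (!is.null(config$protein_M))
               config$protein_M else NA_real_,
             scan_rate = if (!is.null(config$scan_rate_K_min))
               config$scan_rate_K_min else NA_real_)
}

#' Write a thermogram to CSV
#'
#' Degrees Celsius on output, per the instrument convention.
#'
#' @param t A [thermogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram_csv <- function(t, path) {
  out <- data.frame(temperature_C = t$T_K - 273.15,
                    cp_exc_kJ_mol_K = t$cp_exc)
  utils::write.csv(format(out, digits = 12, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mass-spectrometry peak list CSV
#'
#' Accepts either a deconvolved neutral-mass list (`mass_da`, `intensity`)
#' or a raw m/z trace (`mz`, `intensity`); the column names decide which.
#'
#' @param path CSV path.
#' @return For neutral lists, a data frame `mass`, `intensity` of class
#'   `neutral_peaklist`; for raw traces, a data frame `mz`, `intensity`.
#' @export
read_peaklist_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("mass_da" %in% names(df)) {
    df <- read_csv_checked(path, c("mass_da", "intensity"))
    if (any(df$mass_da <= 0)) stop("neutral masses must be positive")
    structure(data.frame(mass = df$mass_da, intensity = df$intensity),
              class = c("neutral_peaklist", "data.frame"))
  } else if ("mz" %in% names(df)) {
    read_csv_checked(path, c("mz", "intensity"))
  } else {
    stop("file ", path, " lacks required column(s): mass_da or mz")
  }
}

#' Write a peak list to CSV
#'
#' @param x A `neutral_peaklist` (columns `mass`, `intensity`) or a raw
#'   trace (columns `mz`, `intensity`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(x, path) {
  out <- if ("mass" %in% names(x))
    data.frame(mass_da = x$mass, intensity = x$intensity)
  else data.frame(mz = x$mz, intensity = x$intensity)
  utils::write.csv(format(out, digits = 12, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_report_list <- function(x) {
  if (inherits(x, "binding_fit")) {
    list(model = "binding_1to1", method = x$method, K_M = x$K,
         se_K = x$se_K, delta_eps = x$delta_eps,
         epsilon_PtL = x$epsilon_PtL, lambda_star_nm = x$lambda_star,
         iterations = x$iterations, delta_eps_trace = x$trace,
         converged = x$converged, K_unreliable = x$K_unreliable)
  } else if (inherits(x, "scatchard_fit")) {
    list(model = "scatchard", n = x$n, se_n = x$se_n, K_M = x$K,
         se_K = x$se_K, delta_eps = x$delta_eps,
         n_poorly_determined = x$n_poorly_determined,
         K_unreliable = x$K_unreliable)
  } else if (inherits(x, "dsc_fit")) {
    list(model = "two_state_dsc", status = x$status,
         T_d_C = x$T_d - 273.15, dH_vH_kJ_mol = x$dH_vH,
         dH_cal_kJ_mol = x$dH_cal, dS_d_kJ_mol_K = x$dS_d,
         cooperativity_ratio = x$cooperativity_ratio,
         rms_residual = x$rms_residual, peak_height = x$peak_height)
  } else if (is.list(x)) {
    x
  } else {
    stop("don't know how to report an object of class ",
         paste(class(x), collapse = "/"))
  }
}

#' Write a machine-readable analysis report
#'
#' Serializes fit results (or any list) to JSON with a provenance block:
#' package version, seed and configuration echo, so a run can be reproduced
#' from its report alone.
#'
#' @param results A fit object (`binding_fit`, `scatchard_fit`, `dsc_fit`),
#'   a list of them, or a plain list.
#' @param path Output JSON path.
#' @param seed The RNG seed the run used (echoed, not applied).
#' @param config Optional configuration list to echo.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = NULL) {
  body <- if (is.list(results) && !inherits(results, c("binding_fit",
                                                       "scatchard_fit",
                                                       "dsc_fit"))) {
    lapply(results, as_report_list)
  } else {
    as_report_list(results)
  }
  out <- list(
    provenance = list(
      package = "ptbind",
      version = as.character(utils::packageVersion("ptbind")),
      seed = seed,
      config = config,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    results = body)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
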