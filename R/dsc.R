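# Gas constant, kJ mol^-1 K^-1 (CODATA).
R_GAS <- 8.314462618e-3

#' Construct a thermogram
#'
#' Holds an excess molar heat capacity curve on a strictly increasing
#' temperature grid. Temperatures are stored in kelvin internally; instrument
#' files are in degrees Celsius and converted exactly (T_K = T_C + 273.15)
#' at I/O time.
#'
#' @param temperature Temperature grid, strictly increasing.
#' @param cp_exc Excess molar heat capacity (kJ mol^-1 K^-1), same length.
#' @param unit `"K"` (default) or `"C"` for the input grid.
#' @param protein_M Protein molarity (metadata).
#' @param scan_rate Scan rate in K/min (metadata).
#' @return A data frame of class `thermogram` with columns `T_K`, `cp_exc`.
#' @export
thermogram <- function(temperature, cp_exc, unit = c("K", "C"),
                       protein_M = NA_real_, scan_rate = NA_real_) {
  unit <- match.arg(unit)
  TK <- if (unit == "C") temperature + 273.15 else temperature
  if (length(TK) != length(cp_exc))
    stop("temperature and cp_exc must have equal length")
  if (anyNA(TK) || is.unsorted(TK, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
  structure(data.frame(T_K = as.numeric(TK), cp_exc = as.numeric(cp_exc)),
            protein_M = protein_M, scan_rate = scan_rate,
            class = c("thermogram", "data.frame"))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Subtract a sigmoidal progress baseline
#'
#' Removes the chemical (pre/post-transition) baseline from a thermogram:
#' straight lines are fitted in a pre-transition and a post-transition
#' window, and connected through the transition by the normalized running
#' integral of the signal (the extent-of-conversion weighting), iterated
#' twice. This handles the asymmetric endotherms typical of protein
#' denaturation better than a plain chord. The result is approximately zero
#' inside both windows and the peak area is preserved.
#'
#' @param raw A [thermogram()].
#' @param pre_window,post_window Length-2 numeric `c(T_lo, T_hi)` in K
#'   delimiting the baseline windows. Defaults: first and last 10% of the
#'   scanned range.
#' @param iterations Number of progress-baseline refinements (default 2).
#' @return The baseline-subtracted `thermogram`.
#' @export
subtract_baseline <- function(raw, pre_window = NULL, post_window = NULL,
                              iterations = 2) {
  TK <- raw$T_K; y <- raw$cp_exc
  rng <- range(TK); span <- diff(rng)
  if (is.null(pre_window)) pre_window <- c(rng[1], rng[1] + 0.1 * span)
  if (is.null(post_window)) post_window <- c(rng[2] - 0.1 * span, rng[2])
  pre_i <- TK >= pre_window[1] & TK <= pre_window[2]
  post_i <- TK >= post_window[1] & TK <= post_window[2]
  if (sum(pre_i) < 5L || sum(post_i) < 5L)
    stop("each baseline window must contain at least 5 points")
  ipk <- which.max(y)
  prominent <- y[ipk] > max(mean(y[pre_i]), mean(y[post_i]))
  if (prominent && (pre_i[ipk] || post_i[ipk]))
    stop("baseline window overlaps the transition peak")
  pre_fit <- stats::lm(y[pre_i] ~ TK[pre_i])
  post_fit <- stats::lm(y[post_i] ~ TK[post_i])
  pre_line <- stats::coef(pre_fit)[1] + stats::coef(pre_fit)[2] * TK
  post_line <- stats::coef(post_fit)[1] + stats::coef(post_fit)[2] * TK
  cumtrapz <- function(x, v) {
    c(0, cumsum(diff(x) * (v[-1] + v[-length(v)]) / 2))
  }
  alpha <- local({
    ct <- cumtrapz(TK, y - pre_line)
    tot <- ct[length(ct)]
    if (tot == 0) rep(0.5, length(TK)) else pmin(1, pmax(0, ct / tot))
  })
  b <- (1 - alpha) * pre_line + alpha * post_line
  for (i in seq_len(iterations)) {
    s <- y - b
    ct <- cumtrapz(TK, s)
    tot <- ct[length(ct)]
    alpha <- if (tot == 0) rep(0.5, length(TK)) else
      pmin(1, pmax(0, ct / tot))
    b <- (1 - alpha) * pre_line + alpha * post_line
  }
  out <- raw
  out$cp_exc <- y - b
  out
}

#' Calorimetric denaturation enthalpy
#'
#' The denaturation enthalpy is the area under the (baseline-subtracted)
#' excess heat capacity peak: the trapezoidal integral of `cp_exc` over T.
#'
#' @param t A baseline-subtracted [thermogram()].
#' @return Enthalpy in kJ/mol.
#' @export
integrate_enthalpy <- function(t) trapz(t$T_K, t$cp_exc)

#' Denaturation temperature from a thermogram
#'
#' Returns the temperature of maximum excess heat capacity, refined by a
#' quadratic through the three grid points around the maximum. A warning is
#' emitted for multimodal (shouldered) thermograms - secondary local maxima
#' above half the global peak - and for ties (the lowest-temperature maximum
#' is returned).
#'
#' @param t A [thermogram()].
#' @return Temperature in K.
#' @export
find_td <- function(t) {
  TK <- t$T_K; y <- t$cp_exc
  imax <- which(y == max(y))
  if (length(imax) > 1L)
    warning("multiple equal maxima: returning the lowest temperature")
  i <- imax[1]
  # shoulder detection: local maxima above 50% of the peak, separated from it
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  loc <- loc[y[loc] > 0.5 * y[i] & abs(TK[loc] - TK[i]) > 1]
  if (length(loc) > 0L)
    warning("thermogram appears multimodal/shouldered (",
            length(loc), " secondary maximum/maxima above half peak)")
  if (i == 1L || i == length(y)) return(TK[i])
  # vertex of the parabola through the three points around the maximum
  x1 <- TK[i - 1L] - TK[i]; x2 <- TK[i + 1L] - TK[i]
  y1 <- y[i - 1L] - y[i]; y2 <- y[i + 1L] - y[i]
  den <- x1 * y2 - x2 * y1
  if (den == 0) return(TK[i])
  TK[i] + 0.5 * (x1^2 * y2 - x2^2 * y1) / den
}

#' Two-state excess heat capacity model
#'
#' The single-step (two-state, N <-> D) equilibrium model for the excess
#' molar heat capacity of protein denaturation:
#' `dG(T) = dH_vH (1 - T/T_d) + dCp ((T - T_d) - T log(T/T_d))`,
#' `K_eq = exp(-dG/(R T))`, denatured fraction `f_D = K_eq/(1+K_eq)`, and
#' `Cp_exc = dH(T) * df_D/dT + f_D * dCp` with the temperature-consistent
#' enthalpy `dH(T) = dH_vH + dCp (T - T_d)` and the analytic derivative
#' `df_D/dT = dH(T) f_D (1-f_D) / (R T^2)`. With `dCp = 0` the peak value
#' is `dH_vH^2 / (4 R T_d^2)` at `T = T_d` and the area equals `dH_vH`.
#'
#' @param T Temperature(s) in K (> 0).
#' @param dH_vH Van't Hoff enthalpy (kJ/mol).
#' @param T_d Denaturation temperature (K), where `f_D = 1/2`.
#' @param dCp Denaturational heat-capacity increment
#'   (kJ mol^-1 K^-1, default 0).
#' @return Excess heat capacity (kJ mol^-1 K^-1), vectorized over `T`.
#' @export
two_state_cp <- function(T, dH_vH, T_d, dCp = 0) {
  if (any(T <= 0)) stop("temperature must be positive (K)")
  dG <- dH_vH * (1 - T / T_d) + dCp * ((T - T_d) - T * log(T / T_d))
  # f_D = 1/(1+exp(dG/RT)) computed through plogis for overflow safety
  fD <- stats::plogis(-dG / (R_GAS * T))
  dH_T <- dH_vH + dCp * (T - T_d)
  dfdT <- dH_T * fD * (1 - fD) / (R_GAS * T^2)
  dH_T * dfdT + fD * dCp
}

#' Denaturation entropy at the midpoint
#'
#' At `T_d` the two states are equally populated, `dG(T_d) = 0`, so the
#' standard denaturation entropy is `dS = dH / T_d`. This is the quantity
#' through which thermal destabilization by a bound ligand is usually
#' expressed as "entropic" when `dH` is unchanged while `T_d` drops.
#'
#' @param dH Denaturation enthalpy (kJ/mol), or a `dsc_fit` object (then
#'   the calorimetric enthalpy and fitted `T_d` are used).
#' @param T_d Denaturation temperature (K). Ignored when `dH` is a fit.
#' @return Entropy in kJ mol^-1 K^-1.
#' @export
entropy_at_td <- function(dH, T_d) {
  if (inherits(dH, "dsc_fit")) {
    T_d <- dH$T_d
    dH <- dH$dH_cal
  }
  if (any(T_d <= 0)) stop("T_d must be positive (K)")
  dH / T_d
}

#' Correct a thermogram for native-protein loss on incubation
#'
#' Prolonged incubation irreversibly removes a fraction of the native
#' protein, shrinking the denaturation endotherm without changing its
#' profile; dividing by the surviving fraction restores the per-mole scale.
#' Multiple sequential losses (e.g. a fraction after 24 h and a further
#' fraction over the next 24 h) compose multiplicatively: pass them as a
#' vector and the signal is scaled by `1 / prod(1 - loss_fraction)`.
#'
#' @param t A [thermogram()].
#' @param loss_fraction One or more loss fractions, each in `[0, 1)`.
#' @return The rescaled `thermogram`.
#' @export
#' @examples
#' \dontrun{
#' correct_native_loss(tg, 0.12)          # 24 h incubation
#' correct_native_loss(tg, c(0.12, 0.09)) # 48 h: composed losses
#' }
correct_native_loss <- function(t, loss_fraction) {
  if (any(loss_fraction < 0) || any(loss_fraction >= 1))
    stop("loss_fraction must be in [0, 1)")
  out <- t
  out$cp_exc <- t$cp_exc / prod(1 - loss_fraction)
  out
}
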