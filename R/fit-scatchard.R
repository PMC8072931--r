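#' Scatchard analysis of equivalent sites
#'
#' Fits the linearized independent-equivalent-sites model: regressing
#' `Y = C_protein (C_PtL delta_eps - dA) / dA` on
#' `X = (C_PtL delta_eps - dA)` gives slope `1/(n delta_eps)` and intercept
#' `1/(n K)`, whence `n = 1/(slope * delta_eps)` and
#' `K = slope * delta_eps / intercept`. Since
#' `C_PtL delta_eps - dA = delta_eps * [PtL]_free`, this is the classical
#' Scatchard line `[L]/r = 1/(nK) + [L]/n` written in absorbance variables.
#' The transform is exact for data lying on `r = n K [L] / (1 + K [L])`.
#'
#' `delta_eps` is not estimated here: it comes from the amplitude of the
#' binding isotherm and is confirmed by the iterative 1:1 analysis
#' ([fit_binding()]).
#'
#' @param iso A [build_isotherm()] result.
#' @param delta_eps Molar absorptivity change (M^-1 cm^-1, signed, non-zero),
#'   sign-consistent with the isotherm.
#' @param ... Unused.
#' @return An object of class `scatchard_fit` with `n` (sites per protein),
#'   `K` (M^-1), `slope`, `intercept`, standard errors (delta method for
#'   `n` and `K`), an `n_poorly_determined` flag (raised when the abscissa,
#'   proportional to the free-ligand concentration, spans less than one
#'   decade), and the transformed points.
#' @export
fit_scatchard <- function(iso, delta_eps, ...) {
  if (!is.numeric(delta_eps) || length(delta_eps) != 1L || delta_eps == 0)
    stop("delta_eps must be a single non-zero number")
  pts <- prepare_isotherm_points(iso)
  if (sign(delta_eps) != sign(pts$dA[which.max(abs(pts$dA))]))
    stop("delta_eps sign inconsistent with the isotherm")
  X <- pts$C_PtL * delta_eps - pts$dA   # = delta_eps * [PtL]_free
  Y <- pts$C_protein * X / pts$dA
  fit <- stats::lm(Y ~ X)
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  n <- 1 / (slope * delta_eps)
  K <- slope * delta_eps / intercept
  se_slope <- sqrt(vc[2, 2]); se_int <- sqrt(vc[1, 1])
  se_n <- abs(n) * se_slope / abs(slope)
  se_K <- abs(K) * sqrt((se_slope / slope)^2 + (se_int / intercept)^2 -
                          2 * vc[1, 2] / (slope * intercept))
  span <- max(abs(X)) / min(abs(X))
  n_poor <- span < 10
  if (n_poor)
    warning("free-ligand abscissa spans only ",
            formatC(span, digits = 3), "x (< 1 decade): ",
            "n poorly determined")
  t_int <- intercept / se_int
  K_unreliable <- !is.finite(t_int) || abs(t_int) < 2
  if (K_unreliable)
    warning("K unreliable: intercept not distinguishable from 0 (|t| = ",
            formatC(abs(t_int), digits = 3), " < 2)")
  out <- list(n = n, K = K, delta_eps = delta_eps,
              slope = slope, intercept = intercept,
              se_slope = se_slope, se_intercept = se_int,
              se_n = se_n, se_K = se_K,
              n_poorly_determined = n_poor, K_unreliable = K_unreliable,
              points = data.frame(X = X, Y = Y,
                                  C_PtL = pts$C_PtL,
                                  C_protein = pts$C_protein, dA = pts$dA),
              lm = fit)
  class(out) <- "scatchard_fit"
  out
}

#' @export
print.scatchard_fit <- function(x, digits = 4, ...) {
  cat("Scatchard (equivalent sites) fit\n")
  cat("  n = ", formatC(x$n, digits = digits, format = "g"),
      " sites/protein  (SE ", formatC(x$se_n, digits = 3, format = "g"),
      ")\n", sep = "")
  cat("  K = ", formatC(x$K, digits = digits, format = "g"),
      " M^-1  (SE ", formatC(x$se_K, digits = 3, format = "g"), ")\n",
      sep = "")
  if (isTRUE(x$n_poorly_determined))
    cat("  [n poorly determined: narrow free-ligand range]\n")
  if (isTRUE(x$K_unreliable)) cat("  [K flagged unreliable]\n")
  invisible(x)
}

#' @export
summary.scatchard_fit <- function(object, ...) {
  object$lm_summary <- suppressWarnings(summary(object$lm))
  class(object) <- c("summary.scatchard_fit", class(object))
  object
}

#' @export
print.summary.scatchard_fit <- function(x, ...) {
  print.scatchard_fit(x, ...)
  cat("  linear fit R^2 = ",
      formatC(x$lm_summary$r.squared, digits = 5), "\n", sep = "")
  invisible(x)
}

#' @export
coef.scatchard_fit <- function(object, ...) {
  c(n = object$n, K = object$K)
}

#' @export
residuals.scatchard_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
plot.scatchard_fit <- function(x, ...) {
  graphics::plot(x$points$X, x$points$Y,
                 xlab = expression(C[PtL] * Delta * epsilon - Delta * A),
                 ylab = expression(C[protein] *
                                     (C[PtL] * Delta * epsilon - Delta * A) /
                                     Delta * A), ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
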