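#' Define a reactive metal fragment
#'
#' A metal fragment is the part of a coordination complex that stays bound
#' to the protein after loss of the labile ligand - e.g. the dicationic
#' [Pt(phenyl-terpyridine)]2+ fragment left when the chloride or iodide
#' leaves. On the neutral-mass scale of deconvolved spectra, a fragment
#' carrying charge `q` displaces `q` protons from the protein, so each
#' bound fragment adds `average_mass(formula) - q * hydrogen_mass`.
#'
#' @param label Short name for reports.
#' @param formula Fragment composition (`chem_formula` or string), e.g.
#'   `"PtC21H15N3"`.
#' @param charge_displaced Protons displaced per bound fragment
#'   (integer 0, 1 or 2).
#' @param note Free-text provenance (parent complex, labile ligand lost).
#' @return An object of class `fragment_spec`.
#' @export
#' @examples
#' fragment_spec("Pt(phterpy)", "PtC21H15N3", 2,
#'               note = "complex 2 minus iodide")
fragment_spec <- function(label, formula, charge_displaced = 2, note = "") {
  if (!charge_displaced %in% 0:2)
    stop("charge_displaced must be 0, 1 or 2")
  structure(list(label = label, formula = as_chem_formula(formula),
                 q = as.integer(charge_displaced), note = note),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat("<fragment> ", x$label, " = ", format(x$formula), " (",
      formatC(average_mass(x$formula), format = "f", digits = 3),
      " Da), displaces ", x$q, " H\n", sep = "")
  if (nzchar(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' Predicted neutral mass of a protein-metal adduct
#'
#' `M0 + k * (average_mass(fragment) - q * hydrogen_mass)`: each of the `k`
#' bound fragments contributes its average mass minus one hydrogen atom per
#' displaced proton. The mass increment is independent of `M0` and additive
#' in `k` by construction.
#'
#' @param M0 Free protein neutral mass (Da, > 0).
#' @param frag A [fragment_spec()].
#' @param k Stoichiometry (>= 0; 0 returns `M0`).
#' @return Predicted neutral mass (Da).
#' @export
#' @examples
#' frag <- fragment_spec("Pt(phterpy)", "PtC21H15N3", 2)
#' predict_adduct_mass(13682, frag, 1)  # RNase A mono-adduct, ~14184 Da
predict_adduct_mass <- function(M0, frag, k = 1) {
  if (any(M0 <= 0)) stop("M0 must be positive")
  if (any(k < 0)) stop("k must be >= 0")
  M0 + k * (average_mass(frag$formula) - frag$q * hydrogen_mass)
}

#' Assign deconvolved peaks to protein-fragment-adduct compositions
#'
#' Matches each observed neutral mass against the composition grid
#' `free protein + k x fragment (+ optionally one small-anion adduct)` for
#' `k = 0..k_max` over all supplied fragments, choosing the composition
#' that minimizes the absolute mass error within the tolerance. Commercial
#' RNase A preparations carry isobaric sulphuric/phosphoric acid adducts
#' (+98 Da); both acids are in the default small-adduct list, and whenever
#' two candidate compositions fall within the tolerance *and* within 0.5 Da
#' of each other the peak is flagged ambiguous with all candidates listed,
#' never silently resolved.
#'
#' @param peaks Numeric vector of neutral masses (Da), or a data frame with
#'   columns `mass` (Da) and optionally `intensity`.
#' @param M0 Free protein neutral mass (Da).
#' @param fragments A [fragment_spec()] or list of them.
#' @param k_max Maximum fragments per protein (default 2).
#' @param small_adducts Named list of small-molecule adduct formulas added
#'   neutrally (default sulphuric and phosphoric acid).
#' @param tolerance Match tolerance in Da (default 1.5, reflecting the
#'   1 Da-scale spread of deconvolved protein masses).
#' @return A data frame of class `adduct_assignment` with one row per peak:
#'   `observed`, `predicted`, `composition`, `fragment`, `k`, `adduct`,
#'   `error_da`, `matched`, `ambiguous`, `candidates` (all within-tolerance
#'   compositions, ";"-separated).
#' @export
assign_adducts <- function(peaks, M0, fragments, k_max = 2,
                           small_adducts = list(H2SO4 = "H2SO4",
                                                H3PO4 = "H3PO4"),
                           tolerance = 1.5) {
  if (is.data.frame(peaks)) {
    masses <- peaks$mass
  } else {
    masses <- as.numeric(peaks)
  }
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (inherits(fragments, "fragment_spec")) fragments <- list(fragments)
  anion_mass <- vapply(small_adducts,
                       function(f) average_mass(as_chem_formula(f)),
                       numeric(1))
  anion_names <- c("", names(small_adducts))
  anion_mass <- c(0, anion_mass)
  # candidate composition table
  cand <- do.call(rbind, lapply(seq_along(fragments), function(fi) {
    frag <- fragments[[fi]]
    do.call(rbind, lapply(0:k_max, function(k) {
      data.frame(fragment = if (k == 0) "" else frag$label,
                 k = k,
                 adduct = anion_names,
                 predicted = predict_adduct_mass(M0, frag, k) + anion_mass,
                 stringsAsFactors = FALSE)
    }))
  }))
  cand <- unique(cand)
  label_of <- function(row) {
    parts <- "protein"
    if (row$k > 0) parts <- c(parts, paste0(row$k, "x", row$fragment))
    if (nzchar(row$adduct)) parts <- c(parts, row$adduct)
    paste(parts, collapse = " + ")
  }
  rows <- lapply(masses, function(m) {
    err <- cand$predicted - m
    hit <- which(abs(err) <= tolerance)
    if (length(hit) == 0L) {
      return(data.frame(observed = m, predicted = NA_real_,
                        composition = "unassigned", fragment = NA_character_,
                        k = NA_integer_, adduct = NA_character_,
                        error_da = NA_real_, matched = FALSE,
                        ambiguous = FALSE, candidates = "",
                        stringsAsFactors = FALSE))
    }
    best <- hit[which.min(abs(err[hit]))]
    # isobaric ambiguity: another within-tolerance candidate whose
    # predicted mass lies within 0.5 Da of the best one
    near <- hit[abs(cand$predicted[hit] - cand$predicted[best]) <= 0.5]
    amb <- length(near) > 1L
    labs <- vapply(near, function(i) label_of(cand[i, ]), character(1))
    data.frame(observed = m, predicted = cand$predicted[best],
               composition = label_of(cand[best, ]),
               fragment = cand$fragment[best], k = cand$k[best],
               adduct = cand$adduct[best],
               error_da = m - cand$predicted[best],
               matched = TRUE, ambiguous = amb,
               candidates = paste(labs, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.data.frame(peaks) && !is.null(peaks$intensity))
    out$intensity <- peaks$intensity
  class(out) <- c("adduct_assignment", "data.frame")
  out
}

#' m/z of a neutral mass at a positive charge state
#'
#' Positive-mode electrospray convention: `(M + z * m_p) / z` with `m_p`
#' the proton mass. No acquisition-window filtering is applied here.
#'
#' @param M Neutral mass (Da).
#' @param z Positive integer charge.
#' @return m/z value(s).
#' @export
#' @examples
#' mz_from_mass(14304, 10)  # 1431.41
mz_from_mass <- function(M, z) {
  if (any(z < 1)) stop("charge z must be >= 1")
  (M + z * proton_mass) / z
}

# local maxima of a profile trace above a floor, with FWHM-region centroids
profile_centroids <- function(mz, intensity, floor_frac = 0.02) {
  n <- length(mz)
  if (n < 3L) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  floor <- floor_frac * max(intensity)
  is_max <- c(FALSE, intensity[2:(n - 1)] > intensity[1:(n - 2)] &
                intensity[2:(n - 1)] >= intensity[3:n], FALSE) &
    intensity > floor
  idx <- which(is_max)
  if (length(idx) == 0L)
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  cents <- vapply(idx, function(i) {
    half <- intensity[i] / 2
    l <- i; while (l > 1L && intensity[l - 1L] > half &&
                   intensity[l - 1L] < intensity[l]) l <- l - 1L
    r <- i; while (r < n && intensity[r + 1L] > half &&
                   intensity[r + 1L] < intensity[r]) r <- r + 1L
    w <- l:r
    sum(mz[w] * intensity[w]) / sum(intensity[w])
  }, numeric(1))
  data.frame(mz = cents, intensity = intensity[idx])
}

#' Minimal charge-envelope deconvolution
#'
#' Recovers neutral masses from a positive-mode multi-charge envelope.
#' Centroids of the profile spectrum are detected, every centroid/charge
#' combination proposes a candidate neutral mass, and each candidate is
#' scored by the summed intensity of centroids found within `tol_mz` of its
#' predicted m/z across the charge range. Candidates matched in at least
#' `min_charge_states` charge states and scoring above `rel_threshold` of
#' the best score are kept; accepted masses are refined as the
#' intensity-weighted average of the matched-peak implied masses and
#' de-duplicated within `mass_step`.
#'
#' @param raw Data frame with columns `mz` and `intensity` (profile trace).
#' @param z_range Integer vector of charge states to consider.
#' @param tol_mz Matching tolerance in m/z (default 0.5).
#' @param mass_step Neutral-mass resolution for de-duplicating candidates
#'   (Da, default 2).
#' @param rel_threshold Keep candidates scoring at least this fraction of
#'   the best score (default 0.1).
#' @param min_charge_states Minimum matched charge states (default 3).
#' @return A data frame (class `neutral_peaklist`) with columns `mass`
#'   (Da) and `intensity` (summed matched intensity), sorted by mass;
#'   empty (with a warning) when nothing passes the threshold.
#' @export
deconvolve_envelope <- function(raw, z_range = 6:15, tol_mz = 0.5,
                                mass_step = 2, rel_threshold = 0.1,
                                min_charge_states = 3) {
  empty <- structure(data.frame(mass = numeric(0), intensity = numeric(0)),
                     class = c("neutral_peaklist", "data.frame"))
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("empty spectrum: nothing to deconvolve")
    return(empty)
  }
  cents <- profile_centroids(raw$mz, raw$intensity)
  if (nrow(cents) == 0L) {
    warning("no peaks detected above the intensity floor")
    return(empty)
  }
  z_range <- sort(unique(as.integer(z_range)))
  cand_mass <- as.vector(outer(cents$mz, z_range,
                               function(m, z) m * z - z * proton_mass))
  score_one <- function(M) {
    tot <- 0; nmatch <- 0L; wm <- 0; ww <- 0
    for (z in z_range) {
      pred <- mz_from_mass(M, z)
      d <- abs(cents$mz - pred)
      j <- which.min(d)
      if (d[j] <= tol_mz) {
        tot <- tot + cents$intensity[j]
        nmatch <- nmatch + 1L
        implied <- cents$mz[j] * z - z * proton_mass
        wm <- wm + cents$intensity[j] * implied
        ww <- ww + cents$intensity[j]
      }
    }
    c(score = tot, n = nmatch, mass = if (ww > 0) wm / ww else NA_real_)
  }
  sc <- t(vapply(cand_mass, score_one, numeric(3)))
  ok <- sc[, "n"] >= min(min_charge_states, length(z_range)) &
    is.finite(sc[, "mass"])
  if (!any(ok)) {
    warning("no neutral-mass candidate matched enough charge states")
    return(empty)
  }
  sc <- sc[ok, , drop = FALSE]
  keep <- sc[, "score"] >= rel_threshold * max(sc[, "score"])
  sc <- sc[keep, , drop = FALSE]
  # greedy de-duplication by refined mass, best score first
  ord <- order(sc[, "score"], decreasing = TRUE)
  out_mass <- numeric(0); out_int <- numeric(0)
  for (i in ord) {
    m <- sc[i, "mass"]
    if (length(out_mass) == 0L || min(abs(out_mass - m)) > mass_step) {
      out_mass <- c(out_mass, m)
      out_int <- c(out_int, sc[i, "score"])
    }
  }
  o <- order(out_mass)
  structure(data.frame(mass = out_mass[o], intensity = out_int[o]),
            class = c("neutral_peaklist", "data.frame"))
}
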