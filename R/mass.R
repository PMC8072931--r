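# Element mass table. Average masses are the IUPAC 2021 conventional
# (abridged) standard atomic weights; monoisotopic masses are those of the
# most abundant stable isotope. Fixed at build time so that every predicted
# adduct mass is reproducible bit-for-bit.
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "Na", "P", "S", "Cl", "K",
             "Fe", "Cu", "Zn", "Br", "I", "Pt"),
  average = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 30.974,
              32.06, 35.45, 39.098, 55.845, 63.546, 65.38, 79.904,
              126.904, 195.084),
  monoisotopic = c(1.00782503207, 12, 14.0030740048, 15.9949146196,
                   18.99840322, 22.9897692809, 30.97376163, 31.97207100,
                   34.96885268, 38.96370668, 55.9349375, 62.9295975,
                   63.9291422, 78.9183371, 126.904473, 194.9647911),
  stringsAsFactors = FALSE
)

#' Physical mass constants (Da)
#'
#' `proton_mass` is the mass of H+ used to convert between neutral mass and
#' m/z in positive-mode ESI; `hydrogen_mass` is the mass of a neutral
#' hydrogen atom, subtracted once per displaced proton when a charged metal
#' fragment binds covalently/ionically to a protein.
#'
#' @format Length-one numeric constants, in daltons.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
proton_mass <- 1.007276466

#' @rdname mass-constants
#' @export
hydrogen_mass <- 1.00782503207

#' Element mass table
#'
#' The built-in table of per-element average and monoisotopic masses that
#' underlies all formula-mass and adduct-mass computations.
#'
#' @return A data frame with columns `symbol`, `average` and `monoisotopic`
#'   (Da).
#' @export
#' @examples
#' element_masses()
element_masses <- function() .element_table

.element_average <- structure(.element_table$average,
                              names = .element_table$symbol)
.element_mono <- structure(.element_table$monoisotopic,
                           names = .element_table$symbol)

#' Parse a molecular formula
#'
#' Parses a Hill-notation molecular formula string ("C21H15N3Pt", "H3PO4",
#' ...) into a named count vector. Parsing is case-sensitive on element
#' symbols: an uppercase letter optionally followed by one lowercase letter,
#' optionally followed by an integer count (default 1). Only elements in
#' [element_masses()] are accepted.
#'
#' @param text Formula string. The empty string yields the empty formula.
#' @return An object of class `chem_formula`: a named integer vector of
#'   strictly positive element counts, in Hill order (C, then H, then the
#'   rest alphabetically; fully alphabetical when no carbon is present).
#' @export
#' @examples
#' parse_formula("C21H15N3Pt")   # the Pt(phenyl-terpyridine) fragment
#' parse_formula("H3PO4")
parse_formula <- function(text) {
  if (inherits(text, "chem_formula")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single formula string")
  if (nchar(text) == 0L) return(new_chem_formula(integer(0)))
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop("malformed formula: ", sQuote(text))
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- sub("^[A-Za-z]+", "", tokens)
  unknown <- setdiff(syms, names(.element_average))
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  n <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  if (anyNA(n)) stop("malformed count in formula: ", sQuote(text))
  if (any(n == 0L)) stop("zero count not allowed in formula: ", sQuote(text))
  counts <- tapply(n, syms, sum)
  new_chem_formula(structure(as.integer(counts), names = names(counts)))
}

new_chem_formula <- function(counts) {
  counts <- counts[counts > 0L]
  structure(as.integer(counts)[hill_order(names(counts))],
            names = names(counts)[hill_order(names(counts))],
            class = "chem_formula")
}

hill_order <- function(syms) {
  if (is.null(syms)) return(integer(0))
  if ("C" %in% syms) {
    rank <- match(syms, c("C", "H"))
    rank[is.na(rank)] <- 3L
    order(rank, syms)
  } else {
    order(syms)
  }
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) f
  else if (is.character(f)) parse_formula(f)
  else if (is.numeric(f) && !is.null(names(f)))
    new_chem_formula(structure(as.integer(f), names = names(f)))
  else stop("cannot interpret `f` as a molecular formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (average mass ",
      formatC(average_mass(x), format = "f", digits = 3), " Da)\n", sep = "")
  invisible(x)
}

#' Combine two formulas
#'
#' Element-wise sum of the counts of two formulas, e.g. to add a small-anion
#' adduct to a metal fragment.
#'
#' @param e1,e2 `chem_formula` objects (or strings).
#' @return A `chem_formula`.
#' @export
"+.chem_formula" <- function(e1, e2) {
  a <- as_chem_formula(e1); b <- as_chem_formula(e2)
  syms <- union(names(a), names(b))
  cnt <- vapply(syms, function(s) {
    sum(c(unclass(a)[s], unclass(b)[s]), na.rm = TRUE)
  }, integer(1))
  new_chem_formula(cnt)
}

#' Average and monoisotopic formula masses
#'
#' Sums count x atomic mass over the elements of a formula, using the
#' embedded mass table (see [element_masses()]). Deconvolved intact-protein
#' masses are on the average-mass scale, so `average_mass()` is the one used
#' throughout adduct prediction; `monoisotopic_mass()` is provided for
#' completeness.
#'
#' @param f A `chem_formula`, or a formula string which is parsed first.
#' @return Mass in Da (0 for the empty formula).
#' @export
#' @examples
#' average_mass("H2O")          # 18.015
#' average_mass("PtC21H15N3")   # the reactive fragment, ~504.5 Da
average_mass <- function(f) {
  f <- as_chem_formula(f)
  if (length(f) == 0L) return(0)
  sum(unclass(f) * .element_average[names(f)])
}

#' @rdname average_mass
#' @export
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  if (length(f) == 0L) return(0)
  sum(unclass(f) * .element_mono[names(f)])
}
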