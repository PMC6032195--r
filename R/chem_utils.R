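## Small-molecule arithmetic: formula parsing, molar masses, mass->molar
## concentration conversion and singly protonated m/z.

## Atomic masses pinned in-code (IUPAC 2021 conventional atomic weights and
## principal-isotope monoisotopic masses, 6 decimals) so results are
## bit-stable across environments.
.atomic_mass <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
              "Na", "K", "Mg", "Ca", "Fe", "Zn", "Se", "B", "Si"),
  average = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.973762,
              18.998403, 35.45, 79.904, 126.90447,
              22.989769, 39.0983, 24.305, 40.078, 55.845, 65.38,
              78.971, 10.81, 28.085),
  mono = c(1.007825, 12.0, 14.003074, 15.994915, 31.972071, 30.973762,
           18.998403, 34.968853, 78.918338, 126.904473,
           22.989769, 38.963706, 23.985042, 39.962591, 55.934936,
           63.929142, 79.916522, 11.009305, 27.976927),
  stringsAsFactors = FALSE)

.proton_mass <- 1.00728  # Da, for [M+H]+

#' Parse a molecular formula
#'
#' Parses Hill-style formulas such as `"C15H14N4O"` (nevirapine) into an
#' element -> count mapping. Counts must be positive integers and every
#' element must be in the package's pinned mass table.
#'
#' @param formula a formula string, or a named numeric vector of counts.
#' @return named integer vector of element counts, class
#'   `molecular_formula`.
#' @export
molecular_formula <- function(formula) {
  if (inherits(formula, "molecular_formula")) return(formula)
  if (is.character(formula)) {
    stopifnot(length(formula) == 1L)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (!length(toks) || sum(attr(m, "match.length")) != nchar(formula))
      stop("cannot parse formula: '", formula, "'")
    el <- sub("[0-9]*$", "", toks)
    ct <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), 1L))
    counts <- tapply(ct, el, sum)
    counts <- setNames(as.integer(counts), names(counts))
  } else {
    counts <- setNames(as.integer(formula), names(formula))
  }
  unknown <- setdiff(names(counts), .atomic_mass$element)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (!length(counts) || any(counts <= 0))
    stop("formula must contain at least one atom of each listed element")
  structure(counts, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat(paste0(names(x), ifelse(unclass(x) > 1, unclass(x), ""),
             collapse = ""), "\n")
  invisible(x)
}

#' Molar mass of a molecular formula
#'
#' Sum of element masses times counts: conventional atomic weights for
#' `kind = "average"` (g/mol), principal-isotope masses for
#' `kind = "monoisotopic"` (Da).
#'
#' @param f a [molecular_formula()] (or a formula string).
#' @param kind `"average"` or `"monoisotopic"`.
#' @return mass in g/mol (average) or Da (monoisotopic).
#' @export
molar_mass <- function(f, kind = c("average", "monoisotopic")) {
  f <- molecular_formula(f)
  kind <- match.arg(kind)
  m <- match(names(f), .atomic_mass$element)
  col <- if (kind == "average") .atomic_mass$average else .atomic_mass$mono
  sum(col[m] * unclass(f))
}

#' Convert a mass concentration to a molar concentration
#'
#' `ug/mL -> uM` via the average molar mass:
#' `uM = ug_per_ml / M * 1000`. For nevirapine (C15H14N4O, 266.30 g/mol),
#' 100 ug/mL is 375.5 uM.
#'
#' @param ug_per_ml mass concentration, micrograms per millilitre (>= 0).
#' @param f a [molecular_formula()] (or formula string).
#' @return molar concentration in micromolar.
#' @export
mass_conc_to_molar <- function(ug_per_ml, f) {
  if (any(ug_per_ml < 0)) stop("concentration must be >= 0")
  ug_per_ml / molar_mass(f, "average") * 1000
}

#' Singly protonated ion m/z
#'
#' Monoisotopic mass plus one proton (1.00728 Da), charge 1 -- the MS
#' precursor `[M+H]+`. Nevirapine gives 267.1.
#'
#' @param f a [molecular_formula()] (or formula string).
#' @return m/z of the `[M+H]+` ion.
#' @export
protonated_mz <- function(f) {
  molar_mass(f, "monoisotopic") + .proton_mass
}
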