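#' Monoisotopic atomic masses and related physical constants
#'
#' Monoisotopic masses (Da) of the elements handled by the formula
#' calculator, plus the proton and electron masses used for ion m/z
#' arithmetic. The carbon-12 mass is exactly 12 by definition of the
#' unified atomic mass scale.
#'
#' @format A named list with components `atoms` (named numeric vector of
#'   monoisotopic masses in Da), `proton` and `electron` (Da).
#' @export
mass_constants <- local({
  atoms <- c(
    H = 1.0078250319,
    C = 12,
    N = 14.0030740052,
    O = 15.9949146221,
    P = 30.97376151,
    S = 31.97207069
  )
  list(atoms = atoms, proton = 1.00727646, electron = 0.00054858)
})

#' Parse a molecular formula string
#'
#' Parses formulas written in Hill-style element-count notation, e.g.
#' `"C18H39NO3"` (implicit count 1 for bare symbols) or the singly charged
#' cation form `"C26H52NO6+"` with a trailing plus sign.
#'
#' @param text Formula string. Element symbols must be among those in
#'   [mass_constants] (H, C, N, O, P, S).
#' @return An object of class `chem_formula`: a list with `counts` (named
#'   integer vector, element -> count) and `charge` (0 or +1).
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("C26H52NO6+")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string")
  }
  body <- text
  charge <- 0L
  if (grepl("\\+$", body)) {
    charge <- 1L
    body <- sub("\\+$", "", body)
  }
  if (!nzchar(body)) stop("formula '", text, "' has no elements")
  parts <- regmatches(body, gregexpr("[A-Z][a-z]?[0-9]*", body))[[1]]
  if (sum(nchar(parts)) != nchar(body)) {
    stop("formula '", text, "' does not match the element-count grammar")
  }
  counts <- integer(0)
  for (part in parts) {
    sym <- sub("[0-9]*$", "", part)
    num <- sub("^[A-Za-z]+", "", part)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(mass_constants$atoms)) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    }
    if (n < 1L) stop("element '", sym, "' has count < 1 in formula '", text, "'")
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  structure(list(counts = counts, charge = charge), class = "chem_formula")
}

as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else parse_formula(f)
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(
    paste0(names(x$counts), ifelse(x$counts > 1L, x$counts, ""), collapse = ""),
    if (x$charge > 0L) "+" else ""
  )
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (charge ", x$charge, ")\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of atomic monoisotopic masses; the formal charge is ignored (the
#' atom-sum of the written composition is returned).
#'
#' @param f A `chem_formula` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H10O5") # 162.0528, a glycosyl (sugar) unit
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(mass_constants$atoms[names(f$counts)] * f$counts)
}

#' Calculated ion m/z for a formula
#'
#' Two conventions are supported: `"protonated_neutral"` treats the formula
#' as a neutral molecule M and returns the [M+H]+ m/z (atom-sum plus the
#' proton mass); `"as_written_cation"` treats the formula as the complete
#' ion already carrying one positive charge (written with a trailing `+`)
#' and returns the atom-sum minus one electron mass. Both agree for an
#' [M+H]+ ion written either way.
#'
#' @param f A `chem_formula` or formula string.
#' @param adduct `"protonated_neutral"` (requires charge 0) or
#'   `"as_written_cation"` (requires charge +1).
#' @return m/z in Da.
#' @examples
#' ion_mz("C28H44O3")          # 429.3363, ergosterol peroxide [M+H]+
#' ion_mz("C26H52NO6+", "as_written_cation")
#' @export
ion_mz <- function(f, adduct = c("protonated_neutral", "as_written_cation")) {
  f <- as_formula(f)
  adduct <- match.arg(adduct)
  if (adduct == "protonated_neutral") {
    if (f$charge != 0L) {
      stop("protonated_neutral requires a neutral formula (charge 0), got charge ", f$charge)
    }
    monoisotopic_mass(f) + mass_constants$proton
  } else {
    if (f$charge != 1L) {
      stop("as_written_cation requires a +1 formula (trailing '+'), got charge ", f$charge)
    }
    monoisotopic_mass(f) - mass_constants$electron
  }
}

#' Signed mass error in parts per million
#'
#' `(calculated - detected) / calculated * 1e6`: a detected m/z above the
#' calculated value yields a negative error.
#'
#' @param detected_mz Observed m/z (Da), positive.
#' @param calculated_mz Theoretical m/z (Da), positive.
#' @return Signed error in ppm.
#' @examples
#' ppm_error(429.3355, ion_mz("C28H44O3")) # 1.9 ppm
#' @export
ppm_error <- function(detected_mz, calculated_mz) {
  if (any(detected_mz <= 0) || any(calculated_mz <= 0)) {
    stop("detected and calculated m/z must be positive")
  }
  (calculated_mz - detected_mz) / calculated_mz * 1e6
}
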