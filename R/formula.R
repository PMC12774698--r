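## Elemental-formula arithmetic and monoisotopic masses.
##
## Formulas are named integer vectors (element symbol -> count) kept in a
## fixed canonical order so that mass summation is deterministic. "D" is the
## deuterium label (2H), needed for deuterated internal standards such as
## CE(16:0)-d7.

## Canonical element order: Hill convention (C, H first), D immediately after
## H, remaining supported elements after.
.ELEMENT_ORDER <- c("C", "H", "D", "N", "O", "P", "S", "Na", "K", "Cl")

## Monoisotopic masses (Da) of the most abundant isotope, IUPAC/CODATA,
## fixed to >= 6 decimals. Immutable at run time.
.ISOTOPE_MASS <- c(
  C  = 12.000000000,
  H  = 1.007825032,
  D  = 2.014101778,
  N  = 14.003074005,
  O  = 15.994914620,
  P  = 30.973761998,
  S  = 31.972071174,
  Na = 22.989769282,
  K  = 38.963706486,
  Cl = 34.968852682
)

.ELECTRON_MASS <- 0.000548580

#' Monoisotopic isotope mass table
#'
#' Returns the fixed table of monoisotopic masses (Da) used throughout the
#' package, one entry per supported element symbol. \code{"D"} is the
#' deuterium label mapped to the \eqn{^2}H mass.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' isotopeMasses()[["O"]]
isotopeMasses <- function() .ISOTOPE_MASS

#' Electron rest mass
#'
#' @return Electron mass in Da, used in adduct m/z arithmetic.
#' @export
electronMass <- function() .ELECTRON_MASS

#' Create an empty elemental formula
#'
#' The empty formula (all counts zero) is valid and has mass 0; it can only
#' be produced through this constructor, never by parsing an empty string.
#'
#' @return Named integer vector of length 0 with class behaviour of a formula.
#' @export
emptyFormula <- function() {
  structure(integer(0), names = character(0))
}

#' Parse an elemental formula string
#'
#' Parses Hill-style concatenated element symbols with optional positive
#' integer counts, e.g. \code{"C36H72NO8P"}. The deuterium label \code{"D"}
#' is accepted as an element. Unknown symbols and malformed counts are
#' errors; the empty string is rejected (use \code{\link{emptyFormula}}).
#'
#' @param text Single formula string.
#' @return Named integer vector (element -> count) in canonical order.
#' @export
#' @examples
#' parseFormula("H2O")
#' parseFormula("C43H69D7O2")  # CE(16:0)-d7
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) {
    stop("empty formula string; use emptyFormula() for the empty formula")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    stop("malformed formula string: ", text)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  bad <- setdiff(sym, names(.ISOTOPE_MASS))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- ifelse(nzchar(cnt), suppressWarnings(as.integer(cnt)), 1L)
  if (anyNA(n) || any(n <= 0L)) stop("malformed count in formula: ", text)
  counts <- tapply(n, factor(sym, levels = .ELEMENT_ORDER), sum)
  counts <- counts[!is.na(counts)]
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

.normalizeFormula <- function(f) {
  f <- f[f != 0L]
  f[order(match(names(f), .ELEMENT_ORDER))]
}

#' Add two elemental formulas
#'
#' @param a,b Named integer vectors as from \code{\link{parseFormula}}.
#' @return Element-wise sum in canonical order.
#' @export
addFormulas <- function(a, b) {
  els <- union(names(a), names(b))
  out <- integer(length(els))
  names(out) <- els
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .normalizeFormula(out)
}

#' Subtract one elemental formula from another
#'
#' Subtraction that would produce a negative element count is an error: a
#' composition cannot contain a negative number of atoms.
#'
#' @param a,b Named integer vectors; computes \code{a - b}.
#' @return Element-wise difference in canonical order.
#' @export
subtractFormulas <- function(a, b) {
  els <- union(names(a), names(b))
  out <- integer(length(els))
  names(out) <- els
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0L)) {
    stop("subtraction would give negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  }
  .normalizeFormula(out)
}

#' Multiply an elemental formula by a non-negative integer
#'
#' @param f Named integer vector.
#' @param n Non-negative integer multiplier.
#' @return Scaled formula.
#' @export
multiplyFormula <- function(f, n) {
  stopifnot(length(n) == 1L, n >= 0, n == as.integer(n))
  .normalizeFormula(f * as.integer(n))
}

#' Format an elemental formula as a string
#'
#' @param f Named integer vector.
#' @return Hill-style string, e.g. \code{"C36H72NO8P"}; \code{""} for the
#'   empty formula.
#' @export
formulaToString <- function(f) {
  f <- .normalizeFormula(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Neutral monoisotopic mass of a formula
#'
#' Sums count times isotope mass over the elements of the formula, in
#' canonical element order (deterministic). Additive by construction:
#' \code{monoisotopicMass(addFormulas(a, b))} equals
#' \code{monoisotopicMass(a) + monoisotopicMass(b)} to machine precision.
#'
#' @param f Named integer vector as from \code{\link{parseFormula}}.
#' @param table Isotope mass table; defaults to \code{\link{isotopeMasses}}.
#' @return Mass in Da (0 for the empty formula).
#' @export
#' @examples
#' monoisotopicMass(parseFormula("H2O"))  # 18.010565
monoisotopicMass <- function(f, table = isotopeMasses()) {
  if (!length(f)) return(0)
  missing <- setdiff(names(f), names(table))
  if (length(missing)) {
    stop("no isotope mass for element(s): ", paste(missing, collapse = ", "))
  }
  f <- .normalizeFormula(f)
  sum(as.numeric(f) * table[names(f)])
}
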