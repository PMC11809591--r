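# Elemental-formula algebra: Hill-notation parsing, monoisotopic masses,
# and subtraction/addition used by the neutral-loss bookkeeping.

#' Parse a Hill-notation molecular formula
#'
#' Accepts element symbols with optional counts (e.g. "C15H39O7PSi4") and an
#' optional single trailing charge sign ("+" or "-").  Isotope-in-formula
#' syntax is deliberately not supported; tracer labeling is handled
#' separately by the isotopologue machinery.
#'
#' @param text Formula string.
#' @return An object of class \code{mol_formula}: a named integer vector of
#'   element counts with a \code{charge} attribute.
#' @examples
#' parse_formula("C15H39O7PSi4")
#' parse_formula("C24H61NO9PSi6+")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (!nzchar(s)) stop("empty formula string")
  charge <- 0L
  last <- substr(s, nchar(s), nchar(s))
  if (last == "+") { charge <- 1L;  s <- substr(s, 1L, nchar(s) - 1L) }
  if (last == "-") { charge <- -1L; s <- substr(s, 1L, nchar(s) - 1L) }
  if (!nzchar(s)) stop("formula has a charge sign but no elements: ", text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    covered <- unlist(Map(function(st, len) seq(st, st + len - 1L),
                          as.integer(m), attr(m, "match.length")))
    bad <- setdiff(seq_len(nchar(s)), covered)
    stop("malformed formula near '", substr(s, min(bad), min(bad)),
         "' in: ", text)
  }
  known <- names(.ISOTOPE_DATA)
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    if (!sym %in% known)
      stop("unrecognized element symbol '", sym, "' in: ", text)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  mol_formula(counts, charge = charge)
}

#' Construct a molecular formula object
#'
#' @param counts Named integer vector of element counts (all >= 0, at least
#'   one positive).
#' @param charge Signed integer charge.
#' @return A \code{mol_formula} object.
#' @export
mol_formula <- function(counts, charge = 0L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula must contain at least one element")
  bad <- setdiff(names(counts), names(.ISOTOPE_DATA))
  if (length(bad)) stop("unrecognized element symbol(s): ",
                        paste(bad, collapse = ", "))
  x <- as.integer(counts)
  names(x) <- names(counts)
  # Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(x)),
           sort(setdiff(names(x), c("C", "H"))))
  x <- x[ord]
  structure(x, charge = as.integer(charge), class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  body <- paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""),
                 collapse = "")
  q <- attr(x, "charge")
  sgn <- if (q > 0L) strrep("+", q) else if (q < 0L) strrep("-", -q) else ""
  paste0(body, sgn)
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format(x), "\n")
  invisible(x)
}

#' Count of one element in a formula
#' @param formula A \code{mol_formula}.
#' @param element Element symbol, e.g. "C".
#' @return Integer count (0 if absent).
#' @export
element_count <- function(formula, element) {
  stopifnot(inherits(formula, "mol_formula"))
  n <- unclass(formula)[element]
  if (is.na(n)) 0L else as.integer(n)
}

#' Subtract one formula from another
#'
#' Used for neutral-loss arithmetic.  Errors if any element count would
#' become negative (the loss is then not applicable to the parent).
#'
#' @param a,b \code{mol_formula} objects; \code{b} is subtracted from
#'   \code{a}.  The charge of \code{a} is retained.
#' @return A \code{mol_formula}.
#' @export
formula_subtract <- function(a, b) {
  stopifnot(inherits(a, "mol_formula"), inherits(b, "mol_formula"))
  els <- union(names(a), names(b))
  ca <- vapply(els, function(e) element_count(a, e), integer(1))
  cb <- vapply(els, function(e) element_count(b, e), integer(1))
  d <- ca - cb
  if (any(d < 0))
    stop("loss not applicable: negative count for ",
         paste(els[d < 0], collapse = ", "))
  mol_formula(d[d > 0], charge = attr(a, "charge"))
}

#' Add two formulas (or add atoms to a formula)
#' @param a,b \code{mol_formula} objects; charges are summed.
#' @return A \code{mol_formula}.
#' @export
formula_add <- function(a, b) {
  stopifnot(inherits(a, "mol_formula"), inherits(b, "mol_formula"))
  els <- union(names(a), names(b))
  s <- vapply(els, function(e) element_count(a, e) + element_count(b, e),
              integer(1))
  mol_formula(s, charge = attr(a, "charge") + attr(b, "charge"))
}

#' Monoisotopic mass or m/z of a formula
#'
#' Sums the lightest-isotope masses of all atoms.  For a charged species the
#' electron mass is subtracted (cations) or added (anions) per unit charge
#' and the result divided by the absolute charge, i.e. an ion m/z is
#' returned; the reporting convention is to present these values rounded
#' to 4 decimals.
#'
#' @param formula A \code{mol_formula} or formula string.
#' @param isotopes Isotope table, see \code{\link{isotope_table}}.
#' @return Mass (neutral) or m/z (charged) in amu, unrounded.
#' @examples
#' round(monoisotopic_mass(parse_formula("C15H39O7PSi4")), 4)
#' round(monoisotopic_mass(parse_formula("C24H61NO9PSi6+")), 4)
#' @export
monoisotopic_mass <- function(formula, isotopes = isotope_table()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "mol_formula"))
  els <- names(formula)
  bad <- setdiff(els, names(isotopes))
  if (length(bad)) stop("element(s) missing from isotope table: ",
                        paste(bad, collapse = ", "))
  m <- sum(vapply(els, function(e)
    isotopes[[e]]$masses[1] * element_count(formula, e), numeric(1)))
  q <- attr(formula, "charge")
  if (q == 0L) m else (m - q * .ELECTRON_MASS) / abs(q)
}

#' Nominal (integer) mass of a formula
#'
#' Integer-rounded monoisotopic mass, used only for fragment naming
#' (e.g. "3PGA_357").
#' @inheritParams monoisotopic_mass
#' @return Integer nominal mass.
#' @export
nominal_mass <- function(formula, isotopes = isotope_table()) {
  as.integer(round(monoisotopic_mass(formula, isotopes)))
}
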