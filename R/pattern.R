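# Forward isotopologue model: convolution of per-atom isotope distributions
# over integer mass-shift channels (M+0, M+1, ...).  This is the model that
# the NIA/tracer-purity correction inverts.

# open convolution of two abundance vectors
.conv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  r <- numeric(n)
  for (i in seq_along(a))
    if (a[i] != 0)
      r[i:(i + length(b) - 1L)] <- r[i:(i + length(b) - 1L)] + a[i] * b
  r
}

# per-atom distribution over integer mass-shift channels for one element
.atom_dist <- function(entry) {
  shifts <- round(entry$masses - entry$masses[1])
  d <- numeric(max(shifts) + 1L)
  for (i in seq_along(shifts)) d[shifts[i] + 1L] <- d[shifts[i] + 1L] +
    entry$abundances[i]
  d
}

#' Natural isotopologue pattern of a molecular formula
#'
#' Convolves the isotope distributions of every atom in the formula into a
#' probability vector over integer mass-shift channels M+0, M+1, ....  The
#' full-support vector sums to one; if \code{length.out} is given the vector
#' is truncated (not renormalized), so truncated patterns sum to slightly
#' less than one.
#'
#' @param formula \code{mol_formula} or formula string.
#' @param isotopes Isotope table; set \code{isotope_table(c13 = ...)} to
#'   change the carbon NIA.
#' @param length.out Optional truncation length.
#' @return Numeric abundance vector starting at M+0.
#' @export
natural_isotope_pattern <- function(formula, isotopes = isotope_table(),
                                    length.out = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "mol_formula"))
  pat <- 1
  for (el in names(formula)) {
    entry <- isotopes[[el]]
    if (is.null(entry)) stop("element missing from isotope table: ", el)
    d <- .atom_dist(entry)
    n <- element_count(formula, el)
    if (length(d) == 1L) next  # monoisotopic element
    for (k in seq_len(n)) {
      pat <- .conv(pat, d)
      if (!is.null(length.out) && length(pat) > 4L * length.out)
        pat <- pat[seq_len(4L * length.out)]  # keep the window generous
    }
  }
  if (!is.null(length.out)) {
    if (length(pat) < length.out) pat <- c(pat, numeric(length.out - length(pat)))
    pat <- pat[seq_len(length.out)]
  }
  pat
}

#' Theoretical isotopologue pattern of a fragment under tracer labeling
#'
#' Forward model for a fragment whose labelable (parent-metabolite) carbons
#' draw from a tracer-fed carbon pool while derivatization carbons and all
#' non-carbon atoms stay at natural abundance.  Each labelable carbon is 13C
#' with probability \code{p13_labelable * purity}: \code{p13_labelable} is
#' the 13C content of the carbon source feeding those positions, and the
#' tracer isotopic purity scales it.  A natural (unlabeled) species is the
#' pattern at \code{p13_labelable = p13_natural, purity = 1}.
#'
#' @param frag A \code{fragment_spec}.
#' @param p13_labelable 13C fraction of the labelable-carbon source, in
#'   [0, 1].
#' @param p13_natural Natural 13C abundance used for the non-labelable
#'   carbons (default 0.01109).
#' @param purity Tracer isotopic purity in (0, 1].
#' @param length.out Optional truncation length (no renormalization).
#' @return Probability vector over M+0 ... (sums to one at full support).
#' @export
theoretical_isotopologue_pattern <- function(frag, p13_labelable,
                                             p13_natural = 0.01109,
                                             purity = 1,
                                             length.out = NULL) {
  stopifnot(inherits(frag, "fragment_spec"),
            p13_labelable >= 0, p13_labelable <= 1,
            purity >= 0, purity <= 1)
  n <- frag$n_labelable_carbons
  p_eff <- p13_labelable * purity
  lab <- if (n > 0) stats::dbinom(0:n, n, p_eff) else 1
  residual <- .residual_formula(frag)
  nat <- if (is.null(residual)) 1
         else natural_isotope_pattern(residual, isotope_table(c13 = p13_natural))
  pat <- .conv(lab, nat)
  if (!is.null(length.out)) {
    if (length(pat) < length.out) pat <- c(pat, numeric(length.out - length(pat)))
    pat <- pat[seq_len(length.out)]
  }
  pat
}

# formula of the fragment minus its labelable carbons (NULL if nothing left)
.residual_formula <- function(frag) {
  cnt <- unclass(frag$formula)
  attributes(cnt) <- list(names = names(frag$formula))
  cnt["C"] <- cnt["C"] - frag$n_labelable_carbons
  cnt <- cnt[cnt > 0]
  if (length(cnt) == 0L) return(NULL)
  mol_formula(cnt, charge = attr(frag$formula, "charge"))
}
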