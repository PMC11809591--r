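# Fragment bookkeeping: which parent-metabolite carbon positions a measured
# ion retains (labelable carbons) versus carbons introduced by TMS/MEOX
# derivatization (never labeled), plus the neutral-loss library that links
# parent and fragment formulas.

#' Define a measurable fragment ion
#'
#' @param id Fragment label, e.g. "3PGA_357".
#' @param formula \code{mol_formula} or formula string (charge included).
#' @param retained_positions Integer vector of parent-metabolite carbon
#'   positions retained by the fragment (the labelable carbons); may be
#'   empty for derivatization-only fragments.
#' @param n_derivatization_carbons Number of carbons contributed by TMS/MEOX
#'   moieties.  Together with the retained positions this must account for
#'   every carbon in the formula.
#' @param instrument_mode "EI", "APCI", or "both".
#' @param note Optional free-text provenance note.
#' @return A \code{fragment_spec} object.
#' @export
fragment_spec <- function(id, formula, retained_positions = integer(0),
                          n_derivatization_carbons,
                          instrument_mode = c("both", "EI", "APCI"),
                          note = "") {
  if (is.character(formula)) formula <- parse_formula(formula)
  instrument_mode <- match.arg(instrument_mode)
  retained_positions <- sort(unique(as.integer(retained_positions)))
  n_lab <- length(retained_positions)
  n_c <- element_count(formula, "C")
  if (n_lab + n_derivatization_carbons != n_c)
    stop("fragment ", id, ": labelable (", n_lab, ") + derivatization (",
         n_derivatization_carbons, ") carbons must equal total C (", n_c, ")")
  structure(list(id = id, formula = formula,
                 retained_positions = retained_positions,
                 n_labelable_carbons = n_lab,
                 n_derivatization_carbons = as.integer(n_derivatization_carbons),
                 instrument_mode = instrument_mode, note = note),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat("<fragment_spec>", x$id, format(x$formula),
      sprintf("(nominal %d)", nominal_mass(x$formula)), "\n")
  cat("  labelable C:", x$n_labelable_carbons,
      if (x$n_labelable_carbons)
        paste0("(positions ", paste(x$retained_positions, collapse = ","), ")")
      else "", "\n")
  cat("  derivatization C:", x$n_derivatization_carbons,
      " mode:", x$instrument_mode, "\n")
  invisible(x)
}

#' Define a neutral loss
#'
#' @param name Loss label, e.g. "CH3", "TMSCOOH".
#' @param formula \code{mol_formula} or string of the lost neutral.
#' @param carbons_removed Parent carbon positions removed with the loss
#'   (empty when the loss takes only derivatization atoms).
#' @return A \code{neutral_loss} object.
#' @export
neutral_loss <- function(name, formula, carbons_removed = integer(0)) {
  if (is.character(formula)) formula <- parse_formula(formula)
  structure(list(name = name, formula = formula,
                 carbons_removed = sort(unique(as.integer(carbons_removed)))),
            class = "neutral_loss")
}

#' Shipped neutral-loss library
#'
#' Radical dissociations of EI ([M]+ losses) and neutral eliminations of
#' APCI ([M+H]+ losses) observed for TMS-derivatized metabolites.  The
#' TMSCOO/TMSCOOH losses remove the 1-C carboxyl carbon of 3PGA; CO and CO2
#' likewise remove 1-C.
#'
#' @return Named list of \code{neutral_loss} objects.
#' @export
neutral_loss_library <- function() {
  list(
    CH3     = neutral_loss("CH3",     "CH3"),
    CH4     = neutral_loss("CH4",     "CH4"),
    H2O     = neutral_loss("H2O",     "H2O"),
    TMSOH   = neutral_loss("TMSOH",   "C3H10OSi"),
    TMSCOO  = neutral_loss("TMSCOO",  "C4H9O2Si",  carbons_removed = 1L),
    TMSCOOH = neutral_loss("TMSCOOH", "C4H10O2Si", carbons_removed = 1L),
    CO      = neutral_loss("CO",      "CO",        carbons_removed = 1L),
    CO2     = neutral_loss("CO2",     "CO2",       carbons_removed = 1L)
  )
}

#' Apply a neutral loss to a parent formula
#'
#' EI route: the loss is subtracted from the molecular radical cation [M]+.
#' APCI route (\code{protonate = TRUE}): one H is added first, modelling the
#' proton adduct [M+H]+ that undergoes neutral elimination.  Either way the
#' resulting fragment carries charge +1.
#'
#' @param parent \code{mol_formula} (neutral parent) or string.
#' @param loss A \code{neutral_loss} (or \code{mol_formula}/string treated as
#'   a loss with no parent carbons removed).
#' @param protonate Logical; add one H before subtraction (APCI route).
#' @return \code{mol_formula} of the fragment cation (charge +1).
#' @examples
#' m <- parse_formula("C15H39O7PSi4")  # 3PGA (4TMS)
#' apply_loss(m, neutral_loss_library()$CH3)                    # m/z 459
#' apply_loss(m, neutral_loss_library()$TMSCOOH, protonate = TRUE)  # m/z 357
#' @export
apply_loss <- function(parent, loss, protonate = FALSE) {
  if (is.character(parent)) parent <- parse_formula(parent)
  lf <- if (inherits(loss, "neutral_loss")) loss$formula
        else if (is.character(loss)) parse_formula(loss)
        else loss
  p <- parent
  if (protonate) p <- formula_add(p, mol_formula(c(H = 1L)))
  out <- formula_subtract(p, lf)
  mol_formula(unclass(out), charge = 1L)
}

#' Derive a fragment spec from a parent spec and a neutral loss
#'
#' The derived fragment retains the parent positions minus the loss's
#' \code{carbons_removed}; derivatization carbons are adjusted by the
#' remaining carbon difference.
#'
#' @param id Label for the derived fragment.
#' @param parent A \code{fragment_spec} describing the intact derivatized
#'   molecule (its "retained positions" are all metabolite carbons).
#' @param loss A \code{neutral_loss}.
#' @param protonate Logical, APCI route.
#' @param instrument_mode Instrument mode label for the derived fragment.
#' @return A \code{fragment_spec}.
#' @export
derive_fragment <- function(id, parent, loss, protonate = FALSE,
                            instrument_mode = "both") {
  stopifnot(inherits(parent, "fragment_spec"), inherits(loss, "neutral_loss"))
  f <- apply_loss(parent$formula, loss, protonate = protonate)
  retained <- setdiff(parent$retained_positions, loss$carbons_removed)
  n_deriv <- element_count(f, "C") - length(retained)
  if (n_deriv < 0) stop("loss removes more metabolite carbons than declared")
  fragment_spec(id, f, retained_positions = retained,
                n_derivatization_carbons = n_deriv,
                instrument_mode = instrument_mode,
                note = paste0("derived: ", parent$id, " - ", loss$name,
                              if (protonate) " (+H)" else ""))
}

#' Load the fragment library
#'
#' Reads a plain-text TSV fragment table (id, formula, instrument mode,
#' retained parent positions, derivatization carbon count, provenance note).
#' The shipped default covers the 3PGA fragments 459 and 357 used for paired
#' positional enrichment, the non-labeled 3PGA qualifier fragments 299 and
#' 315, the G6P 706 reference fragment, and glucose/sorbitol
#' [M+H-CH4]+ fragments.  Users may point \code{path} at their own table to
#' extend the library.
#'
#' @param path Path to a TSV; default is the table shipped with the package.
#' @return Named list of \code{fragment_spec} objects.
#' @export
fragment_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fragment_library.tsv",
                        package = "poslabel", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("id", "formula", "instrument_mode", "retained_positions",
            "n_derivatization_carbons")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fragment library missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"note" %in% names(df)) df$note <- ""
  out <- lapply(seq_len(nrow(df)), function(i) {
    pos <- df$retained_positions[i]
    pos <- if (is.na(pos) || !nzchar(trimws(pos)) || trimws(pos) == "-")
             integer(0)
           else as.integer(strsplit(trimws(pos), ",")[[1]])
    fragment_spec(df$id[i], df$formula[i], retained_positions = pos,
                  n_derivatization_carbons = df$n_derivatization_carbons[i],
                  instrument_mode = df$instrument_mode[i], note = df$note[i])
  })
  names(out) <- df$id
  out
}
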