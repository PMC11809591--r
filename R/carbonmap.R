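# Carbon-fate maps from glucose (via G6P) to 3PGA for the EMP and OPP
# pathways, and the RUBISCO carboxylation mapping of RuBP + CO2 onto two
# 3PGA molecules.  A map lists product 3PGA molecules as ordered source
# triples (what feeds 1-C, 2-C, 3-C) with molar weights; predicted
# positional enrichments for a tracer are product-weighted fractions of
# labeled sources.  Source atoms are labeled "g1".."g6" (glucose carbons),
# "co2", or "r1".."r5" (RuBP carbons).

#' Construct a carbon-fate map
#'
#' @param pathway Pathway label.
#' @param products Data frame with columns \code{product}, \code{weight}
#'   (> 0) and \code{src1}, \code{src2}, \code{src3} (source atoms feeding
#'   the 1-C, 2-C, 3-C positions of that 3PGA).
#' @param pga_per_glucose Moles of 3PGA produced per mole of glucose
#'   consumed by the pathway (2 for EMP, 5/3 for OPP).
#' @return A \code{carbon_fate_map}.
#' @export
carbon_fate_map <- function(pathway, products, pga_per_glucose) {
  need <- c("product", "weight", "src1", "src2", "src3")
  stopifnot(all(need %in% names(products)), all(products$weight > 0),
            nrow(products) >= 1L)
  structure(list(pathway = pathway, products = products,
                 pga_per_glucose = pga_per_glucose),
            class = "carbon_fate_map")
}

#' @export
print.carbon_fate_map <- function(x, ...) {
  cat("<carbon_fate_map>", x$pathway,
      sprintf("(%.3g 3PGA per glucose)\n", x$pga_per_glucose))
  print(x$products, row.names = FALSE)
  invisible(x)
}

#' EMP (glycolysis) glucose-to-3PGA carbon map
#'
#' One glucose yields two 3PGA: the "top" triose (1-C from g3, 2-C from g2,
#' 3-C from g1; the DHAP-derived half is carbon-mirrored) and the "bottom"
#' triose (1-C from g4, 2-C from g5, 3-C from g6).
#'
#' @return A \code{carbon_fate_map}.
#' @export
emp_map <- function() {
  carbon_fate_map("EMP", data.frame(
    product = c("top", "bottom"), weight = c(1, 1),
    src1 = c("g3", "g4"), src2 = c("g2", "g5"), src3 = c("g1", "g6"),
    stringsAsFactors = FALSE), pga_per_glucose = 2)
}

#' OPP (oxidative pentose-phosphate) glucose-to-3PGA carbon map
#'
#' The oxidative phase decarboxylates 1-C of G6P; three pentose phosphates
#' are rearranged by transketolase/transaldolase into two fructose
#' 6-phosphates and one triose, so three G6P yield five 3PGA.  Three of the
#' five carry (g4, g5, g6) at (1-C, 2-C, 3-C).  The two rearranged products
#' have g2 and g3 at their 1-C positions; their remaining positions are
#' fixed by the canonical non-oxidative PPP atom transitions, giving
#' (1-C g2, 2-C g3, 3-C g2') and (1-C g3, 2-C g3', 3-C g2'') with primes
#' marking atoms from different glucose molecules (irrelevant for
#' enrichment predictions).
#'
#' @return A \code{carbon_fate_map} with weights per 3 glucose consumed.
#' @export
opp_map <- function() {
  carbon_fate_map("OPP", data.frame(
    product = c("gap_tk1", "gap_f6p_a", "gap_f6p_b", "dhap_f6p_a",
                "dhap_f6p_b"),
    weight = rep(1, 5),
    src1 = c("g4", "g4", "g4", "g2", "g3"),
    src2 = c("g5", "g5", "g5", "g3", "g3"),
    src3 = c("g6", "g6", "g6", "g2", "g2"),
    stringsAsFactors = FALSE), pga_per_glucose = 5 / 3)
}

#' RUBISCO carboxylation map of RuBP + CO2 onto two 3PGA
#'
#' Product A receives the assimilated carbon at 1-C and contains 1,2-C2 of
#' RuBP mapped inversely onto its 2,3-C2; product B contains 3,4,5-C3 of
#' RuBP mapped in order onto 1,2,3-C3.
#'
#' @return A \code{carbon_fate_map} (weights per RuBP carboxylated; the
#'   \code{pga_per_glucose} slot holds 3PGA per RuBP, i.e. 2).
#' @export
rubisco_map <- function() {
  carbon_fate_map("RUBISCO", data.frame(
    product = c("A", "B"), weight = c(1, 1),
    src1 = c("co2", "r3"), src2 = c("r2", "r4"), src3 = c("r1", "r5"),
    stringsAsFactors = FALSE), pga_per_glucose = 2)
}

#' Positional enrichment predicted by a fate map
#'
#' Product-weighted fraction of labeled source atoms per 3PGA position,
#' scaled by tracer purity.
#'
#' @param map A \code{carbon_fate_map}.
#' @param labeled_sources Character vector of labeled source atoms, e.g.
#'   \code{c("g3", "g4")} or \code{"co2"}.
#' @param purity Tracer isotopic purity.
#' @return Named vector \code{c(e1, e23, e123)} of pool enrichments.
#' @export
predict_map_enrichment <- function(map, labeled_sources, purity = 1) {
  stopifnot(inherits(map, "carbon_fate_map"))
  pr <- map$products
  w <- pr$weight / sum(pr$weight)
  lab <- function(src) as.numeric(src %in% labeled_sources) * purity
  e_pos <- c(sum(w * lab(pr$src1)), sum(w * lab(pr$src2)),
             sum(w * lab(pr$src3)))
  structure(c(e1 = e_pos[1], e23 = mean(e_pos[2:3]), e123 = mean(e_pos)),
            positions = e_pos)
}

#' Steady-state positional 3PGA enrichment for a glucose tracer
#'
#' Combines the EMP and OPP fate maps for a positionally labeled glucose
#' tracer and a pathway flux mixture.  Products are weighted by molar 3PGA
#' yield by default (2 per glucose through EMP, 5/3 through OPP, scaled by
#' the flux fractions), because enrichment is a property of the 3PGA pool;
#' raw flux-fraction weighting is available for comparison.
#'
#' @param tracer_positions Labeled glucose carbon positions, subset of 1:6.
#' @param f_emp,f_opp Glucose-consumption flux fractions (must sum to 1).
#' @param purity Tracer isotopic purity.
#' @param weighting "yield" (default) or "flux".
#' @return Named vector \code{c(e1, e23, e123)}.
#' @examples
#' predict_positional_enrichment(c(3, 4), f_emp = 1, f_opp = 0)  # e1 = 1
#' predict_positional_enrichment(c(3, 4), f_emp = 0, f_opp = 1)  # e1 = 0.8
#' @export
predict_positional_enrichment <- function(tracer_positions, f_emp = 1,
                                          f_opp = 1 - f_emp, purity = 1,
                                          weighting = c("yield", "flux")) {
  weighting <- match.arg(weighting)
  stopifnot(all(tracer_positions %in% 1:6), f_emp >= 0, f_opp >= 0,
            abs(f_emp + f_opp - 1) < 1e-9)
  labeled <- paste0("g", tracer_positions)
  maps <- list(emp = emp_map(), opp = opp_map())
  pool_w <- if (weighting == "yield") {
    c(emp = f_emp * maps$emp$pga_per_glucose,
      opp = f_opp * maps$opp$pga_per_glucose)
  } else c(emp = f_emp, opp = f_opp)
  if (sum(pool_w) == 0) stop("degenerate mixture")
  pool_w <- pool_w / sum(pool_w)
  ee <- predict_map_enrichment(maps$emp, labeled, purity)
  eo <- predict_map_enrichment(maps$opp, labeled, purity)
  structure(pool_w[["emp"]] * as.numeric(ee) + pool_w[["opp"]] *
              as.numeric(eo),
            names = c("e1", "e23", "e123"),
            positions = pool_w[["emp"]] * attr(ee, "positions") +
              pool_w[["opp"]] * attr(eo, "positions"))
}

#' Serialize a fate map as a tidy table
#'
#' Long-format view (product, position, source atom, weight) for inspection
#' or user override.
#'
#' @param map A \code{carbon_fate_map}.
#' @return Data frame with one row per product x position.
#' @export
fate_map_table <- function(map) {
  stopifnot(inherits(map, "carbon_fate_map"))
  pr <- map$products
  data.frame(pathway = map$pathway,
             product = rep(pr$product, each = 3L),
             position = rep(1:3, times = nrow(pr)),
             source = as.vector(t(as.matrix(pr[, c("src1", "src2",
                                                   "src3")]))),
             weight = rep(pr$weight, each = 3L),
             stringsAsFactors = FALSE)
}
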