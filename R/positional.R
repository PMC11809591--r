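# Carbon-positional algebra: combining the paired fragment enrichments
# E13C(1,2,3-C3) (fragment 459) and E13C(2,3-C2) (fragment 357) into the
# enrichment at the 1-C carboxyl position and molar positional 13C
# concentrations.  The identities used are that the enrichment of a
# substructure equals the average enrichment across its carbon positions:
#   E123 = (E1 + E2 + E3) / 3,  E23 = (E2 + E3) / 2
# hence E1 = 3 * E123 - 2 * E23.

#' Positional enrichment at 1-C from a paired fragment measurement
#'
#' \code{e1 = 3 * e123 - 2 * e23}.  Because this is a difference, noise can
#' push the result outside [0, 1]; such values are returned as-is with an
#' \code{out_of_bounds} attribute (never silently clamped), so downstream
#' rate fits can exclude them without biasing early time points toward 0.
#'
#' @param e123 Enrichment of the complete 1,2,3-C3 structure (fragment 459).
#' @param e23 Enrichment of the 2,3-C2 substructure (fragment 357).
#' @return Numeric vector of 1-C enrichments with a logical
#'   \code{out_of_bounds} attribute.
#' @examples
#' e1_from_pair(0.6, 0.45)  # 0.9
#' @export
e1_from_pair <- function(e123, e23) {
  stopifnot(is.numeric(e123), is.numeric(e23),
            all(e123 >= 0 & e123 <= 1, na.rm = TRUE),
            all(e23 >= 0 & e23 <= 1, na.rm = TRUE))
  e1 <- 3 * e123 - 2 * e23
  structure(e1, out_of_bounds = !is.na(e1) & (e1 < 0 | e1 > 1))
}

#' Relative enrichment of 2,3-C2 versus 1-C, in percent
#'
#' \code{e23 / e1 * 100}.  During photosynthetic pulse labeling this ratio
#' starts near 0\% (only 1-C labeled by the carboxylation reaction) and
#' approaches 100\% as the CBB cycle redistributes label; it cannot exceed
#' 100\%.  For \code{e1} below \code{eps} (pre-pulse samples) the ratio is
#' meaningless and \code{NA} is returned as the undefined-result marker.
#'
#' @param e23 Enrichment of 2,3-C2.
#' @param e1 Enrichment at 1-C.
#' @param eps Denominator threshold below which the ratio is undefined
#'   (default 0.01).
#' @return Percent values; \code{NA} where undefined.
#' @export
rel_e23_over_1 <- function(e23, e1, eps = 0.01) {
  stopifnot(is.numeric(e23), is.numeric(e1))
  ifelse(!is.na(e1) & e1 > eps, e23 / e1 * 100, NA_real_)
}

#' Molar positional 13C concentrations
#'
#' Multiplies enrichments by the metabolite concentration with
#' carbon-count weighting: \code{c13c_1 = 1 * e1 * c},
#' \code{c13c_23 = 2 * e23 * c}, \code{c13c_123 = 3 * e123 * c}, so that the
#' additivity \code{c13c_123 = c13c_1 + c13c_23} holds exactly whenever
#' \code{e1} comes from \code{\link{e1_from_pair}}.  Units follow the
#' concentration input, conventionally nmol 13C per OD750 per mL.
#'
#' @param e123,e23,e1 Positional enrichments.
#' @param c_3pga Metabolite concentration (nmol * OD750^-1 * mL^-1).
#' @param per_position Logical; if TRUE report per-position averages
#'   (divide out the carbon-count factors 3/2/1).
#' @return Data frame with columns \code{c13c_123}, \code{c13c_23},
#'   \code{c13c_1}.
#' @export
positional_c13c <- function(e123, e23, e1, c_3pga, per_position = FALSE) {
  stopifnot(all(c_3pga >= 0, na.rm = TRUE))
  w <- if (per_position) c(1, 1, 1) else c(3, 2, 1)
  data.frame(c13c_123 = w[1] * e123 * c_3pga,
             c13c_23  = w[2] * e23  * c_3pga,
             c13c_1   = w[3] * e1   * c_3pga)
}

#' Adjust a measured enrichment to a labeled reference
#'
#' Rescales a target enrichment by the ratio of the theoretical to the
#' measured enrichment of a co-measured reference (e.g. intracellular G6P
#' adjusted to 100\% under fully labeled glucose or to 33.3\% under
#' 2-of-6-position labeled glucoses), absorbing intracellular label dilution
#' and tracer-purity differences between feeding experiments.
#'
#' @param e_target Measured target enrichment (fraction).
#' @param e_reference_measured Measured reference enrichment (fraction,
#'   > 0).
#' @param e_reference_theoretical Theoretical reference enrichment, in
#'   percent (e.g. 100 or 33.3).
#' @return Adjusted target enrichment in percent.
#' @export
adjust_to_reference <- function(e_target, e_reference_measured,
                                e_reference_theoretical) {
  if (any(e_reference_measured <= 0))
    stop("reference enrichment must be positive")
  e_target / e_reference_measured * e_reference_theoretical
}

#' Positional analysis of a paired-enrichment table
#'
#' Tidy wrapper: takes per-sample paired enrichments (and optionally 3PGA
#' concentrations) and returns the positional quantities with data-quality
#' flags.  Samples with out-of-bounds 1-C enrichment are flagged
#' \code{"e1_out_of_bounds"}; samples whose relative enrichment exceeds
#' 100\% are flagged \code{"rel_e_gt_100"} (an instrument-bias symptom);
#' samples without a concentration are marked enrichment-only.
#'
#' @param pairs Data frame with columns \code{sample_id}, \code{e123},
#'   \code{e23} and optionally \code{time_min} and \code{c_3pga}.
#' @return Data frame with e1, rel_e_pct, molar 13C columns and
#'   \code{flags}.
#' @export
positional_analysis <- function(pairs) {
  need <- c("sample_id", "e123", "e23")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  e1 <- e1_from_pair(pairs$e123, pairs$e23)
  oob <- attr(e1, "out_of_bounds")
  rel <- rel_e23_over_1(pairs$e23, as.numeric(e1))
  flags <- character(nrow(pairs))
  flags[oob] <- "e1_out_of_bounds"
  bad_rel <- !is.na(rel) & rel > 100
  flags[bad_rel] <- trimws(paste(flags[bad_rel], "rel_e_gt_100"))
  out <- data.frame(sample_id = pairs$sample_id,
                    e123 = pairs$e123, e23 = pairs$e23,
                    e1 = as.numeric(e1), rel_e_pct = rel,
                    stringsAsFactors = FALSE)
  for (extra in intersect(c("time_min", "genotype", "condition",
                            "replicate", "od750_ml"), names(pairs)))
    out[[extra]] <- pairs[[extra]]
  if ("c_3pga" %in% names(pairs)) {
    cc <- positional_c13c(pairs$e123, pairs$e23, as.numeric(e1), pairs$c_3pga)
    out$c_3pga <- pairs$c_3pga
    out <- cbind(out, cc)
    no_c <- is.na(pairs$c_3pga)
    flags[no_c] <- trimws(paste(flags[no_c], "enrichment_only"))
  }
  out$flags <- flags
  out
}
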