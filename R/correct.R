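# NIA / tracer-purity correction of measured isotopologue distributions.
# Standard tracer-correction formalism: the correction matrix maps
# tracer-isotopologue fractions (exactly j tracer-derived labels) to the
# observed mass-shift channels; correcting a measurement solves that linear
# model, by non-negative least squares by default.

#' Correction configuration
#'
#' @param tracer_purity Isotopic purity of the tracer in (0, 1]; default
#'   0.99 (99\% pure 13CO2).
#' @param resolution_mode "full" corrects for heavy isotopes of every
#'   element in the fragment (TMS silicon included); "carbon_only" corrects
#'   only for the natural 13C of derivatization carbons.
#' @param nonnegativity "constrained" solves a non-negative least-squares
#'   problem (default; unbiased near the 0 and 1 enrichment boundaries);
#'   "clip" does an unconstrained least-squares solve and clips negative
#'   components to zero.
#' @param p13_natural Natural 13C abundance (default 0.01109).
#' @param abundance_limits Optional named list of c(low, high) raw-abundance
#'   validity limits per fragment id, used by
#'   \code{\link{validity_range_check}}.
#' @return A \code{correction_config} list.
#' @export
correction_config <- function(tracer_purity = 0.99,
                              resolution_mode = c("full", "carbon_only"),
                              nonnegativity = c("constrained", "clip"),
                              p13_natural = 0.01109,
                              abundance_limits = NULL) {
  stopifnot(tracer_purity > 0, tracer_purity <= 1,
            p13_natural >= 0, p13_natural < 1)
  structure(list(tracer_purity = tracer_purity,
                 resolution_mode = match.arg(resolution_mode),
                 nonnegativity = match.arg(nonnegativity),
                 p13_natural = p13_natural,
                 abundance_limits = abundance_limits),
            class = "correction_config")
}

#' Build the NIA/tracer-purity correction matrix for a fragment
#'
#' Column j (j = 0..n labelable carbons) is the theoretical observed pattern
#' of a species carrying exactly j tracer-derived labels: each labeled
#' position is 13C with probability equal to the tracer purity, each
#' unlabeled labelable position is 13C at natural abundance, and the rest of
#' the formula contributes its natural-abundance pattern (all elements in
#' "full" mode; derivatization carbons only in "carbon_only" mode).  The
#' matrix has \code{n_obs} rows (observed channels); with \code{n_obs}
#' larger than n+1 the extra rows capture the heavy-isotope tail of
#' Si-rich TMS fragments and the solve is done in the least-squares sense.
#'
#' @param frag A \code{fragment_spec}.
#' @param cfg A \code{correction_config}.
#' @param n_obs Number of observed channels (rows); default
#'   \code{n_labelable + 4}.
#' @return An \code{n_obs x (n_labelable + 1)} matrix; columns sum to at
#'   most one (less the truncated tail mass).
#' @export
build_correction_matrix <- function(frag, cfg = correction_config(),
                                    n_obs = NULL) {
  stopifnot(inherits(frag, "fragment_spec"),
            inherits(cfg, "correction_config"))
  n <- frag$n_labelable_carbons
  if (is.null(n_obs)) n_obs <- n + 5L
  if (n_obs < n + 1L)
    stop("n_obs must be at least n_labelable + 1 (", n + 1L, ")")
  nat_res <- .residual_pattern(frag, cfg)
  M <- matrix(0, nrow = n_obs, ncol = n + 1L)
  for (j in 0:n) {
    labeled   <- if (j > 0) stats::dbinom(0:j, j, cfg$tracer_purity) else 1
    unlabeled <- if (n - j > 0) stats::dbinom(0:(n - j), n - j,
                                              cfg$p13_natural) else 1
    col <- .conv(.conv(labeled, unlabeled), nat_res)
    if (length(col) < n_obs) col <- c(col, numeric(n_obs - length(col)))
    M[, j + 1L] <- col[seq_len(n_obs)]
  }
  dimnames(M) <- list(paste0("M+", 0:(n_obs - 1L)), paste0("x", 0:n))
  M
}

# natural-abundance pattern of the non-labelable part of the fragment
.residual_pattern <- function(frag, cfg) {
  iso <- isotope_table(c13 = cfg$p13_natural)
  if (cfg$resolution_mode == "carbon_only") {
    nd <- frag$n_derivatization_carbons
    if (nd == 0) return(1)
    return(stats::dbinom(0:nd, nd, cfg$p13_natural))
  }
  residual <- .residual_formula(frag)
  if (is.null(residual)) 1 else natural_isotope_pattern(residual, iso)
}

#' Correct a measured isotopologue distribution
#'
#' Solves \code{M x = measured} for the tracer-isotopologue vector
#' \code{x >= 0}, where M is the fragment's correction matrix, and derives
#' the relative isotopologue abundance (RIA) distribution, the corrected
#' total abundance, and the fractional enrichment E13C.
#'
#' @param abundances Raw abundance vector indexed M+0, M+1, ... (arbitrary
#'   units); must have at least \code{n_labelable + 1} entries.
#' @param frag A \code{fragment_spec}.
#' @param cfg A \code{correction_config}.
#' @return An \code{enrichment_result}: list with \code{corrected} (vector
#'   over 0..n labels), \code{ria} (corrected, normalized to sum one),
#'   \code{total} (sum of corrected abundances) and \code{e13c}.
#' @export
correct_isotopologues <- function(abundances, frag,
                                  cfg = correction_config()) {
  stopifnot(is.numeric(abundances), inherits(frag, "fragment_spec"))
  if (any(abundances < 0)) stop("negative abundances")
  if (all(abundances == 0)) stop("no signal: all abundances are zero")
  n <- frag$n_labelable_carbons
  if (length(abundances) < n + 1L)
    stop("measured vector shorter than n_labelable + 1 (", n + 1L, ")")
  M <- build_correction_matrix(frag, cfg, n_obs = length(abundances))
  if (qr(M)$rank < ncol(M)) stop("singular correction matrix")
  y <- as.numeric(abundances)
  s <- sum(y)  # solve on the unit scale; NNLS tolerances are absolute
  x <- if (cfg$nonnegativity == "constrained") {
    s * pracma::lsqnonneg(M, y / s)$x
  } else {
    pmax(stats::lm.fit(M, y)$coefficients, 0)
  }
  x <- as.numeric(x)
  total <- sum(x)
  if (total <= 0) stop("no signal after correction")
  structure(list(corrected = x, ria = x / total, total = total,
                 # qualifier fragments (no labelable C) have no enrichment
                 e13c = if (n >= 1L) enrichment(x, n) else NA_real_,
                 fragment_id = frag$id),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>", x$fragment_id, "\n")
  cat("  E13C:", format(x$e13c, digits = 6),
      " total:", format(x$total, digits = 6), "\n")
  cat("  RIA:", paste(format(round(x$ria, 4), nsmall = 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Fractional 13C enrichment of a corrected distribution
#'
#' E13C is the average fraction of 13C across the labelable carbon
#' positions: \code{sum(i * x[i]) / (n * sum(x))} over label counts i.
#'
#' @param corrected Non-negative vector over 0..k labels.
#' @param n_labelable Number of labelable carbons (>= 1).
#' @return E13C in [0, 1].
#' @export
enrichment <- function(corrected, n_labelable) {
  stopifnot(is.numeric(corrected), all(corrected >= 0), n_labelable >= 1)
  s <- sum(corrected)
  if (s == 0) stop("zero-sum corrected vector")
  sum((seq_along(corrected) - 1) * corrected) / (n_labelable * s)
}

#' Check a sample's raw abundance against the validated range
#'
#' NIA correction is only accurate inside the calibration-derived abundance
#' window; below it, noise inflates apparent enrichment, above it detector
#' saturation distorts the isotopologue distribution.  Flagged samples are
#' excluded from downstream enrichment use.
#'
#' @param total_abundance Total raw abundance value(s).
#' @param limits Numeric c(low, high) validity limits in the same units.
#' @return Character vector with entries "ok", "below_range" or "saturated".
#' @export
validity_range_check <- function(total_abundance, limits) {
  stopifnot(is.numeric(limits), length(limits) == 2L, limits[1] <= limits[2])
  ifelse(total_abundance < limits[1], "below_range",
         ifelse(total_abundance > limits[2], "saturated", "ok"))
}
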