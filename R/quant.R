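# Calibration-based absolute quantification of 3PGA.  Concentrations are
# derived from the NIA-corrected sum of isotopologue abundances of fragment
# 357, normalized to the 13C6-sorbitol internal standard, calibrated against
# a dilution series of non-labeled reference compound, and expressed as
# nmol per OD750 per mL.

# molar mass of 3PGA free acid C3H7O7P (g/mol); overridable in quantify()
.MM_3PGA <- 186.06

#' Fit a quantification calibration line
#'
#' Ordinary least squares of abundance on injected amount, restricted to
#' the linear range.  The linear range is auto-detected as the longest
#' contiguous window of amounts whose log-log slope stays within 1 +/- 0.1
#' (saturation plateaus and sub-detection points fall outside); an explicit
#' \code{range} always wins.
#'
#' @param amount_ng Injected amounts (ng), at least 4 distinct values > 0.
#' @param abundance Measured (internal-standard normalized) abundances.
#' @param range Optional c(low, high) ng window overriding auto-detection.
#' @param auto_detect Logical, detect the linear range (default TRUE).
#' @param slope_tol Log-log slope tolerance for auto-detection.
#' @return A \code{calibration_fit} with slope, intercept, valid_range,
#'   r_squared and the underlying \code{lm} fit.
#' @export
fit_calibration <- function(amount_ng, abundance, range = NULL,
                            auto_detect = TRUE, slope_tol = 0.1) {
  stopifnot(is.numeric(amount_ng), is.numeric(abundance),
            length(amount_ng) == length(abundance))
  if (any(amount_ng <= 0)) stop("amounts must be positive")
  if (length(unique(amount_ng)) < 4L)
    stop("need at least 4 distinct calibration amounts")
  if (stats::sd(abundance) == 0)
    stop("zero variance: all calibration abundances identical")
  keep <- rep(TRUE, length(amount_ng))
  if (!is.null(range)) {
    keep <- amount_ng >= range[1] & amount_ng <= range[2]
  } else if (auto_detect) {
    keep <- .detect_linear_range(amount_ng, abundance, slope_tol)
  }
  if (length(unique(amount_ng[keep])) < 4L)
    stop("fewer than 4 distinct amounts inside the linear range")
  fit <- stats::lm(abundance ~ amount_ng, subset = keep)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 valid_range = c(min(amount_ng[keep]), max(amount_ng[keep])),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = sum(keep), fit = fit),
            class = "calibration_fit")
}

# longest contiguous amount window with log-log slope within 1 +/- tol
.detect_linear_range <- function(amount_ng, abundance, tol) {
  amt <- sort(unique(amount_ng))
  if (length(amt) < 4L) return(rep(TRUE, length(amount_ng)))
  means <- vapply(amt, function(a) mean(abundance[amount_ng == a]),
                  numeric(1))
  ok_mean <- means > 0
  best <- c(1L, length(amt))
  best_len <- 0L
  for (i in seq_along(amt)) {
    if (i + 3L > length(amt)) break
    for (j in (i + 3L):length(amt)) {
      idx <- i:j
      if (!all(ok_mean[idx])) next
      sl <- stats::coef(stats::lm(log(means[idx]) ~ log(amt[idx])))[2]
      # every adjacent step must be near-proportional too, so a saturation
      # plateau at the window edge cannot hide behind the overall slope
      sl_adj <- diff(log(means[idx])) / diff(log(amt[idx]))
      if (abs(sl - 1) <= tol && all(abs(sl_adj - 1) <= 3 * tol) &&
          (j - i) > best_len) {
        best <- c(i, j); best_len <- j - i
      }
    }
  }
  amount_ng >= amt[best[1]] & amount_ng <= amt[best[2]]
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  abundance = %.6g * ng %+.6g   (r^2 = %.6f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  linear range: %.3g - %.3g ng injected\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @export
predict.calibration_fit <- function(object, amount_ng, ...) {
  object$intercept + object$slope * amount_ng
}

#' Quantify a metabolite concentration from corrected abundance
#'
#' Converts the NIA-corrected total abundance of a quantification fragment
#' into a molar concentration: internal-standard ratio -> ng injected via
#' the calibration line (calibration samples carry the same internal
#' standard so the normalization cancels) -> nmol via molar mass -> divided
#' by the harvested OD750 * mL equivalent.
#'
#' @param abundance Corrected total abundance of the sample.
#' @param is_abundance Internal-standard abundance (> 0).
#' @param od_ml Harvested biomass, OD750 * mL (> 0).
#' @param model A \code{calibration_fit} fitted on internal-standard
#'   normalized abundances.
#' @param molar_mass Molar mass used for ng -> nmol (default 186.06, the
#'   3PGA free acid C3H7O7P).
#' @param purity_factor Chemical purity of the calibration reference
#'   substance (default 1.0).
#' @param volume_factor Extraction-to-injection volume ratio scaling the
#'   on-column amount back to the whole sample (default 100: 1 uL
#'   injected of a 100 uL extract).
#' @return A one-row data frame: \code{c_3pga} (nmol * OD750^-1 * mL^-1),
#'   \code{normalized_abundance}, \code{amount_ng}, \code{in_range}.
#' @export
quantify <- function(abundance, is_abundance, od_ml, model,
                     molar_mass = .MM_3PGA, purity_factor = 1.0,
                     volume_factor = 100) {
  stopifnot(inherits(model, "calibration_fit"))
  if (any(is_abundance <= 0)) stop("internal-standard abundance must be > 0")
  if (any(od_ml <= 0)) stop("od_ml must be > 0")
  ratio <- abundance / is_abundance
  ng <- (ratio - model$intercept) / model$slope
  in_range <- ng >= model$valid_range[1] & ng <= model$valid_range[2]
  nmol <- ng * volume_factor * purity_factor / molar_mass
  data.frame(c_3pga = pmax(nmol, 0) / od_ml,
             normalized_abundance = ratio,
             amount_ng = ng, in_range = in_range)
}

#' Relative standard deviation of a replicate group
#'
#' @param values At least two replicate values.
#' @return RSD in percent (100 * sample sd / mean); \code{NA} when the mean
#'   is zero.
#' @export
replicate_rsd <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("need at least 2 replicate values")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Cross-fragment abundance consistency report
#'
#' Pearson correlations between per-sample abundances of the quantification
#' fragment and its qualifier fragments (e.g. 3PGA fragments 357, 459, 299,
#' 315).  Qualifier fragments serve correlation checks only, never
#' quantification.  Negative correlations are flagged as inconsistencies;
#' constant columns yield \code{NA} (undefined marker).
#'
#' @param abundances Numeric matrix or data frame, samples in rows and
#'   fragments in columns (>= 10 samples).
#' @return List with \code{r} (correlation matrix) and
#'   \code{inconsistent} (character vector of flagged pairs).
#' @export
cross_fragment_consistency <- function(abundances) {
  m <- as.matrix(abundances)
  if (nrow(m) < 10L) stop("need at least 10 samples")
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  pairs <- which(upper.tri(r) & !is.na(r) & r < 0, arr.ind = TRUE)
  inconsistent <- if (nrow(pairs)) {
    paste(colnames(m)[pairs[, 1]], colnames(m)[pairs[, 2]], sep = " vs ")
  } else character(0)
  list(r = r, inconsistent = inconsistent)
}
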