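# Labeling-kinetics fitting.  Molar 13C concentration time courses are
# fitted with the standard logistic I(t) = i_max / (1 + exp(-a (t - t_mid)))
# whose maximum slope -- the assimilation rate A13C -- has the closed form
# i_max * a / 4, and alternatively with the saturating exponential
# I(t) = i_max (1 - exp(-k t)) whose initial slope is k * i_max.  Fitting is
# seeded multi-start least squares (random starts in data-driven bounds,
# best-SSE selection, nls polish) with a soft penalty keeping the model
# value at t = 0 near zero.

# run code with a private, restored RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

.logistic <- function(t, i_max, a, t_mid) i_max / (1 + exp(-a * (t - t_mid)))

#' Fit a logistic labeling curve
#'
#' Multi-start nonlinear least squares of
#' \code{I(t) = i_max / (1 + exp(-a (t - t_mid)))}.  Residuals are
#' weighted by the inverse squared model value (floored at 5\% of the data
#' maximum), i.e. relative least squares, the appropriate objective for
#' abundance-derived values whose errors are multiplicative; unweighted
#' raw-scale SSE is also reported.  Random starts (\code{n_starts},
#' default 1000) are drawn inside data-driven parameter bounds, the
#' objective is evaluated at all of them, the best few are refined by
#' simplex minimization and an \code{nls} polish, and the overall best
#' solution is kept; the restart sweep doubles as the robustness check for
#' the sigmoidal classification.  The objective adds a soft penalty for
#' model values at t = 0 above \code{t0_tol * i_max} (the logistic never
#' reaches 0 exactly, but labeling starts at zero).
#'
#' Classification: \code{"no_signal"} when the data carry no usable signal;
#' \code{"ambiguous"} when the observed maximum never reaches
#' \code{threshold_ratio * i_max} (no plateau inside the window) or the
#' fitted t = 0 value exceeds twice the tolerance; otherwise
#' \code{"sigmoidal"}.
#'
#' @param times Time points (minutes), strictly increasing, starting at 0.
#' @param values Non-negative responses (C13C or E13C) at \code{times}.
#' @param n_starts Number of random starts (default 1000).
#' @param seed Optional integer seed making the start sweep reproducible.
#' @param t0_tol Tolerated model value at t = 0 as a fraction of i_max.
#' @param t0_penalty_weight Weight of the soft t = 0 penalty relative to
#'   the data scale.
#' @param threshold_ratio Fraction of i_max the data must reach for a
#'   "sigmoidal" classification (default 0.75).
#' @return A \code{logistic_fit}: parameters \code{i_max}, \code{a},
#'   \code{t_mid}, the assimilation rate \code{a13c = i_max * a / 4},
#'   \code{fit_class}, \code{sse} and the data.
#' @export
fit_logistic <- function(times, values, n_starts = 1000L, seed = NULL,
                         t0_tol = 0.05, t0_penalty_weight = 10,
                         threshold_ratio = 0.75) {
  stopifnot(length(times) == length(values), length(times) >= 5L,
            !is.unsorted(times, strictly = TRUE))
  if (any(values < 0)) stop("values must be non-negative")
  out <- list(times = times, values = values, model = "logistic")
  vmax <- max(values)
  if (vmax <= 0 || stats::sd(values) == 0) {
    out <- c(out, list(i_max = NA_real_, a = NA_real_, t_mid = NA_real_,
                       a13c = NA_real_, sse = NA_real_,
                       fit_class = "no_signal", converged = FALSE))
    class(out) <- c("logistic_fit", "labeling_fit")
    return(out)
  }
  tmax <- max(times)
  # the fitted maximum slope (i_max a / 4) cannot meaningfully exceed
  # twice the steepest secant the data actually show; without this cap a
  # noisy sparse rise admits near-step fits with arbitrarily large a
  s_max <- max(diff(values) / diff(times))
  a_hi <- if (s_max > 0) max(0.1, min(5, 12 * s_max / vmax)) else 5
  lo <- c(i_max = 0.5 * vmax, a = 0.02, t_mid = min(times[times > 0]) / 2)
  hi <- c(i_max = 2.0 * vmax, a = a_hi, t_mid = tmax)
  wfloor <- vmax / 20
  obj <- function(p) {
    if (any(p < lo) || any(p > hi)) return(Inf)
    f <- .logistic(times, p[1], p[2], p[3])
    pen <- max(0, .logistic(0, p[1], p[2], p[3]) - t0_tol * p[1])
    sum(((values - f) / pmax(f, wfloor))^2) +
      t0_penalty_weight * length(values) * (pen / p[1])^2
  }
  best <- .with_seed(seed, {
    starts <- cbind(stats::runif(n_starts, lo[1], hi[1]),
                    stats::runif(n_starts, lo[2], hi[2]),
                    stats::runif(n_starts, lo[3], hi[3]))
    sse0 <- apply(starts, 1, obj)
    top <- starts[order(sse0)[seq_len(min(5L, n_starts))], , drop = FALSE]
    cand <- lapply(seq_len(nrow(top)), function(i)
      tryCatch(stats::optim(top[i, ], obj, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-12)),
               error = function(e) NULL))
    cand <- Filter(Negate(is.null), cand)
    cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  })
  p <- best$par
  # weighted nls polish (weights frozen at the current fit: one IRLS step)
  w <- 1 / pmax(.logistic(times, p[1], p[2], p[3]), wfloor)^2
  polish <- tryCatch(suppressWarnings(
    stats::nls(values ~ i_max / (1 + exp(-a * (times - t_mid))),
               start = list(i_max = p[1], a = p[2], t_mid = p[3]),
               weights = w, lower = lo, upper = hi, algorithm = "port",
               control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(polish)) {
    pp <- stats::coef(polish)
    if (is.finite(obj(pp)) && obj(pp) <= best$value) p <- pp
  }
  names(p) <- c("i_max", "a", "t_mid")
  sse <- sum((values - .logistic(times, p[1], p[2], p[3]))^2)
  # the plateau must be sampled, not merely touched by the final point
  reached <- sum(values >= threshold_ratio * p[["i_max"]]) >= 2L
  t0_ok <- .logistic(0, p[1], p[2], p[3]) <= 2 * t0_tol * p[["i_max"]]
  # the curve must have flattened inside the observation window: the model
  # slope at the last time point may not exceed half the midpoint slope
  p_end <- 1 / (1 + exp(-p[["a"]] * (tmax - p[["t_mid"]])))
  flat_end <- 4 * p_end * (1 - p_end) <= 0.5
  fit_class <- if (reached && t0_ok && flat_end) "sigmoidal"
               else "ambiguous"
  out <- c(out, list(i_max = p[["i_max"]], a = p[["a"]],
                     t_mid = p[["t_mid"]],
                     a13c = p[["i_max"]] * p[["a"]] / 4,
                     sse = sse, fit_class = fit_class,
                     converged = is.finite(sse)))
  class(out) <- c("logistic_fit", "labeling_fit")
  out
}

#' Fit a saturating-exponential labeling curve
#'
#' Least squares of \code{I(t) = i_max (1 - exp(-k t))}; the initial slope
#' (the first derivative at t = 0) is \code{k * i_max}.  Lag phases in the
#' data are not captured by this model; compare with
#' \code{\link{fit_logistic}} and treat discrepancies above ~25\% of the
#' logistic rate as lag evidence.
#'
#' @inheritParams fit_logistic
#' @return An \code{exp_fit} with \code{i_max}, \code{k},
#'   \code{initial_slope}, \code{fit_class} and \code{sse}.
#' @export
fit_exponential <- function(times, values, n_starts = 200L, seed = NULL) {
  stopifnot(length(times) == length(values), length(times) >= 3L,
            !is.unsorted(times, strictly = TRUE))
  out <- list(times = times, values = values, model = "exponential")
  vmax <- max(values)
  if (vmax <= 0 || stats::sd(values) == 0) {
    out <- c(out, list(i_max = NA_real_, k = NA_real_,
                       initial_slope = NA_real_, sse = NA_real_,
                       fit_class = "no_signal", converged = FALSE))
    class(out) <- c("exp_fit", "labeling_fit")
    return(out)
  }
  lo <- c(i_max = 0.5 * vmax, k = 1e-4)
  hi <- c(i_max = 2.0 * vmax, k = 5)
  wfloor <- vmax / 20
  obj <- function(p) {
    if (any(p < lo) || any(p > hi)) return(Inf)
    f <- p[1] * (1 - exp(-p[2] * times))
    sum(((values - f) / pmax(f, wfloor))^2)
  }
  best <- .with_seed(seed, {
    starts <- cbind(stats::runif(n_starts, lo[1], hi[1]),
                    exp(stats::runif(n_starts, log(lo[2]), log(hi[2]))))
    sse0 <- apply(starts, 1, obj)
    top <- starts[order(sse0)[seq_len(min(5L, n_starts))], , drop = FALSE]
    cand <- lapply(seq_len(nrow(top)), function(i)
      tryCatch(stats::optim(top[i, ], obj, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-12)),
               error = function(e) NULL))
    cand <- Filter(Negate(is.null), cand)
    cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  })
  p <- best$par
  w <- 1 / pmax(p[1] * (1 - exp(-p[2] * times)), wfloor)^2
  polish <- tryCatch(suppressWarnings(
    stats::nls(values ~ i_max * (1 - exp(-k * times)),
               start = list(i_max = p[1], k = p[2]), weights = w,
               lower = lo, upper = hi, algorithm = "port",
               control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(polish)) {
    pp <- stats::coef(polish)
    if (is.finite(obj(pp)) && obj(pp) <= best$value) p <- pp
  }
  names(p) <- c("i_max", "k")
  sse <- sum((values - p[1] * (1 - exp(-p[2] * times)))^2)
  out <- c(out, list(i_max = p[["i_max"]], k = p[["k"]],
                     initial_slope = p[["i_max"]] * p[["k"]],
                     sse = sse, fit_class = "exponential",
                     converged = is.finite(sse)))
  class(out) <- c("exp_fit", "labeling_fit")
  out
}

#' @export
coef.labeling_fit <- function(object, ...) {
  if (object$model == "logistic")
    c(i_max = object$i_max, a = object$a, t_mid = object$t_mid)
  else c(i_max = object$i_max, k = object$k)
}

#' @export
predict.labeling_fit <- function(object, times = object$times, ...) {
  if (object$model == "logistic")
    .logistic(times, object$i_max, object$a, object$t_mid)
  else object$i_max * (1 - exp(-object$k * times))
}

#' @export
fitted.labeling_fit <- function(object, ...) predict(object)

#' @export
residuals.labeling_fit <- function(object, ...)
  object$values - predict(object)

#' @export
print.labeling_fit <- function(x, ...) {
  cat("<", x$model, " labeling fit>  class: ", x$fit_class, "\n", sep = "")
  if (x$fit_class == "no_signal") return(invisible(x))
  if (x$model == "logistic") {
    cat(sprintf("  i_max = %.4g  a = %.4g /min  t_mid = %.4g min\n",
                x$i_max, x$a, x$t_mid))
    cat(sprintf("  A13C (max slope) = %.4g units/min   SSE = %.4g\n",
                x$a13c, x$sse))
  } else {
    cat(sprintf("  i_max = %.4g  k = %.4g /min\n", x$i_max, x$k))
    cat(sprintf("  initial slope = %.4g units/min   SSE = %.4g\n",
                x$initial_slope, x$sse))
  }
  invisible(x)
}

#' @export
summary.labeling_fit <- function(object, ...) {
  print(object)
  if (object$fit_class != "no_signal") {
    cat(sprintf("  residual sd = %.4g on %d points\n",
                stats::sd(residuals(object)), length(object$times)))
  }
  invisible(object)
}

#' @export
plot.labeling_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, xlab = "time (min)", ylab = "value",
                 main = paste(x$model, "labeling fit"), ...)
  if (x$fit_class != "no_signal") {
    tt <- seq(min(x$times), max(x$times), length.out = 200)
    graphics::lines(tt, predict(x, tt))
    if (x$model == "logistic")
      graphics::abline(v = x$t_mid, lty = 2)
  }
  invisible(x)
}

#' Welch two-group comparison
#'
#' Heteroscedastic two-tailed Student's t-test (Welch-Satterthwaite degrees
#' of freedom) with the conventional significance stars (* <= 0.05,
#' ** <= 0.01, *** <= 0.001).
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @return List with \code{t}, \code{df}, \code{p_value}, \code{stars}.
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  p <- tt$p.value
  stars <- if (is.na(p)) "" else if (p <= 0.001) "***"
           else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = p, stars = stars)
}

#' Cross-instrument enrichment regression
#'
#' OLS regression of one instrument's paired E13C readings on the other's,
#' with Pearson r^2; flags systematic bias when the confidence interval of
#' the slope excludes 1 or that of the intercept excludes 0.
#'
#' @param x Reference measurements (>= 10 pairs).
#' @param y Comparison measurements.
#' @param conf_level Confidence level for the bias flags.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{biased} (logical) or NA components for constant input.
#' @export
correlate_instruments <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) stop("need at least 10 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, biased = NA))
  fit <- stats::lm(y ~ x)
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  biased <- ci["x", 1] > 1 || ci["x", 2] < 1 ||
    ci["(Intercept)", 1] > 0 || ci["(Intercept)", 2] < 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       biased = biased)
}
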