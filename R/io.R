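# File I/O and the end-to-end pipeline: raw isotopologue tables ->
# NIA/purity-corrected enrichments -> paired positional enrichments ->
# calibrated concentrations -> molar positional 13C -> kinetic rate fits
# and group statistics.  All tables are tidy long-format CSV, UTF-8,
# '.' decimal; "n.d." (not detected) is an explicit sentinel distinct from
# 0 and from missing.

#' Read and validate an isotopologue measurement table
#'
#' Required columns: sample_id, fragment_id, isotopologue_index, abundance
#' (optional instrument_mode).  Duplicated (sample, fragment, index) keys,
#' negative abundances and gaps in the isotopologue index are rejected with
#' the offending row or key named.
#'
#' @param x CSV path or data frame.
#' @return Validated data frame ordered by sample, fragment, index.
#' @export
read_measurements <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
        else as.data.frame(x)
  need <- c("sample_id", "fragment_id", "isotopologue_index", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no samples: empty measurement table")
  bad <- which(df$abundance < 0)
  if (length(bad)) stop("negative abundance at row ", bad[1])
  key <- paste(df$sample_id, df$fragment_id, df$isotopologue_index)
  if (anyDuplicated(key))
    stop("duplicate (sample, fragment, index) key: ",
         key[duplicated(key)][1])
  df <- df[order(df$sample_id, df$fragment_id, df$isotopologue_index), ]
  sp <- split(df$isotopologue_index, paste(df$sample_id, df$fragment_id))
  for (k in names(sp)) {
    idx <- sort(sp[[k]])
    if (!identical(as.integer(idx), seq(0L, length(idx) - 1L)))
      stop("gap in isotopologue indices for ", k)
  }
  rownames(df) <- NULL
  df
}

#' Read a sample metadata table
#'
#' @param x CSV path or data frame with at least sample_id; typical columns
#'   are time_min, genotype, condition, replicate, od750_ml, is_abundance.
#' @return Validated data frame.
#' @export
read_metadata <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
        else as.data.frame(x)
  if (!"sample_id" %in% names(df)) stop("missing column(s): sample_id")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  df
}

#' Read a calibration series table
#'
#' @param x CSV path or data frame with columns fragment_id, amount_ng,
#'   abundance (optional is_abundance, replicate).
#' @return Validated data frame.
#' @export
read_calibration <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
        else as.data.frame(x)
  need <- c("fragment_id", "amount_ng", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$amount_ng <= 0)) stop("calibration amounts must be positive")
  df
}

#' Pipeline configuration
#'
#' @param correction A \code{correction_config}.
#' @param frag_123,frag_23 Fragment ids of the complete-molecule and
#'   2,3-C2 features (defaults 3PGA_459 / 3PGA_357).
#' @param quant_fragment Fragment used for concentration (default
#'   3PGA_357).
#' @param fit_max_time Upper time bound (min) for rate fits; later samples
#'   enter enrichment outputs only (default 60).
#' @param n_starts,kinetics_seed Multi-start budget and seed for the
#'   logistic fits.
#' @param molar_mass,purity_factor,volume_factor Passed to
#'   \code{\link{quantify}}.
#' @param rel_eps Denominator threshold for the relative-enrichment ratio.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(correction = correction_config(),
                            frag_123 = "3PGA_459", frag_23 = "3PGA_357",
                            quant_fragment = "3PGA_357",
                            fit_max_time = 60, n_starts = 1000L,
                            kinetics_seed = 1L, molar_mass = .MM_3PGA,
                            purity_factor = 1.0, volume_factor = 100,
                            rel_eps = 0.01) {
  structure(list(correction = correction, frag_123 = frag_123,
                 frag_23 = frag_23, quant_fragment = quant_fragment,
                 fit_max_time = fit_max_time, n_starts = as.integer(n_starts),
                 kinetics_seed = as.integer(kinetics_seed),
                 molar_mass = molar_mass, purity_factor = purity_factor,
                 volume_factor = volume_factor, rel_eps = rel_eps),
            class = "pipeline_config")
}

#' Run the full positional-enrichment pipeline
#'
#' Corrects every measured fragment for NIA and tracer purity, pairs the
#' complete-molecule and 2,3-C2 enrichments per sample, computes 1-C
#' enrichment and the relative-enrichment ratio, quantifies 3PGA through
#' the calibration model and internal standard, converts to molar
#' positional 13C, fits logistic labeling curves per genotype x condition x
#' replicate x position, and reports Welch comparisons of the fitted rates
#' against the first genotype.  Every exclusion (out-of-validity-range
#' abundance, out-of-bounds 1-C, undefined ratio, missing concentration) is
#' logged with its reason.  Deterministic given inputs and the kinetics
#' seed.
#'
#' @param measurements Measurement table (path or data frame).
#' @param metadata Metadata table (path or data frame).
#' @param calibration Optional calibration table (path or data frame);
#'   without it the pipeline is enrichment-only.
#' @param config A \code{pipeline_config}.
#' @param fraglib Fragment library.
#' @return A \code{poslabel_pipeline} object: list with
#'   \code{enrichments}, \code{positional}, \code{calibration_fit},
#'   \code{fits}, \code{tests}, \code{log}.
#' @export
run_pipeline <- function(measurements, metadata, calibration = NULL,
                         config = pipeline_config(),
                         fraglib = fragment_library()) {
  meas <- read_measurements(measurements)
  meta <- read_metadata(metadata)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  # --- stage: correction ------------------------------------------------
  keys <- unique(meas[, c("sample_id", "fragment_id")])
  keys <- keys[order(keys$sample_id, keys$fragment_id), ]
  enr <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$sample_id[i]; fid <- keys$fragment_id[i]
    frag <- fraglib[[fid]]
    if (is.null(frag)) {
      note("correction: skipped unknown fragment ", fid)
      return(NULL)
    }
    y <- meas$abundance[meas$sample_id == sid & meas$fragment_id == fid]
    res <- tryCatch(correct_isotopologues(y, frag, config$correction),
                    error = function(e)
                      stop("correction stage failed for sample ", sid,
                           " fragment ", fid, ": ", conditionMessage(e)))
    lim <- config$correction$abundance_limits[[fid]]
    flag <- if (is.null(lim)) "ok" else validity_range_check(sum(y), lim)
    data.frame(sample_id = sid, fragment_id = fid, e13c = res$e13c,
               total = res$total, raw_total = sum(y),
               range_flag = flag, stringsAsFactors = FALSE)
  }))
  excl <- enr$range_flag != "ok"
  if (any(excl))
    note("enrichment: excluded ", sum(excl),
         " sample-fragment pair(s) outside the validated abundance range")

  # --- stage: pairing + positional -------------------------------------
  ok <- enr[enr$range_flag == "ok", ]
  e123 <- ok[ok$fragment_id == config$frag_123,
             c("sample_id", "e13c", "total")]
  e23 <- ok[ok$fragment_id == config$frag_23,
            c("sample_id", "e13c", "total")]
  names(e123)[2:3] <- c("e123", "total_123")
  names(e23)[2:3] <- c("e23", "total_23")
  pairs <- merge(e123, e23, by = "sample_id")
  if (nrow(pairs) == 0L) stop("positional stage: no paired samples")
  pairs$e123 <- pmin(pmax(pairs$e123, 0), 1)
  pairs$e23 <- pmin(pmax(pairs$e23, 0), 1)
  pairs <- merge(pairs, meta, by = "sample_id")

  # --- stage: quantification -------------------------------------------
  cal_fit <- NULL
  if (!is.null(calibration)) {
    cal <- read_calibration(calibration)
    cal <- cal[cal$fragment_id == config$quant_fragment, ]
    ab <- if ("is_abundance" %in% names(cal))
            cal$abundance / cal$is_abundance else cal$abundance
    cal_fit <- fit_calibration(cal$amount_ng, ab)
    q <- quantify(pairs$total_23, pairs$is_abundance, pairs$od750_ml,
                  cal_fit, molar_mass = config$molar_mass,
                  purity_factor = config$purity_factor,
                  volume_factor = config$volume_factor)
    pairs$c_3pga <- ifelse(q$in_range, q$c_3pga, NA_real_)
    if (any(!q$in_range))
      note("quantification: ", sum(!q$in_range),
           " sample(s) outside the calibration range, marked ",
           "enrichment-only")
  }

  positional <- positional_analysis(pairs)
  n_oob <- sum(grepl("e1_out_of_bounds", positional$flags))
  if (n_oob) note("positional: ", n_oob,
                  " sample(s) with out-of-bounds 1-C enrichment, ",
                  "excluded from rate fits")
  n_rel <- sum(is.na(positional$rel_e_pct))
  if (n_rel) note("positional: relative enrichment undefined for ", n_rel,
                  " sample(s) (1-C enrichment below threshold)")

  # --- stage: kinetics --------------------------------------------------
  fits <- NULL; tests <- NULL
  if (!is.null(cal_fit) &&
      all(c("time_min", "genotype", "condition", "replicate") %in%
          names(positional))) {
    fits <- .fit_rates(positional, config, note)
    tests <- .rate_tests(fits)
  }

  structure(list(enrichments = enr, positional = positional,
                 calibration_fit = cal_fit, fits = fits, tests = tests,
                 log = log),
            class = "poslabel_pipeline")
}

# per genotype x condition x replicate x positional group logistic fits
.fit_rates <- function(pos, config, note) {
  groups <- unique(pos[, c("genotype", "condition", "replicate")])
  groups <- groups[order(groups$genotype, groups$condition,
                         groups$replicate), ]
  cols <- c(c13c_123 = "c13c_123", c13c_23 = "c13c_23", c13c_1 = "c13c_1")
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- pos[pos$genotype == g$genotype & pos$condition == g$condition &
                 pos$replicate == g$replicate &
                 pos$time_min <= config$fit_max_time, ]
    sub <- sub[order(sub$time_min), ]
    usable <- !grepl("e1_out_of_bounds|enrichment_only", sub$flags)
    sub <- sub[usable, ]
    scale123 <- suppressWarnings(max(sub$c13c_123, 0, na.rm = TRUE))
    for (pc in names(cols)) {
      v <- sub[[cols[[pc]]]]
      keep <- !is.na(v)
      if (sum(keep) < 5L) {
        note("kinetics: skipped ", g$genotype, "/", g$condition,
             "/rep", g$replicate, " ", pc, " (<5 usable points)")
        next
      }
      # detection limit: a positional series never rising above 10% of the
      # complete-molecule signal carries no usable labeling kinetics
      if (pc != "c13c_123" && scale123 > 0 &&
          max(v[keep]) < 0.10 * scale123) {
        out[[length(out) + 1L]] <- data.frame(
          genotype = g$genotype, condition = g$condition,
          replicate = g$replicate, series = pc,
          i_max = NA_real_, a = NA_real_, t_mid = NA_real_,
          a13c = NA_real_, sse = NA_real_, fit_class = "no_signal",
          detected = "n.d.", stringsAsFactors = FALSE)
        next
      }
      f <- fit_logistic(sub$time_min[keep], v[keep],
                        n_starts = config$n_starts,
                        seed = config$kinetics_seed + i)
      nd <- f$fit_class == "no_signal"
      out[[length(out) + 1L]] <- data.frame(
        genotype = g$genotype, condition = g$condition,
        replicate = g$replicate, series = pc,
        i_max = f$i_max, a = f$a, t_mid = f$t_mid, a13c = f$a13c,
        sse = f$sse, fit_class = f$fit_class,
        detected = if (nd) "n.d." else "detected",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Welch tests of fitted rates against the reference (first) genotype
.rate_tests <- function(fits) {
  if (is.null(fits) || !nrow(fits)) return(NULL)
  ref <- sort(unique(fits$genotype))[1]
  out <- list()
  for (cond in sort(unique(fits$condition))) {
    for (ser in sort(unique(fits$series))) {
      base <- fits$a13c[fits$genotype == ref & fits$condition == cond &
                          fits$series == ser & fits$fit_class == "sigmoidal"]
      for (g in setdiff(sort(unique(fits$genotype)), ref)) {
        other <- fits$a13c[fits$genotype == g & fits$condition == cond &
                             fits$series == ser &
                             fits$fit_class == "sigmoidal"]
        if (length(base) < 2L || length(other) < 2L) next
        tt <- compare_groups(base, other)
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, series = ser, reference = ref, genotype = g,
          t = tt$t, df = tt$df, p_value = tt$p_value, stars = tt$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.poslabel_pipeline <- function(x, ...) {
  cat("<poslabel_pipeline>\n")
  cat("  corrected enrichments:", nrow(x$enrichments), "sample-fragments\n")
  cat("  paired positional samples:", nrow(x$positional), "\n")
  if (!is.null(x$calibration_fit))
    cat(sprintf("  calibration: r^2 = %.5f, linear %.3g-%.3g ng\n",
                x$calibration_fit$r_squared,
                x$calibration_fit$valid_range[1],
                x$calibration_fit$valid_range[2]))
  if (!is.null(x$fits)) {
    nd <- x$fits$detected == "n.d."
    cat("  rate fits:", nrow(x$fits), "series;",
        sum(nd), "not detected (n.d.)\n")
    if (any(nd)) {
      pos_lab <- c(c13c_123 = "1,2,3-C3", c13c_23 = "2,3-C2",
                   c13c_1 = "1-C")
      lab <- unique(paste0(x$fits$genotype[nd], " ",
                           pos_lab[x$fits$series[nd]], ": not detected"))
      cat("    n.d.:", paste(lab, collapse = "; "), "\n")
    }
  }
  for (l in x$log) cat("  log:", l, "\n")
  invisible(x)
}

#' Write pipeline results as tidy CSV files
#'
#' Writes enrichments.csv, positional.csv, fits.csv, tests.csv and
#' log.txt into \code{dir} with fixed formatting (15 significant digits,
#' '.' decimal, sorted rows), so identical inputs produce byte-identical
#' outputs.
#'
#' @param result A \code{poslabel_pipeline}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "poslabel_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    for (cl in names(df))
      if (is.numeric(df[[cl]]))
        df[[cl]] <- sprintf("%.15g", df[[cl]])
    df
  }
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(fmt(df), p, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  wr(result$enrichments, "enrichments.csv")
  wr(result$positional, "positional.csv")
  wr(result$fits, "fits.csv")
  wr(result$tests, "tests.csv")
  writeLines(result$log, file.path(dir, "log.txt"))
  paths <- c(paths, file.path(dir, "log.txt"))
  invisible(paths)
}
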