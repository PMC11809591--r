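# Seeded synthetic-data generator emulating dynamic 13CO2 pulse-labeling
# experiments: positional labeling kinetics, raw fragment isotopologue
# tables convolved with natural isotope abundance and tracer purity,
# calibration series, instrument-bias variants, and steady-state
# glucose-isotopomer feeding outcomes.  Every generator is deterministic
# given its seed; truth sidecars carry all generating values.

# genotype presets: phenomenology of WT-like, CBB-modulating (gapdh1-like)
# and CBB-deficient (gapdh2-like) cells.  Midpoint times 5.4/8.4 min
# (1-C vs 2,3-C2) and concentrations per genotype follow the observed WT
# kinetics; steepness a = 0.5 /min reproduces an assimilation rate of
# ~0.16 nmol/OD750/mL/min at the WT 1-C plateau.  The 2,3-C2 plateau is
# scaled by an anaplerotic dilution factor < 1 (storage-carbohydrate carbon
# keeps saturation below 100%); the CBB-deficient preset has no 2,3-C2
# labeling at all.
.GENOTYPE_PRESETS <- list(
  WT = list(e1_plateau = 0.95, a1 = 0.5, t_mid1 = 5.4, lag = 3.0,
            a23 = 0.5, c_3pga = 1.32),
  gapdh1 = list(e1_plateau = 0.95, a1 = 0.5, t_mid1 = 6.1, lag = 2.7,
                a23 = 0.5, c_3pga = 1.42),
  gapdh2 = list(e1_plateau = 0.34, a1 = 0.5, t_mid1 = 10.3, lag = 3.0,
                a23 = 0.5, c_3pga = 0.99)
)
# anaplerotic plateau by condition: LC-preacclimated cells hold less
# storage carbohydrate, so less unlabeled carbon dilutes 2,3-C2
.CONDITION_PRESETS <- list(
  "HC-HC" = list(ana_plateau = 0.90, t_shift = 0.0),
  "LC-HC" = list(ana_plateau = 0.97, t_shift = -0.8)
)

#' Simulation configuration
#'
#' Bundles the kinetic truth, noise model and instrument model for the
#' synthetic pulse-labeling generator.  Genotype and condition presets give
#' the study-like defaults; every component can be overridden.
#'
#' @param genotype "WT", "gapdh1" (CBB-modulating) or "gapdh2"
#'   (CBB-deficient; no 2,3-C2 labeling).
#' @param condition "HC-HC" (steady state) or "LC-HC" (shift; faster
#'   labeling, higher anaplerotic plateau).
#' @param times Sampling grid in minutes (default 0/5/10/15/30/60).
#' @param n_replicates Biological replicates (default 3).
#' @param noise_sd Sample-level multiplicative log-normal noise sd applied
#'   to whole-peak abundances and replicate biology (default 0.10).
#' @param channel_noise_sd Per-channel multiplicative noise sd (default
#'   0.02; isotopologue ratios within one peak are far more precise than
#'   total peak abundances).
#' @param floor Additive abundance noise floor (arbitrary units; drives
#'   enrichment inflation at low signal).
#' @param ceiling Detector saturation ceiling (abundance units).
#' @param tracer_purity Isotopic purity of the 13CO2 tracer (default 0.99).
#' @param od_ml Harvested biomass per sample (OD750 * mL).
#' @param dilution Fraction of the extracted sample reaching the injector
#'   (ng on-column = c_3pga * od_ml * molar mass * dilution).
#' @param is_abundance Internal-standard abundance level.
#' @param kinetics Optional list overriding preset kinetic truth fields
#'   (e1_plateau, a1, t_mid1, lag, a23, ana_plateau, c_3pga).
#' @param seed Mandatory integer seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(genotype = c("WT", "gapdh1", "gapdh2"),
                       condition = c("HC-HC", "LC-HC"),
                       times = c(0, 5, 10, 15, 30, 60),
                       n_replicates = 3L, noise_sd = 0.10,
                       channel_noise_sd = 0.02, floor = 0,
                       ceiling = Inf, tracer_purity = 0.99, od_ml = 10,
                       dilution = 1e-2, is_abundance = 5e4,
                       kinetics = list(), seed) {
  genotype <- match.arg(genotype)
  condition <- match.arg(condition)
  if (missing(seed)) stop("seed is mandatory")
  kin <- utils::modifyList(.GENOTYPE_PRESETS[[genotype]], kinetics)
  if (is.null(kin$ana_plateau))
    kin$ana_plateau <- if (genotype == "gapdh2") 0
                       else .CONDITION_PRESETS[[condition]]$ana_plateau
  if (is.null(kin$t_shift))
    kin$t_shift <- .CONDITION_PRESETS[[condition]]$t_shift
  stopifnot(kin$ana_plateau >= 0, kin$ana_plateau <= 1, kin$lag >= 0)
  structure(list(genotype = genotype, condition = condition, times = times,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, channel_noise_sd = channel_noise_sd,
                 floor = floor, ceiling = ceiling,
                 tracer_purity = tracer_purity, od_ml = od_ml,
                 dilution = dilution, is_abundance = is_abundance,
                 kinetics = kin, seed = as.integer(seed)),
            class = "sim_config")
}

# logistic anchored to exactly 0 at t = 0 (labeling starts at zero)
.anchored_logistic <- function(t, a, t_mid) {
  L <- function(x) 1 / (1 + exp(-a * (x - t_mid)))
  (L(t) - L(0)) / (1 - L(0))
}

#' True positional enrichment time course
#'
#' The 1-C position follows an anchored logistic (zero at pulse start); the
#' 2,3-C2 positions follow a lagged logistic scaled by the anaplerotic
#' plateau; the complete-molecule enrichment is \code{(e1 + 2 e23) / 3} by
#' construction, so the positional algebra holds exactly on the truth.
#'
#' @param cfg A \code{sim_config}.
#' @param times Optional time grid overriding \code{cfg$times}.
#' @return Data frame: time_min, e1, e23, e123, rel_e_pct.
#' @export
simulate_enrichment_course <- function(cfg, times = cfg$times) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$kinetics
  t1 <- k$t_mid1 + k$t_shift
  e1 <- k$e1_plateau * .anchored_logistic(times, k$a1, t1)
  e23 <- k$ana_plateau * k$e1_plateau *
    .anchored_logistic(times, k$a23, t1 + k$lag)
  e123 <- (e1 + 2 * e23) / 3
  rel <- ifelse(e1 > 0, e23 / e1 * 100, NA_real_)
  rel[times == 0] <- NA_real_
  data.frame(time_min = times, e1 = e1, e23 = e23, e123 = e123,
             rel_e_pct = rel)
}

# tracer-label count distribution over positions with marginal
# tracer-derived fractions p (Poisson-binomial)
.label_count_dist <- function(p) {
  d <- 1
  for (pi in p) d <- .conv(d, c(1 - pi, pi))
  d
}

# expected raw abundance vector for a fragment given positional
# tracer-derived fractions, via the forward correction matrix
.fragment_channels <- function(frag, positions_p, total, cfg_corr,
                               n_extra = 4L) {
  n <- frag$n_labelable_carbons
  x <- .label_count_dist(positions_p)
  M <- build_correction_matrix(frag, cfg_corr, n_obs = n + 1L + n_extra)
  as.numeric(M %*% x) * total
}

.noisy <- function(y, noise_sd, channel_noise_sd, floor, ceiling) {
  if (noise_sd > 0) y <- y * stats::rlnorm(1, 0, noise_sd)
  if (channel_noise_sd > 0)
    y <- y * stats::rlnorm(length(y), 0, channel_noise_sd)
  if (floor > 0) y <- y + floor * stats::rexp(length(y))
  pmin(y, ceiling)
}

#' Emit a raw isotopologue measurement table
#'
#' Full forward model: positional labeling truth -> fragment tracer-count
#' distributions (positions independent, the maximum-entropy choice exactly
#' consistent with the positional averaging identities) -> observed
#' channels via NIA/purity convolution -> abundance scaling through the
#' metabolite amount on-column -> multiplicative noise, additive floor and
#' saturation clipping.  Qualifier fragments (299/315) and the
#' internal-standard channel are emitted alongside.
#'
#' @param cfg A \code{sim_config}.
#' @param fraglib Fragment library (default shipped).
#' @param fragments Fragment ids to emit.
#' @return List with \code{measurements} (long CSV-shaped data frame),
#'   \code{metadata} (per sample) and \code{truth} (generating values).
#' @export
emit_isotopologue_table <- function(cfg, fraglib = fragment_library(),
                                    fragments = c("3PGA_459", "3PGA_357",
                                                  "3PGA_299", "3PGA_315")) {
  stopifnot(inherits(cfg, "sim_config"))
  course <- simulate_enrichment_course(cfg)
  cfg_corr <- correction_config(tracer_purity = cfg$tracer_purity)
  mm <- .MM_3PGA
  resp <- c("3PGA_459" = 500, "3PGA_357" = 1000, "3PGA_299" = 1200,
            "3PGA_315" = 800)  # a.u. per ng, per-fragment response
  .with_seed(cfg$seed, {
    meas <- list(); meta <- list(); truth <- list(); idx <- 0L
    for (r in seq_len(cfg$n_replicates)) {
      # replicate-level biology: concentration varies between cultures
      c_rep <- cfg$kinetics$c_3pga *
        (if (cfg$noise_sd > 0) stats::rlnorm(1, 0, cfg$noise_sd) else 1)
      for (i in seq_along(cfg$times)) {
        idx <- idx + 1L
        tmin <- cfg$times[i]
        sid <- sprintf("%s_%s_r%d_t%03d", cfg$genotype,
                       gsub("-", "", cfg$condition), r, tmin)
        ng <- c_rep * cfg$od_ml * mm * cfg$dilution
        pos <- c(course$e1[i], course$e23[i], course$e23[i])
        is_ab <- cfg$is_abundance *
          (if (cfg$noise_sd > 0) stats::rlnorm(1, 0, cfg$noise_sd / 2) else 1)
        for (fid in fragments) {
          frag <- fraglib[[fid]]
          if (is.null(frag)) stop("fragment not in library: ", fid)
          p <- if (frag$n_labelable_carbons)
                 pos[frag$retained_positions] else numeric(0)
          y <- .fragment_channels(frag, p, resp[[fid]] * ng, cfg_corr)
          y <- .noisy(y, cfg$noise_sd, cfg$channel_noise_sd, cfg$floor,
                      cfg$ceiling)
          meas[[length(meas) + 1L]] <- data.frame(
            sample_id = sid, fragment_id = fid,
            isotopologue_index = seq_along(y) - 1L, abundance = y,
            instrument_mode = frag$instrument_mode,
            stringsAsFactors = FALSE)
        }
        meta[[idx]] <- data.frame(
          sample_id = sid, time_min = tmin, genotype = cfg$genotype,
          condition = cfg$condition, replicate = r, od750_ml = cfg$od_ml,
          is_abundance = is_ab, stringsAsFactors = FALSE)
        truth[[idx]] <- data.frame(
          sample_id = sid, time_min = tmin, replicate = r,
          e1 = course$e1[i], e23 = course$e23[i], e123 = course$e123[i],
          c_3pga = c_rep, amount_ng = ng, stringsAsFactors = FALSE)
      }
    }
    list(measurements = do.call(rbind, meas),
         metadata = do.call(rbind, meta),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a quantification calibration series
#'
#' Linear detector response with optional saturation plateau and
#' multiplicative noise, in independent replicates; emitted with the
#' internal-standard channel so calibration can be normalized the same way
#' as samples.
#'
#' @param amounts Injected amounts (ng).
#' @param n_replicates Replicates per amount (default 3).
#' @param response Abundance per ng (true slope).
#' @param saturation_abundance Abundance ceiling (default \code{Inf}).
#' @param noise_sd Multiplicative noise sd.
#' @param is_abundance Internal-standard abundance level.
#' @param seed Integer seed.
#' @return Data frame: fragment_id, amount_ng, abundance, is_abundance,
#'   replicate.
#' @export
simulate_calibration_series <- function(amounts = c(1, 2, 5, 10, 25, 50,
                                                    75, 100, 150),
                                        n_replicates = 3L, response = 1000,
                                        saturation_abundance = Inf,
                                        noise_sd = 0.05,
                                        is_abundance = 5e4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  .with_seed(seed, {
    g <- expand.grid(amount_ng = amounts,
                     replicate = seq_len(n_replicates))
    y <- pmin(response * g$amount_ng, saturation_abundance)
    if (noise_sd > 0) y <- y * stats::rlnorm(length(y), 0, noise_sd)
    data.frame(fragment_id = "3PGA_357", amount_ng = g$amount_ng,
               abundance = y, is_abundance = is_abundance,
               replicate = g$replicate, stringsAsFactors = FALSE)
  })
}

#' Simulate steady-state glucose-isotopomer feeding
#'
#' Emits G6P and 3PGA fragment isotopologue tables for a positional
#' glucose tracer metabolized through an EMP/OPP mixture, the in vivo
#' validation design: the G6P reference fragment reports tracer uptake and
#' dilution, the paired 3PGA fragments report the pathway-predicted
#' positional labeling.
#'
#' @param tracer_positions Labeled glucose positions (subset of 1:6).
#' @param f_opp OPP flux fraction (default 0.11).
#' @param uptake Fraction of the intracellular hexose pool derived from the
#'   fed tracer at sampling (label dilution).
#' @param purity Tracer isotopic purity.
#' @param n_replicates Replicates (default 2).
#' @param noise_sd Multiplicative noise sd.
#' @param seed Integer seed.
#' @param fraglib Fragment library.
#' @return List with \code{measurements}, \code{metadata} and \code{truth}
#'   (the generating positional enrichments).
#' @export
simulate_ecoli_feeding <- function(tracer_positions, f_opp = 0.11,
                                   uptake = 0.95, purity = 0.99,
                                   n_replicates = 2L, noise_sd = 0.02,
                                   seed, fraglib = fragment_library()) {
  if (missing(seed)) stop("seed is mandatory")
  e <- predict_positional_enrichment(tracer_positions, f_emp = 1 - f_opp,
                                     f_opp = f_opp)
  pos3 <- attr(e, "positions")
  g6p_pos <- uptake * as.numeric(1:6 %in% tracer_positions)
  pga_pos <- uptake * pos3
  cfg_corr <- correction_config(tracer_purity = purity)
  totals <- c(G6P_706 = 4e5, `3PGA_459` = 3e5, `3PGA_357` = 5e5)
  pos_by_frag <- list(G6P_706 = g6p_pos, `3PGA_459` = pga_pos,
                      `3PGA_357` = pga_pos[2:3])
  .with_seed(seed, {
    meas <- list(); meta <- list()
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("ecoli_%s_r%d",
                     paste0("c", paste(sort(tracer_positions),
                                       collapse = "")), r)
      for (fid in names(pos_by_frag)) {
        frag <- fraglib[[fid]]
        y <- .fragment_channels(frag, pos_by_frag[[fid]], totals[[fid]],
                                cfg_corr)
        if (noise_sd > 0) y <- y * stats::rlnorm(length(y), 0, noise_sd)
        meas[[length(meas) + 1L]] <- data.frame(
          sample_id = sid, fragment_id = fid,
          isotopologue_index = seq_along(y) - 1L, abundance = y,
          instrument_mode = frag$instrument_mode, stringsAsFactors = FALSE)
      }
      meta[[r]] <- data.frame(sample_id = sid, replicate = r,
                              tracer = paste(sort(tracer_positions),
                                             collapse = ","),
                              f_opp = f_opp, uptake = uptake,
                              stringsAsFactors = FALSE)
    }
    list(measurements = do.call(rbind, meas),
         metadata = do.call(rbind, meta),
         truth = data.frame(e1 = pga_pos[1], e23 = mean(pga_pos[2:3]),
                            e123 = mean(pga_pos), g6p_e = uptake))
  })
}

#' Apply an instrument-bias model to an isotopologue vector
#'
#' Nominal-mass-resolution EI spectra carry a small constant spectral-noise
#' floor in every channel, which mechanically inflates apparent enrichment
#' of low-labeled samples and deflates that of highly labeled samples; the
#' high-resolution APCI model is near-unbiased.
#'
#' @param abundances Raw abundance vector.
#' @param mode "EI" or "APCI".
#' @param floor_frac EI floor as a fraction of the total abundance.
#' @return Biased abundance vector.
#' @export
apply_instrument_bias <- function(abundances, mode = c("EI", "APCI"),
                                  floor_frac = 0.01) {
  mode <- match.arg(mode)
  if (mode == "APCI") return(abundances)
  abundances + floor_frac * sum(abundances) / length(abundances)
}
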