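# Synthetic-data generator: kinetics truth, forward emission, feeding
# designs and the instrument-bias model.

lib <- fragment_library()

test_that("generators are deterministic given the seed", {
  a <- emit_isotopologue_table(sim_config("WT", "HC-HC", seed = 9))
  b <- emit_isotopologue_table(sim_config("WT", "HC-HC", seed = 9))
  expect_identical(a, b)
  d <- emit_isotopologue_table(sim_config("WT", "HC-HC", seed = 10))
  expect_false(identical(a$measurements$abundance,
                         d$measurements$abundance))
  c1 <- simulate_calibration_series(seed = 3)
  c2 <- simulate_calibration_series(seed = 3)
  expect_identical(c1, c2)
  expect_error(sim_config("WT"), "seed")
})

test_that("enrichment courses start at zero and saturate at the plateau", {
  cfg <- sim_config("WT", "HC-HC", seed = 1,
                    kinetics = list(e1_plateau = 1, ana_plateau = 1))
  co <- simulate_enrichment_course(cfg, times = c(0, 500))
  expect_equal(unlist(co[1, c("e1", "e23", "e123")]),
               c(e1 = 0, e23 = 0, e123 = 0))
  expect_equal(unlist(co[2, c("e1", "e23", "e123")]),
               c(e1 = 1, e23 = 1, e123 = 1), tolerance = 1e-6)
  expect_equal(co$rel_e_pct[2], 100, tolerance = 1e-4)
})

test_that("relative enrichment rises monotonically, stays under 100%, and is higher after LC preacclimation", {
  tt <- seq(1, 90, 0.5)
  hc <- simulate_enrichment_course(sim_config("WT", "HC-HC", seed = 1),
                                   times = tt)
  lc <- simulate_enrichment_course(sim_config("WT", "LC-HC", seed = 1),
                                   times = tt)
  expect_true(all(diff(hc$rel_e_pct) > -1e-9))
  expect_true(all(hc$rel_e_pct <= 100 + 1e-9))
  expect_true(all(lc$rel_e_pct >= hc$rel_e_pct - 1e-9))
})

test_that("truth sidecars obey the positional averaging identity exactly", {
  b <- emit_isotopologue_table(sim_config("gapdh1", "LC-HC", seed = 12))
  expect_equal(b$truth$e123, (b$truth$e1 + 2 * b$truth$e23) / 3,
               tolerance = 1e-15)
})

test_that("the noise-free bundle round-trips through the full pipeline", {
  cfg <- sim_config("WT", "HC-HC", seed = 21, noise_sd = 0,
                    channel_noise_sd = 0)
  b <- emit_isotopologue_table(cfg)
  cal <- simulate_calibration_series(noise_sd = 0, seed = 22)
  res <- run_pipeline(b$measurements, b$metadata, cal,
                      config = pipeline_config(n_starts = 100L))
  m <- merge(res$positional, b$truth, by = "sample_id",
             suffixes = c("", "_true"))
  expect_equal(m$e1, m$e1_true, tolerance = 1e-6)
  expect_equal(m$e23, m$e23_true, tolerance = 1e-6)
  expect_equal(m$c_3pga, m$c_3pga_true, tolerance = 1e-6)
})

test_that("a saturation ceiling triggers the validity flag", {
  cfg <- sim_config("WT", "HC-HC", seed = 23, ceiling = 1e4)
  b <- emit_isotopologue_table(cfg)
  y <- b$measurements$abundance[b$measurements$fragment_id == "3PGA_357" &
                                  b$measurements$sample_id ==
                                  b$measurements$sample_id[1]]
  expect_true(any(y == 1e4))
  # the raw total now sits above a validity limit set below the ceiling sum
  expect_equal(validity_range_check(sum(y), c(10, 1e4)), "saturated")
})

test_that("the CBB-deficient preset labels only 1-C and reports n.d.", {
  b <- emit_isotopologue_table(sim_config("gapdh2", "HC-HC", seed = 25))
  cal <- simulate_calibration_series(seed = 26)
  res <- run_pipeline(b$measurements, b$metadata, cal,
                      config = pipeline_config(n_starts = 200L))
  late <- res$positional[res$positional$time_min >= 30, ]
  expect_true(all(late$e23 < 0.05))
  expect_true(all(late$e1 > 0.2))
  f23 <- res$fits[res$fits$series == "c13c_23", ]
  expect_true(all(f23$detected == "n.d."))
  expect_true(all(res$fits$detected[res$fits$series == "c13c_1"] ==
                    "detected"))
})

test_that("glucose-feeding simulations recover the pathway predictions", {
  cfg_corr <- correction_config()
  run_one <- function(tracer, f_opp) {
    sim <- simulate_ecoli_feeding(tracer, f_opp = f_opp, seed = 30,
                                  noise_sd = 0)
    ms <- sim$measurements
    one <- function(fid) {
      y <- ms$abundance[ms$fragment_id == fid &
                          ms$sample_id == ms$sample_id[1]]
      correct_isotopologues(y, lib[[fid]], cfg_corr)$e13c
    }
    list(g6p = one("G6P_706"), e123 = one("3PGA_459"),
         e23 = one("3PGA_357"))
  }
  # uniformly labeled control: reference-adjusted labeling reads 100%
  full <- run_one(1:6, f_opp = 0.11)
  expect_equal(adjust_to_reference(full$e123, full$g6p, 100), 100,
               tolerance = 0.5)
  # 3,4-labeled glucose through pure EMP leaves 2,3-C2 clean
  emp <- run_one(c(3, 4), f_opp = 0)
  expect_lt(emp$e23, 1e-6)
  # an active OPP shunt diverts label away from 1-C
  mix <- run_one(c(3, 4), f_opp = 0.12)
  e1_emp <- 3 * emp$e123 - 2 * emp$e23
  e1_mix <- 3 * mix$e123 - 2 * mix$e23
  expect_lt(e1_mix, e1_emp)
  expect_gt(mix$e23, emp$e23)
})

test_that("the EI bias model inflates low and deflates high enrichment", {
  cfg <- correction_config()
  frag <- lib$`3PGA_357`
  M <- build_correction_matrix(frag, cfg, n_obs = 8L)
  unl <- as.numeric(M %*% c(1, 0, 0)) * 1e5
  lab <- as.numeric(M %*% c(0, 0, 1)) * 1e5
  e_unl_ei <- correct_isotopologues(apply_instrument_bias(unl, "EI"),
                                    frag, cfg)$e13c
  e_lab_ei <- correct_isotopologues(apply_instrument_bias(lab, "EI"),
                                    frag, cfg)$e13c
  expect_gt(e_unl_ei, 0)
  expect_lt(e_lab_ei, 1)
  e_unl_apci <- correct_isotopologues(apply_instrument_bias(unl, "APCI"),
                                      frag, cfg)$e13c
  e_lab_apci <- correct_isotopologues(apply_instrument_bias(lab, "APCI"),
                                      frag, cfg)$e13c
  expect_lt(abs(e_unl_apci - 0), 0.002)
  expect_lt(abs(e_lab_apci - 1), 0.002)
  # regressing EI readings on the truth shows the systematic pattern:
  # slope below one with a positive offset
  e_true <- seq(0, 1, length.out = 12)
  e_ei <- sapply(e_true, function(e) {
    x <- dbinom(0:2, 2, e)
    y <- as.numeric(M %*% x) * 1e5
    correct_isotopologues(apply_instrument_bias(y, "EI"), frag, cfg)$e13c
  })
  r <- correlate_instruments(e_true, e_ei)
  expect_lt(r$slope, 1)
  expect_gt(r$intercept, 0)
})
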