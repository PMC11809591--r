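# NIA / tracer-purity correction: matrix construction, inversion,
# enrichment and validity flags.

lib <- fragment_library()

test_that("correction matrix reduces to identity for an ideal carbon skeleton", {
  toy <- fragment_spec("toy_C4", "C4", retained_positions = 1:4,
                       n_derivatization_carbons = 0L)
  cfg <- correction_config(tracer_purity = 1, p13_natural = 0)
  M <- build_correction_matrix(toy, cfg, n_obs = 5L)
  expect_equal(unname(M), diag(5)[, 1:5], tolerance = 1e-14)
})

test_that("column 0 is the natural-abundance pattern of the fragment", {
  cfg <- correction_config()
  M <- build_correction_matrix(lib$`3PGA_357`, cfg, n_obs = 9L)
  nat <- theoretical_isotopologue_pattern(lib$`3PGA_357`,
                                          p13_labelable = cfg$p13_natural,
                                          purity = 1, length.out = 9L)
  expect_equal(unname(M[, 1]), nat, tolerance = 1e-12)
})

test_that("matrix columns match the polynomial-expansion oracle for all shipped fragments", {
  cfg <- correction_config()
  for (frag in lib) {
    n <- frag$n_labelable_carbons
    n_obs <- n + 5L
    M <- build_correction_matrix(frag, cfg, n_obs = n_obs)
    for (j in 0:n) {
      oc <- oracle_matrix_column(frag, j, cfg$tracer_purity,
                                 cfg$p13_natural, n_obs)
      expect_equal(unname(M[, j + 1L]), oc, tolerance = 1e-10,
                   label = paste(frag$id, "column", j))
    }
    sums <- colSums(M)
    expect_true(all(sums <= 1 + 1e-12))
    expect_true(all(sums >= 0.9))  # truncated tail mass is small
  }
})

test_that("matrix columns match exhaustive enumeration on small formulas", {
  toy <- fragment_spec("toy", "C3H2O", retained_positions = 1:2,
                       n_derivatization_carbons = 1L)
  cfg <- correction_config(tracer_purity = 0.97)
  M <- build_correction_matrix(toy, cfg, n_obs = 6L)
  # enumerate: labeled positions as two-isotope "elements" is equivalent to
  # binomials; check against the fully enumerated residual instead
  for (j in 0:2) {
    lab <- if (j > 0) dbinom(0:j, j, 0.97) else 1
    unl <- if (2 - j > 0) dbinom(0:(2 - j), 2 - j, cfg$p13_natural) else 1
    resid <- oracle_pattern_enum("CH2O",
                                 isotope_table(c13 = cfg$p13_natural))
    ref <- oracle_poly_mult(oracle_poly_mult(lab, unl), resid)
    ref <- c(ref, numeric(6))[1:6]
    expect_equal(unname(M[, j + 1L]), ref, tolerance = 1e-12)
  }
})

test_that("natural-abundance samples correct to zero enrichment", {
  cfg <- correction_config()
  nat <- theoretical_isotopologue_pattern(lib$`3PGA_357`, 0.01109,
                                          purity = 1, length.out = 8L)
  res <- correct_isotopologues(nat * 1e5, lib$`3PGA_357`, cfg)
  expect_equal(res$e13c, 0, tolerance = 1e-6)
  expect_equal(sum(res$ria), 1, tolerance = 1e-9)
  expect_equal(res$total, 1e5, tolerance = 1)
})

test_that("a saturated pool at 99% tracer purity corrects to full enrichment", {
  cfg <- correction_config(tracer_purity = 0.99)
  full <- theoretical_isotopologue_pattern(lib$`3PGA_459`, 1,
                                           purity = 0.99, length.out = 9L)
  res <- correct_isotopologues(full * 2e5, lib$`3PGA_459`, cfg)
  expect_equal(res$e13c, 1, tolerance = 1e-6)
})

test_that("correction inverts the forward model exactly without noise", {
  cfg <- correction_config()
  set.seed(11)
  for (fid in c("3PGA_357", "3PGA_459", "G6P_706")) {
    frag <- lib[[fid]]
    n <- frag$n_labelable_carbons
    for (rep in 1:5) {
      x <- runif(n + 1)
      x <- x / sum(x)
      M <- build_correction_matrix(frag, cfg, n_obs = n + 5L)
      y <- as.numeric(M %*% x)
      res <- correct_isotopologues(y, frag, cfg)
      expect_equal(res$ria, x, tolerance = 1e-8, label = fid)
    }
  }
})

test_that("clip mode agrees with the constrained solve on clean data", {
  cfg_clip <- correction_config(nonnegativity = "clip")
  x <- c(0.2, 0.3, 0.5)
  M <- build_correction_matrix(lib$`3PGA_357`, cfg_clip, n_obs = 8L)
  y <- as.numeric(M %*% x)
  expect_equal(correct_isotopologues(y, lib$`3PGA_357`, cfg_clip)$ria, x,
               tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with informative errors", {
  cfg <- correction_config()
  expect_error(correct_isotopologues(numeric(8), lib$`3PGA_357`, cfg),
               "no signal")
  expect_error(correct_isotopologues(c(-1, 1, 1), lib$`3PGA_357`, cfg),
               "negative")
  expect_error(correct_isotopologues(c(1, 1), lib$`3PGA_357`, cfg),
               "shorter")
})

test_that("enrichment is the per-carbon average label fraction", {
  expect_equal(enrichment(c(0, 0, 1), 2), 1)
  expect_equal(enrichment(c(0.5, 0, 0.5), 2), 0.5)
  expect_equal(enrichment(c(1, 1, 1, 1), 3), 0.5)  # (0+1+2+3)/(4*3)
  expect_error(enrichment(c(0, 0, 0), 2), "zero-sum")
  # bounded and monotone: moving mass upward never decreases enrichment
  set.seed(3)
  for (i in 1:20) {
    x <- runif(4)
    e0 <- enrichment(x, 3)
    expect_gte(e0, 0); expect_lte(e0, 1)
    x2 <- x
    x2[4] <- x2[4] + 0.5
    expect_gte(enrichment(x2, 3), e0)
  }
})

test_that("validity range flags below-range and saturated samples", {
  lim <- c(100, 1e5)
  expect_equal(validity_range_check(5e3, lim), "ok")
  expect_equal(validity_range_check(2e5, lim), "saturated")
  expect_equal(validity_range_check(0, lim), "below_range")
  expect_equal(validity_range_check(c(0, 5e3, 2e5), lim),
               c("below_range", "ok", "saturated"))
})

test_that("enrichment bias is small at mid-range abundance and grows at low signal", {
  cfg <- correction_config()
  frag <- lib$`3PGA_357`
  nat <- theoretical_isotopologue_pattern(frag, 0.01109, purity = 1,
                                          length.out = 8L)
  set.seed(5)
  bias_at <- function(total, n = 400) {
    e <- numeric(n)
    for (i in seq_len(n)) {
      y <- nat * total * rlnorm(8, 0, 0.01) + 20 * rexp(8)
      e[i] <- correct_isotopologues(y, frag, cfg)$e13c
    }
    mean(e)
  }
  mid <- bias_at(5e4)
  low <- bias_at(2e2)
  expect_lt(abs(mid), 0.002)
  expect_gt(low, 10 * abs(mid))  # noise floor inflates enrichment
})

test_that("carbon-only mode ignores Si isotopes and overestimates on TMS fragments", {
  cfg_c <- correction_config(resolution_mode = "carbon_only")
  nat <- theoretical_isotopologue_pattern(lib$`3PGA_357`, 0.01109,
                                          purity = 1, length.out = 8L)
  e_c <- correct_isotopologues(nat * 1e5, lib$`3PGA_357`, cfg_c)$e13c
  expect_gt(e_c, 0)  # Si M+1/M+2 misread as label
  # fragments with negligible non-C heavy-isotope mass: modes agree closely
  toy <- fragment_spec("toy_C8H2", "C8H2", retained_positions = 1:4,
                       n_derivatization_carbons = 4L)
  pat <- theoretical_isotopologue_pattern(toy, 0.3, purity = 0.99,
                                          length.out = 8L)
  ef <- correct_isotopologues(pat * 1e5, toy, correction_config())$e13c
  ec <- correct_isotopologues(pat * 1e5, toy, cfg_c)$e13c
  expect_lt(abs(ef - ec), 0.001)
})
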