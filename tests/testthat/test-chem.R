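# Formula algebra, monoisotopic masses, neutral-loss arithmetic and the
# forward isotopologue model.

test_that("Hill-notation formulas parse with counts and trailing charge", {
  f <- parse_formula("C15H39O7PSi4")
  expect_equal(element_count(f, "C"), 15L)
  expect_equal(element_count(f, "H"), 39L)
  expect_equal(element_count(f, "O"), 7L)
  expect_equal(element_count(f, "P"), 1L)
  expect_equal(element_count(f, "Si"), 4L)
  expect_equal(attr(f, "charge"), 0L)

  g <- parse_formula("C24H61NO9PSi6+")
  expect_equal(element_count(g, "N"), 1L)
  expect_equal(attr(g, "charge"), 1L)

  h <- parse_formula("C")
  expect_equal(element_count(h, "C"), 1L)

  expect_error(parse_formula("C3Xx2"), "unrecognized element")
  expect_error(parse_formula("C3h4"), "malformed|unrecognized")
  expect_error(parse_formula(""), "empty")
})

test_that("monoisotopic masses reproduce the derivative ion values", {
  m459 <- monoisotopic_mass(parse_formula("C15H39O7PSi4"))
  # printed reference 474.1511; embedded-table accuracy tolerance 0.003 amu
  expect_lt(abs(m459 - 474.1511), 0.003)
  expect_equal(round(m459, 4), 474.1510)
  # singly charged G6P fragment: electron mass must be accounted for
  expect_equal(round(monoisotopic_mass(parse_formula("C24H61NO9PSi6+")), 4),
               706.2694)
  expect_equal(monoisotopic_mass(parse_formula("C")), 12)
  expect_error(monoisotopic_mass(parse_formula("C"), isotopes = list()),
               "missing from isotope table")
})

test_that("13C exchange mass shifts follow the isotope table", {
  expect_equal(round(isotope_mass_shift(1), 4), 1.0034)
  expect_equal(isotope_mass_shift(0), 0)
  expect_equal(round(isotope_mass_shift(3), 4), 3.0101)
  tab <- isotope_table()
  expect_equal(isotope_mass_shift(3),
               3 * (tab$C$masses[2] - tab$C$masses[1]))
})

test_that("neutral-loss arithmetic yields the paired 3PGA fragments", {
  parent <- parse_formula("C15H39O7PSi4")
  losses <- neutral_loss_library()
  f459 <- apply_loss(parent, losses$CH3)
  expect_equal(format(f459), "C14H36O7PSi4+")
  expect_equal(nominal_mass(f459), 459L)
  # APCI route: protonation then CH4 elimination gives the same cation
  expect_equal(format(apply_loss(parent, losses$CH4, protonate = TRUE)),
               format(f459))
  f357 <- apply_loss(parent, losses$TMSCOOH, protonate = TRUE)
  expect_equal(nominal_mass(f357), 357L)
  # EI route: TMSCOO radical from the molecular radical cation
  expect_equal(format(apply_loss(parent, losses$TMSCOO)), format(f357))
  # loss larger than parent is rejected
  expect_error(apply_loss(parse_formula("CH4"), losses$TMSCOOH),
               "not applicable")
})

test_that("fragment-parent mass differences equal the loss masses", {
  parent <- parse_formula("C15H39O7PSi4")
  mp <- monoisotopic_mass(parent)
  mh <- monoisotopic_mass(parse_formula("H"))
  for (loss in neutral_loss_library()) {
    for (protonate in c(FALSE, TRUE)) {
      frag <- tryCatch(apply_loss(parent, loss, protonate = protonate),
                       error = function(e) NULL)
      if (is.null(frag)) next
      mf <- monoisotopic_mass(mol_formula(unclass(frag), charge = 0L))
      expected <- mp + (if (protonate) mh else 0) -
        monoisotopic_mass(loss$formula)
      expect_equal(mf, expected, tolerance = 1e-10)
    }
  }
})

test_that("derived fragments lose the removed parent carbons", {
  parent <- fragment_spec("3PGA_4TMS", "C15H39O7PSi4",
                          retained_positions = 1:3,
                          n_derivatization_carbons = 12L)
  d <- derive_fragment("frag357", parent, neutral_loss_library()$TMSCOOH,
                       protonate = TRUE, instrument_mode = "APCI")
  expect_equal(d$retained_positions, c(2L, 3L))
  expect_equal(d$n_labelable_carbons, 2L)
  expect_equal(d$n_derivatization_carbons, 9L)
  d459 <- derive_fragment("frag459", parent, neutral_loss_library()$CH3)
  expect_equal(d459$retained_positions, 1:3)
})

test_that("the shipped fragment library is internally consistent", {
  lib <- fragment_library()
  expect_true(all(c("3PGA_459", "3PGA_357", "3PGA_299", "3PGA_315",
                    "G6P_706") %in% names(lib)))
  for (frag in lib) {
    expect_s3_class(frag, "fragment_spec")
    expect_equal(frag$n_labelable_carbons + frag$n_derivatization_carbons,
                 element_count(frag$formula, "C"))
    # fragment ids carry the nominal mass
    nom <- as.integer(sub(".*_", "", frag$id))
    expect_equal(nominal_mass(frag$formula), nom)
  }
  expect_lt(abs(monoisotopic_mass(lib$G6P_706$formula) - 706.2694), 0.003)
})

test_that("theoretical isotopologue patterns sum to one and match special cases", {
  lib <- fragment_library()
  frag <- lib$`3PGA_357`
  for (p in c(0, 0.3, 1)) {
    pat <- theoretical_isotopologue_pattern(frag, p, purity = 0.99)
    expect_equal(sum(pat), 1, tolerance = 1e-12)
    expect_true(all(pat >= 0))
  }
  # indistinguishable pools: source at natural 13C with pure tracer gives
  # exactly the natural-abundance pattern of the whole formula
  nat <- theoretical_isotopologue_pattern(frag, 0.01109, purity = 1)
  ref <- natural_isotope_pattern(frag$formula)
  expect_equal(nat, ref, tolerance = 1e-14)
  # no labelable carbons: pattern independent of the labeling probability
  q <- lib$`3PGA_299`
  expect_equal(theoretical_isotopologue_pattern(q, 0),
               theoretical_isotopologue_pattern(q, 1), tolerance = 1e-14)
  # pure-carbon toy fragment: closed-form binomial at purity 0.99
  toy <- fragment_spec("toy_C3", "C3", retained_positions = 1:3,
                       n_derivatization_carbons = 0L)
  expect_equal(theoretical_isotopologue_pattern(toy, 1, purity = 0.99),
               dbinom(0:3, 3, 0.99), tolerance = 1e-14)
})

test_that("patterns agree with exhaustive isotope-assignment enumeration", {
  for (txt in c("C2H3", "CHO2", "OSi2", "C3HS", "N2O2")) {
    expect_equal(natural_isotope_pattern(txt),
                 oracle_pattern_enum(txt), tolerance = 1e-12,
                 label = txt)
  }
})
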