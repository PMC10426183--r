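test_that("formula parsing handles implicit counts, case sensitivity and errors", {
  f <- parseFormula("C24H18Cl2N10O2")
  expect_identical(formulaCounts(f),
                   c(C = 24L, H = 18L, Cl = 2L, N = 10L, O = 2L))
  expect_identical(formulaCounts(parseFormula("C")), c(C = 1L))
  # repeated symbols accumulate
  expect_identical(formulaCounts(parseFormula("CHC"))[["C"]], 2L)
  expect_error(parseFormula("Xx9"), "unknown element")
  expect_error(parseFormula("C0H4"), "zero or negative")
  expect_error(parseFormula(""), "nonempty")
  expect_error(parseFormula("c24"), "malformed")
})

test_that("formatting is Hill-ordered and round-trips through the parser", {
  expect_identical(formatFormula(parseFormula("O2N10Cl2H18C24")),
                   "C24H18Cl2N10O2")
  expect_identical(formatFormula(parseFormula("ClNa")), "ClNa")  # no carbon: alphabetical
  set.seed(11)
  for (i in 1:25) {
    s <- random_formula_string()
    f <- parseFormula(s)
    expect_identical(formulaCounts(parseFormula(formatFormula(f))),
                     formulaCounts(f))
  }
})

test_that("monoisotopic masses reproduce exact-mass (HRMS calcd) arithmetic", {
  expect_equal(round(monoisotopicMass(parseFormula("C30H32N10O2")), 4), 564.2710)
  expect_equal(round(monoisotopicMass(parseFormula("C24H16N14O10")), 4), 660.1174)
  expect_identical(monoisotopicMass(parseFormula("C")), 12)
  tab <- defaultMassTables()
  expect_error(monoisotopicMass(parseFormula("NaI"),
                                new("MassTables",
                                    averageWeight = tab@averageWeight,
                                    principalIsotopeMass = c(Na = 22.98977),
                                    version = "partial")),
               "no principal-isotope mass entry")
})

test_that("adduct masses follow the proton-transfer convention", {
  f <- parseFormula("C30H32N10O2")
  expect_equal(adductMass(f, "M"), monoisotopicMass(f))
  h2o <- parseFormula("H2O")
  expect_equal(adductMass(h2o, "M+H") - adductMass(h2o, "M"),
               1.00728, tolerance = 1e-5)
  expect_equal(adductMass(parseFormula("C24H16N14O10"), "M+H"),
               661.1247, tolerance = 2e-4)
  # M-H mirrors M+H around the neutral mass
  expect_equal(adductMass(h2o, "M") - adductMass(h2o, "M-H"),
               adductMass(h2o, "M+H") - adductMass(h2o, "M"))
  # without electron correction the shift is exactly one 1H
  expect_equal(adductMass(h2o, "M+H", electronCorrection = FALSE) -
                 adductMass(h2o, "M"), 1.00782503207)
  expect_error(adductMass(f, "M+Na"))
})

test_that("average molar masses match hand sums with conventional weights", {
  expect_equal(averageMolarMass(parseFormula("C24H16N14O10")), 660.48,
               tolerance = 0.02 / 660)
  expect_equal(averageMolarMass(parseFormula("H2")), 2.016)
  expect_equal(averageMolarMass(parseFormula("C24H18Cl2N10O2")), 549.38,
               tolerance = 0.02 / 549)
})

test_that("elemental percentages reproduce Anal. Calcd. digits and close to 100", {
  p6a <- elementalPercentages(parseFormula("C24H18Cl2N10O2"))
  expect_equal(roundHalfEven(p6a[["N"]], 2), 25.50)
  p6d <- elementalPercentages(parseFormula("C24H16N14O10"))
  expect_equal(roundHalfEven(p6d[["C"]], 2), 43.64)
  set.seed(7)
  for (i in 1:20) {
    p <- elementalPercentages(parseFormula(random_formula_string()))
    expect_lt(abs(sum(p) - 100), 1e-9)
  }
})

test_that("nitrogen percent projects the percentage table", {
  expect_equal(nitrogenPercent(parseFormula("C24H16N14O10")), 29.69,
               tolerance = 0.02 / 29.69)
  expect_identical(nitrogenPercent(parseFormula("CH4")), 0)
  expect_equal(nitrogenPercent(parseFormula("N2")), 100)
})

test_that("oxygen balance conventions and algebra behave", {
  expect_equal(as.numeric(oxygenBalance(parseFormula("CO2"))), 0)
  ob6d <- oxygenBalance(parseFormula("C24H16N14O10"))
  expect_equal(as.numeric(ob6d), -111.4, tolerance = 0.1 / 111.4)
  expect_identical(attr(ob6d, "convention"), "CHNO-classic")
  # linearity: doubling all counts leaves OB unchanged
  expect_equal(as.numeric(oxygenBalance(parseFormula("C48H32N28O20"))),
               as.numeric(ob6d))
  # halogen-HX lowers the hydrogen demand by nX/2 atoms of H
  f <- parseFormula("C24H18Cl2N10O2")
  obClassic <- as.numeric(oxygenBalance(f))
  obHX <- as.numeric(oxygenBalance(f, convention = "halogen-HX"))
  expect_equal(obHX - obClassic, 1600 * (2 / 2) / averageMolarMass(f))
  expect_error(oxygenBalance(parseFormula("CS2")), "C/H/N/O/halogen")
  ed <- energeticDescriptors(parseFormula("C24H16N14O10"))
  expect_s4_class(ed, "EnergeticDescriptors")
  expect_equal(ed@nitrogenPercent, nitrogenPercent(parseFormula("C24H16N14O10")))
})

test_that("monoisotopic mass stays below the average molar mass over CHNOCl", {
  set.seed(3)
  for (i in 1:20) {
    f <- parseFormula(random_formula_string())
    expect_lt(monoisotopicMass(f), averageMolarMass(f))
  }
})

test_that("masses agree with an independent per-atom summation oracle", {
  set.seed(19)
  for (i in 1:20) {
    s <- random_formula_string()
    f <- parseFormula(s)
    expect_equal(monoisotopicMass(f), oracle_mass(s, "iso"), tolerance = 1e-6)
    expect_equal(averageMolarMass(f), oracle_mass(s, "avg"), tolerance = 1e-6)
  }
})
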