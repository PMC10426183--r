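test_that("condensed indices are the direct finite charge differences", {
  cs <- chargeSet(1:2, c(6L, 7L), qCation = c(0.7, 0.3),
                  qNeutral = c(0, 0), qAnion = c(-0.2, -0.8))
  ft <- as.data.frame(condensedFukui(cs))
  expect_equal(ft$f_minus, c(0.7, 0.3))
  expect_equal(ft$f_plus, c(0.2, 0.8))
  expect_equal(ft$f_zero, c(0.45, 0.55))
  expect_equal(ft$dual, c(-0.5, 0.5))
})

test_that("the radical index is the arithmetic mean at report rounding", {
  expect_equal(roundHalfEven(fukuiZero(0.9837, 0), 4), 0.4918)
  expect_equal(roundHalfEven(fukuiZero(0, 0.4526), 4), 0.2263)
  expect_identical(fukuiZero(0, 0), 0)
  expect_error(fukuiZero(NaN, 0))
})

test_that("fixture charge triples regenerate the published anchor rows", {
  fx <- builtinSeries()
  anchors <- expectedValues(fx)$fukui
  for (id in unique(anchors$id)) {
    ft <- as.data.frame(condensedFukui(charges(records(fx)[[id]])))
    a <- anchors[anchors$id == id, ]
    rows <- ft[match(a$atom, ft$atom), ]
    expect_equal(rows$f_minus, a$f_minus, tolerance = 1e-12)
    expect_equal(rows$f_plus, a$f_plus, tolerance = 1e-12)
    # agree with each printed f0 to the half-ulp of its printed digits
    # (one table entry is truncated rather than rounded in the source)
    expect_true(all(abs(rows$f_zero - a$f_zero) <=
                      0.51 * 10^-a$f_zero_digits))
    # the two prose-confirmed key sites round exactly
    expect_equal(roundHalfEven(rows$f_zero[a$atom %in% c(10L)], 4),
                 a$f_zero[a$atom %in% c(10L)])
  }
})

test_that("columns obey the unit sum rules on synthetic triples", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    fm <- runif(n); fm <- fm / sum(fm)
    fp <- runif(n); fp <- fp / sum(fp)
    ft <- condensedFukui(chargeTripleFromFukui(fm, fp))
    expect_equal(sum(ft@fMinus), 1, tolerance = 1e-12)
    expect_equal(sum(ft@fPlus), 1, tolerance = 1e-12)
    expect_equal(ft@fZero, (ft@fMinus + ft@fPlus) / 2)  # exact identity
  }
})

test_that("condensed indices match a brute-force per-atom subtraction", {
  set.seed(9)
  for (i in 1:10) {
    qc <- runif(5); qn <- rnorm(5); qa <- rnorm(5)
    qc <- qc + (1 - sum(qc) + sum(qn)) / 5     # force unit closure
    qa <- qa + (sum(qn) - 1 - sum(qa)) / 5
    ft <- condensedFukui(chargeSet(1:5, rep(6L, 5), qc, qn, qa))
    for (k in 1:5) {
      expect_equal(ft@fMinus[k], qc[k] - qn[k], tolerance = 1e-12)
      expect_equal(ft@fPlus[k], qn[k] - qa[k], tolerance = 1e-12)
    }
  }
})

test_that("site ranking follows the labeled attack mode with index tie-breaks", {
  fx <- builtinSeries()
  ft6d <- condensedFukui(charges(records(fx)[["6d"]]))
  ft6f <- condensedFukui(charges(records(fx)[["6f"]]))
  # paper labeling: f- answers susceptibility to nucleophilic attack
  expect_identical(rankSites(ft6d, "nucleophilic_attack")[1], 10L)
  expect_identical(rankSites(ft6f, "nucleophilic_attack")[1], 31L)
  expect_identical(rankSites(ft6f, "electrophilic_attack")[1], 10L)
  # standard labeling swaps the two charge-transfer modes
  expect_identical(rankSites(ft6f, "nucleophilic_attack", "standard")[1], 10L)
  expect_identical(rankSites(ft6f, "electrophilic_attack", "standard")[1], 31L)
  # radical mode is labeling-independent
  expect_identical(rankSites(ft6d, "radical"),
                   rankSites(ft6d, "radical", "standard"))
  # single-atom table tops every mode
  one <- condensedFukui(chargeTripleFromFukui(1, 1))
  for (m in c("nucleophilic_attack", "electrophilic_attack", "radical"))
    expect_identical(rankSites(one, m), 1L)
  # exact ties resolve by ascending atom index
  tie <- condensedFukui(chargeTripleFromFukui(c(0.5, 0.5), c(0.5, 0.5)))
  expect_identical(rankSites(tie, "radical"), c(1L, 2L))
})

test_that("closure violations produce an explicit diagnostic", {
  zero <- chargeSet(1:3, rep(6L, 3), qCation = rep(0, 3),
                    qNeutral = rep(0, 3), qAnion = rep(0, 3))
  expect_warning(ft <- condensedFukui(zero), "charge-closure violation")
  expect_true(all(as.data.frame(ft)$f_zero == 0))
  expect_error(condensedFukui(zero, strict = TRUE), "charge-closure violation")
})

test_that("negative condensed values are retained and flagged, not clipped", {
  cs <- chargeSet(1:2, c(6L, 6L), qCation = c(1.1, -0.1),
                  qNeutral = c(0, 0), qAnion = c(-0.5, -0.5))
  ft <- condensedFukui(cs)
  expect_equal(ft@fMinus, c(1.1, -0.1))
  expect_identical(ft@negativeFlag, c(FALSE, TRUE))
})

test_that("malformed charge states are rejected", {
  expect_error(chargeSet(1:2, 6L, qCation = c(0, 1), qNeutral = c(0, 0),
                         qAnion = c(0, -1)), "identical atom lists")
  expect_error(chargeSet(c(1L, 1L), c(6L, 6L), c(0.5, 0.5), c(0, 0),
                         c(-0.5, -0.5)), "unique")
})
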