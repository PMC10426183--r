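test_that("single-mode vibrational entropy matches the closed form", {
  v <- vibrationalSet(1000)
  expect_equal(vibrationalTerms(v, 298.15)$S, 0.392, tolerance = 0.001 / 0.392)
  # closed-form hand evaluation with standalone constants
  theta <- 6.62607015e-34 * 2.99792458e10 * 1000 / 1.380649e-23
  x <- theta / 298.15
  expect_equal(vibrationalTerms(v, 298.15)$S,
               8.314462618 * (x / (exp(x) - 1) - log(1 - exp(-x))),
               tolerance = 1e-12)
})

test_that("vibrational terms have the correct limits", {
  v <- vibrationalSet(c(120, 900, 2100))
  # S_vib -> 0 as T -> 0+, without overflow
  expect_lt(vibrationalTerms(v, 0.5)$S, 1e-8)
  expect_true(is.finite(vibrationalTerms(v, 1e-3)$S))
  # equipartition: Cv per mode -> R at T = 100 * theta
  theta <- 6.62607015e-34 * 2.99792458e10 * 500 / 1.380649e-23
  cv <- vibrationalTerms(vibrationalSet(500), 100 * theta)$Cv
  expect_equal(cv, 8.314462618, tolerance = 0.01)
  expect_error(vibrationalTerms(v, -10), "positive")
  expect_error(vibrationalTerms(v, 0), "positive")
})

test_that("zero-point energy toggle shifts E by exactly sum(h c nu)/2", {
  v <- vibrationalSet(c(300, 1500))
  theta <- 6.62607015e-34 * 2.99792458e10 * c(300, 1500) / 1.380649e-23
  d <- vibrationalTerms(v, 298.15, zpe = TRUE)$E -
    vibrationalTerms(v, 298.15, zpe = FALSE)$E
  expect_equal(d, 8.314462618 * sum(theta) / 2, tolerance = 1e-12)
})

test_that("translational entropy matches the Sackur-Tetrode closed form", {
  arAtm <- rigidBody(39.948)                  # default 1 atm
  arBar <- rigidBody(39.948, pressure = 1e5)
  stAtm <- translationalRotationalTerms(arAtm, 298.15)
  stBar <- translationalRotationalTerms(arBar, 298.15)
  expect_equal(stAtm$S_trans, oracle_sackur_tetrode(39.948, 298.15, 101325),
               tolerance = 1e-9)
  expect_equal(stBar$S_trans, oracle_sackur_tetrode(39.948, 298.15, 1e5),
               tolerance = 1e-9)
  # standard molar entropy of argon (1 bar standard state)
  expect_equal(stBar$S_trans, 154.85, tolerance = 0.01 / 154.85)
  # a monatomic body has no rotational terms
  expect_identical(stAtm$S_rot, 0)
  expect_identical(stAtm$E_rot, 0)
  expect_equal(stAtm$E_trans / 1000, 3.718, tolerance = 0.001 / 3.718)
})

test_that("doubling the symmetry number lowers S_rot by exactly R ln 2", {
  b1 <- rigidBody(100, c(1, 2, 3), symmetryNumber = 1L)
  b2 <- rigidBody(100, c(1, 2, 3), symmetryNumber = 2L)
  d <- translationalRotationalTerms(b1, 298.15)$S_rot -
    translationalRotationalTerms(b2, 298.15)$S_rot
  expect_equal(d, 8.314462618 * log(2), tolerance = 1e-12)
  # linear rotor: same R ln 2 shift, E_rot = RT
  l1 <- rigidBody(28, 57, symmetryNumber = 1L)
  l2 <- rigidBody(28, 57, symmetryNumber = 2L)
  expect_equal(translationalRotationalTerms(l1, 300)$S_rot -
                 translationalRotationalTerms(l2, 300)$S_rot,
               8.314462618 * log(2), tolerance = 1e-12)
  expect_equal(translationalRotationalTerms(l1, 300)$E_rot,
               8.314462618 * 300, tolerance = 1e-12)
})

test_that("vibrational entropy is additive over mode sets", {
  a <- vibrationalSet(c(100, 700))
  b <- vibrationalSet(c(1500, 2500, 3100))
  ab <- vibrationalSet(c(100, 700, 1500, 2500, 3100))
  expect_equal(vibrationalTerms(ab, 350)$S,
               vibrationalTerms(a, 350)$S + vibrationalTerms(b, 350)$S,
               tolerance = 1e-12)
})

test_that("profiles are monotone with G = H - T S on the default 10-500 K grid", {
  set.seed(23)
  for (i in 1:5) {
    r <- randomRecord(100 + i, nAtoms = sample(5:20, 1))
    prof <- thermoProfile(vibrations(r), rigidBodyOf(r))
    df <- as.data.frame(prof)
    expect_identical(df$T_K, seq(10, 500, by = 10))
    expect_true(all(diff(df$S_J_molK) > 0))
    expect_true(all(diff(df$H_kJ_mol) > 0))
    resid <- df$G_kJ_mol - (df$H_kJ_mol - df$T_K * df$S_J_molK / 1000)
    expect_lt(max(abs(resid)) / max(abs(df$G_kJ_mol)), 1e-9)
    # Cv >= 0 across the grid
    cv <- vapply(df$T_K, function(Tk)
      vibrationalTerms(vibrations(r), Tk)$Cv, numeric(1))
    expect_true(all(cv >= 0))
  }
})

test_that("a single-point grid equals the pointwise evaluation", {
  r <- randomRecord(77, nAtoms = 8)
  prof <- thermoProfile(vibrations(r), rigidBodyOf(r), temperatures = 298.15)
  vt <- vibrationalTerms(vibrations(r), 298.15)
  tr <- translationalRotationalTerms(rigidBodyOf(r), 298.15)
  expect_equal(prof@entropy, tr$S_trans + tr$S_rot + vt$S, tolerance = 1e-12)
  expect_equal(prof@enthalpy,
               (tr$E_trans + tr$E_rot + vt$E + 8.314462618 * 298.15) / 1000,
               tolerance = 1e-12)
})

test_that("imaginary modes are dropped with a warning and counted", {
  expect_warning(v <- vibrationalSet(c(-50, 0, 200, 1800)), "2 non-positive")
  expect_identical(v@droppedImaginary, 2L)
  expect_identical(v@frequencies, c(200, 1800))
  expect_error(thermoProfile(v, rigidBody(100, c(1, 2, 3)),
                             temperatures = numeric(0)), "empty")
  expect_error(thermoProfile(v, rigidBody(100, c(1, 2, 3)),
                             temperatures = c(100, 50)), "ascending")
})
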