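# Independent oracles, deliberately written without reusing package code
# paths: a standalone per-atom mass summation with its own constant tables,
# and a standalone Sackur-Tetrode closed form.

oracle_weights <- list(
  avg = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, Cl = 35.45),
  iso = c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
          O = 15.9949146196, Cl = 34.968852682)
)

# token-by-token summation, its own tiny parser
oracle_mass <- function(text, kind = c("iso", "avg")) {
  kind <- match.arg(kind)
  w <- oracle_weights[[kind]]
  total <- 0
  rest <- text
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    rest <- substring(rest, nchar(m) + 1)
    d <- regmatches(rest, regexpr("^[0-9]*", rest))
    rest <- substring(rest, nchar(d) + 1)
    n <- if (nzchar(d)) as.numeric(d) else 1
    total <- total + n * w[[m]]
  }
  total
}

# Sackur-Tetrode, standalone constants
oracle_sackur_tetrode <- function(M_g_mol, T, P) {
  h <- 6.62607015e-34; kB <- 1.380649e-23
  NA_ <- 6.02214076e23; R <- 8.314462618
  m <- M_g_mol / 1000 / NA_
  R * (log((2 * pi * m * kB * T / h^2)^1.5 * kB * T / P) + 2.5)
}

# random Hill-ordered CHNOCl formula string
random_formula_string <- function() {
  els <- c("C", "H", "N", "O", "Cl")
  use <- els[runif(5) < 0.7]
  if (!length(use)) use <- "C"
  n <- sample(1:40, length(use), replace = TRUE)
  paste0(use, ifelse(n == 1, "", n), collapse = "")
}

expect_record_equal <- function(a, b, tol = 1e-12) {
  expect_identical(compoundId(a), compoundId(b))
  expect_identical(formulaCounts(molecularFormula(a)),
                   formulaCounts(molecularFormula(b)))
  expect_identical(a@provenance, b@provenance)
  expect_identical(is.null(orbitals(a)), is.null(orbitals(b)))
  if (!is.null(orbitals(a))) {
    expect_equal(eHomo(orbitals(a)), eHomo(orbitals(b)), tolerance = tol)
    expect_equal(eLumo(orbitals(a)), eLumo(orbitals(b)), tolerance = tol)
    expect_identical(energyUnit(orbitals(a)), energyUnit(orbitals(b)))
  }
  expect_identical(is.null(charges(a)), is.null(charges(b)))
  if (!is.null(charges(a)))
    expect_equal(as.data.frame(charges(a)), as.data.frame(charges(b)),
                 tolerance = tol)
  expect_identical(is.null(vibrations(a)), is.null(vibrations(b)))
  if (!is.null(vibrations(a))) {
    expect_equal(vibrations(a)@frequencies, vibrations(b)@frequencies,
                 tolerance = tol)
    expect_identical(vibrations(a)@droppedImaginary,
                     vibrations(b)@droppedImaginary)
  }
  expect_identical(is.null(rigidBodyOf(a)), is.null(rigidBodyOf(b)))
  if (!is.null(rigidBodyOf(a))) {
    ba <- rigidBodyOf(a); bb <- rigidBodyOf(b)
    expect_equal(ba@molarMass, bb@molarMass, tolerance = tol)
    expect_equal(ba@rotationalConstants, bb@rotationalConstants,
                 tolerance = tol)
    expect_identical(ba@symmetryNumber, bb@symmetryNumber)
    expect_equal(ba@pressure, bb@pressure, tolerance = tol)
    expect_identical(ba@electronicDegeneracy, bb@electronicDegeneracy)
  }
}
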