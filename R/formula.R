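#' @include AllClasses.R
NULL

#' Default atomic mass tables
#'
#' Standard atomic weights (IUPAC conventional values, e.g. C 12.011,
#' H 1.008, N 14.007, O 15.999, Cl 35.45) and principal-isotope masses
#' (12C = 12 exactly, 1H = 1.00782503, 14N = 14.00307400, 16O = 15.99491462,
#' 35Cl = 34.96885268). These reproduce routine "Anal. Calcd." and
#' "HRMS calcd" arithmetic to the usual printed precision.
#'
#' @return A [MassTables-class] object.
#' @export
#' @examples
#' tab <- defaultMassTables()
#' massTablesVersion(tab)
defaultMassTables <- function() {
  new("MassTables",
      averageWeight = .averageWeights,
      principalIsotopeMass = .principalIsotopeMasses,
      version = .massTablesVersion)
}

#' @rdname defaultMassTables
#' @param tables A [MassTables-class] object.
#' @export
massTablesVersion <- function(tables) tables@version

#' Parse a molecular formula string
#'
#' Parses a plain formula string such as `"C24H18Cl2N10O2"` into an
#' element-to-count map. Symbols are case-sensitive (one capital letter
#' optionally followed by one lowercase letter); a symbol without a trailing
#' integer has implicit count 1. Parentheses, charges, hydrates and isotope
#' labels are not supported: formulas only.
#'
#' @param text Formula string.
#' @param tables [MassTables-class] whose element set defines which symbols
#'   are recognized.
#' @return A [MolecularFormula-class]; counts are stored in Hill order.
#' @export
#' @examples
#' parseFormula("C24H18Cl2N10O2")
parseFormula <- function(text, tables = defaultMassTables()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single nonempty string")
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(parts)) != nchar(text))
    stop("malformed formula string: '", text, "'")
  sym <- sub("[0-9]*$", "", parts)
  num <- sub("^[A-Z][a-z]?", "", parts)
  cnt <- ifelse(nzchar(num), suppressWarnings(as.integer(num)), 1L)
  if (any(is.na(cnt)) || any(cnt < 1L))
    stop("zero or negative atom count in formula '", text, "'")
  known <- names(tables@averageWeight)
  bad <- setdiff(sym, known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnt, sym, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  new("MolecularFormula", counts = counts[.hillOrder(names(counts))])
}

.hillOrder <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else sort(symbols)
}

#' Format a formula in Hill order
#'
#' Canonical text form: carbon first, hydrogen second, remaining elements
#' alphabetical (all alphabetical without carbon); unit counts are implicit.
#' `parseFormula(formatFormula(x))` recovers `x` exactly.
#'
#' @param formula A [MolecularFormula-class].
#' @return A single string.
#' @export
formatFormula <- function(formula) {
  cts <- formula@counts[.hillOrder(names(formula@counts))]
  paste0(names(cts), ifelse(cts == 1L, "", cts), collapse = "")
}

.lookupMasses <- function(formula, table, what) {
  sym <- names(formula@counts)
  missing <- setdiff(sym, names(table))
  if (length(missing))
    stop("no ", what, " entry for element(s): ", paste(missing, collapse = ", "))
  table[sym]
}

#' Monoisotopic mass
#'
#' Sum of principal-isotope (most abundant isotope) masses over all atoms:
#' the exact-mass quantity reported as "HRMS calcd" for the neutral molecule.
#'
#' @param formula A [MolecularFormula-class].
#' @param tables A [MassTables-class].
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopicMass(parseFormula("C30H32N10O2"))  # 564.2710
monoisotopicMass <- function(formula, tables = defaultMassTables()) {
  m <- .lookupMasses(formula, tables@principalIsotopeMass, "principal-isotope mass")
  sum(formula@counts * m)
}

#' Adduct exact masses
#'
#' `"M"` returns the neutral monoisotopic mass; `"M+H"` adds one 1H and, by
#' mass-spectrometry convention, subtracts one electron mass (i.e. adds a
#' proton, 1.007276 Da); `"M-H"` is the symmetric deprotonated anion.
#'
#' @param formula A [MolecularFormula-class].
#' @param adduct One of `"M"`, `"M+H"`, `"M-H"`.
#' @param tables A [MassTables-class].
#' @param electronCorrection Subtract/add the electron mass (0.00054858 Da)
#'   for charged adducts. `TRUE` by default; set `FALSE` for parity with
#'   conventions that neglect it.
#' @return Mass in Da.
#' @export
adductMass <- function(formula, adduct = c("M", "M+H", "M-H"),
                       tables = defaultMassTables(),
                       electronCorrection = TRUE) {
  adduct <- match.arg(adduct)
  m0 <- monoisotopicMass(formula, tables)
  mH <- tables@principalIsotopeMass[["H"]]
  me <- if (electronCorrection) .constants$electronDa else 0
  switch(adduct,
         "M" = m0,
         "M+H" = m0 + mH - me,
         "M-H" = m0 - mH + me)
}

#' Average molar mass
#'
#' Sum of standard atomic weights over all atoms, the denominator of
#' elemental-analysis percentages.
#'
#' @inheritParams monoisotopicMass
#' @return Mass in g/mol.
#' @export
averageMolarMass <- function(formula, tables = defaultMassTables()) {
  w <- .lookupMasses(formula, tables@averageWeight, "atomic-weight")
  sum(formula@counts * w)
}

#' Elemental-analysis percentages
#'
#' Mass percent of each element: 100 * count * weight / molar mass. The raw
#' values sum to 100 (to within floating-point closure); round for report
#' parity with printed "Anal. Calcd." digits using [roundHalfEven()].
#'
#' @inheritParams monoisotopicMass
#' @return Named numeric vector of unrounded percentages, in Hill order.
#' @export
#' @examples
#' p <- elementalPercentages(parseFormula("C24H18Cl2N10O2"))
#' roundHalfEven(p[["N"]], 2)  # 25.50
elementalPercentages <- function(formula, tables = defaultMassTables()) {
  w <- .lookupMasses(formula, tables@averageWeight, "atomic-weight")
  100 * formula@counts * w / averageMolarMass(formula, tables)
}

#' Nitrogen mass percentage
#'
#' Projection of [elementalPercentages()] onto nitrogen; 0 for
#' nitrogen-free formulas. High nitrogen content is a design target for
#' tetrazole-based energetic materials (decomposition to N2 gas).
#'
#' @inheritParams monoisotopicMass
#' @return Percent by mass.
#' @export
nitrogenPercent <- function(formula, tables = defaultMassTables()) {
  p <- elementalPercentages(formula, tables)
  if ("N" %in% names(p)) unname(p[["N"]]) else 0
}

#' Oxygen balance
#'
#' Oxygen surplus or deficit relative to complete combustion to CO2 and
#' H2O, in grams of oxygen per 100 g of compound:
#' \deqn{OB\% = 1600 (n_O - 2 n_C - n_H/2) / MW}
#' The default `"CHNO-classic"` convention ignores halogens in the balance
#' (they still contribute to MW). The `"halogen-HX"` variant assumes each
#' halogen atom binds one hydrogen as HX, replacing the hydrogen term by
#' (n_H - n_X)/2. An exactly stoichiometric formula (n_O = 2 n_C + n_H/2,
#' e.g. CO2) has OB = 0.
#'
#' @inheritParams monoisotopicMass
#' @param convention `"CHNO-classic"` (default) or `"halogen-HX"`.
#' @return Percent, signed; the convention is attached as attribute
#'   `"convention"`.
#' @export
#' @examples
#' oxygenBalance(parseFormula("CO2"))             # 0
#' oxygenBalance(parseFormula("C24H16N14O10"))    # about -111.4
oxygenBalance <- function(formula, tables = defaultMassTables(),
                          convention = c("CHNO-classic", "halogen-HX")) {
  convention <- match.arg(convention)
  halogens <- c("F", "Cl", "Br", "I")
  allowed <- c("C", "H", "N", "O", halogens)
  bad <- setdiff(names(formula@counts), allowed)
  if (length(bad))
    stop("oxygen balance is defined for C/H/N/O/halogen formulas only; found: ",
         paste(bad, collapse = ", "))
  cts <- formula@counts
  n <- function(el) if (el %in% names(cts)) cts[[el]] else 0L
  nX <- sum(vapply(halogens, n, numeric(1)))
  hTerm <- if (convention == "CHNO-classic") n("H") / 2 else (n("H") - nX) / 2
  ob <- 1600 * (n("O") - 2 * n("C") - hTerm) / averageMolarMass(formula, tables)
  structure(ob, convention = convention)
}

#' Energetic-material descriptors of a formula
#'
#' Bundles [nitrogenPercent()] and [oxygenBalance()] with the convention tag.
#'
#' @inheritParams oxygenBalance
#' @return An [EnergeticDescriptors-class] object.
#' @export
energeticDescriptors <- function(formula, tables = defaultMassTables(),
                                 convention = c("CHNO-classic", "halogen-HX")) {
  convention <- match.arg(convention)
  ob <- oxygenBalance(formula, tables, convention)
  new("EnergeticDescriptors",
      nitrogenPercent = nitrogenPercent(formula, tables),
      oxygenBalance = as.numeric(ob),
      convention = convention)
}

#' Round half to even
#'
#' IEEE "banker's" rounding at `digits` decimals, the rule used for report
#' parity with printed tables (base `round()` already implements it; this
#' wrapper exists so report code names the convention explicitly).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
roundHalfEven <- function(x, digits = 0) round(x, digits)
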