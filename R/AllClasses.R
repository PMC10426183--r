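#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Molecular formula
#'
#' An element-to-count map obtained from [parseFormula()]. Counts are stored
#' in Hill order (C first, then H, then the remaining elements
#' alphabetically; fully alphabetical when no carbon is present).
#'
#' @slot counts Named integer vector, element symbol -> atom count (>= 1).
#' @seealso [parseFormula()], [formatFormula()]
#' @exportClass MolecularFormula
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
  cts <- object@counts
  if (length(cts) == 0L) return("formula has no elements")
  if (is.null(names(cts)) || any(!nzchar(names(cts))))
    return("counts must be named by element symbol")
  if (anyDuplicated(names(cts))) return("duplicate element symbols")
  if (any(is.na(cts)) || any(cts < 1L)) return("every count must be >= 1")
  if (any(!grepl("^[A-Z][a-z]?$", names(cts))))
    return("element symbols must be one capital optionally followed by one lowercase letter")
  TRUE
})

#' Atomic mass tables
#'
#' Versioned tables of standard atomic weights (for average molar mass and
#' elemental-analysis percentages) and principal-isotope masses (for
#' monoisotopic / exact masses). The version string is carried into every
#' report so a run can be reproduced against the same constants.
#'
#' @slot averageWeight Named numeric, element -> standard atomic weight (g/mol).
#' @slot principalIsotopeMass Named numeric, element -> most-abundant-isotope
#'   mass (Da).
#' @slot version Single string identifying the table revision.
#' @seealso [defaultMassTables()]
#' @exportClass MassTables
setClass("MassTables", representation(
  averageWeight = "numeric",
  principalIsotopeMass = "numeric",
  version = "character"
))

setValidity("MassTables", function(object) {
  if (length(object@version) != 1L || !nzchar(object@version))
    return("version must be a nonempty string")
  if (is.null(names(object@averageWeight)) ||
      is.null(names(object@principalIsotopeMass)))
    return("mass tables must be named by element symbol")
  if (any(object@averageWeight <= 0) || any(object@principalIsotopeMass <= 0))
    return("masses must be positive")
  TRUE
})

#' Energetic-material formula descriptors
#'
#' Nitrogen mass percentage and oxygen balance of a formula, together with
#' the oxygen-balance convention that produced them.
#'
#' @slot nitrogenPercent Mass percent of nitrogen, in [0, 100].
#' @slot oxygenBalance Signed oxygen balance in percent (g O per 100 g).
#' @slot convention Convention tag, `"CHNO-classic"` or `"halogen-HX"`.
#' @seealso [energeticDescriptors()], [oxygenBalance()]
#' @exportClass EnergeticDescriptors
setClass("EnergeticDescriptors", representation(
  nitrogenPercent = "numeric",
  oxygenBalance = "numeric",
  convention = "character"
))

setValidity("EnergeticDescriptors", function(object) {
  np <- object@nitrogenPercent
  if (length(np) != 1L || is.na(np) || np < 0 || np > 100)
    return("nitrogenPercent must be a single value in [0, 100]")
  if (length(object@oxygenBalance) != 1L || is.na(object@oxygenBalance))
    return("oxygenBalance must be a single finite value")
  if (!object@convention %in% c("CHNO-classic", "halogen-HX"))
    return("unknown oxygen-balance convention")
  TRUE
})

#' Frontier orbital energies
#'
#' HOMO and LUMO energies of a gapped closed-shell ground state. Energies are
#' stored in the unit given by `unit` ("hartree" internally throughout the
#' package; conversion happens at the presentation layer).
#'
#' @slot eHomo Energy of the highest occupied molecular orbital.
#' @slot eLumo Energy of the lowest unoccupied molecular orbital.
#' @slot unit `"hartree"` or `"eV"`.
#' @seealso [globalDescriptors()]
#' @exportClass OrbitalEnergies
setClass("OrbitalEnergies", representation(
  eHomo = "numeric", eLumo = "numeric", unit = "character"
))

setValidity("OrbitalEnergies", function(object) {
  if (length(object@eHomo) != 1L || length(object@eLumo) != 1L)
    return("eHomo and eLumo must be single values")
  if (is.na(object@eHomo) || is.na(object@eLumo))
    return("orbital energies must be finite")
  if (!(object@eHomo < object@eLumo))
    return("eHomo must be strictly below eLumo (gapped closed-shell state)")
  if (!object@unit %in% c("hartree", "eV")) return("unit must be hartree or eV")
  TRUE
})

#' Global conceptual-DFT reactivity descriptors
#'
#' The Koopmans-type descriptor set derived from frontier orbital energies:
#' ionization potential I = -E_HOMO, electron affinity A = -E_LUMO,
#' gap = I - A, electronegativity chi = (I + A)/2, chemical potential
#' mu = -chi (stored signed), hardness eta = (I - A)/2, softness
#' S = 1/(2 eta) and electrophilicity index omega = mu^2 / (2 eta).
#'
#' @slot ionizationPotential,electronAffinity,gap,electronegativity,chemicalPotential,hardness,softness,electrophilicity
#'   Scalar descriptor values in `unit` (softness in its reciprocal).
#' @slot unit Energy unit of the input orbitals.
#' @seealso [globalDescriptors()], [seriesRanking()]
#' @exportClass GlobalReactivity
setClass("GlobalReactivity", representation(
  ionizationPotential = "numeric",
  electronAffinity = "numeric",
  gap = "numeric",
  electronegativity = "numeric",
  chemicalPotential = "numeric",
  hardness = "numeric",
  softness = "numeric",
  electrophilicity = "numeric",
  unit = "character"
))

setValidity("GlobalReactivity", function(object) {
  if (object@hardness <= 0) return("hardness must be positive")
  if (abs(object@gap - 2 * object@hardness) > 1e-12 * max(1, abs(object@gap)))
    return("gap must equal 2 * hardness")
  if (abs(object@chemicalPotential + object@electronegativity) > 1e-12)
    return("chemical potential must equal -electronegativity")
  TRUE
})

#' Per-atom charges of the N-1/N/N+1 electron states
#'
#' Parallel charge vectors for the cation (N-1 electrons), neutral (N) and
#' anion (N+1) states of one molecule, the inputs of the condensed Fukui
#' finite-difference scheme. Atom indexing is 1-based.
#'
#' @slot atom Integer atom indices (1-based, unique).
#' @slot z Integer atomic numbers.
#' @slot qCation,qNeutral,qAnion Numeric charge vectors per state.
#' @slot scheme Population-analysis scheme label (free text, e.g. "Mulliken").
#' @seealso [condensedFukui()], [chargeClosure()]
#' @exportClass ChargeSet
setClass("ChargeSet", representation(
  atom = "integer", z = "integer",
  qCation = "numeric", qNeutral = "numeric", qAnion = "numeric",
  scheme = "character"
))

setValidity("ChargeSet", function(object) {
  n <- length(object@atom)
  if (n == 0L) return("charge set is empty")
  if (anyDuplicated(object@atom)) return("atom indices must be unique")
  if (any(object@atom < 1L)) return("atom indices are 1-based")
  lens <- c(length(object@z), length(object@qCation),
            length(object@qNeutral), length(object@qAnion))
  if (any(lens != n))
    return("the three charge states must cover identical atom lists")
  if (any(object@z < 1L)) return("atomic numbers must be positive")
  if (any(!is.finite(c(object@qCation, object@qNeutral, object@qAnion))))
    return("charges must be finite")
  TRUE
})

#' Condensed Fukui index table
#'
#' Per-atom condensed Fukui indices f-, f+, the radical index
#' f0 = (f- + f+)/2 and the dual descriptor f+ - f-, computed by
#' [condensedFukui()]. Negative condensed values (a known artifact of
#' Mulliken-type population schemes) are retained and flagged, never clipped.
#'
#' @slot atom,z Atom indices (1-based) and atomic numbers.
#' @slot fMinus,fPlus,fZero,dual Numeric index vectors.
#' @slot negativeFlag Logical, TRUE where f- or f+ is negative.
#' @slot closureTol Tolerance used for the unit-charge closure check.
#' @seealso [condensedFukui()], [rankSites()]
#' @exportClass FukuiTable
setClass("FukuiTable", representation(
  atom = "integer", z = "integer",
  fMinus = "numeric", fPlus = "numeric", fZero = "numeric", dual = "numeric",
  negativeFlag = "logical", closureTol = "numeric"
))

setValidity("FukuiTable", function(object) {
  n <- length(object@atom)
  if (n == 0L) return("table is empty")
  if (any(c(length(object@fMinus), length(object@fPlus),
            length(object@fZero), length(object@dual),
            length(object@z), length(object@negativeFlag)) != n))
    return("all columns must have equal length")
  if (max(abs(object@fZero - (object@fMinus + object@fPlus) / 2)) > 0)
    return("fZero must equal (fMinus + fPlus)/2 exactly")
  TRUE
})

#' Harmonic vibrational mode set
#'
#' Retained (positive) harmonic wavenumbers plus a count of discarded
#' imaginary/non-positive modes.
#'
#' @slot frequencies Wavenumbers in 1/cm, all > 0.
#' @slot droppedImaginary Number of non-positive modes dropped on input.
#' @seealso [vibrationalSet()], [vibrationalTerms()]
#' @exportClass VibrationalSet
setClass("VibrationalSet", representation(
  frequencies = "numeric", droppedImaginary = "integer"
))

setValidity("VibrationalSet", function(object) {
  if (any(!is.finite(object@frequencies)) || any(object@frequencies <= 0))
    return("all retained frequencies must be positive and finite")
  if (object@droppedImaginary < 0L) return("droppedImaginary must be >= 0")
  TRUE
})

#' Rigid-body data for translational/rotational partition functions
#'
#' @slot molarMass Molar mass in g/mol.
#' @slot rotationalConstants Rotational constants in GHz: length 3 for a
#'   nonlinear top, length 1 for a linear molecule, length 0 for an atom.
#' @slot symmetryNumber Rotational symmetry number (>= 1).
#' @slot pressure Standard-state pressure in Pa.
#' @slot electronicDegeneracy Ground-state electronic degeneracy (>= 1).
#' @seealso [rigidBody()], [translationalRotationalTerms()]
#' @exportClass RigidBody
setClass("RigidBody", representation(
  molarMass = "numeric", rotationalConstants = "numeric",
  symmetryNumber = "integer", pressure = "numeric",
  electronicDegeneracy = "integer"
))

setValidity("RigidBody", function(object) {
  if (length(object@molarMass) != 1L || object@molarMass <= 0)
    return("molarMass must be a single positive value")
  if (!length(object@rotationalConstants) %in% c(0L, 1L, 3L))
    return("rotationalConstants must have length 0 (atom), 1 (linear) or 3 (nonlinear)")
  if (any(object@rotationalConstants <= 0))
    return("rotational constants must be positive")
  if (object@symmetryNumber < 1L) return("symmetryNumber must be >= 1")
  if (object@pressure <= 0) return("pressure must be positive")
  if (object@electronicDegeneracy < 1L)
    return("electronicDegeneracy must be >= 1")
  TRUE
})

#' Thermodynamic profile over a temperature grid
#'
#' Total entropy S(T) in J/(mol K), thermal enthalpy H(T) in kJ/mol
#' (relative to 0 K; whether the zero-point energy is included is recorded)
#' and Gibbs energy G(T) = H(T) - T S(T) in kJ/mol.
#'
#' @slot temperature Temperature grid in K, positive and ascending.
#' @slot entropy,enthalpy,gibbs Numeric vectors on the grid.
#' @slot zpeIncluded Whether the ZPE is included in H.
#' @slot pressure Standard-state pressure (Pa) of the run.
#' @seealso [thermoProfile()]
#' @exportClass ThermoProfile
setClass("ThermoProfile", representation(
  temperature = "numeric", entropy = "numeric",
  enthalpy = "numeric", gibbs = "numeric",
  zpeIncluded = "logical", pressure = "numeric"
))

setValidity("ThermoProfile", function(object) {
  n <- length(object@temperature)
  if (n == 0L) return("empty temperature grid")
  if (any(object@temperature <= 0)) return("temperatures must be positive")
  if (is.unsorted(object@temperature, strictly = TRUE))
    return("temperature grid must be strictly ascending")
  if (any(c(length(object@entropy), length(object@enthalpy),
            length(object@gibbs)) != n))
    return("S, H, G must be evaluated on the full grid")
  resid <- object@gibbs - (object@enthalpy - object@temperature * object@entropy / 1000)
  if (max(abs(resid)) > 1e-9 * max(1, max(abs(object@gibbs))))
    return("G must equal H - T*S")
  TRUE
})

setClassUnion("OrbitalEnergiesOrNULL", c("OrbitalEnergies", "NULL"))
setClassUnion("ChargeSetOrNULL", c("ChargeSet", "NULL"))
setClassUnion("VibrationalSetOrNULL", c("VibrationalSet", "NULL"))
setClassUnion("RigidBodyOrNULL", c("RigidBody", "NULL"))

#' One compound's computational input bundle
#'
#' Aggregates everything the characterization pipeline can consume for one
#' compound: identifier, molecular formula, frontier orbital energies and,
#' optionally, charge states, harmonic frequencies and rigid-body data.
#' Optional sections that are absent stay `NULL`; downstream report sections
#' are simply skipped for them.
#'
#' @slot id Compound label, e.g. "6d"; nonempty, unique within a series.
#' @slot formula A [MolecularFormula-class].
#' @slot orbitals A [OrbitalEnergies-class] or NULL.
#' @slot charges A [ChargeSet-class] or NULL.
#' @slot vibrations A [VibrationalSet-class] or NULL.
#' @slot body A [RigidBody-class] or NULL.
#' @slot provenance Free-text source tag.
#' @seealso [compoundRecord()], [readRecord()], [runCharacterization()]
#' @exportClass CompoundRecord
setClass("CompoundRecord", representation(
  id = "character",
  formula = "MolecularFormula",
  orbitals = "OrbitalEnergiesOrNULL",
  charges = "ChargeSetOrNULL",
  vibrations = "VibrationalSetOrNULL",
  body = "RigidBodyOrNULL",
  provenance = "character"
))

setValidity("CompoundRecord", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("id must be a nonempty string")
  TRUE
})

#' Built-in series fixture
#'
#' The reconstructed input records of the six bis-tetrazole acetamides
#' 6a-6f together with the published descriptor values they are expected to
#' reproduce. See [builtinSeries()].
#'
#' @slot records Named list of [CompoundRecord-class] objects.
#' @slot expected List of published-value tables keyed by quantity.
#' @exportClass SeriesFixture
setClass("SeriesFixture", representation(records = "list", expected = "list"))

setValidity("SeriesFixture", function(object) {
  if (!all(vapply(object@records, is, logical(1), "CompoundRecord")))
    return("records must all be CompoundRecord objects")
  ids <- vapply(object@records, function(r) r@id, character(1))
  if (anyDuplicated(ids)) return("record ids must be unique")
  TRUE
})

#' Full characterization report
#'
#' The report bundle produced by [runCharacterization()]: a descriptor table
#' (one row per compound), per-compound Fukui tables, per-compound
#' thermodynamic profiles, a formula/energetic table, ranking summaries and
#' run metadata sufficient to reproduce the run.
#'
#' @slot descriptors data.frame of global reactivity descriptors.
#' @slot fukui Named list of per-compound Fukui data.frames.
#' @slot thermo Named list of per-compound long-format thermo data.frames.
#' @slot formulaTable data.frame of masses, percentages, N% and OB%.
#' @slot rankings List of series ranking summaries.
#' @slot metadata List: settings, constants/table versions, timestamp.
#' @exportClass CharacterizationReport
setClass("CharacterizationReport", representation(
  descriptors = "data.frame",
  fukui = "list",
  thermo = "list",
  formulaTable = "data.frame",
  rankings = "list",
  metadata = "list"
))
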