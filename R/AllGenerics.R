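#' @include AllClasses.R
NULL

#' Accessors for postDFT objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `formulaCounts()` returns the named atom-count vector of a formula,
#' `eHomo()`/`eLumo()`/`energyUnit()` read frontier orbital energies,
#' `compoundId()`, `molecularFormula()`, `orbitals()`, `charges()`,
#' `vibrations()` and `rigidBodyOf()` read the sections of a
#' [CompoundRecord-class], and `records()`/`expectedValues()` read a
#' [SeriesFixture-class].
#'
#' @param x The object to access.
#' @return The corresponding component; `NULL` for absent optional sections.
#' @name accessors
#' @aliases formulaCounts eHomo eLumo energyUnit compoundId molecularFormula
#'   orbitals charges vibrations rigidBodyOf records expectedValues
#' @examples
#' f <- parseFormula("C24H16N14O10")
#' formulaCounts(f)
NULL

#' @rdname accessors
#' @export
setGeneric("formulaCounts", function(x) standardGeneric("formulaCounts"))
#' @rdname accessors
#' @export
setGeneric("eHomo", function(x) standardGeneric("eHomo"))
#' @rdname accessors
#' @export
setGeneric("eLumo", function(x) standardGeneric("eLumo"))
#' @rdname accessors
#' @export
setGeneric("energyUnit", function(x) standardGeneric("energyUnit"))
#' @rdname accessors
#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))
#' @rdname accessors
#' @export
setGeneric("molecularFormula", function(x) standardGeneric("molecularFormula"))
#' @rdname accessors
#' @export
setGeneric("orbitals", function(x) standardGeneric("orbitals"))
#' @rdname accessors
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))
#' @rdname accessors
#' @export
setGeneric("vibrations", function(x) standardGeneric("vibrations"))
#' @rdname accessors
#' @export
setGeneric("rigidBodyOf", function(x) standardGeneric("rigidBodyOf"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("expectedValues", function(x) standardGeneric("expectedValues"))

setMethod("formulaCounts", "MolecularFormula", function(x) x@counts)
setMethod("eHomo", "OrbitalEnergies", function(x) x@eHomo)
setMethod("eLumo", "OrbitalEnergies", function(x) x@eLumo)
setMethod("energyUnit", "OrbitalEnergies", function(x) x@unit)
setMethod("energyUnit", "GlobalReactivity", function(x) x@unit)
setMethod("compoundId", "CompoundRecord", function(x) x@id)
setMethod("molecularFormula", "CompoundRecord", function(x) x@formula)
setMethod("orbitals", "CompoundRecord", function(x) x@orbitals)
setMethod("charges", "CompoundRecord", function(x) x@charges)
setMethod("vibrations", "CompoundRecord", function(x) x@vibrations)
setMethod("rigidBodyOf", "CompoundRecord", function(x) x@body)
setMethod("records", "SeriesFixture", function(x) x@records)
setMethod("expectedValues", "SeriesFixture", function(x) x@expected)

#' @export
as.data.frame.ChargeSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(atom = x@atom, z = x@z, q_cation = x@qCation,
             q_neutral = x@qNeutral, q_anion = x@qAnion)
}

#' @export
as.data.frame.FukuiTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(atom = x@atom, z = x@z, f_minus = x@fMinus, f_plus = x@fPlus,
             f_zero = x@fZero, dual = x@dual, negative_flag = x@negativeFlag)
}

#' @export
as.data.frame.ThermoProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(T_K = x@temperature, S_J_molK = x@entropy,
             H_kJ_mol = x@enthalpy, G_kJ_mol = x@gibbs)
}

#' @export
as.data.frame.GlobalReactivity <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(I = x@ionizationPotential, A = x@electronAffinity, gap = x@gap,
             chi = x@electronegativity, mu = x@chemicalPotential,
             mu_abs = abs(x@chemicalPotential), eta = x@hardness,
             S = x@softness, omega = x@electrophilicity, unit = x@unit)
}

setMethod("as.data.frame", "ChargeSet", as.data.frame.ChargeSet)
setMethod("as.data.frame", "FukuiTable", as.data.frame.FukuiTable)
setMethod("as.data.frame", "ThermoProfile", as.data.frame.ThermoProfile)
setMethod("as.data.frame", "GlobalReactivity", as.data.frame.GlobalReactivity)
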