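#' @include AllClasses.R
NULL

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", formatFormula(object),
      sprintf("(%d atoms)\n", sum(object@counts)))
})

setMethod("show", "MassTables", function(object) {
  cat("MassTables [", object@version, "]: ",
      length(object@averageWeight), " elements\n", sep = "")
})

setMethod("show", "OrbitalEnergies", function(object) {
  cat(sprintf("OrbitalEnergies: HOMO %.6f, LUMO %.6f %s (gap %.6f)\n",
              object@eHomo, object@eLumo, object@unit,
              object@eLumo - object@eHomo))
})

setMethod("show", "GlobalReactivity", function(object) {
  cat("GlobalReactivity (", object@unit, ")\n", sep = "")
  v <- as.data.frame(object)
  print(signif(unlist(v[vapply(v, is.numeric, logical(1))]), 6))
})

setMethod("show", "EnergeticDescriptors", function(object) {
  cat(sprintf("EnergeticDescriptors: N%% = %.2f, OB%% = %.2f [%s]\n",
              object@nitrogenPercent, object@oxygenBalance,
              object@convention))
})

setMethod("show", "ChargeSet", function(object) {
  cat(sprintf("ChargeSet (%s): %d atoms; closure residuals %+0.2e / %+0.2e\n",
              object@scheme, length(object@atom),
              chargeClosure(object)[["cation"]],
              chargeClosure(object)[["anion"]]))
})

setMethod("show", "FukuiTable", function(object) {
  cat(sprintf("FukuiTable: %d atoms (%d negative-flagged)\n",
              length(object@atom), sum(object@negativeFlag)))
  cat(sprintf("  top f-: atom %d; top f+: atom %d; top f0: atom %d\n",
              object@atom[which.max(object@fMinus)],
              object@atom[which.max(object@fPlus)],
              object@atom[which.max(object@fZero)]))
})

setMethod("show", "VibrationalSet", function(object) {
  cat(sprintf("VibrationalSet: %d modes (%.1f-%.1f 1/cm), %d imaginary dropped\n",
              length(object@frequencies),
              if (length(object@frequencies)) min(object@frequencies) else NA,
              if (length(object@frequencies)) max(object@frequencies) else NA,
              object@droppedImaginary))
})

setMethod("show", "RigidBody", function(object) {
  kind <- c("atomic", "linear", "", "nonlinear")[length(object@rotationalConstants) + 1L]
  cat(sprintf("RigidBody: %.3f g/mol, %s, sigma = %d, P = %.0f Pa\n",
              object@molarMass, kind, object@symmetryNumber, object@pressure))
})

setMethod("show", "ThermoProfile", function(object) {
  rng <- range(object@temperature)
  cat(sprintf("ThermoProfile: %d points on %.0f-%.0f K (ZPE %s, P = %.0f Pa)\n",
              length(object@temperature), rng[1], rng[2],
              if (object@zpeIncluded) "included" else "excluded",
              object@pressure))
})

setMethod("show", "CompoundRecord", function(object) {
  has <- function(x) if (is.null(x)) "-" else "+"
  cat(sprintf("CompoundRecord %s [%s]: orbitals %s, charges %s, vibrations %s, body %s\n",
              object@id, formatFormula(object@formula),
              has(object@orbitals), has(object@charges),
              has(object@vibrations), has(object@body)))
})

setMethod("show", "SeriesFixture", function(object) {
  cat("SeriesFixture:", length(object@records), "records (",
      paste(names(object@records), collapse = ", "), ")\n")
})

setMethod("show", "CharacterizationReport", function(object) {
  cat("CharacterizationReport\n")
  cat(sprintf("  descriptors: %d compounds\n", nrow(object@descriptors)))
  cat(sprintf("  fukui tables: %d; thermo profiles: %d\n",
              length(object@fukui), length(object@thermo)))
  cat(sprintf("  formula table: %d compounds\n", nrow(object@formulaTable)))
})
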