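#' @include AllClasses.R
NULL

.defaultSettings <- function() {
  list(
    units = "hartree",            # presentation unit for descriptors
    obConvention = "CHNO-classic",
    labeling = "paper",           # Fukui attack-mode labeling
    temperatures = seq(10, 500, by = 10),
    zpe = TRUE,
    closureTol = 1e-3,
    round = NULL                  # NULL = raw doubles in tables
  )
}

.maybeRound <- function(x, digits) {
  if (is.null(digits)) x else roundHalfEven(x, digits)
}

#' Run the full characterization over a record set
#'
#' Orchestrates every analysis the package implements over a list of
#' [CompoundRecord-class] objects and collects the results into a
#' [CharacterizationReport-class]:
#' \itemize{
#'   \item global reactivity descriptor table (one row per compound with
#'     orbital energies) plus series rankings;
#'   \item per-compound condensed Fukui tables (compounds with charge
#'     states) and top-site rankings;
#'   \item per-compound S/H/G profiles on the temperature grid (compounds
#'     with frequencies and rigid-body data);
#'   \item formula table: molar mass, monoisotopic and [M+H]+ masses,
#'     elemental percentages, nitrogen percent and oxygen balance.
#' }
#' Sections are computed only where the inputs exist; a compound lacking an
#' optional input is skipped for that section with a message. Given the same
#' records and settings the report is fully deterministic (the metadata
#' timestamp aside).
#'
#' @param records List of [CompoundRecord-class] objects (>= 1, unique ids).
#' @param settings Named list overriding the defaults: `units`
#'   ("hartree"/"eV"), `obConvention`, `labeling` ("paper"/"standard"),
#'   `temperatures`, `zpe`, `closureTol`, `round` (digits or NULL).
#' @return A [CharacterizationReport-class].
#' @export
#' @examples
#' rep <- runCharacterization(records(builtinSeries()))
#' rep@rankings$reactivity$softest
runCharacterization <- function(records, settings = list()) {
  if (length(records) == 0L) stop("empty input: need at least one record")
  if (!all(vapply(records, is, logical(1), "CompoundRecord")))
    stop("records must be CompoundRecord objects")
  ids <- vapply(records, compoundId, character(1))
  if (anyDuplicated(ids)) stop("duplicate compound ids")
  names(records) <- ids
  s <- utils::modifyList(.defaultSettings(), settings)
  if (!s$units %in% c("hartree", "eV")) stop("invalid settings: units")
  tables <- defaultMassTables()

  ## --- global reactivity -----------------------------------------------
  withOrb <- Filter(function(r) !is.null(orbitals(r)), records)
  descriptors <- data.frame()
  rankings <- list()
  if (length(withOrb)) {
    gds <- lapply(withOrb, function(r) {
      o <- orbitals(r)
      if (s$units != energyUnit(o))
        o <- orbitalEnergies(convertEnergy(eHomo(o), energyUnit(o), s$units),
                             convertEnergy(eLumo(o), energyUnit(o), s$units),
                             unit = s$units)
      globalDescriptors(o)
    })
    descriptors <- do.call(rbind, lapply(gds, as.data.frame))
    descriptors <- cbind(id = names(gds), descriptors, row.names = NULL)
    num <- vapply(descriptors, is.numeric, logical(1))
    descriptors[num] <- lapply(descriptors[num], .maybeRound, digits = s$round)
    rankings$reactivity <- seriesRanking(gds)[c("softest", "hardest",
                                                "mostElectrophilic",
                                                "lowestIonization")]
  }

  ## --- condensed Fukui ---------------------------------------------------
  fukui <- list()
  topSites <- list()
  for (id in ids) {
    ch <- charges(records[[id]])
    if (is.null(ch)) { message("no charge states for ", id,
                               "; skipping Fukui section"); next }
    ft <- condensedFukui(ch, closureTol = s$closureTol)
    df <- as.data.frame(ft)
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "atom" &
      names(df) != "z"
    df[num] <- lapply(df[num], .maybeRound, digits = s$round)
    fukui[[id]] <- df
    topSites[[id]] <- list(
      nucleophilic_attack = rankSites(ft, "nucleophilic_attack", s$labeling)[1],
      electrophilic_attack = rankSites(ft, "electrophilic_attack", s$labeling)[1],
      radical = rankSites(ft, "radical", s$labeling)[1])
  }
  if (length(topSites)) rankings$fukuiTopSites <- topSites

  ## --- thermochemistry ---------------------------------------------------
  thermo <- list()
  for (id in ids) {
    r <- records[[id]]
    if (is.null(vibrations(r)) || is.null(rigidBodyOf(r))) {
      message("no vibrational/rigid-body data for ", id,
              "; skipping thermo section")
      next
    }
    prof <- thermoProfile(vibrations(r), rigidBodyOf(r),
                          temperatures = s$temperatures, zpe = s$zpe)
    thermo[[id]] <- cbind(id = id, as.data.frame(prof), row.names = NULL)
  }

  ## --- formula / energetic descriptors -----------------------------------
  formulaTable <- do.call(rbind, lapply(ids, function(id) {
    f <- molecularFormula(records[[id]])
    pct <- elementalPercentages(f, tables)
    ed <- energeticDescriptors(f, tables, s$obConvention)
    row <- data.frame(
      id = id, formula = formatFormula(f),
      MW_g_mol = averageMolarMass(f, tables),
      monoisotopic_Da = monoisotopicMass(f, tables),
      MH_adduct_Da = adductMass(f, "M+H", tables),
      pct_C = if ("C" %in% names(pct)) pct[["C"]] else 0,
      pct_H = if ("H" %in% names(pct)) pct[["H"]] else 0,
      N_percent = ed@nitrogenPercent,
      OB_percent = ed@oxygenBalance,
      OB_convention = ed@convention,
      mass_tables_version = tables@version)
    row
  }))
  num <- vapply(formulaTable, is.numeric, logical(1))
  formulaTable[num] <- lapply(formulaTable[num], .maybeRound, digits = s$round)
  rankings$highestNitrogen <- formulaTable$id[
    order(-formulaTable$N_percent, formulaTable$id, method = "radix")][1]
  rankings$smallestOxygenBalanceMagnitude <- formulaTable$id[
    order(abs(formulaTable$OB_percent), formulaTable$id, method = "radix")][1]

  new("CharacterizationReport",
      descriptors = descriptors, fukui = fukui, thermo = thermo,
      formulaTable = formulaTable, rankings = rankings,
      metadata = list(
        settings = s,
        constants_version = .constantsVersion,
        mass_tables_version = tables@version,
        n_records = length(records),
        ids = ids,
        timestamp = format(Sys.time(), tz = "UTC")))
}

#' Write a characterization report bundle
#'
#' Serializes every section of a [CharacterizationReport-class] into a
#' directory: `descriptors.(csv|json)`, `fukui_<id>.*`, `thermo_<id>.*`,
#' `formula.*`, plus `metadata.json` (settings, versions, rankings).
#'
#' @param report A [CharacterizationReport-class].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"json"` for the tables.
#' @return The directory, invisibly.
#' @export
writeReportBundle <- function(report, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- format
  meta <- list(mass_tables_version = report@metadata$mass_tables_version)
  if (nrow(report@descriptors))
    writeReport(report@descriptors, file.path(dir, paste0("descriptors.", ext)),
                format, meta)
  for (id in names(report@fukui))
    writeReport(report@fukui[[id]],
                file.path(dir, paste0("fukui_", id, ".", ext)), format, meta)
  for (id in names(report@thermo))
    writeReport(report@thermo[[id]],
                file.path(dir, paste0("thermo_", id, ".", ext)), format, meta)
  writeReport(report@formulaTable, file.path(dir, paste0("formula.", ext)),
              format, meta)
  jsonlite::write_json(list(metadata = report@metadata,
                            rankings = report@rankings),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
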