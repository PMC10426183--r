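#' @include AllClasses.R
NULL

.elementZ <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Mg = 12L,
  Si = 14L, P = 15L, S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L,
  Br = 35L, I = 53L
)

.zToSymbol <- function(z) {
  sym <- names(.elementZ)[match(z, .elementZ)]
  if (any(is.na(sym)))
    stop("no symbol known for atomic number(s): ",
         paste(unique(z[is.na(sym)]), collapse = ", "))
  sym
}

#' Construct a compound record
#'
#' @param id Compound label (nonempty).
#' @param formula A [MolecularFormula-class] or a formula string.
#' @param orbitals Optional [OrbitalEnergies-class].
#' @param charges Optional [ChargeSet-class].
#' @param vibrations Optional [VibrationalSet-class].
#' @param body Optional [RigidBody-class].
#' @param provenance Free-text source tag.
#' @return A [CompoundRecord-class].
#' @export
compoundRecord <- function(id, formula, orbitals = NULL, charges = NULL,
                           vibrations = NULL, body = NULL, provenance = "") {
  if (is.character(formula)) formula <- parseFormula(formula)
  new("CompoundRecord", id = id, formula = formula, orbitals = orbitals,
      charges = charges, vibrations = vibrations, body = body,
      provenance = provenance)
}

## ---- record-json -----------------------------------------------------------

.recordToList <- function(record) {
  out <- list(id = record@id,
              formula = formatFormula(record@formula),
              provenance = record@provenance)
  if (!is.null(record@orbitals))
    out$orbitals <- list(e_homo = record@orbitals@eHomo,
                         e_lumo = record@orbitals@eLumo,
                         unit = record@orbitals@unit)
  if (!is.null(record@charges))
    out$charges <- list(scheme = record@charges@scheme,
                        atom = record@charges@atom,
                        z = record@charges@z,
                        q_cation = record@charges@qCation,
                        q_neutral = record@charges@qNeutral,
                        q_anion = record@charges@qAnion)
  if (!is.null(record@vibrations))
    out$vibrations <- list(frequencies = record@vibrations@frequencies,
                           dropped_imaginary = record@vibrations@droppedImaginary)
  if (!is.null(record@body))
    out$body <- list(molar_mass = record@body@molarMass,
                     rotational_constants_ghz = record@body@rotationalConstants,
                     symmetry_number = record@body@symmetryNumber,
                     pressure_pa = record@body@pressure,
                     electronic_degeneracy = record@body@electronicDegeneracy)
  out
}

.recordFromList <- function(x) {
  if (is.null(x$id) || is.null(x$formula))
    stop("malformed record: id and formula are required")
  orb <- if (!is.null(x$orbitals)) {
    if (is.null(x$orbitals$e_homo) || is.null(x$orbitals$e_lumo))
      stop("malformed record: orbital section without both frontier energies")
    orbitalEnergies(x$orbitals$e_homo, x$orbitals$e_lumo,
                    unit = x$orbitals$unit %||% "hartree")
  }
  chg <- if (!is.null(x$charges)) {
    with(x$charges, chargeSet(atom, z, q_cation, q_neutral, q_anion,
                              scheme = scheme %||% "unspecified"))
  }
  vib <- if (!is.null(x$vibrations)) {
    v <- new("VibrationalSet",
             frequencies = as.numeric(x$vibrations$frequencies),
             droppedImaginary = as.integer(x$vibrations$dropped_imaginary %||% 0L))
    validObject(v); v
  }
  bdy <- if (!is.null(x$body)) {
    rigidBody(x$body$molar_mass,
              as.numeric(x$body$rotational_constants_ghz %||% numeric(0)),
              symmetryNumber = x$body$symmetry_number %||% 1L,
              pressure = x$body$pressure_pa %||% .constants$atm_Pa,
              electronicDegeneracy = x$body$electronic_degeneracy %||% 1L)
  }
  compoundRecord(x$id, x$formula, orbitals = orb, charges = chg,
                 vibrations = vib, body = bdy,
                 provenance = x$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- log dialect -----------------------------------------------------------

.fmtNum <- function(x) formatC(x, digits = 17, format = "g")

.writeLogDialect <- function(record, path) {
  ln <- c(sprintf(" Entering postdft log, compound %s", record@id),
          sprintf(" Stoichiometry    %s", formatFormula(record@formula)))
  if (nzchar(record@provenance))
    ln <- c(ln, sprintf(" Provenance: %s", record@provenance))
  if (!is.null(record@orbitals)) {
    o <- record@orbitals
    ## one filler eigenvalue on each side so extraction of the frontier
    ## pair is exercised, as in real eigenvalue listings
    ln <- c(ln,
      sprintf(" Alpha  occ. eigenvalues --  %s  %s",
              .fmtNum(o@eHomo - 0.25), .fmtNum(o@eHomo)),
      sprintf(" Alpha virt. eigenvalues --  %s  %s",
              .fmtNum(o@eLumo), .fmtNum(o@eLumo + 0.25)))
  }
  if (!is.null(record@charges)) {
    ch <- record@charges
    sym <- .zToSymbol(ch@z)
    for (state in c("cation", "neutral", "anion")) {
      q <- slot(ch, switch(state, cation = "qCation", neutral = "qNeutral",
                           anion = "qAnion"))
      ln <- c(ln, sprintf(" %s charges (%s):", ch@scheme, state),
              sprintf("   %4d  %-2s  %s", ch@atom, sym, .fmtNum(q)),
              sprintf(" Sum of %s charges (%s) = %s", ch@scheme, state,
                      .fmtNum(sum(q))))
    }
  }
  if (!is.null(record@vibrations)) {
    v <- record@vibrations@frequencies
    idx <- split(seq_along(v), ceiling(seq_along(v) / 3))
    ln <- c(ln, vapply(idx, function(i)
      paste(" Frequencies --", paste(.fmtNum(v[i]), collapse = "  ")),
      character(1)))
    if (record@vibrations@droppedImaginary > 0L)
      ln <- c(ln, sprintf(" Dropped imaginary modes  %d",
                          record@vibrations@droppedImaginary))
  }
  if (!is.null(record@body)) {
    b <- record@body
    ln <- c(ln,
      if (length(b@rotationalConstants))
        sprintf(" Rotational constants (GHZ):  %s",
                paste(.fmtNum(b@rotationalConstants), collapse = "  ")),
      sprintf(" Molecular mass:  %s amu", .fmtNum(b@molarMass)),
      sprintf(" Rotational symmetry number  %d", b@symmetryNumber),
      sprintf(" Pressure  %s Pa", .fmtNum(b@pressure)),
      sprintf(" Electronic degeneracy  %d", b@electronicDegeneracy))
  }
  writeLines(c(ln, " Normal termination"), path)
}

.numsOn <- function(line, after) {
  rest <- sub(after, "", line)
  as.numeric(strsplit(trimws(rest), "\\s+")[[1]])
}

.readLogDialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("malformed log: empty file")
  idLine <- grep("^\\s*Entering postdft log, compound\\s+\\S+", lines, value = TRUE)
  if (length(idLine) == 0L) stop("malformed log: no compound header")
  id <- sub("^\\s*Entering postdft log, compound\\s+(\\S+).*", "\\1", idLine[1])
  stoich <- grep("^\\s*Stoichiometry\\s+\\S+", lines, value = TRUE)
  if (length(stoich) == 0L) stop("malformed log: no stoichiometry line")
  formula <- sub("^\\s*Stoichiometry\\s+(\\S+).*", "\\1", stoich[1])
  provLine <- grep("^\\s*Provenance:", lines, value = TRUE)
  prov <- if (length(provLine)) sub("^\\s*Provenance:\\s*", "", provLine[1]) else ""

  occ <- unlist(lapply(grep("eigenvalues --", lines, value = TRUE), function(l) {
    if (grepl("occ\\. eigenvalues --", l)) .numsOn(l, ".*occ\\. eigenvalues --")
  }))
  virt <- unlist(lapply(grep("eigenvalues --", lines, value = TRUE), function(l) {
    if (grepl("virt\\. eigenvalues --", l)) .numsOn(l, ".*virt\\. eigenvalues --")
  }))
  orb <- NULL
  if (length(occ) || length(virt)) {
    if (!length(occ) || !length(virt))
      stop("malformed log: orbital section without both frontier energies")
    orb <- orbitalEnergies(max(occ), min(virt), unit = "hartree")
  }

  chg <- NULL
  hdr <- grep("^\\s*\\S+ charges \\((cation|neutral|anion)\\):", lines)
  if (length(hdr)) {
    blocks <- list()
    scheme <- sub("^\\s*(\\S+) charges.*", "\\1", lines[hdr[1]])
    for (h in hdr) {
      state <- sub("^.*\\((cation|neutral|anion)\\):.*", "\\1", lines[h])
      i <- h + 1L
      rows <- list()
      ## collect rows up to the block's Sum sentinel, skipping stray lines;
      ## a block is parsed fully or rejected, never silently misassigned
      while (i <= length(lines) && !grepl("^\\s*Sum of .* charges", lines[i])) {
        if (grepl("^\\s*\\S+ charges \\((cation|neutral|anion)\\):", lines[i]))
          stop("malformed log: unterminated charge block (", state, ")")
        if (grepl("^\\s*\\d+\\s+[A-Z][a-z]?\\s+-?[0-9]", lines[i])) {
          f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
          rows[[length(rows) + 1L]] <- list(atom = as.integer(f[1]),
                                            sym = f[2], q = as.numeric(f[3]))
        }
        i <- i + 1L
      }
      if (i > length(lines))
        stop("malformed log: unterminated charge block (", state, ")")
      blocks[[state]] <- rows
    }
    need <- c("cation", "neutral", "anion")
    if (!all(need %in% names(blocks)))
      stop("malformed log: charge states incomplete (need cation/neutral/anion)")
    n <- lengths(blocks[need])
    if (length(unique(n)) != 1L)
      stop("malformed log: charge states with unequal atom counts")
    atoms <- vapply(blocks$neutral, `[[`, integer(1), "atom")
    syms <- vapply(blocks$neutral, `[[`, character(1), "sym")
    for (state in c("cation", "anion")) {
      if (!identical(vapply(blocks[[state]], `[[`, integer(1), "atom"), atoms) ||
          !identical(vapply(blocks[[state]], `[[`, character(1), "sym"), syms))
        stop("malformed log: charge states cover different atoms")
    }
    qs <- lapply(need, function(s) vapply(blocks[[s]], `[[`, numeric(1), "q"))
    chg <- chargeSet(atoms, unname(.elementZ[syms]),
                     qCation = qs[[1]], qNeutral = qs[[2]], qAnion = qs[[3]],
                     scheme = scheme)
  }

  freqLines <- grep("^\\s*Frequencies --", lines, value = TRUE)
  vib <- NULL
  if (length(freqLines)) {
    fr <- unlist(lapply(freqLines, .numsOn, after = "^\\s*Frequencies --"))
    drop <- grep("^\\s*Dropped imaginary modes\\s+\\d+", lines, value = TRUE)
    nDrop <- if (length(drop)) as.integer(sub(".*modes\\s+(\\d+).*", "\\1", drop[1])) else 0L
    vib <- new("VibrationalSet", frequencies = fr, droppedImaginary = nDrop)
    validObject(vib)
  }

  massLine <- grep("^\\s*Molecular mass:", lines, value = TRUE)
  bdy <- NULL
  if (length(massLine)) {
    mass <- as.numeric(sub("^\\s*Molecular mass:\\s*(\\S+)\\s*amu.*", "\\1", massLine[1]))
    rotLine <- grep("^\\s*Rotational constants \\(GHZ\\):", lines, value = TRUE)
    rot <- if (length(rotLine))
      .numsOn(rotLine[1], "^\\s*Rotational constants \\(GHZ\\):") else numeric(0)
    symLine <- grep("^\\s*Rotational symmetry number\\s+\\d+", lines, value = TRUE)
    sigma <- if (length(symLine)) as.integer(sub(".*number\\s+(\\d+).*", "\\1", symLine[1])) else 1L
    pLine <- grep("^\\s*Pressure\\s+\\S+\\s+Pa", lines, value = TRUE)
    pres <- if (length(pLine))
      as.numeric(sub("^\\s*Pressure\\s+(\\S+)\\s+Pa.*", "\\1", pLine[1])) else .constants$atm_Pa
    gLine <- grep("^\\s*Electronic degeneracy\\s+\\d+", lines, value = TRUE)
    g <- if (length(gLine)) as.integer(sub(".*degeneracy\\s+(\\d+).*", "\\1", gLine[1])) else 1L
    bdy <- rigidBody(mass, rot, symmetryNumber = sigma, pressure = pres,
                     electronicDegeneracy = g)
  }

  compoundRecord(id, formula, orbitals = orb, charges = chg,
                 vibrations = vib, body = bdy, provenance = prov)
}

#' Read and write compound records
#'
#' Two on-disk formats carry a [CompoundRecord-class]:
#' \describe{
#'   \item{record-json}{A documented JSON schema with keys `id`, `formula`
#'     (Hill-order string), `provenance`, and optional `orbitals`
#'     (`e_homo`, `e_lumo`, `unit`), `charges` (`scheme`, `atom`, `z`,
#'     `q_cation`, `q_neutral`, `q_anion`), `vibrations` (`frequencies`,
#'     `dropped_imaginary`) and `body` (`molar_mass`,
#'     `rotational_constants_ghz`, `symmetry_number`, `pressure_pa`,
#'     `electronic_degeneracy`).}
#'   \item{log-dialect}{A plain-text layout modeled on quantum-chemistry
#'     program logs: `occ.`/`virt.` eigenvalue runs in hartree, per-atom
#'     charge tables (index, symbol, charge) for the cation/neutral/anion
#'     states, `Frequencies --` triples in 1/cm and rigid-body lines. The
#'     reader is tolerant: unrecognized lines are ignored, but a present
#'     block is always parsed fully or rejected, never silently
#'     misassigned.}
#' }
#' `readRecord(writeRecord(r, ...))` is the identity in both formats.
#' Missing optional sections stay absent on re-read; no defaults are
#' invented.
#'
#' @param path File path.
#' @param format `"record-json"` or `"log-dialect"`.
#' @param record A [CompoundRecord-class] (for writing).
#' @return `readRecord`: a validated [CompoundRecord-class];
#'   `writeRecord`: the path, invisibly.
#' @export
readRecord <- function(path, format = c("record-json", "log-dialect")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "record-json") {
    x <- tryCatch(
      jsonlite::read_json(path, simplifyVector = TRUE),
      error = function(e) stop("malformed record-json: ", conditionMessage(e)))
    .recordFromList(x)
  } else {
    .readLogDialect(path)
  }
}

#' @rdname readRecord
#' @export
writeRecord <- function(record, path, format = c("record-json", "log-dialect")) {
  format <- match.arg(format)
  stopifnot(is(record, "CompoundRecord"))
  validObject(record)
  if (format == "record-json") {
    jsonlite::write_json(.recordToList(record), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    .writeLogDialect(record, path)
  }
  invisible(path)
}

#' Write a report table
#'
#' Serializes a result table (one row per compound or per atom) to CSV
#' (RFC-4180, with a `#`-prefixed metadata header) or JSON (an object with
#' `metadata` and `rows`). Column order is preserved as given; metadata
#' always records the constants and mass-table versions so the run can be
#' reproduced.
#'
#' @param table Nonempty data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param metadata Named list merged over the default version fields.
#' @return The path, invisibly.
#' @export
writeReport <- function(table, path, format = c("csv", "json"),
                        metadata = list()) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0L || ncol(table) == 0L)
    stop("report table must be a nonempty data.frame")
  meta <- utils::modifyList(
    list(constants_version = .constantsVersion,
         mass_tables_version = .massTablesVersion),
    metadata)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v, digits = 15),
                                                      collapse = " "),
                              character(1))), con)
    utils::write.csv(table, con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(metadata = meta, rows = table), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
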