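#' @include AllClasses.R
NULL

#' Construct frontier orbital energies
#'
#' @param eHomo,eLumo HOMO/LUMO energies, `eHomo < eLumo`.
#' @param unit `"hartree"` (default) or `"eV"`.
#' @return An [OrbitalEnergies-class] object.
#' @export
#' @examples
#' orbitalEnergies(-0.31875, -0.18960)
orbitalEnergies <- function(eHomo, eLumo, unit = "hartree") {
  new("OrbitalEnergies", eHomo = as.numeric(eHomo),
      eLumo = as.numeric(eLumo), unit = unit)
}

#' Global conceptual-DFT reactivity descriptors
#'
#' Koopmans-type descriptors from frontier orbital energies of a gapped
#' closed-shell molecule:
#' I = -E_HOMO, A = -E_LUMO, gap = I - A = E_LUMO - E_HOMO,
#' electronegativity chi = (I + A)/2, chemical potential mu = -chi (stored
#' signed, negative for bound systems), hardness eta = (I - A)/2, softness
#' S = 1/(2 eta), electrophilicity index omega = mu^2 / (2 eta)
#' (Parr-Szentpaly-Liu). A degenerate input (zero gap) has zero hardness, so
#' softness and electrophilicity are undefined: this is an error, not an
#' infinity.
#'
#' @param orbitals An [OrbitalEnergies-class] object.
#' @return A [GlobalReactivity-class] object in the unit of the input.
#' @export
#' @examples
#' gd <- globalDescriptors(orbitalEnergies(-0.31875, -0.18960))
#' as.data.frame(gd)
globalDescriptors <- function(orbitals) {
  stopifnot(is(orbitals, "OrbitalEnergies"))
  I <- -orbitals@eHomo
  A <- -orbitals@eLumo
  eta <- (I - A) / 2
  if (eta <= 0)
    stop("zero hardness: eHomo equals eLumo, softness and electrophilicity undefined")
  chi <- (I + A) / 2
  mu <- -chi
  new("GlobalReactivity",
      ionizationPotential = I, electronAffinity = A, gap = I - A,
      electronegativity = chi, chemicalPotential = mu, hardness = eta,
      softness = 1 / (2 * eta), electrophilicity = mu^2 / (2 * eta),
      unit = orbitals@unit)
}

#' Convert energies between hartree and eV
#'
#' Exact linear scaling with 1 hartree = 27.211386 eV; identity when the
#' units are equal.
#'
#' @param value Numeric energies.
#' @param from,to `"hartree"` or `"eV"`.
#' @return Converted energies.
#' @export
convertEnergy <- function(value, from = c("hartree", "eV"),
                          to = c("hartree", "eV")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(value)
  if (from == "hartree") value * .constants$hartree_eV
  else value / .constants$hartree_eV
}

#' Rank a compound series by reactivity descriptors
#'
#' Summarizes a series: softest (largest softness), hardest (largest
#' hardness), most electrophilic (largest electrophilicity index) and lowest
#' ionization potential. Orderings are deterministic; ties are broken by
#' compound id, lexicographically ascending.
#'
#' @param reactivities Named list of [GlobalReactivity-class] objects (names
#'   are compound ids).
#' @return List with elements `softest`, `hardest`, `mostElectrophilic`,
#'   `lowestIonization` (single ids) and `table`, a data.frame of descriptor
#'   values ordered by descending softness.
#' @export
seriesRanking <- function(reactivities) {
  if (length(reactivities) == 0L) stop("empty series")
  ids <- names(reactivities)
  if (is.null(ids) || any(!nzchar(ids))) stop("reactivities must be named by compound id")
  tab <- do.call(rbind, lapply(reactivities, as.data.frame))
  tab <- cbind(id = ids, tab, row.names = NULL)
  pick <- function(values, decreasing) {
    o <- order(values, ids, decreasing = c(decreasing, FALSE), method = "radix")
    ids[o[1L]]
  }
  list(
    softest = pick(tab$S, TRUE),
    hardest = pick(tab$eta, TRUE),
    mostElectrophilic = pick(tab$omega, TRUE),
    lowestIonization = pick(tab$I, FALSE),
    table = tab[order(tab$S, tab$id, decreasing = c(TRUE, FALSE),
                      method = "radix"), , drop = FALSE]
  )
}
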