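#' @include AllClasses.R
NULL

#' Construct a charge set for the three electron states
#'
#' @param atom 1-based atom indices.
#' @param z Atomic numbers.
#' @param qCation,qNeutral,qAnion Per-atom charges of the N-1, N and N+1
#'   electron states (same atom order in all three).
#' @param scheme Population-analysis scheme label.
#' @return A [ChargeSet-class] object.
#' @export
chargeSet <- function(atom, z, qCation, qNeutral, qAnion,
                      scheme = "unspecified") {
  new("ChargeSet", atom = as.integer(atom), z = as.integer(z),
      qCation = as.numeric(qCation), qNeutral = as.numeric(qNeutral),
      qAnion = as.numeric(qAnion), scheme = scheme)
}

#' Unit-charge closure of a charge set
#'
#' For charges q = Z - p, removing one electron raises the total charge by
#' exactly +1 and adding one lowers it by 1, so
#' sum(qCation) - sum(qNeutral) = +1 and sum(qNeutral) - sum(qAnion) = +1.
#' Deviations measure the population analysis' numerical noise.
#'
#' @param x A [ChargeSet-class].
#' @return Named numeric: the two closure residuals
#'   (`cation` = sum deviation of the first difference from +1, `anion`
#'   likewise for the second).
#' @export
chargeClosure <- function(x) {
  c(cation = sum(x@qCation) - sum(x@qNeutral) - 1,
    anion  = sum(x@qNeutral) - sum(x@qAnion) - 1)
}

#' Condensed Fukui indices from finite charge differences
#'
#' Charge-based finite-difference condensed Fukui functions for every atom
#' k of a molecule, from the per-atom charges of the N-1 (cation), N
#' (neutral) and N+1 (anion) electron states:
#' \deqn{f^-_k = q_k(N-1) - q_k(N), \quad f^+_k = q_k(N) - q_k(N+1),}
#' \deqn{f^0_k = (f^-_k + f^+_k)/2, \quad \Delta f_k = f^+_k - f^-_k.}
#' Each column sums to 1 when the charge states close to unit total-charge
#' steps; a closure violation beyond `closureTol` raises a diagnostic
#' warning (or an error with `strict = TRUE`) stating the residuals.
#' Negative condensed values, a known artifact of Mulliken-type schemes, are
#' retained and flagged, never clipped.
#'
#' @param charges A [ChargeSet-class].
#' @param closureTol Tolerance on the unit-charge closure sums (default 1e-3).
#' @param strict Escalate closure violations to errors.
#' @return A [FukuiTable-class].
#' @export
#' @examples
#' cs <- chargeSet(1:2, c(6L, 7L), qCation = c(0.7, 0.3),
#'                 qNeutral = c(0, 0), qAnion = c(-0.2, -0.8))
#' as.data.frame(condensedFukui(cs))
condensedFukui <- function(charges, closureTol = 1e-3, strict = FALSE) {
  stopifnot(is(charges, "ChargeSet"))
  resid <- chargeClosure(charges)
  if (any(abs(resid) > closureTol)) {
    msg <- sprintf(
      "charge-closure violation: sum(q[N-1])-sum(q[N]) = %+.6f, sum(q[N])-sum(q[N+1]) = %+.6f (each should be +1 within %g)",
      resid[["cation"]] + 1, resid[["anion"]] + 1, closureTol)
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  fm <- charges@qCation - charges@qNeutral
  fp <- charges@qNeutral - charges@qAnion
  new("FukuiTable",
      atom = charges@atom, z = charges@z,
      fMinus = fm, fPlus = fp, fZero = (fm + fp) / 2, dual = fp - fm,
      negativeFlag = fm < 0 | fp < 0, closureTol = closureTol)
}

#' Radical Fukui index
#'
#' Arithmetic mean of the electron-removal and electron-attachment indices,
#' f0 = (f- + f+)/2: the intrinsic (radical) reactivity of a site.
#'
#' @param fMinus,fPlus Finite condensed indices (vectors recycle).
#' @return f0, elementwise.
#' @export
#' @examples
#' fukuiZero(0.9837, 0)          # 0.49185; prints as 0.4918 at 4 decimals
fukuiZero <- function(fMinus, fPlus) {
  stopifnot(all(is.finite(fMinus)), all(is.finite(fPlus)))
  (fMinus + fPlus) / 2
}

#' Rank atomic sites by condensed Fukui index
#'
#' Orders atoms by descending index for a given attack mode; ties are broken
#' by ascending atom index. Which column answers which mode depends on the
#' labeling convention: under `labeling = "paper"` (default) f- localizes
#' susceptibility to nucleophilic attack and f+ to electrophilic attack, as
#' in some applied reports; `labeling = "standard"` uses the common
#' conceptual-DFT reading (f+ marks the site attacked by a nucleophile,
#' f- the site attacked by an electrophile). The radical mode always ranks
#' on f0. The computation of the indices themselves is convention-free.
#'
#' @param table A [FukuiTable-class].
#' @param mode `"nucleophilic_attack"`, `"electrophilic_attack"` or
#'   `"radical"`.
#' @param labeling `"paper"` or `"standard"`.
#' @return Integer atom indices, most reactive first.
#' @export
rankSites <- function(table,
                      mode = c("nucleophilic_attack", "electrophilic_attack",
                               "radical"),
                      labeling = c("paper", "standard")) {
  stopifnot(is(table, "FukuiTable"))
  mode <- match.arg(mode)
  labeling <- match.arg(labeling)
  column <- switch(mode,
    radical = table@fZero,
    nucleophilic_attack = if (labeling == "paper") table@fMinus else table@fPlus,
    electrophilic_attack = if (labeling == "paper") table@fPlus else table@fMinus)
  table@atom[order(-column, table@atom, method = "radix")]
}
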