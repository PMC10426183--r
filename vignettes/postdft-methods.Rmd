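---
title: "Methods: reactivity descriptors, condensed Fukui indices, RRHO thermochemistry and energetic-material formula metrics"
author: "postDFT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postDFT)
```

# Scope and model

postDFT post-processes electronic-structure results for a series of small
molecules — here a bis-tetrazole acetamide series labelled 6a–6f — into the
four standard desk-side characterizations: global conceptual-DFT reactivity
descriptors, condensed Fukui site reactivity, ideal-gas rigid-rotor/
harmonic-oscillator (RRHO) thermodynamic functions, and molecular-formula
descriptors relevant to energetic materials. It deliberately contains no
electronic-structure engine: the inputs are the quantities such engines
print (frontier orbital energies, per-atom charges of the N−1/N/N+1
electron states, harmonic frequencies, masses and rotational constants),
bundled per compound in a `CompoundRecord`.

# Global reactivity descriptors

For a gapped closed-shell molecule the Koopmans-type approximations
$I = -E_\mathrm{HOMO}$ and $A = -E_\mathrm{LUMO}$ give

$$\chi = \tfrac{1}{2}(I + A),\quad \mu = -\chi,\quad
\eta = \tfrac{1}{2}(I - A),\quad S = \frac{1}{2\eta},\quad
\omega = \frac{\mu^2}{2\eta}.$$

Two conventions deserve a note because published tables are not always
internally consistent about them:

* **Electrophilicity.** We implement the Parr–Szentpály–Liu index
  $\omega = \mu^2/(2\eta)$. Shorthand notations such as "$\mu/2\eta$"
  appear in the applied literature, but tabulated values in this series
  (e.g. $0.254175^2/0.12915 = 0.50023$ for compound 6b) are consistent only
  with the quadratic form, which is also the defined index.
* **Sign of $\mu$.** The chemical potential of a bound system is negative;
  we store it signed and additionally report $|\mu|$ because comparative
  tables usually print the magnitude.
* **Softness.** "$S = 1/2\eta$" is parsed as $1/(2\eta)$, the global
  softness reciprocal to twice the hardness; tabulated softness values in
  the series match this reading.

A degenerate pair ($E_\mathrm{HOMO} = E_\mathrm{LUMO}$) has zero hardness,
leaving $S$ and $\omega$ undefined; construction of such a pair is an error
rather than an infinity. All energies are carried in hartree internally
(1 hartree = 27.211386 eV); conversion is a presentation-layer operation,
and every descriptor transforms covariantly ($\eta$, $\mu$, $\omega$
linearly; $S$ inversely).

`seriesRanking()` orders a series deterministically, breaking exact ties by
compound id, so reports are reproducible byte for byte.

# Condensed Fukui indices

The charge-based finite-difference definition is used: with per-atom
charges $q_k$ of the cation ($N-1$), neutral ($N$) and anion ($N+1$)
states,

$$f^-_k = q_k(N\!-\!1) - q_k(N),\qquad f^+_k = q_k(N) - q_k(N\!+\!1),$$
$$f^0_k = \tfrac{1}{2}(f^-_k + f^+_k),\qquad \Delta f_k = f^+_k - f^-_k.$$

Because total charges step by exactly one electron, each column sums to 1;
the closure residuals are checked against a configurable tolerance
(default $10^{-3}$) and violations produce an explicit diagnostic rather
than silent renormalization. Negative condensed values — a familiar
artifact of Mulliken-type population schemes — are retained and flagged,
never clipped.

**Labeling.** The series' source discussion maps $f^-$ to susceptibility to
*nucleophilic* attack and $f^+$ to *electrophilic* attack, which is the
reverse of the common conceptual-DFT reading. The computation is
convention-free; only `rankSites()` labels depend on it. The default
`labeling = "paper"` reproduces the source's usage, `"standard"` the common
one — a deliberate design choice so neither camp's label is hard-coded.
Atom indexing is 1-based throughout, matching published per-atom tables.

# RRHO thermochemistry

Totals on a temperature grid are assembled from the standard ideal-gas
partition-function terms (CODATA 2018 constants):

* translation: Sackur–Tetrode entropy at the stored standard-state
  pressure, $E_\mathrm{trans} = \tfrac{3}{2}RT$;
* rotation: classical rigid rotor (nonlinear
  $S_\mathrm{rot} = R[\tfrac{3}{2} + \ln(\sqrt{\pi}/\sigma\,
  (T^3/\Theta_A\Theta_B\Theta_C)^{1/2})]$ with
  $\Theta = hB/k_B$; linear and atomic cases handled separately);
* vibration: per harmonic mode with $x = hc\tilde\nu/k_BT$,
  $S = R[x/(e^x-1) - \ln(1-e^{-x})]$ and
  $E = R\,\theta[\tfrac12 + 1/(e^{\theta/T}-1)]$, evaluated in an
  overflow-safe form so the 10 K end of the grid is exact rather than NaN;
* $H(T) = E_\mathrm{trans}+E_\mathrm{rot}+E_\mathrm{vib}+RT$ and
  $G = H - TS$, with entropy in J mol⁻¹ K⁻¹ and H, G in kJ mol⁻¹.

Defaults and toggles: standard state 1 atm (101325 Pa), the convention of
quantum-chemistry program thermochemistry pages (note that standard *molar*
entropies tabulated at 1 bar differ by $R\ln 1.01325 \approx 0.11$
J mol⁻¹ K⁻¹ — argon at 298.15 K is 154.74 at 1 atm and 154.85 at 1 bar);
enthalpy is relative to 0 K with the zero-point energy included by default,
both recorded in the profile; imaginary (non-positive) frequencies are
dropped with a warning and counted, and no quasi-RRHO low-frequency damping
is applied — the plain harmonic sum is the stated model. The default grid
is 10–500 K in 10 K steps.

# Formula and energetic-material descriptors

The formula parser accepts plain concatenated element symbols with
optional counts (case-sensitive, no parentheses or charges — formulas are
the package's structural ceiling by design) and canonicalizes to Hill
order. Two versioned mass tables drive all arithmetic: IUPAC conventional
atomic weights (C 12.011, H 1.008, N 14.007, O 15.999, Cl 35.45) for molar
mass and elemental-analysis percentages, and principal-isotope masses
(¹²C = 12 exactly, ¹H = 1.00782503, ¹⁴N = 14.00307400, ¹⁶O = 15.99491462,
³⁵Cl = 34.96885268) for monoisotopic/exact masses. These reproduce the
series' printed "Anal. Calcd." and exact-mass values to the printed
precision (occasional last-digit differences of 0.01 in published
percentage tables trace to unstated weight-table choices upstream).
Protonated/deprotonated adduct masses shift by one ¹H and one electron
mass (0.00054858 Da), the mass-spectrometry convention; the electron
correction can be disabled for parity with sources that neglect it.

Oxygen balance follows the classic CO₂/H₂O combustion convention

$$\mathrm{OB\%} = \frac{1600\,(n_O - 2n_C - n_H/2)}{M_W},$$

with halogens ignored in the balance (they still weigh in $M_W$); a
`halogen-HX` variant, which lets each halogen consume one hydrogen as HX,
sits behind a flag. The applied default is the literature's usual choice
when a source does not print its formula. Report rounding is half-to-even
at the printed precision, with raw doubles retained internally.

# The synthetic series fixture

`builtinSeries()` reconstructs the six compounds' inputs from their
published values: formulas from the elemental-analysis blocks, orbital
energies as $(-I, -A)$ from the published descriptor table, and — for the
two compounds with published per-atom tables (6d, 6f) — charge triples
built by inverting the Fukui definition (`chargeTripleFromFukui()`:
$q(N) = 0$, $q(N\!-\!1) = f^-$, $q(N\!+\!1) = -f^+$), so the
prose-confirmed rows are regenerated exactly while the remaining index
mass is spread uniformly over the unanchored atoms to keep the unit sum
rules exact. Only rows confirmed unambiguously by the source prose are
anchored; collapsed table rows are excluded.

No harmonic frequencies are published for the series, so the fixture's
vibrational sets are synthetic: $3N-6$ modes per compound, log-uniform on
20–3500 cm⁻¹ under a fixed seed (20230814), with rotational constants
typical of a ~550 Da organic. Consequently thermochemistry over the
fixture is validated by properties (closed-form Sackur–Tetrode agreement,
monotonicity of $S$ and $H$, the $G = H - TS$ identity, equipartition and
symmetry-number limits), *not* by comparison to any published curve; a
passing suite demonstrates the statistical mechanics is right, and says
nothing about the real compounds' absolute entropies. The same caveat
applies to what the randomized records (`randomRecord()`) can show: they
exercise invariants and round-trips, not chemistry.

# Numerical choices

* Half-to-even rounding for all report parity checks; raw doubles kept.
* Closure tolerance default $10^{-3}$ electrons, the scale of printed
  charge round-off; fixtures close to $10^{-12}$ by construction.
* Vibrational terms evaluated via $e^{-x}$ forms, finite for all $x$.
* Record round-trips write floats at 17 significant digits so
  `readRecord(writeRecord(r))` is lossless in both the JSON schema and the
  text-log dialect; the log reader ignores unrecognized lines but parses a
  present block fully or rejects it — never a silent misassignment.
* Test and regression problem sizes (100 seeded round-trip records, 50-pair
  identity sweeps, five-compound thermo grids) were chosen as the smallest
  sets that exercise every code path and invariant; the full suite runs in
  well under a minute.

# Known limitations

Formulas only (no SMILES/InChI, no isotope patterns); no anharmonic or
hindered-rotor corrections; no heat-of-formation or detonation-performance
prediction; the log-dialect reader targets this package's own writer
grammar (modeled on common quantum-chemistry text layouts), not the full
output of any particular engine.
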