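Package: postDFT
Title: Post-Processing of Quantum-Chemical Results for Reactivity and
    Energetic-Material Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the standard desk-side characterization of a small-
    molecule series from electronic-structure outputs: global conceptual-DFT
    reactivity descriptors (ionization potential, electron affinity,
    electronegativity, chemical potential, hardness, softness,
    electrophilicity) from frontier orbital energies; condensed Fukui site
    reactivity indices from atomic charges of the N-1/N/N+1 electron states;
    ideal-gas rigid-rotor/harmonic-oscillator thermodynamic functions S(T),
    H(T) and G(T) from harmonic frequencies; and molecular-formula
    descriptors (monoisotopic and adduct masses, elemental-analysis
    percentages, nitrogen content, oxygen balance) relevant to energetic
    materials. Includes tolerant readers for quantum-chemistry text logs, a
    JSON record schema, report writers, and a synthetic fixture generator
    for a bis-tetrazole acetamide series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'formula.R'
    'reactivity.R'
    'fukui.R'
    'thermochem.R'
    'qc_io.R'
    'synthetic.R'
    'pipeline.R'
    'show-methods.R'
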