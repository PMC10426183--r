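## Physical constants (CODATA 2018, exact where the SI defines them) and
## the atomic mass tables used throughout the package.

.constants <- list(
  h    = 6.62607015e-34,    # Planck, J s
  c    = 2.99792458e8,      # speed of light, m/s
  kB   = 1.380649e-23,      # Boltzmann, J/K
  NA_  = 6.02214076e23,     # Avogadro, 1/mol
  R    = 8.314462618,       # gas constant, J/(mol K)
  hartree_eV  = 27.211386,  # 1 hartree in eV
  electronDa  = 0.000548579909, # electron mass, Da
  atm_Pa = 101325           # standard atmosphere, Pa
)

.constantsVersion <- "CODATA-2018"

## Standard atomic weights: IUPAC conventional (abridged) values.
.averageWeights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403163, Na = 22.98976928, Mg = 24.305, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, K = 39.0983, Ca = 40.078,
  Ar = 39.948, Br = 79.904, I = 126.90447
)

## Most-abundant-isotope (principal) masses in Da.
.principalIsotopeMasses <- c(
  H = 1.00782503207, B = 11.00930536, C = 12.0, N = 14.0030740048,
  O = 15.9949146196, F = 18.9984031627, Na = 22.9897692820,
  Mg = 23.985041697, Si = 27.97692653465, P = 30.97376199842,
  S = 31.9720711744, Cl = 34.968852682, K = 38.9637064864,
  Ca = 39.962590863, Ar = 39.9623831237, Br = 78.9183376,
  I = 126.9044719
)

.massTablesVersion <- "IUPAC-conventional-2021/AME-principal-isotopes"
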