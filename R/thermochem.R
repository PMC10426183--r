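#' @include AllClasses.R
NULL

#' Construct a vibrational mode set
#'
#' Non-positive (imaginary) wavenumbers are not physical vibrations of a
#' minimum-energy structure: they are dropped with a warning and counted in
#' `droppedImaginary`.
#'
#' @param frequencies Harmonic wavenumbers in 1/cm.
#' @return A [VibrationalSet-class].
#' @export
vibrationalSet <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  bad <- !is.finite(frequencies) | frequencies <= 0
  if (any(bad))
    warning(sprintf("dropped %d non-positive/imaginary mode(s)", sum(bad)),
            call. = FALSE)
  new("VibrationalSet", frequencies = frequencies[!bad],
      droppedImaginary = sum(bad))
}

#' Construct rigid-body data
#'
#' @param molarMass Molar mass, g/mol.
#' @param rotationalConstants Rotational constants in GHz: three for a
#'   nonlinear top, one for a linear molecule, none for an atom.
#' @param symmetryNumber Rotational symmetry number.
#' @param pressure Standard-state pressure in Pa (default 1 atm).
#' @param electronicDegeneracy Ground-state electronic degeneracy.
#' @return A [RigidBody-class].
#' @export
#' @examples
#' rigidBody(39.948)   # a monatomic gas (argon-like)
rigidBody <- function(molarMass, rotationalConstants = numeric(0),
                      symmetryNumber = 1L, pressure = .constants$atm_Pa,
                      electronicDegeneracy = 1L) {
  new("RigidBody", molarMass = as.numeric(molarMass),
      rotationalConstants = as.numeric(rotationalConstants),
      symmetryNumber = as.integer(symmetryNumber),
      pressure = as.numeric(pressure),
      electronicDegeneracy = as.integer(electronicDegeneracy))
}

#' Harmonic-oscillator vibrational contributions
#'
#' Per-mode harmonic-oscillator terms summed over all modes, with
#' x = h c nu / (k_B T) (nu in 1/cm):
#' \deqn{S_{vib} = R \sum_i [x_i/(e^{x_i}-1) - \ln(1-e^{-x_i})]}
#' \deqn{E_{vib} = R \sum_i \theta_i [1/2 + 1/(e^{\theta_i/T}-1)]}
#' where theta = h c nu / k_B is the vibrational temperature; the 1/2 term
#' is the zero-point energy, toggleable via `zpe`. The heat capacity is the
#' Einstein form Cv = R sum x^2 e^x / (e^x - 1)^2. Evaluation is overflow-
#' safe at low T (large x), where every term decays to zero.
#'
#' @param vib A [VibrationalSet-class].
#' @param temperature Temperature in K, > 0 (scalar).
#' @param zpe Include the zero-point term in the energy.
#' @return List: `S` (J/(mol K)), `E` (J/mol), `Cv` (J/(mol K)).
#' @export
vibrationalTerms <- function(vib, temperature, zpe = TRUE) {
  stopifnot(is(vib, "VibrationalSet"))
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive value")
  R <- .constants$R
  theta <- .constants$h * (.constants$c * 100) * vib@frequencies / .constants$kB
  x <- theta / temperature
  emx <- exp(-x)
  ## x/(e^x - 1) = x e^-x / (1 - e^-x); safe for large x
  sTerm <- x * emx / (1 - emx) - log1p(-emx)
  eTherm <- theta * emx / (1 - emx)
  cvTerm <- x^2 * emx / (1 - emx)^2
  list(
    S = R * sum(sTerm),
    E = R * (sum(eTherm) + if (zpe) sum(theta) / 2 else 0),
    Cv = R * sum(cvTerm)
  )
}

#' Translational and rotational contributions
#'
#' Ideal-gas translational entropy via the Sackur-Tetrode equation at the
#' body's standard-state pressure, and classical rigid-rotor rotational
#' entropy:
#' \deqn{S_{trans} = R[\ln((2\pi m k T/h^2)^{3/2} kT/P) + 5/2]}
#' \deqn{S_{rot}^{nonlin} = R[3/2 + \ln(\sqrt{\pi}/\sigma\,
#'   (T^3/(\Theta_A\Theta_B\Theta_C))^{1/2})]}
#' with rotational temperatures Theta = h B / k_B. A linear molecule uses
#' q_rot = T/(sigma Theta) with E_rot = RT; an atom has no rotational terms.
#' Translational energy is 3/2 RT always; rotational energy 3/2 RT
#' (nonlinear), RT (linear), 0 (atom).
#'
#' @param body A [RigidBody-class].
#' @param temperature Temperature in K (scalar, > 0).
#' @return List: `S_trans`, `S_rot` (J/(mol K)), `E_trans`, `E_rot` (J/mol).
#' @export
#' @examples
#' ar <- rigidBody(39.948)
#' translationalRotationalTerms(ar, 298.15)$S_trans  # 154.85 J/(mol K)
translationalRotationalTerms <- function(body, temperature) {
  stopifnot(is(body, "RigidBody"))
  if (length(temperature) != 1L || !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive value")
  k <- .constants
  m <- body@molarMass / 1000 / k$NA_           # kg per molecule
  qt <- (2 * pi * m * k$kB * temperature / k$h^2)^1.5 *
    k$kB * temperature / body@pressure
  sTrans <- k$R * (log(qt) + 2.5)
  nrot <- length(body@rotationalConstants)
  if (nrot == 0L) {
    sRot <- 0; eRot <- 0
  } else {
    thetas <- k$h * body@rotationalConstants * 1e9 / k$kB
    if (nrot == 1L) {
      qr <- temperature / (body@symmetryNumber * thetas)
      sRot <- k$R * (log(qr) + 1)
      eRot <- k$R * temperature
    } else {
      qr <- sqrt(pi) / body@symmetryNumber *
        sqrt(temperature^3 / prod(thetas))
      sRot <- k$R * (log(qr) + 1.5)
      eRot <- 1.5 * k$R * temperature
    }
  }
  list(S_trans = sTrans, S_rot = sRot,
       E_trans = 1.5 * k$R * temperature, E_rot = eRot)
}

#' Thermodynamic profile on a temperature grid
#'
#' Rigid-rotor/harmonic-oscillator ideal-gas totals per grid point:
#' S = S_trans + S_rot + S_vib + R ln(g_el), H = E_trans + E_rot + E_vib +
#' RT (ZPE included in E_vib when `zpe = TRUE`, recorded in the result) and
#' G = H - T S. Entropy is reported in J/(mol K), H and G in kJ/mol.
#'
#' @param vib A [VibrationalSet-class].
#' @param body A [RigidBody-class].
#' @param temperatures Positive ascending grid in K; default 10-500 K in
#'   steps of 10 K.
#' @param zpe Include the zero-point vibrational energy in H.
#' @return A [ThermoProfile-class].
#' @export
thermoProfile <- function(vib, body, temperatures = seq(10, 500, by = 10),
                          zpe = TRUE) {
  if (length(temperatures) == 0L) stop("empty temperature grid")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop("temperatures must be positive")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperature grid must be strictly ascending")
  R <- .constants$R
  g <- body@electronicDegeneracy
  S <- H <- numeric(length(temperatures))
  for (i in seq_along(temperatures)) {
    Tk <- temperatures[i]
    vt <- vibrationalTerms(vib, Tk, zpe = zpe)
    tr <- translationalRotationalTerms(body, Tk)
    S[i] <- tr$S_trans + tr$S_rot + vt$S + R * log(g)
    H[i] <- (tr$E_trans + tr$E_rot + vt$E + R * Tk) / 1000
  }
  new("ThermoProfile", temperature = as.numeric(temperatures),
      entropy = S, enthalpy = H, gibbs = H - temperatures * S / 1000,
      zpeIncluded = zpe, pressure = body@pressure)
}
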