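#' Ion species for GHK analysis
#'
#' @param name species label (e.g. `"K"`, `"Ca"`).
#' @param valence integer valence, non-zero.
#' @param conc_cyt,conc_lum concentrations on the cytosolic and luminal
#'   sides (mM, >= 0; used as activities).
#' @param permeability relative permeability P (dimensionless, >= 0).
#' @return object of class `ion_species`.
#' @examples
#' ion_species("K", 1, conc_cyt = 150, conc_lum = 0)
#' @export
ion_species <- function(name, valence, conc_cyt, conc_lum, permeability = 1) {
  stopifnot(is.numeric(valence), length(valence) == 1L, valence == round(valence))
  if (valence == 0) stop("valence must be non-zero")
  stopifnot(conc_cyt >= 0, conc_lum >= 0, permeability >= 0)
  structure(list(name = as.character(name), valence = as.integer(valence),
                 conc_cyt = conc_cyt, conc_lum = conc_lum,
                 permeability = permeability),
            class = "ion_species")
}

#' GHK setup: species mixture and temperature
#'
#' The voltage convention throughout is V = phi_cytosol - phi_lumen
#' (vacuolar electrophysiology standard); positive current is carried by
#' net cation movement cytosol-to-lumen.
#'
#' @param species list of [ion_species()] (at least one with
#'   permeability > 0).
#' @param temperature kelvin (default 298.15).
#' @return object of class `ghk_setup`.
#' @export
ghk_setup <- function(species, temperature = 298.15) {
  if (inherits(species, "ion_species")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "ion_species")),
            temperature > 0)
  if (!any(vapply(species, `[[`, numeric(1), "permeability") > 0))
    stop("at least one species must have positive permeability")
  structure(list(species = species, temperature = temperature,
                 convention = "V = phi_cytosol - phi_lumen"),
            class = "ghk_setup")
}

#' GHK flux of one species
#'
#' Constant-field (Goldman-Hodgkin-Katz) charge-weighted flux
#' \deqn{\Phi = P z^2 \frac{F V}{R T}\,
#'       \frac{[X]_{cyt} - [X]_{lum} e^{-zFV/RT}}{1 - e^{-zFV/RT}},}
#' with the analytic limit \eqn{\Phi \to P z ([X]_{cyt} - [X]_{lum})} as
#' V -> 0 taken via series expansion for |zFV/RT| < 1e-6 (continuous to
#' better than 1e-10 of scale).  Sign: positive = net cation charge
#' moving cytosol-to-lumen.  Multiplying by the Faraday constant and
#' summing species gives the GHK current ([total_current()]).
#'
#' @param species an [ion_species()].
#' @param voltage transmembrane voltage (V), finite.
#' @param temperature kelvin.
#' @return flux in (permeability x mM) units.
#' @export
ghk_flux <- function(species, voltage, temperature = 298.15) {
  stopifnot(inherits(species, "ion_species"), temperature > 0)
  if (any(!is.finite(voltage))) stop("voltage must be finite")
  z <- species$valence
  P <- species$permeability
  cc <- species$conc_cyt
  cl <- species$conc_lum
  u <- z * .FARADAY * voltage / (.RGAS * temperature)
  small <- abs(u) < 1e-6
  phi <- numeric(length(u))
  if (any(small)) {
    us <- u[small]
    ## P z g(u) (cc - cl e^{-u}), g(u) = u/(1-e^{-u}) = 1 + u/2 + u^2/12 + ...
    phi[small] <- P * z * (1 + us / 2 + us^2 / 12) *
      (cc - cl * (1 - us + us^2 / 2))
  }
  if (any(!small)) {
    ub <- u[!small]  # = z F V / RT, so P z^2 (FV/RT) = P z ub
    phi[!small] <- P * z * ub * (cc - cl * exp(-ub)) / (-expm1(-ub))
  }
  phi
}

#' Total GHK current of a mixture
#'
#' Sum of the species' charge-weighted fluxes times the Faraday
#' constant; strictly increasing in voltage whenever some permeant
#' species is present on at least one side.
#'
#' @param setup a [ghk_setup()].
#' @param voltage voltage(s) in volts.
#' @return current (arbitrary units), same length as `voltage`.
#' @export
total_current <- function(setup, voltage) {
  stopifnot(inherits(setup, "ghk_setup"))
  fl <- vapply(setup$species, ghk_flux, numeric(length(voltage)),
               voltage = voltage, temperature = setup$temperature)
  .FARADAY * rowSums(matrix(fl, nrow = length(voltage)))
}

#' Reversal potential of a GHK mixture
#'
#' The voltage at which the total GHK current is zero, found by Brent
#' root search on the (monotone) current-voltage relation.
#'
#' @param setup a [ghk_setup()].
#' @param bracket search interval in volts.
#' @param tol root tolerance (volts).
#' @return reversal potential in volts (convention
#'   V = phi_cytosol - phi_lumen).
#' @examples
#' k <- ion_species("K", 1, 150, 15)
#' reversal_potential(ghk_setup(k))  # Nernst: about -0.0592 V
#' @export
reversal_potential <- function(setup, bracket = c(-0.5, 0.5), tol = 1e-12) {
  stopifnot(inherits(setup, "ghk_setup"), length(bracket) == 2L,
            bracket[1] < bracket[2])
  f <- function(v) total_current(setup, v)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (sign(flo) == sign(fhi) && flo != 0 && fhi != 0)
    stop("total current does not change sign on [", bracket[1], ", ",
         bracket[2], "] V (I = ", signif(flo, 4), " and ", signif(fhi, 4), ")")
  uniroot(f, bracket, tol = tol)$root
}

#' Bi-ionic relative permeability from a reversal potential
#'
#' Under bi-ionic conditions (species A on the cytosolic side, species B
#' on the luminal side) the zero-current condition at the measured
#' reversal potential fixes the permeability ratio:
#' \deqn{P_B / P_A = -\Phi_A(P{=}1, V_{rev}) / \Phi_B(P{=}1, V_{rev}),}
#' whose V_rev -> 0 limit is \eqn{(z_A [A]_{cyt}) / (z_B [B]_{lum})}.
#' For 150 mM K+ (cytosol) against 15 mM Ca2+ (lumen) reversing at 0 mV
#' this gives P_Ca/P_K = 5 — the textbook "5:1" relative permeability,
#' obtained even though it implies nothing about single-file pores where
#' the underlying independence assumption fails.
#'
#' @param ion_a cytosolic-side species ([ion_species()]; its luminal
#'   concentration should be 0 for a true bi-ionic condition).
#' @param ion_b luminal-side species.
#' @param v_rev measured reversal potential (V).
#' @param temperature kelvin.
#' @return the ratio P_B / P_A.
#' @examples
#' k <- ion_species("K", 1, conc_cyt = 150, conc_lum = 0)
#' ca <- ion_species("Ca", 2, conc_cyt = 0, conc_lum = 15)
#' bi_ionic_permeability_ratio(k, ca, 0)  # 5
#' @export
bi_ionic_permeability_ratio <- function(ion_a, ion_b, v_rev = 0,
                                        temperature = 298.15) {
  stopifnot(inherits(ion_a, "ion_species"), inherits(ion_b, "ion_species"),
            is.finite(v_rev))
  unit <- function(s) {
    s$permeability <- 1
    s
  }
  phi_a <- ghk_flux(unit(ion_a), v_rev, temperature)
  phi_b <- ghk_flux(unit(ion_b), v_rev, temperature)
  if (phi_a == 0 || phi_b == 0)
    stop("degenerate concentrations: one species carries no flux at ",
         "V_rev, the ratio is undetermined")
  ratio <- -phi_a / phi_b
  if (ratio <= 0)
    stop("no positive permeability ratio solves zero current at V_rev = ",
         v_rev, " V (both fluxes have the same direction)")
  ratio
}
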