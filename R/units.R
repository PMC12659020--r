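# Internal unit system: Angstrom / eV / amu, with the derived dynamical time
# unit sqrt(amu A^2 / eV) = 10.1805057 fs.  User-facing quantities are fs
# (time), K (temperature), bar (pressure), g/cm^3 (density), A^2/ps
# (diffusion); conversions happen only at the boundary.

.kB_eV <- 8.617333262e-5          # Boltzmann constant, eV/K
.time_fs <- 10.180505710774743    # fs per internal time unit
.bar_evA3 <- 6.241509074460763e-7 # (eV/A^3) per bar
.avogadro <- 6.02214076e23
.water_molar_mass <- 18.015       # g/mol

.element_mass <- c(H = 1.008, O = 15.999)

#' Unit system used by the package
#'
#' Returns the package's unit system: internal units are Angstrom (length),
#' eV (energy) and amu (mass), from which the internal time unit
#' \eqn{\sqrt{\mathrm{amu}\,\mathrm{\AA}^2/\mathrm{eV}} \approx 10.18} fs
#' follows.  The returned object carries the physical constants and
#' convert-in/convert-out closures for time (fs) and pressure (bar); both
#' conversions round-trip exactly.
#'
#' @return An object of class `unit_system` with elements `kB` (eV/K),
#'   `time_fs` (fs per internal time unit), `bar_evA3` (eV/A^3 per bar),
#'   and functions `to_internal(x, quantity)` / `from_internal(x, quantity)`
#'   for `quantity` in `"time"` (fs) and `"pressure"` (bar).
#' @examples
#' u <- unit_system()
#' u$from_internal(u$to_internal(0.5, "time"), "time")  # 0.5 fs
#' @export
unit_system <- function() {
  to_internal <- function(x, quantity = c("time", "pressure")) {
    quantity <- match.arg(quantity)
    switch(quantity, time = x / .time_fs, pressure = x * .bar_evA3)
  }
  from_internal <- function(x, quantity = c("time", "pressure")) {
    quantity <- match.arg(quantity)
    switch(quantity, time = x * .time_fs, pressure = x / .bar_evA3)
  }
  structure(list(kB = .kB_eV, time_fs = .time_fs, bar_evA3 = .bar_evA3,
                 avogadro = .avogadro, water_molar_mass = .water_molar_mass,
                 to_internal = to_internal, from_internal = from_internal),
            class = "unit_system")
}

#' Cubic box edge from molecular density
#'
#' Computes the edge of a cubic box holding `n_molecules` molecules of molar
#' mass `molar_mass` at mass density `rho`:
#' \eqn{L = (n M / (\rho N_A))^{1/3}} expressed in Angstrom.  126 water
#' molecules at the experimental density 0.997 g/cm^3 give 15.577 A.
#'
#' @param n_molecules number of molecules (>= 1)
#' @param rho mass density in g/cm^3 (> 0)
#' @param molar_mass molar mass in g/mol (default: water, 18.015)
#' @return box edge in Angstrom
#' @seealso [density_from_box()] for the inverse
#' @export
box_edge_from_density <- function(n_molecules, rho,
                                  molar_mass = .water_molar_mass) {
  if (n_molecules < 1 || rho <= 0 || molar_mass <= 0)
    stop("n_molecules must be >= 1 and rho, molar_mass positive")
  v_cm3 <- n_molecules * molar_mass / (rho * .avogadro)
  (v_cm3)^(1 / 3) * 1e8
}

#' Molecular density from a cubic box edge
#'
#' Inverse of [box_edge_from_density()]: mass density in g/cm^3 of
#' `n_molecules` molecules in a cubic box of edge `edge` Angstrom.
#'
#' @param n_molecules number of molecules
#' @param edge cubic box edge in Angstrom
#' @param molar_mass molar mass in g/mol
#' @return density in g/cm^3
#' @export
density_from_box <- function(n_molecules, edge,
                             molar_mass = .water_molar_mass) {
  if (n_molecules < 1 || edge <= 0) stop("inputs must be positive")
  n_molecules * molar_mass / (.avogadro * (edge * 1e-8)^3)
}

.masses_of <- function(elements) {
  m <- .element_mass[elements]
  if (anyNA(m))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  unname(m)
}
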