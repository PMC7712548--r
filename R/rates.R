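## Back-of-the-envelope physical estimators for every rate constant and
## resistance in the analysis: diffusive capture, drift feeding, Arrhenius
## association/dissociation, pore + access resistance, continuum
## conductance/permeability, and the one-sided bulk voltage drop.
## Every estimator returns a transport_estimate record (value + echoed
## inputs) so fitted and estimated rates can be compared in reports.

transport_estimate <- function(value, unit, formula_id, inputs) {
  if (!is.finite(value) || value < 0)
    stop(sprintf("%s: estimate must be finite and non-negative", formula_id),
         call. = FALSE)
  structure(list(value = value, unit = unit, formula_id = formula_id,
                 inputs = inputs),
            class = "transport_estimate")
}

#' @export
print.transport_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4g %s\n", x$formula_id, x$value, x$unit))
  cat("  inputs:", paste(sprintf("%s = %.4g", names(x$inputs),
                                 unlist(x$inputs)), collapse = ", "), "\n")
  invisible(x)
}

#' Diffusive capture rate into the pore mouth
#'
#' kb0 = Theta D c ap: the rate at which ions diffuse from bulk into a
#' capture region of radius `ap`.  The solid-angle factor Theta is 4 for a
#' circular absorbing disc (default), 2 pi for a hemispherical pore mouth,
#' 4 pi for capture by a sphere in solution.
#'
#' @param D diffusion coefficient, nm^2/ns.
#' @param c_per_nm3 bulk concentration, ions/nm^3.
#' @param ap capture (effective pore) radius, nm.
#' @param theta solid-angle factor (4, 2 pi, or 4 pi).
#' @return A `transport_estimate` in ions/ns (~0.5 for the defaults).
#' @examples
#' capture_rate()$value  # ~0.47
#' @export
capture_rate <- function(D = ion_species()$diffusion_nm2_ns,
                         c_per_nm3 = mol_per_L_to_per_nm3(1),
                         ap = pore_geometry()$effective_radius,
                         theta = 4) {
  stopifnot(D >= 0, c_per_nm3 >= 0, ap >= 0, theta >= 0)
  transport_estimate(theta * D * c_per_nm3 * ap, "ions/ns", "capture_rate",
                     list(theta = theta, D = D, c_per_nm3 = c_per_nm3, ap = ap))
}

#' Drift-feed coefficient of the bulk supply
#'
#' kappa_b = pi ap^2 / (q gamma_p hp): the voltage coefficient of the
#' drift-fed bulk supply rate, obtained by equating the pore-dominated
#' continuum current to the rate of ions the bulk drift must deliver.
#'
#' @param ap effective pore radius, nm.
#' @param gamma_p pore resistivity, Ohm m (the single-carrier convention is
#'   twice the bulk KCl value).
#' @param hp effective pore length, nm.
#' @return A `transport_estimate` in ions/(V ns); multiply by 1e9 for
#'   ions/(V s).
#' @examples
#' drift_feed_coefficient()$value * 1e9  # ~1.4e9 ions/(V s)
#' @export
drift_feed_coefficient <- function(ap = pore_geometry()$effective_radius,
                                   gamma_p = 2 * conditions()$bulk_resistivity,
                                   hp = pore_geometry()$effective_length) {
  stopifnot(ap >= 0, gamma_p > 0, hp > 0)
  ## SI evaluation, converted to ions/(V ns)
  kappa_si <- pi * (ap * 1e-9)^2 / (phys_constants$e * gamma_p * (hp * 1e-9))
  transport_estimate(kappa_si * 1e-9, "ions/(V ns)", "drift_feed_coefficient",
                     list(ap = ap, gamma_p = gamma_p, hp = hp))
}

#' Barrierless dissociation rate from the drift picture
#'
#' kd = mu exp(-Ud) E_p / Delta_p with E_p = V / hp: an ion in the internal
#' site of length Delta_p drifts out under the pore field, with an optional
#' Arrhenius exit barrier Ud (kBT).  Linear in voltage.
#'
#' @param ion an [ion_species()] (mobility).
#' @param Ud exit barrier, kBT.
#' @param V applied voltage, V.
#' @param hp effective pore length (field drop distance), nm.
#' @param delta_p internal-site length, nm.
#' @return A `transport_estimate` in ions/ns (~76 at 1 V for
#'   Delta_p = hp = 1 nm; ~190 for Delta_p = 0.4 nm).
#' @examples
#' dissociation_rate(V = 1)$value  # ~190
#' @export
dissociation_rate <- function(ion = ion_species(), Ud = 0, V = 1,
                              hp = pore_geometry()$effective_length,
                              delta_p = pore_geometry()$internal_site_length) {
  stopifnot(Ud >= 0, V >= 0, hp > 0, delta_p > 0)
  Ep <- V / (hp * 1e-9)                        # V/m
  vd <- ion$mobility * exp(-Ud) * Ep           # m/s
  transport_estimate(vd / (delta_p * 1e-9) * 1e-9, "ions/ns", "dissociation_rate",
                     list(mu = ion$mobility, Ud = Ud, V = V, hp = hp,
                          delta_p = delta_p))
}

#' Arrhenius-suppressed rate
#'
#' k = k0 exp(-U) for a barrier U in kBT.
#'
#' @param k0 barrierless rate, ions/ns.
#' @param U barrier height, kBT.
#' @return Rate in ions/ns.
#' @export
arrhenius_rate <- function(k0, U) {
  stopifnot(k0 >= 0, U >= 0)
  k0 * exp(-U)
}

#' Pore plus access resistance of a cylindrical pore
#'
#' R = gamma (1 / (2 ap) + hp / (pi ap^2)) for a homogeneous medium: the
#' two-sided access term plus the cylindrical pore term.  `hp = 0` leaves
#' the pure (two-sided) access resistance.
#'
#' @param gamma resistivity, Ohm m.
#' @param ap pore radius, nm.
#' @param hp pore length, nm.
#' @return Resistance in Ohm.
#' @examples
#' pore_plus_access_resistance(0.071, 1, 1)  # ~5.8e7 Ohm
#' @export
pore_plus_access_resistance <- function(gamma = conditions()$bulk_resistivity,
                                        ap = pore_geometry()$effective_radius,
                                        hp = pore_geometry()$effective_length) {
  stopifnot(gamma > 0, ap > 0, hp >= 0)
  gamma * (1 / (2 * ap * 1e-9) + hp * 1e-9 / (pi * (ap * 1e-9)^2))
}

#' One-sided access resistance
#'
#' Ra = gamma / (4 ap): the convergence resistance of the bulk on one side
#' of the membrane.
#'
#' @inheritParams pore_plus_access_resistance
#' @return Resistance in Ohm.
#' @export
access_resistance <- function(gamma = conditions()$bulk_resistivity,
                              ap = pore_geometry()$effective_radius) {
  stopifnot(gamma > 0, ap > 0)
  gamma / (4 * ap * 1e-9)
}

#' Continuum pore conductance and permeability
#'
#' Gp = q c_p mu_p A_p / hp (conductance) and Pp = D_p / hp (permeability):
#' the continuum-limit transport coefficients of the pore interior.
#'
#' @param c_p_per_nm3 pore concentration, ions/nm^3.
#' @param mu_p pore mobility, m^2/(V s).
#' @param Ap pore area, nm^2.
#' @param hp pore length, nm.
#' @return Conductance in siemens.
#' @export
continuum_pore_conductance <- function(c_p_per_nm3, mu_p, Ap, hp) {
  stopifnot(c_p_per_nm3 >= 0, mu_p >= 0, Ap >= 0, hp > 0)
  phys_constants$e * (c_p_per_nm3 * 1e27) * mu_p * (Ap * 1e-18) / (hp * 1e-9)
}

#' @rdname continuum_pore_conductance
#' @param D_p pore diffusion coefficient, nm^2/ns.
#' @return `continuum_permeability()`: permeability in nm/ns.
#' @export
continuum_permeability <- function(D_p, hp) {
  stopifnot(D_p >= 0, hp > 0)
  D_p / hp
}

#' One-sided bulk (access) voltage drop
#'
#' Vb = pi ap gamma_b V / (4 gamma_p hp): the share of the applied voltage
#' that drops in the bulk on one side when the pore resistance dominates.
#' Returned both in volts and in thermal units (q Vb / kBT).
#'
#' @param V applied voltage, V.
#' @param ap effective pore radius, nm.
#' @param gamma_b bulk resistivity, Ohm m.
#' @param gamma_p pore resistivity, Ohm m.
#' @param hp effective pore length, nm.
#' @param cond a [conditions()] for the thermal voltage.
#' @return List with `Vb` (V) and `Vb_kBT` (~1.5 at 1 V for the defaults).
#' @examples
#' bulk_voltage_drop(1)$Vb_kBT  # ~1.5
#' @export
bulk_voltage_drop <- function(V, ap = pore_geometry()$effective_radius,
                              gamma_b = conditions()$bulk_resistivity,
                              gamma_p = 2 * conditions()$bulk_resistivity,
                              hp = pore_geometry()$effective_length,
                              cond = conditions()) {
  stopifnot(V >= 0, ap > 0, gamma_b > 0, gamma_p > 0, hp > 0)
  Vb <- pi * ap * gamma_b * V / (4 * gamma_p * hp)
  list(Vb = Vb, Vb_kBT = Vb / thermal_voltage(cond))
}

#' Table of analytic transport estimates
#'
#' Evaluates the full set of back-of-the-envelope numbers for a
#' configuration: capture rate, the drift-feed coefficient under the three
#' standard parameter conventions, barrierless dissociation rates at 1 V,
#' the one-sided bulk voltage drop, pore plus access resistance, the
#' diffusion-limited voltage window, the entropic penalties, and the pore
#' radius at 10% strain.
#'
#' @param config a configuration list ([default_config()]).
#' @param V reference voltage for the voltage-dependent entries, V.
#' @return Data frame with columns `quantity`, `value`, `unit`.
#' @examples
#' estimates_table()
#' @export
estimates_table <- function(config = default_config(), V = 1) {
  cond <- config$conditions; ion <- config$ion; geom <- config$geometry
  gb <- cond$bulk_resistivity
  ap <- geom$effective_radius; hp <- geom$effective_length
  win <- diffusion_window(theta = 4, cond = cond, geometry = geom)
  rows <- list(
    c("capture_rate", capture_rate(ion$diffusion_nm2_ns,
                                   cond$concentration_per_nm3, ap)$value, "ions/ns"),
    c("drift_feed_K_resistivity",
      drift_feed_coefficient(ap, 2 * gb, hp)$value * 1e9, "ions/(V s)"),
    c("drift_feed_KCl_resistivity",
      drift_feed_coefficient(ap, gb, hp)$value * 1e9, "ions/(V s)"),
    c("drift_feed_ap_0.13",
      drift_feed_coefficient(0.13, 2 * gb, hp)$value * 1e9, "ions/(V s)"),
    c("kd0_delta_hp", dissociation_rate(ion, 0, V, hp, hp)$value, "ions/ns"),
    c("kd0_delta_site", dissociation_rate(ion, 0, V, hp,
                                          geom$internal_site_length)$value, "ions/ns"),
    c("bulk_voltage_drop_kBT", bulk_voltage_drop(V, ap, gb, 2 * gb, hp,
                                                 cond)$Vb_kBT, "kBT"),
    c("pore_plus_access_resistance",
      pore_plus_access_resistance(gb, ap, hp), "Ohm"),
    c("diffusion_window_min", win$Vmin * 1e3, "mV"),
    c("diffusion_window_max", win$Vmax * 1e3, "mV"),
    c("constriction_entropy", constriction_entropy(geom$abf_radius, 1.2), "kBT"),
    c("crossing_entropy", crossing_entropy(geom$crossing_spread,
                                           geom$abf_radius), "kBT"),
    c("nominal_radius_10pct", nominal_radius(10, geom), "nm"),
    c("debye_length", debye_length(cond), "nm"))
  data.frame(quantity = vapply(rows, `[`, "", 1),
             value = as.numeric(vapply(rows, `[`, "", 2)),
             unit = vapply(rows, `[`, "", 3))
}
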