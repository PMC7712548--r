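## Core domain objects: solution conditions, ion species, pore geometry and
## the rim charge set of the crown-ether pore.  All constructors validate
## their inputs and return lightweight S3 lists.

#' Solution conditions
#'
#' Temperature, electrolyte concentration, bulk resistivity and bulk
#' relative permittivity of the electrolyte the pore sits in.  Defaults are
#' room temperature and 1 mol/L KCl with the resistivity of rigid TIP3P
#' water (0.071 Ohm m).
#'
#' @param temperature temperature in K (> 0).
#' @param concentration electrolyte concentration in mol/L (>= 0).
#' @param bulk_resistivity bulk resistivity gamma_b in Ohm m (> 0).
#' @param epsilon_r relative permittivity of the bulk solvent.
#' @return An object of class `conditions`.
#' @examples
#' cond <- conditions()
#' thermal_voltage(cond)
#' @export
conditions <- function(temperature = 298,
                       concentration = 1,
                       bulk_resistivity = 0.071,
                       epsilon_r = 78.4) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("'temperature' must be a single positive number (K)", call. = FALSE)
  if (!is.numeric(concentration) || length(concentration) != 1 || concentration < 0)
    stop("'concentration' must be a single non-negative number (mol/L)", call. = FALSE)
  if (!is.numeric(bulk_resistivity) || length(bulk_resistivity) != 1 || bulk_resistivity <= 0)
    stop("'bulk_resistivity' must be a single positive number (Ohm m)", call. = FALSE)
  if (!is.numeric(epsilon_r) || length(epsilon_r) != 1 || epsilon_r <= 0)
    stop("'epsilon_r' must be a single positive number", call. = FALSE)
  structure(list(temperature = temperature,
                 concentration = concentration,
                 concentration_per_nm3 = mol_per_L_to_per_nm3(concentration),
                 bulk_resistivity = bulk_resistivity,
                 epsilon_r = epsilon_r),
            class = "conditions")
}

#' @export
print.conditions <- function(x, ...) {
  cat("Solution conditions\n")
  cat(sprintf("  temperature:      %g K  (kBT/e = %.4f V)\n",
              x$temperature, thermal_voltage(x)))
  cat(sprintf("  concentration:    %g mol/L  (%.4f ions/nm^3)\n",
              x$concentration, x$concentration_per_nm3))
  cat(sprintf("  bulk resistivity: %g Ohm m\n", x$bulk_resistivity))
  cat(sprintf("  bulk epsilon_r:   %g\n", x$epsilon_r))
  invisible(x)
}

#' Ion species
#'
#' Valence, mobility/diffusion (linked by the Einstein relation) and the
#' hydration-shell structure of a permeant ion.  The default is potassium
#' with mobility 7.62e-8 m^2/(V s) and two representative hydration shells.
#' If only one of `mobility` and `diffusion` is given the other is filled
#' in via D = mu kBT / (q e); if both are given they must agree.
#'
#' @param valence signed valence in units of the elementary charge.
#' @param mobility mobility in m^2/(V s).
#' @param diffusion diffusion coefficient in m^2/s (optional).
#' @param vdw_radius van der Waals radius of the bare ion, nm.
#' @param hydration_radii strictly increasing shell radii, nm.
#' @param hydration_energies shell dehydration energies, kBT.
#' @param hydration_eta order-one shell factors (nonlinear response of the
#'   hydration energy to partial dehydration).
#' @param temperature temperature (K) used in the Einstein relation.
#' @return An object of class `ion_species`; `diffusion_nm2_ns` holds the
#'   diffusion coefficient in internal units (nm^2/ns).
#' @examples
#' k <- ion_species()          # potassium defaults
#' k$diffusion_nm2_ns          # ~1.96 nm^2/ns
#' @export
ion_species <- function(valence = 1,
                        mobility = 7.62e-8,
                        diffusion = NULL,
                        vdw_radius = 0.152,
                        hydration_radii = c(0.332, 0.57),
                        hydration_energies = c(85, 25),
                        hydration_eta = c(1, 1),
                        temperature = 298) {
  if (!is.numeric(valence) || length(valence) != 1 || valence == 0)
    stop("'valence' must be a single nonzero number", call. = FALSE)
  kT <- kBT_joule(temperature)
  q <- abs(valence) * phys_constants$e
  if (is.null(mobility) && is.null(diffusion))
    stop("supply at least one of 'mobility' or 'diffusion'", call. = FALSE)
  if (is.null(diffusion)) diffusion <- mobility * kT / q
  if (is.null(mobility)) mobility <- diffusion * q / kT
  if (abs(mobility * kT / q - diffusion) > 1e-10 * abs(diffusion))
    stop("'mobility' and 'diffusion' violate the Einstein relation D = mu kBT/q",
         call. = FALSE)
  if (length(hydration_radii) != length(hydration_energies) ||
      length(hydration_radii) != length(hydration_eta))
    stop("hydration radii, energies and eta must have equal length", call. = FALSE)
  if (length(hydration_radii) > 1 && any(diff(hydration_radii) <= 0))
    stop("'hydration_radii' must be strictly increasing", call. = FALSE)
  structure(list(valence = valence,
                 mobility = mobility,
                 diffusion = diffusion,
                 diffusion_nm2_ns = diffusion * 1e9,  # m^2/s -> nm^2/ns
                 vdw_radius = vdw_radius,
                 hydration_radii = hydration_radii,
                 hydration_energies = hydration_energies,
                 hydration_eta = hydration_eta,
                 temperature = temperature),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat("Ion species\n")
  cat(sprintf("  valence: %+g e   mobility: %.3g m^2/(V s)   D: %.3g m^2/s (%.3g nm^2/ns)\n",
              x$valence, x$mobility, x$diffusion, x$diffusion_nm2_ns))
  cat(sprintf("  hydration shells (nm / kBT / eta): %s\n",
              paste(sprintf("%.3g/%.3g/%.3g", x$hydration_radii,
                            x$hydration_energies, x$hydration_eta),
                    collapse = ", ")))
  invisible(x)
}

#' Pore geometry of the crown-ether pore
#'
#' All length scales that enter the analysis.  Defaults are the
#' crown-ether-in-graphene values: nominal (centre to oxygen-centre) radius
#' 0.29 nm at 0% strain, growing 7.5 pm per percent strain; oxygen van der
#' Waals radius 0.152 nm (so the unstrained geometric radius is 0.137 nm);
#' effective radius ap = 0.1 nm; effective membrane thickness hp = 1 nm;
#' internal binding-site length 0.4 nm; staging-site spread 0.1 nm; crossing
#' spread 0.02 nm; biased-sampling cylinder radius 0.28 nm; carbon vdW
#' radius 0.17 nm (sets the slab thickness for the dehydration model).
#'
#' @param nominal_radius_0 nominal radius at zero strain, nm.
#' @param strain_coefficient radius increase per percent strain, nm/%.
#' @param oxygen_vdw_radius rim oxygen van der Waals radius, nm.
#' @param effective_radius effective pore radius ap, nm.
#' @param effective_length effective pore (membrane) length hp, nm.
#' @param internal_site_length internal binding-site length Delta_p, nm.
#' @param staging_spread radial spread of the staging sites rs, nm.
#' @param crossing_spread radial spread of crossing trajectories rc, nm.
#' @param abf_radius radius of the free-energy sampling cylinder, nm.
#' @param carbon_vdw_radius carbon van der Waals radius, nm.
#' @return An object of class `pore_geometry`.
#' @examples
#' geom <- pore_geometry()
#' nominal_radius(10, geom)   # ~0.365 nm
#' @export
pore_geometry <- function(nominal_radius_0 = 0.29,
                          strain_coefficient = 0.0075,
                          oxygen_vdw_radius = 0.152,
                          effective_radius = 0.1,
                          effective_length = 1,
                          internal_site_length = 0.4,
                          staging_spread = 0.1,
                          crossing_spread = 0.02,
                          abf_radius = 0.28,
                          carbon_vdw_radius = 0.17) {
  lens <- c(nominal_radius_0 = nominal_radius_0,
            oxygen_vdw_radius = oxygen_vdw_radius,
            effective_radius = effective_radius,
            effective_length = effective_length,
            internal_site_length = internal_site_length,
            staging_spread = staging_spread,
            crossing_spread = crossing_spread,
            abf_radius = abf_radius,
            carbon_vdw_radius = carbon_vdw_radius)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad))
    stop("pore_geometry: field(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (strain_coefficient < 0)
    stop("'strain_coefficient' must be >= 0", call. = FALSE)
  geom <- structure(c(as.list(lens), list(strain_coefficient = strain_coefficient)),
                    class = "pore_geometry")
  ## geometric radius must stay positive across the working strain range
  gr <- geometric_radius(c(0, 10), geom)
  if (any(gr <= 0))
    stop("geometric radius (nominal - oxygen vdW) must be positive over 0-10% strain",
         call. = FALSE)
  if (!(crossing_spread <= staging_spread && staging_spread <= effective_radius))
    warning("expected ordering rc <= rs <= ap does not hold", call. = FALSE)
  geom
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat("Pore geometry (nm)\n")
  cat(sprintf("  nominal r0: %.3g (+%.4g per %% strain), geometric rp: %.3g\n",
              x$nominal_radius_0, x$strain_coefficient, geometric_radius(0, x)))
  cat(sprintf("  ap: %.3g  hp: %.3g  Delta_p: %.3g  rs: %.3g  rc: %.3g  rABF: %.3g\n",
              x$effective_radius, x$effective_length, x$internal_site_length,
              x$staging_spread, x$crossing_spread, x$abf_radius))
  invisible(x)
}

#' Nominal and geometric pore radius under strain
#'
#' The nominal radius (pore centre to oxygen centre) responds linearly to
#' in-plane strain; the geometric radius subtracts the oxygen van der Waals
#' radius.
#'
#' @param strain_percent strain in percent (>= 0); vectorised.
#' @param geometry a [pore_geometry()].
#' @return Radius in nm.
#' @examples
#' nominal_radius(0)    # 0.29
#' nominal_radius(10)   # ~0.365
#' geometric_radius(0)  # ~0.137
#' @export
nominal_radius <- function(strain_percent, geometry = pore_geometry()) {
  if (!is.numeric(strain_percent) || any(strain_percent < 0))
    stop("'strain_percent' must be non-negative", call. = FALSE)
  geometry$nominal_radius_0 + strain_percent * geometry$strain_coefficient
}

#' @rdname nominal_radius
#' @export
geometric_radius <- function(strain_percent, geometry = pore_geometry()) {
  nominal_radius(strain_percent, geometry) - geometry$oxygen_vdw_radius
}

#' Rim charge set of the pore
#'
#' Groups of point charges at the pore rim, each with a per-atom charge (e),
#' a count, and radial/axial positions (nm).  `crown_ether_charges()` builds
#' the standard crown-ether set: six oxygens carrying `q_oxygen` each at the
#' nominal radius, and twelve adjacent carbons carrying `-q_oxygen/2` each
#' slightly further out, so the set is overall neutral.
#'
#' @param charge per-atom charges, e.
#' @param count atoms per group.
#' @param radial_position radial distances from the pore axis, nm.
#' @param axial_position axial offsets from the membrane mid-plane, nm.
#' @return An object of class `pore_charge_set` with a `total_charge` field.
#' @examples
#' ch <- crown_ether_charges(-0.54)
#' ch$total_charge  # 0
#' @export
pore_charge_set <- function(charge, count, radial_position, axial_position = 0) {
  n <- length(charge)
  if (length(count) != n || length(radial_position) != n)
    stop("'charge', 'count' and 'radial_position' must have equal length", call. = FALSE)
  axial_position <- rep_len(axial_position, n)
  if (any(count < 1) || any(count != round(count)))
    stop("'count' must be positive integers", call. = FALSE)
  if (any(radial_position < 0))
    stop("'radial_position' must be >= 0", call. = FALSE)
  structure(list(charge = as.numeric(charge),
                 count = as.integer(count),
                 radial_position = as.numeric(radial_position),
                 axial_position = as.numeric(axial_position),
                 total_charge = sum(charge * count)),
            class = "pore_charge_set")
}

#' @rdname pore_charge_set
#' @param q_oxygen oxygen partial charge, e (negative).
#' @param geometry a [pore_geometry()]; sets the oxygen ring radius.
#' @param strain_percent strain at which the ring radius is evaluated.
#' @export
crown_ether_charges <- function(q_oxygen = -0.54,
                                geometry = pore_geometry(),
                                strain_percent = 0) {
  r_o <- nominal_radius(strain_percent, geometry)
  ## carbons neighbouring the ring sit roughly one bond length further out
  pore_charge_set(charge = c(q_oxygen, -q_oxygen / 2),
                  count = c(6L, 12L),
                  radial_position = c(r_o, r_o + 0.142),
                  axial_position = c(0, 0))
}

#' @export
print.pore_charge_set <- function(x, ...) {
  cat("Pore charge set\n")
  for (i in seq_along(x$charge))
    cat(sprintf("  %2d x %+.3g e at (r = %.3g nm, z = %.3g nm)\n",
                x$count[i], x$charge[i], x$radial_position[i], x$axial_position[i]))
  cat(sprintf("  total charge: %+.3g e\n", x$total_charge))
  invisible(x)
}

#' Debye screening length
#'
#' Screening length of a symmetric 1:1 electrolyte,
#' sqrt(eps0 eps_r kBT / (2 NA e^2 c)).
#'
#' @param cond a [conditions()] object with concentration > 0.
#' @return Debye length in nm (~0.30 nm at 1 mol/L, 298 K).
#' @examples
#' debye_length(conditions())        # ~0.30
#' debye_length(conditions(concentration = 0.25))  # ~0.61
#' @export
debye_length <- function(cond = conditions()) {
  stopifnot(inherits(cond, "conditions"))
  if (cond$concentration <= 0)
    stop("Debye length is infinite at zero concentration; supply concentration > 0",
         call. = FALSE)
  c_m3 <- cond$concentration * phys_constants$N_A * 1e3   # ions/m^3
  lam <- sqrt(phys_constants$eps0 * cond$epsilon_r * kBT_joule(cond$temperature) /
                (2 * c_m3 * phys_constants$e^2))
  lam * 1e9
}

#' Thermal voltage kBT/e
#'
#' @param cond a [conditions()] object (or a temperature in K).
#' @return kBT/e in volts (~0.0257 V at 298 K).
#' @examples
#' thermal_voltage(conditions())  # ~0.0257
#' @export
thermal_voltage <- function(cond = conditions()) {
  Tk <- if (inherits(cond, "conditions")) cond$temperature else cond
  if (!is.numeric(Tk) || Tk <= 0) stop("temperature must be > 0", call. = FALSE)
  kBT_eV(Tk)
}
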