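## One-dimensional free-energy landscapes: construction, a geometric
## dehydration + screened-Coulomb model, voltage tilting, discrete-gradient
## feature analysis, and entropic-penalty estimates.

#' Free-energy profile along the pore axis
#'
#' A 1D grid of axial position z (nm) versus free energy (kBT), with an
#' optional standard-error column and metadata (strain, oxygen charge,
#' applied voltage).
#'
#' @param z strictly increasing positions, nm.
#' @param F free energy at each position, kBT.
#' @param SE optional standard error per point, kBT.
#' @param strain strain metadata, percent.
#' @param q_oxygen oxygen partial-charge metadata, e.
#' @param voltage applied-voltage metadata, V.
#' @return An object of class `free_energy_profile`.
#' @examples
#' p <- free_energy_profile(seq(-1, 1, 0.1), dnorm(seq(-1, 1, 0.1), sd = 0.2))
#' @export
free_energy_profile <- function(z, F, SE = NULL, strain = NA_real_,
                                q_oxygen = NA_real_, voltage = 0) {
  z <- as.numeric(z); F <- as.numeric(F)
  if (length(z) != length(F))
    stop("'z' and 'F' must have equal length", call. = FALSE)
  if (length(z) < 2 || any(diff(z) <= 0))
    stop("'z' must be strictly increasing with at least 2 points", call. = FALSE)
  if (any(!is.finite(F))) stop("'F' must be finite", call. = FALSE)
  if (!is.null(SE)) {
    SE <- as.numeric(SE)
    if (length(SE) != length(z) || any(SE < 0, na.rm = TRUE))
      stop("'SE' must be non-negative and match 'z' in length", call. = FALSE)
  }
  structure(list(z = z, F = F, SE = SE,
                 strain = strain, q_oxygen = q_oxygen, voltage = voltage),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile: %d points, z in [%.3g, %.3g] nm, F in [%.3g, %.3g] kBT\n",
              length(x$z), min(x$z), max(x$z), min(x$F), max(x$F)))
  cat(sprintf("  strain: %s %%  qO: %s e  voltage: %g V  SE: %s\n",
              format(x$strain), format(x$q_oxygen), x$voltage,
              if (is.null(x$SE)) "absent" else "present"))
  invisible(x)
}

#' Read and write free-energy profiles
#'
#' Plain-text, comma-separated three-column files (`z_nm,F_kBT,SE_kBT`) with
#' `#`-prefixed metadata header lines (`strain`, `q_oxygen`, `voltage`), the
#' format produced by adaptive-biasing-force post-processing here.
#'
#' @param path file path.
#' @return `read_profile()` returns a [free_energy_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# strain: %s", format(profile$strain)),
               sprintf("# q_oxygen: %s", format(profile$q_oxygen)),
               sprintf("# voltage: %s", format(profile$voltage)),
               "z_nm,F_kBT,SE_kBT"), con)
  se <- if (is.null(profile$SE)) rep(NA_real_, length(profile$z)) else profile$SE
  writeLines(sprintf("%.10g,%.10g,%.10g", profile$z, profile$F, se), con)
  invisible(path)
}

#' @rdname write_profile
#' @param profile a [free_energy_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(strain = NA_real_, q_oxygen = NA_real_, voltage = 0)
  for (m in meta_lines) {
    kv <- regmatches(m, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", m))[[1]]
    if (length(kv) == 3 && kv[2] %in% names(meta))
      meta[[kv[2]]] <- suppressWarnings(as.numeric(kv[3]))
  }
  body <- lines[!grepl("^#", lines)]
  tab <- read.csv(text = paste(body, collapse = "\n"))
  need <- c("z_nm", "F_kBT")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("profile file missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  se <- if ("SE_kBT" %in% names(tab) && !all(is.na(tab$SE_kBT))) tab$SE_kBT else NULL
  free_energy_profile(tab$z_nm, tab$F_kBT, SE = se, strain = meta$strain,
                      q_oxygen = meta$q_oxygen, voltage = meta$voltage)
}

#' Fractional dehydration of a hydration shell near the membrane
#'
#' Geometric estimate of the fraction of a spherical hydration shell
#' excluded by the membrane, modelled as a slab of thickness twice the
#' carbon van der Waals radius perforated by a cylinder of the geometric
#' pore radius.  The shell is treated as a thin sphere centred on the pore
#' axis at axial position z; the excluded fraction has a closed form because
#' the geometry is axisymmetric.
#'
#' @param z axial position(s) of the ion, nm (membrane mid-plane at 0).
#' @param layer_index which hydration shell (1 = innermost).
#' @param geometry a [pore_geometry()].
#' @param ion an [ion_species()].
#' @param strain_percent strain used for the geometric pore radius.
#' @return Fraction in `[0, 1]`, vectorised over `z`.
#' @examples
#' dehydration_fraction(0)     # maximal, first shell at the pore centre
#' dehydration_fraction(1.5)   # 0: shell clear of the membrane
#' @export
dehydration_fraction <- function(z, layer_index = 1,
                                 geometry = pore_geometry(),
                                 ion = ion_species(),
                                 strain_percent = 0) {
  R <- ion$hydration_radii[layer_index]
  if (is.na(R) || R <= 0) stop("invalid hydration layer radius", call. = FALSE)
  h <- geometry$carbon_vdw_radius              # slab half-thickness
  rp <- geometric_radius(strain_percent, geometry)
  if (rp >= R) return(rep(0, length(z)))
  s0 <- sqrt(1 - (rp / R)^2)                   # |cos theta| bound outside the pore
  a <- pmax((-h - z) / R, -s0, -1)
  b <- pmin(( h - z) / R,  s0,  1)
  pmax(0, b - a) / 2
}

#' Model free-energy profile from dehydration and rim electrostatics
#'
#' Single-ion energetics as the sum of per-shell dehydration penalties
#' (eta_i f_i(z) E_i, with f_i from [dehydration_fraction()]) and pairwise
#' Coulomb terms between the ion and each rim charge group, using a
#' distance-dependent effective permittivity that switches linearly from
#' `eps_pore` at contact (ion-group distance below the first-shell radius,
#' no intervening water) to the bulk value beyond the second-shell radius
#' (full hydration).
#'
#' @param z axial position(s), nm.
#' @param ion an [ion_species()].
#' @param pore_charges a [pore_charge_set()].
#' @param geometry a [pore_geometry()].
#' @param eps_pore effective relative permittivity at contact (~4).
#' @param cond a [conditions()] (bulk permittivity and temperature).
#' @param strain_percent strain for the dehydration geometry.
#' @param switch_radii optional two lengths (nm) overriding the permittivity
#'   switching window; defaults to the first and second hydration radii.
#' @return Free energy in kBT, vectorised over `z`.
#' @examples
#' model_free_energy(0)    # pore-centre value for the default crown ether
#' model_free_energy(1.5)  # ~0 far from the membrane
#' @export
model_free_energy <- function(z, ion = ion_species(),
                              pore_charges = crown_ether_charges(),
                              geometry = pore_geometry(),
                              eps_pore = 4,
                              cond = conditions(),
                              strain_percent = 0,
                              switch_radii = NULL) {
  if (eps_pore <= 0) stop("'eps_pore' must be positive", call. = FALSE)
  if (is.null(switch_radii)) {
    switch_radii <- if (length(ion$hydration_radii) >= 2) ion$hydration_radii[1:2]
                    else c(ion$hydration_radii[1], 2 * ion$hydration_radii[1])
  }
  r1 <- switch_radii[1]; r2 <- switch_radii[2]
  kT_eV <- kBT_eV(cond$temperature)
  dehyd <- rep(0, length(z))
  for (i in seq_along(ion$hydration_radii)) {
    dehyd <- dehyd + ion$hydration_eta[i] * ion$hydration_energies[i] *
      dehydration_fraction(z, i, geometry, ion, strain_percent)
  }
  coul <- rep(0, length(z))
  for (g in seq_along(pore_charges$charge)) {
    r <- sqrt((z - pore_charges$axial_position[g])^2 +
                pore_charges$radial_position[g]^2)
    if (any(r == 0))
      stop("ion-group distance is zero; charge group coincides with the ion",
           call. = FALSE)
    frac <- pmin(1, pmax(0, (r - r1) / (r2 - r1)))
    eps_eff <- eps_pore + frac * (cond$epsilon_r - eps_pore)
    coul <- coul + ion$valence * pore_charges$charge[g] * pore_charges$count[g] *
      phys_constants$coulomb_eV_nm / (eps_eff * r) / kT_eV
  }
  dehyd + coul
}

#' Tilt a profile by an applied voltage
#'
#' Subtracts q Vext lambda(z) (in kBT) from the profile, where lambda rises
#' linearly from 0 to 1 across `|z| < drop_halfwidth` — the observation that
#' the applied potential drops over about half a nanometre on either side of
#' an atomically thin membrane.  The total drop across the profile is
#' exactly q Vext.
#'
#' @param profile a [free_energy_profile()].
#' @param Vext applied voltage, V (positive drives the ion toward +z).
#' @param drop_halfwidth half-width of the potential-drop region, nm.
#' @param ion an [ion_species()] (valence).
#' @param cond a [conditions()] (temperature for the kBT conversion).
#' @return A new [free_energy_profile()] with updated voltage metadata.
#' @examples
#' p <- free_energy_profile(seq(-1, 1, 0.05), rep(0, 41))
#' tp <- tilt_profile(p, 0.25)
#' range(tp$F)  # total drop ~9.7 kBT
#' @export
tilt_profile <- function(profile, Vext, drop_halfwidth = 0.5,
                         ion = ion_species(), cond = conditions()) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (drop_halfwidth <= 0) stop("'drop_halfwidth' must be positive", call. = FALSE)
  u <- ion$valence * Vext / thermal_voltage(cond)      # total drop, kBT
  lam <- pmin(1, pmax(0, (profile$z + drop_halfwidth) / (2 * drop_halfwidth)))
  free_energy_profile(profile$z, profile$F - u * lam, SE = profile$SE,
                      strain = profile$strain, q_oxygen = profile$q_oxygen,
                      voltage = profile$voltage + Vext)
}

#' Discrete gradients from each minimum to the next maximum
#'
#' Identifies local minima of the profile and pairs each with the next local
#' maximum at larger z (gradients in the negative-z direction assist rather
#' than hinder translocation and are excluded).  Profiles are smoothed with
#' a centred moving average and shallow extrema are pruned by a prominence
#' threshold before pairing, since sampled profiles carry noise at the
#' half-kBT scale.
#'
#' @param profile a [free_energy_profile()].
#' @param smooth_window moving-average window in points (odd; 1 = none).
#' @param min_prominence minimum barrier amplitude retained, kBT.
#' @return A data frame of class `landscape_features` with columns
#'   `z_min`, `F_min`, `z_max`, `F_max`, `gradient` (kBT/nm) and
#'   `mean_position` (nm); zero rows for monotone profiles.
#' @examples
#' z <- seq(-1, 1, 0.01)
#' p <- free_energy_profile(z, 5 * exp(-z^2 / 0.02) - 2 * exp(-(z + 0.5)^2 / 0.01))
#' discrete_gradients(p)
#' @export
discrete_gradients <- function(profile, smooth_window = 3, min_prominence = 0.5) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (length(profile$z) < 3)
    stop("profile needs at least 3 points", call. = FALSE)
  if (smooth_window %% 2 != 1 || smooth_window < 1)
    stop("'smooth_window' must be a positive odd integer", call. = FALSE)
  z <- profile$z
  F <- moving_average(profile$F, smooth_window)
  ext <- alternating_extrema(F)
  ext <- prune_extrema(ext, F, min_prominence)
  feats <- data.frame(z_min = numeric(0), F_min = numeric(0),
                      z_max = numeric(0), F_max = numeric(0),
                      gradient = numeric(0), mean_position = numeric(0))
  if (nrow(ext)) {
    mins <- which(ext$type == "min")
    for (m in mins) {
      if (m < nrow(ext) && ext$type[m + 1] == "max") {
        i <- ext$idx[m]; j <- ext$idx[m + 1]
        feats <- rbind(feats, data.frame(
          z_min = z[i], F_min = F[i], z_max = z[j], F_max = F[j],
          gradient = (F[j] - F[i]) / (z[j] - z[i]),
          mean_position = (z[i] + z[j]) / 2))
      }
    }
  }
  class(feats) <- c("landscape_features", "data.frame")
  feats
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

## interior local extrema as an alternating min/max sequence (plateaus
## collapse to their first index)
alternating_extrema <- function(F) {
  n <- length(F)
  idx <- integer(0); type <- character(0)
  i <- 2
  while (i <= n - 1) {
    left <- F[i] - F[i - 1]
    ## skip forward over plateaus
    j <- i
    while (j < n && F[j + 1] == F[j]) j <- j + 1
    if (j > n - 1) break
    right <- F[j + 1] - F[j]
    if (left < 0 && right > 0) { idx <- c(idx, i); type <- c(type, "min") }
    if (left > 0 && right < 0) { idx <- c(idx, i); type <- c(type, "max") }
    i <- j + 1
  }
  data.frame(idx = idx, type = type, stringsAsFactors = FALSE)
}

## iteratively drop adjacent extremum pairs whose amplitude difference is
## below the prominence threshold
prune_extrema <- function(ext, F, min_prominence) {
  if (min_prominence <= 0 || nrow(ext) < 2) return(ext)
  repeat {
    if (nrow(ext) < 2) break
    amp <- abs(diff(F[ext$idx]))
    k <- which.min(amp)
    if (amp[k] >= min_prominence) break
    ext <- ext[-c(k, k + 1), , drop = FALSE]
  }
  ext
}

#' Classify how landscape features respond to an applied voltage
#'
#' Matches equilibrium features to features of the voltage-tilted profile by
#' nearest mean position, then labels each: `washed_out` (absent from the
#' biased landscape or gradient driven to zero), `reduced` (gradient lowered
#' appreciably, as an ideal uniform field would do), `irrelevant` (gradient
#' essentially unchanged although the ideal field q Vext / (2 w) should have
#' reduced it — the signature of a feature that is not rate limiting and
#' builds no self-consistent potential drop), or `unchanged` (the field
#' itself is too small to discriminate).
#'
#' @param features_eq features of the equilibrium profile
#'   ([discrete_gradients()] output).
#' @param features_biased features of the tilted profile.
#' @param Vext applied voltage, V.
#' @param drop_halfwidth potential-drop half-width, nm.
#' @param match_tol matching tolerance on mean position, nm.
#' @param rel_tol relative gradient-change tolerance.
#' @param ion,cond ion and conditions for the kBT conversion.
#' @return `features_eq` with added columns `biased_gradient`, `matched` and
#'   `label`.
#' @export
classify_feature_relevance <- function(features_eq, features_biased, Vext,
                                       drop_halfwidth = 0.5, match_tol = 0.1,
                                       rel_tol = 0.1,
                                       ion = ion_species(), cond = conditions()) {
  out <- as.data.frame(features_eq)
  ideal_field <- abs(ion$valence * Vext / thermal_voltage(cond)) /
    (2 * drop_halfwidth)                         # kBT/nm
  out$biased_gradient <- NA_real_
  out$matched <- FALSE
  out$label <- NA_character_
  fb <- as.data.frame(features_biased)
  for (i in seq_len(nrow(out))) {
    g0 <- out$gradient[i]
    if (nrow(fb)) {
      dpos <- abs(fb$mean_position - out$mean_position[i])
      j <- which.min(dpos)
    } else j <- integer(0)
    if (length(j) && nrow(fb) && dpos[j] <= match_tol) {
      g1 <- fb$gradient[j]
      out$biased_gradient[i] <- g1
      out$matched[i] <- TRUE
      change <- (g0 - g1) / g0
      out$label[i] <- if (g1 <= 0) "washed_out"
        else if (abs(change) < rel_tol) {
          if (ideal_field > rel_tol * g0) "irrelevant" else "unchanged"
        } else "reduced"
    } else {
      out$label[i] <- "washed_out"     # feature absent under bias
    }
  }
  out
}

#' Entropic penalties of confinement
#'
#' Free-energy costs, in kBT, of confining an ion from bulk (typical
#' inter-ion spacing `l`) into successively narrower regions:
#' `constriction_entropy()` into the sampling cylinder of radius `r_abf`
#' (-ln(pi r^2 l / l^3)); `crossing_entropy()` from the cylinder into the
#' crossing region of radius `r_c` (-ln(r_c^2 / r_abf^2)); `well_entropy()`
#' the axial localisation into a well of length `l_w` (-ln(l_w / l)).
#'
#' @param r_abf sampling-cylinder radius, nm.
#' @param l typical inter-ion spacing in bulk, nm (~1.2 at 1 mol/L).
#' @return Entropy cost in kBT (positive = penalty).
#' @examples
#' constriction_entropy(0.28, 1.2)  # ~1.8
#' crossing_entropy(0.02, 0.28)     # ~5.3
#' well_entropy(0.3, 1.2)           # ~1.4
#' @export
constriction_entropy <- function(r_abf, l) {
  stopifnot(r_abf > 0, l > 0)
  -log(pi * r_abf^2 * l / l^3)
}

#' @rdname constriction_entropy
#' @param r_c crossing-trajectory radial spread, nm.
#' @export
crossing_entropy <- function(r_c, r_abf) {
  stopifnot(r_c > 0, r_abf > 0)
  -log(r_c^2 / r_abf^2)
}

#' @rdname constriction_entropy
#' @param l_w well length, nm.
#' @export
well_entropy <- function(l_w, l) {
  stopifnot(l_w > 0, l > 0)
  -log(l_w / l)
}
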