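## Synthetic-data generation: measurement tables from a ground-truth rate
## set with replica counting noise (the stochastic chain stands in for the
## ion-counting molecular-dynamics runs), and parameterised free-energy
## profiles with the phenomenology of the crown-ether landscape.

#' Specification of the synthetic measurement generator
#'
#' The generator's truth is the fitted kinetic parameter set of the
#' qO = -0.54e pore: diffusive feed kb0 = 0.5 ions/ns, drift-feed
#' coefficient kappa_b = 2.2 ions/(V ns), effective association
#' ktilde_a = 12 ions/ns, and the combined dissociation law
#' kd(s, V) = 3.2 V exp(0.043 qV/kBT + 0.22 s) ions/ns (s in percent
#' strain).  The design grid is 0-10% strain in 2% steps at 0.1, 0.25, 0.5
#' and 1 V with five replicas per point, mirroring a five-run ion-counting
#' campaign of 50 ns per replica.
#'
#' @param kb0 diffusive feed rate, ions/ns.
#' @param kappa_b drift-feed coefficient, ions/(V ns).
#' @param ktilde_a effective association rate, ions/ns.
#' @param kd_prefactor prefactor B of the combined kd law, ions/(V ns).
#' @param kd_voltage_exp voltage exponent b (per qV/kBT).
#' @param kd_strain_exp strain exponent c (per percent strain).
#' @param strains strain grid, percent.
#' @param voltages voltage grid, V.
#' @param n_runs replicas per point.
#' @param run_length simulated time per replica, ns.
#' @param q_oxygen rim charge metadata, e.
#' @param seed RNG seed.
#' @param cond a [conditions()].
#' @return An object of class `generator_spec`.
#' @examples
#' spec <- generator_spec(seed = 1)
#' head(generate_measurements(spec))
#' @export
generator_spec <- function(kb0 = 0.5, kappa_b = 2.2, ktilde_a = 12,
                           kd_prefactor = 3.2, kd_voltage_exp = 0.043,
                           kd_strain_exp = 0.22,
                           strains = seq(0, 10, by = 2),
                           voltages = c(0.1, 0.25, 0.5, 1.0),
                           n_runs = 5, run_length = 50,
                           q_oxygen = -0.54, seed = 1,
                           cond = conditions()) {
  stopifnot(kb0 >= 0, kappa_b >= 0, ktilde_a > 0, kd_prefactor > 0,
            length(strains) >= 1, length(voltages) >= 1,
            n_runs >= 1, run_length > 0)
  spec <- structure(list(kb0 = kb0, kappa_b = kappa_b, ktilde_a = ktilde_a,
                         kd_prefactor = kd_prefactor,
                         kd_voltage_exp = kd_voltage_exp,
                         kd_strain_exp = kd_strain_exp,
                         strains = strains, voltages = voltages,
                         n_runs = n_runs, run_length = run_length,
                         q_oxygen = q_oxygen, seed = seed, cond = cond),
                    class = "generator_spec")
  ## a run should see a usable number of translocation events at the
  ## largest current, or the SE columns will be unreliable
  imax <- max(vapply(spec$voltages, function(V)
    max(vapply(spec$strains, function(s) model_point(spec, s, V)$current,
               numeric(1))), numeric(1)))
  if (imax * run_length < 10)
    warning("fewer than 10 expected events per replica at the largest current; ",
            "increase run_length", call. = FALSE)
  spec
}

#' Ground-truth dissociation rate of a generator spec
#'
#' @param spec a [generator_spec()].
#' @param strain strain, percent.
#' @param V voltage, V.
#' @return kd(s, V) in ions/ns.
#' @export
kd_truth <- function(spec, strain, V) {
  vt <- thermal_voltage(spec$cond)
  spec$kd_prefactor * V * exp(spec$kd_voltage_exp * V / vt +
                                spec$kd_strain_exp * strain)
}

## concrete chain realization of the truth at one design point:
## kb_out = kb (staging site at half filling, ka = 2 ktilde_a), exit site
## drained fast so P3 stays small
truth_rates <- function(spec, strain, V) {
  kb <- spec$kb0 + spec$kappa_b * V
  kd <- kd_truth(spec, strain, V)
  rate_set(kb = kb, kb_out = kb, ka = 2 * spec$ktilde_a, kd = kd,
           kexit_out = 500 * kd)
}

## deterministic model values at one design point: the plateau balance
## kd P2 = (1/kb + 1/(ktilde_a (1-P2)))^-1 with an empty exit site
model_point <- function(spec, strain, V) {
  kb <- spec$kb0 + spec$kappa_b * V
  kd <- kd_truth(spec, strain, V)
  g <- function(P2) kd * P2 - current_from_occupancy(kb, spec$ktilde_a, P2)
  P2 <- uniroot(g, c(0, 1), tol = 1e-14)$root
  list(current = kd * P2, P2 = P2, P3 = 0)
}

#' Generate a synthetic measurement table
#'
#' For each (strain, voltage) design point, produces per-replica currents
#' and occupancies around the deterministic model truth.  With
#' `noise = "counting"` (default) each replica realises the model's
#' pore-site occupancy as a stationary two-state dwell (telegraph) process
#' — occupied intervals ending in a translocation at rate kd, empty
#' intervals refilled at the rate that reproduces the model occupancy — so
#' the reported current is a translocation count over `run_length` and P2 a
#' dwell-time fraction, with standard errors sqrt(var/n) across replicas:
#' the error structure of ion-counting simulation campaigns, unbiased for
#' the model truth.  `noise = "gaussian"` replaces the dwell simulation by
#' Gaussian perturbations with the matching counting variance (fast
#' approximation); `noise = "none"` returns the deterministic model values
#' with zero SE.
#'
#' @param spec a [generator_spec()].
#' @param noise `"counting"`, `"gaussian"` or `"none"`.
#' @return A [measurement_table()] with truth columns `current_model` and
#'   `P2_model` attached for reference.
#' @export
generate_measurements <- function(spec,
                                  noise = c("counting", "gaussian", "none")) {
  stopifnot(inherits(spec, "generator_spec"))
  noise <- match.arg(noise)
  set.seed(spec$seed)
  grid <- expand.grid(strain = spec$strains, voltage = spec$voltages,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- grid$strain[i]; V <- grid$voltage[i]
    truth <- model_point(spec, s, V)
    if (noise == "none") {
      cur <- truth$current; cur_se <- 0
      p2 <- truth$P2; p2_se <- 0
    } else if (noise == "counting") {
      kd <- kd_truth(spec, s, V)
      reps <- vapply(seq_len(spec$n_runs), function(r)
        telegraph_replica(truth$P2, kd, spec$run_length), numeric(2))
      cur_rep <- reps[1, ]; p2_rep <- reps[2, ]
      cur <- mean(cur_rep); cur_se <- sqrt(var(cur_rep) / spec$n_runs)
      p2 <- mean(p2_rep); p2_se <- sqrt(var(p2_rep) / spec$n_runs)
    } else {
      ## Poisson counting variance for the current; occupancy variance from
      ## the two-state dwell structure of the pore site
      sd_cur <- sqrt(truth$current / spec$run_length)
      kd <- kd_truth(spec, s, V)
      tau <- 1 / max(kd, 1e-6)               # occupied dwell scale
      sd_p2 <- sqrt(2 * truth$P2 * (1 - truth$P2) * tau / spec$run_length)
      reps_c <- rnorm(spec$n_runs, truth$current, sd_cur)
      reps_p <- pmin(1, pmax(0, rnorm(spec$n_runs, truth$P2, sd_p2)))
      cur <- mean(reps_c); cur_se <- sqrt(var(reps_c) / spec$n_runs)
      p2 <- mean(reps_p); p2_se <- sqrt(var(reps_p) / spec$n_runs)
    }
    rows[[i]] <- data.frame(strain = s, voltage = V,
                            current = max(cur, 0), current_se = cur_se,
                            P2 = min(1, max(p2, 0)), P2_se = p2_se,
                            q_oxygen = spec$q_oxygen, n_runs = spec$n_runs,
                            current_model = truth$current, P2_model = truth$P2)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  measurement_table(out)
}

## one stationary two-state dwell replica of the pore site: returns
## c(count/T, occupied fraction).  Fill rate chosen so the stationary
## occupancy equals P2 and translocations (occupied -> empty transitions)
## occur at kd P2 per unit time.
telegraph_replica <- function(P2, kd, t_total) {
  if (P2 <= 0) return(c(0, 0))
  if (P2 >= 1) {                     # permanently blocked pore
    ## dissociations immediately refilled: counts are Poisson at rate kd
    return(c(stats::rpois(1, kd * t_total) / t_total, 1))
  }
  fill <- kd * P2 / (1 - P2)
  occupied <- runif(1) < P2          # stationary start
  t <- 0; t_occ <- 0; count <- 0L
  repeat {
    dwell <- stats::rexp(1, if (occupied) kd else fill)
    t_next <- t + dwell
    if (t_next >= t_total) {
      if (occupied) t_occ <- t_occ + (t_total - t)
      break
    }
    if (occupied) { t_occ <- t_occ + dwell; count <- count + 1L }
    occupied <- !occupied
    t <- t_next
  }
  c(count / t_total, t_occ / t_total)
}

#' Specification of a synthetic free-energy profile
#'
#' A sum of Gaussian features emulating the crown-ether landscape: a
#' central electrostatic well whose depth shrinks with strain (the well
#' flattens and disappears as strain pulls the rim charges away), a central
#' dehydration barrier that grows with strain, and satellite features just
#' outside the pore.  Amplitudes are in kBT, positions and widths in nm.
#'
#' @param well_depth_0 central well depth at 0% strain (positive number,
#'   kBT); scaled down by `exp(-well_strain_decay * s)`.
#' @param well_width central well Gaussian width, nm.
#' @param well_strain_decay strain decay constant of the well, per %.
#' @param barrier_height_0 central dehydration barrier at 0% strain, kBT.
#' @param barrier_strain_slope linear growth of the barrier with strain,
#'   kBT per %.
#' @param barrier_width central barrier width, nm.
#' @param satellite_positions positions of satellite features, nm.
#' @param satellite_heights amplitudes of satellite features, kBT
#'   (positive = barrier).
#' @param satellite_width satellite Gaussian width, nm.
#' @param se_level per-point standard error of the profile, kBT.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(well_depth_0 = 10, well_width = 0.12,
                         well_strain_decay = 0.35,
                         barrier_height_0 = 0, barrier_strain_slope = 0.6,
                         barrier_width = 0.08,
                         satellite_positions = c(-0.35, 0.35),
                         satellite_heights = c(3, 3),
                         satellite_width = 0.08,
                         se_level = 0.5) {
  stopifnot(well_width > 0, barrier_width > 0, satellite_width > 0,
            se_level >= 0,
            length(satellite_positions) == length(satellite_heights))
  structure(list(well_depth_0 = well_depth_0, well_width = well_width,
                 well_strain_decay = well_strain_decay,
                 barrier_height_0 = barrier_height_0,
                 barrier_strain_slope = barrier_strain_slope,
                 barrier_width = barrier_width,
                 satellite_positions = satellite_positions,
                 satellite_heights = satellite_heights,
                 satellite_width = satellite_width,
                 se_level = se_level),
            class = "profile_spec")
}

#' Generate a synthetic free-energy profile
#'
#' Evaluates the [profile_spec()] feature sum at the requested strain, adds
#' seeded Gaussian noise at the spec's SE level, and applies the voltage
#' tilt.
#'
#' @param pspec a [profile_spec()].
#' @param strain strain, percent.
#' @param Vext applied voltage, V (0 = equilibrium profile).
#' @param z grid, nm.
#' @param seed RNG seed for the noise (NULL = no noise).
#' @param q_oxygen metadata, e.
#' @param ion,cond ion and conditions for the tilt.
#' @return A [free_energy_profile()].
#' @examples
#' p <- generate_profile(profile_spec(), strain = 0, seed = 1)
#' nrow(discrete_gradients(p)) >= 1
#' @export
generate_profile <- function(pspec = profile_spec(), strain = 0, Vext = 0,
                             z = seq(-1.5, 1.5, by = 0.02), seed = NULL,
                             q_oxygen = -0.54, ion = ion_species(),
                             cond = conditions()) {
  stopifnot(inherits(pspec, "profile_spec"), strain >= 0)
  gauss <- function(z0, w) exp(-(z - z0)^2 / (2 * w^2))
  well <- -pspec$well_depth_0 * exp(-pspec$well_strain_decay * strain) *
    gauss(0, pspec$well_width)
  barrier <- (pspec$barrier_height_0 + pspec$barrier_strain_slope * strain) *
    gauss(0, pspec$barrier_width)
  F <- well + barrier
  for (i in seq_along(pspec$satellite_positions))
    F <- F + pspec$satellite_heights[i] *
      gauss(pspec$satellite_positions[i], pspec$satellite_width)
  se <- rep(pspec$se_level, length(z))
  if (!is.null(seed) && pspec$se_level > 0) {
    set.seed(seed)
    F <- F + rnorm(length(z), 0, pspec$se_level)
  }
  prof <- free_energy_profile(z, F, SE = se, strain = strain,
                              q_oxygen = q_oxygen, voltage = 0)
  if (Vext != 0) prof <- tilt_profile(prof, Vext, ion = ion, cond = cond)
  prof
}
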