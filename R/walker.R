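## Overdamped 1D Brownian dynamics on a (tilted) free-energy profile:
## translocation/reflection statistics, splitting probabilities, and the
## one-way incoming-rate curve whose plateau is the net translocation rate.

#' Simulate overdamped Brownian walkers on a free-energy profile
#'
#' Euler-Maruyama integration of dz = -D F'(z) dt + sqrt(2 D dt) N(0,1)
#' (F in kBT, so the mobility is D), with the force obtained by central
#' differences on the profile grid and linear interpolation in between.
#' Walkers start at `z0` and are absorbed at `z_plus`; the lower plane
#' `z_minus` is absorbing (default) or reflecting (a bulk reservoir that
#' always returns the ion).
#'
#' @param profile a [free_energy_profile()] (energies in kBT).
#' @param D diffusion coefficient, nm^2/ns.
#' @param n_walkers number of independent walkers.
#' @param z0 launch position, nm (`z_minus < z0 < z_plus`).
#' @param z_minus,z_plus lower/upper boundary planes, nm; default the
#'   profile ends.
#' @param dt time step, ns; default chosen so the per-step displacement
#'   sqrt(2 D dt) is one fifth of the grid spacing.
#' @param seed RNG seed (required for reproducibility).
#' @param boundary_lower `"absorbing"` or `"reflecting"`.
#' @param t_max observation window, ns (`Inf` runs until absorption).
#' @param n_store store thinned trajectories for this many walkers.
#' @param store_stride store every this-many steps.
#' @return An object of class `walker_run`: per-walker `outcome`
#'   (`"reflected"`, `"translocated"`, `"active"`), `exit_time` (ns),
#'   `max_z` (running maximum, nm), `final_z`, stored `trajectories`, and
#'   the run parameters.
#' @examples
#' p <- free_energy_profile(seq(-1, 1, 0.05), rep(0, 41))
#' run <- simulate_walkers(p, D = 2, n_walkers = 200, z0 = 0, seed = 1)
#' mean(run$outcome == "translocated")  # ~0.5 by symmetry
#' @export
simulate_walkers <- function(profile, D, n_walkers, z0,
                             z_minus = min(profile$z), z_plus = max(profile$z),
                             dt = NULL, seed = NULL,
                             boundary_lower = c("absorbing", "reflecting"),
                             t_max = Inf, n_store = 0, store_stride = 100) {
  stopifnot(inherits(profile, "free_energy_profile"), D > 0, n_walkers >= 1)
  boundary_lower <- match.arg(boundary_lower)
  if (!(z_minus < z0 && z0 < z_plus))
    stop("need z_minus < z0 < z_plus", call. = FALSE)
  spacing <- min(diff(profile$z))
  if (is.null(dt)) dt <- (0.2 * spacing)^2 / (2 * D)
  step_len <- sqrt(2 * D * dt)
  if (step_len > 0.5 * spacing)
    stop(sprintf(paste0("dt = %g ns violates the stability bound: per-step ",
                        "displacement sqrt(2 D dt) = %.3g nm exceeds half the ",
                        "grid spacing %.3g nm; need dt <= %.3g ns"),
                 dt, step_len, spacing, (0.5 * spacing)^2 / (2 * D)),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grad <- profile_gradient(profile)
  max_steps <- if (is.finite(t_max)) ceiling(t_max / dt) + 1 else 1e10
  res <- cpp_walk(profile$z, grad, D, dt, as.integer(n_walkers), z0,
                  z_minus, z_plus, boundary_lower == "reflecting",
                  if (is.finite(t_max)) t_max else -1, max_steps,
                  as.integer(n_store), as.integer(store_stride))
  if (isTRUE(res$hit_step_cap))
    warning("some walkers hit the internal step cap before absorbing",
            call. = FALSE)
  structure(list(outcome = c("reflected", "translocated", "active")[res$outcome + 1L],
                 exit_time = res$exit_time,
                 max_z = res$max_z,
                 final_z = res$final_z,
                 trajectories = res$trajectories,
                 z0 = z0, z_minus = z_minus, z_plus = z_plus,
                 dt = dt, t_max = t_max, D = D, seed = seed,
                 boundary_lower = boundary_lower,
                 store_stride = store_stride),
            class = "walker_run")
}

## central-difference gradient dF/dz on the profile grid
profile_gradient <- function(profile) {
  z <- profile$z; F <- profile$F
  n <- length(z)
  g <- numeric(n)
  g[1] <- (F[2] - F[1]) / (z[2] - z[1])
  g[n] <- (F[n] - F[n - 1]) / (z[n] - z[n - 1])
  if (n > 2) g[2:(n - 1)] <- (F[3:n] - F[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
  g
}

#' @export
print.walker_run <- function(x, ...) {
  tab <- table(factor(x$outcome, c("translocated", "reflected", "active")))
  cat(sprintf("Brownian walker run: %d walkers, dt = %.3g ns, D = %g nm^2/ns\n",
              length(x$outcome), x$dt, x$D))
  cat(sprintf("  z0 = %g, boundaries [%g (%s), %g (absorbing)] nm\n",
              x$z0, x$z_minus, x$boundary_lower, x$z_plus))
  cat(sprintf("  translocated %d, reflected %d, active %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Event table of a walker run
#'
#' @param run a `walker_run`.
#' @return Data frame with `walker`, `outcome`, `exit_time` (ns) and
#'   `max_z` (nm), suitable for writing as delimited text.
#' @export
walker_events <- function(run) {
  stopifnot(inherits(run, "walker_run"))
  data.frame(walker = seq_along(run$outcome), outcome = run$outcome,
             exit_time = run$exit_time, max_z = run$max_z)
}

#' One-way incoming rate versus z
#'
#' For each plane in `z_grid`, the rate (per ns) at which walkers make
#' their first forward crossing of the plane within the observation window,
#' computed from each walker's running maximum.  With a reflecting source
#' boundary and a window long enough to empty the source region, the curve
#' is flat for a featureless landscape, drops across diffusive constrictions
#' and barriers, and plateaus at the net translocation rate once past the
#' last rate-limiting feature.
#'
#' @param run a `walker_run` (a reflecting lower boundary with a finite
#'   `t_max` mimics a bulk reservoir feeding the pore).
#' @param z_grid planes at which to evaluate the rate, nm.
#' @param n_batches batches for the standard-error estimate.
#' @param normalize divide rates by the feed rate at the first plane.
#' @return Data frame with columns `z`, `rate` (first crossings per ns, or
#'   a fraction of the feed rate if normalised), `se`, and `zero_flag`
#'   marking planes with no crossings.
#' @export
one_way_rate <- function(run, z_grid = NULL, n_batches = 10, normalize = FALSE) {
  stopifnot(inherits(run, "walker_run"))
  if (is.null(z_grid))
    z_grid <- seq(run$z0, run$z_plus, length.out = 25)
  t_obs <- if (is.finite(run$t_max)) run$t_max else max(run$exit_time)
  n <- length(run$max_z)
  batch <- rep_len(seq_len(n_batches), n)
  rate <- se <- numeric(length(z_grid))
  for (i in seq_along(z_grid)) {
    crossed <- run$max_z >= z_grid[i]
    rate[i] <- sum(crossed) / t_obs
    per_batch <- tapply(crossed, batch, sum) * n_batches / t_obs
    se[i] <- sd(per_batch) / sqrt(n_batches)
  }
  out <- data.frame(z = z_grid, rate = rate, se = se, zero_flag = rate == 0)
  if (normalize) {
    feed <- out$rate[1]
    if (feed > 0) { out$rate <- out$rate / feed; out$se <- out$se / feed }
  }
  out
}

#' Net translocation rate of a run
#'
#' Translocated-walker count divided by the observation window (finite
#' `t_max`) or by the total simulated walker time otherwise.
#'
#' @param run a `walker_run`.
#' @return Rate in walkers/ns.
#' @export
translocation_rate <- function(run) {
  stopifnot(inherits(run, "walker_run"))
  t_obs <- if (is.finite(run$t_max)) run$t_max else sum(run$exit_time)
  sum(run$outcome == "translocated") / t_obs
}

#' Closed-form splitting probability under constant drift
#'
#' Probability that a walker started at `x` (fraction of the interval)
#' reaches the upper boundary before the lower one when the profile is a
#' linear ramp with total drop `u` (kBT): (1 - exp(-u x)) / (1 - exp(-u)).
#'
#' @param x relative start position in `[0, 1]`.
#' @param u total free-energy drop across the interval, kBT (0 = flat).
#' @return Probability in `[0, 1]`.
#' @examples
#' splitting_probability(0.5, 0)  # 0.5
#' @export
splitting_probability <- function(x, u) {
  stopifnot(all(x >= 0 & x <= 1))
  ifelse(rep(abs(u) < 1e-12, length(x)), x, (1 - exp(-u * x)) / (1 - exp(-u)))
}

#' Mean first-passage time by double quadrature
#'
#' The 1D Smoluchowski mean first-passage time from `z0` to the absorbing
#' plane `z_plus` with a reflecting plane at `z_minus`:
#' T = (1/D) int_{z0}^{z+} dy e^{F(y)} int_{z-}^{y} dx e^{-F(x)}.
#' Serves as the independent oracle for the stochastic walker.
#'
#' @param profile a [free_energy_profile()] (kBT).
#' @param D diffusion coefficient, nm^2/ns.
#' @param z0 start position, nm.
#' @param z_minus reflecting plane, nm.
#' @param z_plus absorbing plane, nm.
#' @param n_grid quadrature grid size (trapezoidal rule).
#' @return Mean first-passage time in ns.
#' @export
mfpt_quadrature <- function(profile, D, z0,
                            z_minus = min(profile$z), z_plus = max(profile$z),
                            n_grid = 6000) {
  stopifnot(inherits(profile, "free_energy_profile"), D > 0,
            z_minus <= z0, z0 < z_plus)
  yf <- seq(z_minus, z_plus, length.out = n_grid)
  Ff <- approx(profile$z, profile$F, xout = yf, rule = 2)$y
  cumtrapz <- function(x, y)
    c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
  inner <- cumtrapz(yf, exp(-Ff))          # int_{z-}^{y} e^{-F}
  yo <- seq(z0, z_plus, length.out = n_grid)
  Fo <- approx(profile$z, profile$F, xout = yo, rule = 2)$y
  Co <- approx(yf, inner, xout = yo)$y
  integrand <- exp(Fo) * Co
  sum(diff(yo) * (integrand[-length(integrand)] + integrand[-1]) / 2) / D
}
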