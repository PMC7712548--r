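## Transport-regime classification: the diffusion-limited voltage window,
## the chain inequality kb << ktilde_a << kd, the drift-versus-diffusion
## bulk supply comparison, and conductance-linearity classification of
## measurement tables.

#' Diffusion-limited voltage window
#'
#' The two-sided bound Theta kBT c ap hp^2 << q V << Theta kBT hp / (pi ap):
#' below the lower bound ions are not removed fast enough to build a
#' concentration gradient (and landscape features become relevant); above
#' the upper bound bulk drift dominates the supply.  Both bounds are linear
#' in Theta, so their ratio 1/(pi c ap^2 hp) is geometry-only.
#'
#' @param theta solid-angle factor.
#' @param cond a [conditions()] (concentration, temperature).
#' @param geometry a [pore_geometry()] (`ap`, `hp`).
#' @return List with `Vmin`, `Vmax` (V), `ratio` (Vmax/Vmin) and
#'   `no_window` (TRUE when Vmin >= Vmax).
#' @examples
#' w <- diffusion_window()
#' c(w$Vmin, w$Vmax) * 1e3   # ~(6, 330) mV
#' @export
diffusion_window <- function(theta = 4, cond = conditions(),
                             geometry = pore_geometry()) {
  ap <- geometry$effective_radius; hp <- geometry$effective_length
  stopifnot(theta > 0, ap > 0, hp > 0, cond$concentration > 0)
  vt <- thermal_voltage(cond)                        # kBT/q in volts
  c_nm3 <- cond$concentration_per_nm3
  Vmin <- theta * vt * c_nm3 * ap * hp^2             # lengths in nm cancel c in nm^-3
  Vmax <- theta * vt * hp / (pi * ap)
  out <- list(Vmin = Vmin, Vmax = Vmax, ratio = Vmax / Vmin,
              no_window = Vmin >= Vmax)
  if (out$no_window)
    warning("no diffusion-limited window: Vmin >= Vmax", call. = FALSE)
  out
}

#' Margins of the chain inequality kb << ktilde_a << kd
#'
#' Diffusion-limited transport requires both entrance and exit to be fast
#' compared to the bulk supply.  Returns the ratios kb/ktilde_a and
#' ktilde_a/kd and flags the diffusion-limited regime when both fall below
#' `threshold` (the operational meaning of "much less than").
#'
#' @param kb bulk feed rate, ions/ns.
#' @param ktilde_a effective association rate, ions/ns.
#' @param kd dissociation rate, ions/ns.
#' @param threshold margin below which "<<" is declared (default 1/3).
#' @return List with `margin_ba` (kb/ktilde_a), `margin_ad` (ktilde_a/kd),
#'   `diffusion_limited`, and `degenerate` (zero rates involved).
#' @examples
#' chain_inequality_margins(0.5, 12, 150)  # diffusion-limited
#' @export
chain_inequality_margins <- function(kb, ktilde_a, kd, threshold = 1/3) {
  stopifnot(kb >= 0, ktilde_a >= 0, kd >= 0, threshold > 0)
  margin_ba <- if (ktilde_a > 0) kb / ktilde_a else Inf
  margin_ad <- if (kd > 0) ktilde_a / kd else Inf
  list(margin_ba = margin_ba, margin_ad = margin_ad,
       diffusion_limited = margin_ba < threshold && margin_ad < threshold,
       degenerate = kb == 0 || ktilde_a == 0 || kd == 0)
}

#' Drift versus diffusion in the bulk supply
#'
#' Compares the drift-fed component kappa_b V of the bulk supply to the
#' diffusive capture rate kb0, and evaluates the thermal criterion
#' q Vb / kBT for the one-sided bulk voltage drop.  Diffusion dominates the
#' feed when both are small.  The crossover voltage (ratio = 1) is
#' kb0 / kappa_b.
#'
#' @param V applied voltage, V.
#' @param cond,ion,geometry conditions, ion and geometry objects.
#' @param theta capture solid-angle factor.
#' @param gamma_p pore resistivity, Ohm m.
#' @param kappa_b optional drift-feed coefficient, ions/(V ns); overrides
#'   the geometric estimate (e.g. to use a fitted value).
#' @param kb0 optional diffusive feed rate, ions/ns; overrides the capture
#'   estimate.
#' @return List with `drift` (kappa_b V), `diffusion` (kb0), `ratio`,
#'   `qVb_kBT` and `diffusion_dominant` (ratio < 1 and q Vb < kBT).
#' @examples
#' drift_vs_diffusion(0.1)$ratio   # diffusion dominates at 0.1 V
#' @export
drift_vs_diffusion <- function(V, cond = conditions(), ion = ion_species(),
                               geometry = pore_geometry(), theta = 4,
                               gamma_p = 2 * cond$bulk_resistivity,
                               kappa_b = NULL, kb0 = NULL) {
  stopifnot(V >= 0)
  if (is.null(kappa_b))
    kappa_b <- drift_feed_coefficient(geometry$effective_radius, gamma_p,
                                      geometry$effective_length)$value
  if (is.null(kb0))
    kb0 <- capture_rate(ion$diffusion_nm2_ns, cond$concentration_per_nm3,
                        geometry$effective_radius, theta)$value
  drift <- kappa_b * V
  qVb <- bulk_voltage_drop(V, geometry$effective_radius, cond$bulk_resistivity,
                           gamma_p, geometry$effective_length, cond)$Vb_kBT
  list(drift = drift, diffusion = kb0,
       ratio = if (kb0 > 0) drift / kb0 else Inf,
       qVb_kBT = qVb,
       crossover_voltage = if (kappa_b > 0) kb0 / kappa_b else Inf,
       diffusion_dominant = drift < kb0 && qVb < 1)
}

#' Classify conductance linearity per strain
#'
#' Fits the conductance G = I/V against V by weighted least squares within
#' each strain group and classifies the voltage response: `superlinear`
#' (G rises with V: activated, barrier-limited transport), `sublinear`
#' (G falls with V: diffusion-limited), or `ohmic` (slope indistinguishable
#' from zero at the confidence level).
#'
#' @param table a [measurement_table()] (needs >= 2 voltages per strain).
#' @param conf_level confidence level for the slope test.
#' @return Data frame with `strain`, `slope`, `slope_se` and `label`.
#' @export
conductance_linearity <- function(table, conf_level = 0.95) {
  stopifnot(is.data.frame(table))
  out <- do.call(rbind, lapply(split(table, table$strain), function(d) {
    if (length(unique(d$voltage)) < 2)
      stop("conductance_linearity needs at least 2 voltages per strain",
           call. = FALSE)
    G <- d$current / d$voltage
    se_G <- d$current_se / d$voltage
    w <- if (all(is.finite(se_G)) && all(se_G > 0)) 1 / se_G^2 else rep(1, nrow(d))
    fit <- lm(G ~ voltage, data = data.frame(G = G, voltage = d$voltage),
              weights = w)
    sl <- coef(fit)[["voltage"]]
    se <- sqrt(vcov(fit)["voltage", "voltage"])
    zc <- qnorm(1 - (1 - conf_level) / 2)
    label <- if (sl - zc * se > 0) "superlinear"
             else if (sl + zc * se < 0) "sublinear" else "ohmic"
    data.frame(strain = d$strain[1], slope = sl, slope_se = se, label = label)
  }))
  rownames(out) <- NULL
  out
}

#' Per-point transport-regime report
#'
#' Labels each (strain, voltage) measurement from the kinetic balance:
#' `barrier_limited` when the pore site is predominantly occupied
#' (P2 above `p2_threshold`; a localized ion blocks the pore and the
#' dissociation barrier controls the current), otherwise `diffusion_limited`
#' when the bulk feed is much smaller than the effective association rate
#' ktilde_a (1 - P2) and the drift component of the feed does not exceed
#' the diffusive one, `drift_limited` when the supply is bulk-limited but
#' predominantly drift-fed, and `mixed` in between.
#'
#' @param table a [measurement_table()] with a `P2` column.
#' @param kb0 diffusive feed rate, ions/ns.
#' @param kappa_b drift-feed coefficient, ions/(V ns).
#' @param ktilde_a effective association rate, ions/ns.
#' @param threshold "much less than" factor (default 3).
#' @param p2_threshold occupancy above which the pore counts as blocked.
#' @return The table with added columns `kb`, `ka_eff`, `supply_margin`
#'   (ktilde_a (1-P2) / kb) and `regime`.
#' @export
classify_regimes <- function(table, kb0, kappa_b, ktilde_a,
                             threshold = 3, p2_threshold = 0.5) {
  stopifnot(is.data.frame(table), kb0 >= 0, kappa_b >= 0, ktilde_a >= 0)
  kb <- kb0 + kappa_b * table$voltage
  ka_eff <- ktilde_a * (1 - table$P2)
  margin <- ifelse(kb > 0, ka_eff / kb, Inf)
  drift_dominant <- kappa_b * table$voltage > kb0
  regime <- ifelse(table$P2 >= p2_threshold, "barrier_limited",
            ifelse(margin >= threshold & !drift_dominant, "diffusion_limited",
            ifelse(margin >= threshold & drift_dominant, "drift_limited",
                   "mixed")))
  out <- table
  out$kb <- kb
  out$ka_eff <- ka_eff
  out$supply_margin <- margin
  out$regime <- regime
  out
}
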