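test_that("capture rate and drift feed are linear in their inputs", {
  set.seed(3)
  base <- capture_rate(1.9, 0.6, 0.1, 4)$value
  for (i in 1:5) {
    a <- exp(runif(1, -1, 1))
    expect_equal(capture_rate(1.9 * a, 0.6, 0.1, 4)$value, a * base,
                 tolerance = 1e-12)
    expect_equal(capture_rate(1.9, 0.6 * a, 0.1, 4)$value, a * base,
                 tolerance = 1e-12)
    expect_equal(capture_rate(1.9, 0.6, 0.1 * a, 4)$value, a * base,
                 tolerance = 1e-12)
  }
  expect_equal(capture_rate(c_per_nm3 = 0)$value, 0)
  ## solid-angle conventions rescale linearly: 2 pi vs 4
  expect_equal(capture_rate(theta = 2 * pi)$value,
               capture_rate(theta = 4)$value * pi / 2, tolerance = 1e-12)
  ## drift feed: quadratic in ap, inverse in gamma_p and hp
  k0 <- drift_feed_coefficient(0.1, 0.142, 1)$value
  expect_equal(drift_feed_coefficient(0.2, 0.142, 1)$value, 4 * k0,
               tolerance = 1e-12)
  expect_equal(drift_feed_coefficient(0.1, 0.284, 2)$value, k0 / 4,
               tolerance = 1e-12)
})

test_that("dissociation rate is the drift velocity over the site length", {
  ion <- ion_species()
  for (dp in c(0.4, 1)) {
    kd <- dissociation_rate(ion, Ud = 0, V = 1, hp = 1, delta_p = dp)$value
    vd_nm_ns <- ion$mobility * (1 / 1e-9) * 1e-9 * 1e9   # mu E in nm/ns
    expect_equal(kd * dp, vd_nm_ns, tolerance = 1e-12)
  }
  ## linear in voltage, Arrhenius-suppressed by the exit barrier
  expect_equal(dissociation_rate(ion, V = 0.5)$value,
               dissociation_rate(ion, V = 1)$value / 2, tolerance = 1e-12)
  expect_equal(dissociation_rate(ion, Ud = 3, V = 1)$value,
               arrhenius_rate(dissociation_rate(ion, Ud = 0, V = 1)$value, 3),
               tolerance = 1e-12)
  expect_equal(dissociation_rate(ion, Ud = 200, V = 1)$value, 0,
               tolerance = 1e-60)
})

test_that("arrhenius factor behaves", {
  expect_equal(arrhenius_rate(5, 0), 5)
  expect_equal(arrhenius_rate(5, log(2)), 2.5, tolerance = 1e-12)
})

test_that("pore plus access resistance follows the cylindrical-pore formula", {
  ## access only when the pore has no length
  expect_equal(pore_plus_access_resistance(0.071, 1, 0),
               0.071 / (2 * 1e-9), tolerance = 1e-12)
  oracle <- 0.071 * (1 / (2e-9) + 1e-9 / (pi * 1e-18))
  expect_equal(pore_plus_access_resistance(0.071, 1, 1), oracle,
               tolerance = 1e-12)
  ## superlinear decrease with radius
  expect_lt(pore_plus_access_resistance(0.071, 2, 1),
            pore_plus_access_resistance(0.071, 1, 1) / 2)
  expect_equal(access_resistance(0.071, 0.1), 0.071 / (4 * 0.1e-9),
               tolerance = 1e-12)
})

test_that("continuum conductance and permeability respect the Einstein relation", {
  ion <- ion_species()
  cp <- 0.602; Ap <- pi * 0.1^2; hp <- 1
  Gp <- continuum_pore_conductance(cp, ion$mobility, Ap, hp)
  Pp <- continuum_permeability(ion$diffusion_nm2_ns, hp)   # nm/ns == m/s
  ## Gp / (e Pp Ap cp) = mu / D = e / kBT
  ratio <- Gp / (1.602176634e-19 * Pp * (Ap * 1e-18) * (cp * 1e27))
  expect_equal(ratio, 1 / vt298, tolerance = 1e-10)
  expect_equal(continuum_pore_conductance(0, ion$mobility, Ap, hp), 0)
  expect_equal(continuum_pore_conductance(cp, ion$mobility, Ap, 2 * hp),
               Gp / 2, tolerance = 1e-12)
  expect_equal(continuum_permeability(ion$diffusion_nm2_ns, 2), Pp / 2,
               tolerance = 1e-12)
})

test_that("bulk voltage drop ties the access and drift-feed pictures together", {
  expect_equal(bulk_voltage_drop(0)$Vb, 0)
  vb <- bulk_voltage_drop(1, ap = 0.1, gamma_b = 0.071, gamma_p = 0.142,
                          hp = 1)
  expect_equal(vb$Vb, pi * 0.1 * 0.071 / (4 * 0.142 * 1), tolerance = 1e-12)
  ## Vb / Ra equals the drift-feed rate of the Eq.-13 estimate
  Ra <- access_resistance(0.071, 0.1)
  kappa <- drift_feed_coefficient(0.1, 0.142, 1)$value * 1e9   # ions/(V s)
  expect_equal((vb$Vb / Ra) / 1.602176634e-19, kappa * 1, tolerance = 1e-12)
})

test_that("the default pore obeys the printed rate hierarchy", {
  kd0 <- dissociation_rate(V = 1)$value
  drift <- drift_feed_coefficient()$value * 1
  kb0 <- capture_rate()$value
  expect_gt(kd0, drift)
  expect_gt(drift, kb0)
})

test_that("the estimate table collects the headline numbers", {
  est <- estimates_table()
  expect_true(all(c("capture_rate", "drift_feed_K_resistivity",
                    "diffusion_window_min", "constriction_entropy",
                    "nominal_radius_10pct") %in% est$quantity))
  expect_true(all(is.finite(est$value)))
  expect_true(all(est$value >= 0))
})
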