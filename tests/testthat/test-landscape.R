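test_that("dehydration fraction matches a Monte-Carlo volume oracle", {
  geom <- pore_geometry()
  ion <- ion_species()
  ## shell clear of the membrane
  expect_equal(dehydration_fraction(c(-1.5, 1.5), 1, geom, ion), c(0, 0))
  ## rejection-sampling oracle: uniform points on the shell sphere, count
  ## those inside the slab and outside the pore cylinder
  mc_fraction <- function(z0, R, half_slab, rp, n = 4e5) {
    u <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
    zz <- z0 + R * u
    rr <- R * sqrt(1 - u^2)
    mean(abs(zz) <= half_slab & rr >= rp)
  }
  set.seed(11)
  R <- ion$hydration_radii[1]
  for (z0 in c(0, 0.15, 0.3)) {
    expect_equal(dehydration_fraction(z0, 1, geom, ion),
                 mc_fraction(z0, R, geom$carbon_vdw_radius,
                             geometric_radius(0, geom)),
                 tolerance = 0.01)
  }
  ## wide pore swallows the whole shell
  wide <- pore_geometry(nominal_radius_0 = 0.6)
  expect_equal(dehydration_fraction(0, 1, wide, ion), 0)
})

test_that("model free energy reproduces the screened Coulomb closed form", {
  cond <- conditions()
  bare <- ion_species(hydration_energies = c(0, 0))
  single <- pore_charge_set(charge = -1, count = 1, radial_position = 0.5)
  ## constant permittivity 80: -1.44 eV nm / (80 * 0.5 nm) ~ -1.4 kBT
  got <- model_free_energy(0, bare, single, eps_pore = 80,
                           cond = conditions(epsilon_r = 80))
  expected <- -(e_SI / (4 * pi * eps0_SI) * 1e9) / (80 * 0.5) / vt298
  expect_equal(got, expected, tolerance = 1e-10)
  expect_lt(abs(got - (-1.4)), 0.05)
  ## no charges, no dehydration: identically zero
  none <- pore_charge_set(charge = 0, count = 1, radial_position = 0.3)
  expect_equal(model_free_energy(c(-1, 0, 1), bare, none), c(0, 0, 0))
  ## far field stays below kBT for the neutral crown-ether set
  expect_lt(abs(model_free_energy(1.0)), 1)
  expect_lt(abs(model_free_energy(-1.0)), 1)
  ## zero ion-group distance is rejected
  onaxis <- pore_charge_set(charge = -1, count = 1, radial_position = 0)
  expect_error(model_free_energy(0, bare, onaxis), "distance")
})

test_that("model free energy reduces to the bare Coulomb sum without hydration", {
  bare <- ion_species(hydration_energies = c(0, 0))
  ch <- crown_ether_charges(-0.54)
  cond <- conditions()
  z <- seq(-1, 1, 0.1)
  got <- model_free_energy(z, bare, ch, eps_pore = 4, cond = cond)
  r1 <- bare$hydration_radii[1]; r2 <- bare$hydration_radii[2]
  manual <- rep(0, length(z))
  for (g in seq_along(ch$charge)) {
    r <- sqrt((z - ch$axial_position[g])^2 + ch$radial_position[g]^2)
    frac <- pmin(1, pmax(0, (r - r1) / (r2 - r1)))
    eps <- 4 + frac * (cond$epsilon_r - 4)
    manual <- manual + ch$charge[g] * ch$count[g] *
      (e_SI / (4 * pi * eps0_SI) * 1e9) / (eps * r) / vt298
  }
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("voltage tilt drops q Vext across the membrane region", {
  p <- flat_profile(-1, 1, 0.05)
  tp <- tilt_profile(p, 0.25)
  u <- 0.25 / vt298
  ## total drop is exactly q Vext (telescoping)
  expect_equal(tp$F[1] - tp$F[length(tp$F)], -(-u), tolerance = 1e-12)
  ## interior slope ~ -9.7 kBT/nm, the ideal-field magnitude
  interior <- abs(p$z) < 0.45
  slope <- diff(tp$F[interior]) / diff(p$z[interior])
  expect_equal(mean(slope), -u / 1, tolerance = 1e-10)
  expect_lt(abs(mean(slope) + 9.73), 0.05)
  ## identity at zero voltage, additivity of successive tilts
  expect_equal(tilt_profile(p, 0)$F, p$F)
  t12 <- tilt_profile(tilt_profile(p, 0.1), 0.15)
  expect_equal(t12$F, tilt_profile(p, 0.25)$F, tolerance = 1e-12)
})

test_that("discrete gradients pair each minimum with the next maximum", {
  p <- free_energy_profile(c(-0.6, -0.4, -0.2, 0), c(5, 0, 5, 1))
  f <- discrete_gradients(p, smooth_window = 1, min_prominence = 0)
  expect_equal(nrow(f), 1L)
  expect_equal(f$gradient, 25)
  expect_equal(f$mean_position, -0.3)
  ## monotone profile has no climbing features
  mono <- free_energy_profile(seq(0, 1, 0.1), seq(0, 5, 0.5))
  expect_equal(nrow(discrete_gradients(mono)), 0L)
  ## invariance under adding a constant
  p2 <- free_energy_profile(p$z, p$F + 3.7)
  expect_equal(discrete_gradients(p2, 1, 0)$gradient, f$gradient)
})

test_that("discrete gradients agree with a brute-force extrema scan", {
  set.seed(5)
  z <- seq(-1, 1, by = 0.01)
  for (rep in 1:4) {
    centers <- runif(3, -0.7, 0.7)
    amps <- runif(3, -6, 6)
    F <- rowSums(sapply(1:3, function(i)
      amps[i] * exp(-(z - centers[i])^2 / (2 * 0.15^2))))
    p <- free_energy_profile(z, F)
    got <- discrete_gradients(p, smooth_window = 1, min_prominence = 0)
    oracle <- brute_force_features(z, F)
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(oracle))
      expect_equal(got$gradient, oracle$gradient, tolerance = 1e-12)
      expect_equal(got$mean_position, oracle$mean_position, tolerance = 1e-12)
    }
  }
})

test_that("feature relevance classification follows the ideal-field rule", {
  eq <- data.frame(z_min = -0.1, F_min = 0, z_max = 0.1, F_max = 8,
                   gradient = 40, mean_position = 0)
  ## large gradient survives a 0.25 V bias, merely reduced
  biased <- transform(eq, gradient = 30, F_max = 6)
  out <- classify_feature_relevance(eq, biased, Vext = 0.25)
  expect_equal(out$label, "reduced")
  ## feature absent from the biased landscape
  out2 <- classify_feature_relevance(eq, eq[0, ], Vext = 0.25)
  expect_equal(out2$label, "washed_out")
  expect_false(out2$matched)
  ## unchanged gradient despite a field that should bite: irrelevant
  biased3 <- transform(eq, gradient = 39)
  out3 <- classify_feature_relevance(eq, biased3, Vext = 0.25)
  expect_equal(out3$label, "irrelevant")
})

test_that("entropic confinement penalties evaluate and are antisymmetric", {
  expect_equal(constriction_entropy(0.28, 1.2), -log(pi * 0.28^2 / 1.2^2),
               tolerance = 1e-12)
  expect_lt(abs(constriction_entropy(0.28, 1.2) - 1.7), 0.2)
  ## Omega = 1 when the cylinder section equals the bulk cell
  l0 <- sqrt(pi) * 0.28
  expect_equal(constriction_entropy(0.28, l0), 0, tolerance = 1e-12)
  expect_equal(constriction_entropy(0.14, 1.2), -log(pi * 0.14^2 / 1.2^2),
               tolerance = 1e-12)
  expect_lt(abs(constriction_entropy(0.14, 1.2) - 3.2), 0.1)
  expect_equal(crossing_entropy(0.02, 0.28), 2 * log(14), tolerance = 1e-12)
  expect_lt(abs(crossing_entropy(0.02, 0.28) - 5), 0.3)
  expect_equal(crossing_entropy(0.28, 0.28), 0)
  expect_equal(well_entropy(0.3, 1.2), log(4), tolerance = 1e-12)
  ## swapping the length scales flips the sign
  expect_equal(crossing_entropy(0.28, 0.02), -crossing_entropy(0.02, 0.28))
  expect_equal(well_entropy(1.2, 0.3), -well_entropy(0.3, 1.2))
})

test_that("free-energy profiles round-trip through the text format", {
  z <- seq(-1, 1, 0.1)
  p <- free_energy_profile(z, sin(z), SE = rep(0.3, length(z)),
                           strain = 4, q_oxygen = -0.54, voltage = 0.25)
  path <- tempfile(fileext = ".csv")
  write_profile(p, path)
  back <- read_profile(path)
  expect_equal(back$z, p$z)
  expect_equal(back$F, p$F)
  expect_equal(back$SE, p$SE)
  expect_equal(back$strain, 4)
  expect_equal(back$q_oxygen, -0.54)
  expect_equal(back$voltage, 0.25)
})
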