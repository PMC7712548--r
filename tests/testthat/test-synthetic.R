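test_that("generation is fully deterministic under a fixed seed", {
  t1 <- generate_measurements(generator_spec(seed = 4))
  t2 <- generate_measurements(generator_spec(seed = 4))
  expect_identical(t1, t2)
  t3 <- generate_measurements(generator_spec(seed = 5))
  expect_false(identical(t1$current, t3$current))
})

test_that("model truth shows the occupancy and plateau phenomenology", {
  tab <- generate_measurements(generator_spec(seed = 1), noise = "none")
  for (V in unique(tab$voltage)) {
    d <- tab[tab$voltage == V, ]
    d <- d[order(d$strain), ]
    ## occupancy decays with strain; current grows and plateaus
    expect_true(all(diff(d$P2_model) < 0))
    expect_true(all(diff(d$current_model) > -1e-12))
    expect_lt(diff(tail(d$current_model, 2)) / tail(d$current_model, 1), 0.05)
  }
  for (s in unique(tab$strain)) {
    d <- tab[tab$strain == s, ]
    d <- d[order(d$voltage), ]
    expect_true(all(diff(d$P2_model) < 0))   # bias empties the pore
  }
  ## occupancy near one at the zero-strain, low-voltage corner
  expect_gt(tab$P2_model[tab$strain == 0 & tab$voltage == 0.1], 0.9)
  ## noise-free mode returns the deterministic values exactly
  expect_equal(tab$current, tab$current_model)
  expect_equal(tab$P2, tab$P2_model)
  expect_true(all(tab$current_se == 0))
})

test_that("counting noise is unbiased and its SE tracks the replica spread", {
  tab <- generate_measurements(generator_spec(seed = 20))
  z_cur <- (tab$current - tab$current_model) /
    pmax(tab$current_se, 1e-6)
  z_p2 <- (tab$P2 - tab$P2_model) / pmax(tab$P2_se, 1e-6)
  ## standardized deviations behave like unit-scale noise
  expect_gt(mean(abs(z_cur) < 3), 0.8)
  expect_gt(mean(abs(z_p2) < 3), 0.8)
  expect_lt(abs(mean(z_cur)), 0.6)
})

test_that("longer replicas shrink the counting error like a square root", {
  t_short <- generate_measurements(generator_spec(seed = 30, run_length = 50))
  t_long <- generate_measurements(generator_spec(seed = 30, run_length = 200))
  ratio <- median(t_short$current_se) / median(t_long$current_se)
  ## quadrupling the run length should halve the median SE, roughly
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("generated profiles carry the specified landscape features", {
  ## zero-amplitude specification yields a flat landscape
  flat_spec <- profile_spec(well_depth_0 = 0, barrier_strain_slope = 0,
                            satellite_heights = c(0, 0), se_level = 0)
  pf <- generate_profile(flat_spec, strain = 0)
  expect_equal(pf$F, rep(0, length(pf$z)))
  ## the electrostatically stabilised pore: central well with satellite
  ## barriers, giving at least one climbing feature of tens of kBT/nm
  p0 <- generate_profile(profile_spec(), strain = 0, seed = 17)
  feats <- discrete_gradients(p0)
  expect_gte(nrow(feats), 1)
  expect_gt(max(feats$gradient), 10)
  ## the well flattens with strain
  p8 <- generate_profile(profile_spec(se_level = 0), strain = 8)
  p0q <- generate_profile(profile_spec(se_level = 0), strain = 0)
  expect_gt(min(p8$F), min(p0q$F))
  ## voltage tilt is applied through the landscape machinery
  pv <- generate_profile(profile_spec(se_level = 0), strain = 0, Vext = 0.25)
  expect_equal(pv$F[1] - pv$F[length(pv$F)],
               0.25 / vt298, tolerance = 1e-10)
})

test_that("walker escape over a generated barrier matches the quadrature oracle", {
  nob <- profile_spec(well_depth_0 = 0, barrier_height_0 = 0,
                      barrier_strain_slope = 0, satellite_heights = c(0, 0),
                      se_level = 0)
  wb <- profile_spec(well_depth_0 = 0, barrier_height_0 = 4,
                     barrier_strain_slope = 0, satellite_heights = c(0, 0),
                     se_level = 0)
  z <- seq(-0.8, 0.8, 0.04)
  p_free <- generate_profile(nob, strain = 0, z = z)
  p_barr <- generate_profile(wb, strain = 0, z = z)
  D <- 2; z0 <- -0.7
  t_free <- mean(simulate_walkers(p_free, D, 300, z0, seed = 61,
                                  boundary_lower = "reflecting",
                                  t_max = Inf)$exit_time)
  t_barr <- mean(simulate_walkers(p_barr, D, 300, z0, seed = 62,
                                  boundary_lower = "reflecting",
                                  t_max = Inf)$exit_time)
  o_free <- mfpt_quadrature(p_free, D, z0)
  o_barr <- mfpt_quadrature(p_barr, D, z0)
  ## the barrier suppresses the crossing rate by the Kramers factor; the
  ## simulated ratio tracks the quadrature oracle within a factor of two
  expect_gt(o_barr / o_free, 3)
  expect_lt(abs(log((t_barr / t_free) / (o_barr / o_free))), log(2))
})
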