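test_that("measurement tables validate their contract", {
  good <- data.frame(strain = c(0, 2), voltage = 0.1, current = c(0.3, 0.4),
                     current_se = 0.02, P2 = c(0.9, 0.7), P2_se = 0.02)
  expect_s3_class(measurement_table(good), "measurement_table")
  expect_error(measurement_table(good[, -5]), "P2")
  bad <- good; bad$P2[1] <- 1.2
  expect_error(measurement_table(bad), "\\[0, 1\\]")
  dup <- rbind(good, good[1, ])
  expect_error(measurement_table(dup), "duplicate")
  ## file round trip is lossless
  tab <- generate_measurements(generator_spec(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_measurements(tab, path, comments = "round-trip check")
  back <- read_measurements(path)
  for (col in c("strain", "voltage", "current", "current_se", "P2", "P2_se"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
})

test_that("noise-free tables are fitted exactly", {
  tab <- generate_measurements(generator_spec(seed = 5), noise = "none")
  fit <- fit_bulk_model(tab)
  est <- setNames(fit$parameters$estimate, fit$parameters$parameter)
  expect_equal(est[["kb0"]], 0.5, tolerance = 1e-4)
  expect_equal(est[["kappa_b"]], 2.2, tolerance = 1e-4)
  expect_equal(est[["ktilde_a"]], 12, tolerance = 1e-3)
  expect_gt(fit$r_squared, 1 - 1e-8)
})

test_that("counting-noise tables recover the generating parameters within 2 SE", {
  tab <- generate_measurements(generator_spec(seed = 1))
  fit <- fit_bulk_model(tab)
  truth <- c(kb0 = 0.5, kappa_b = 2.2, ktilde_a = 12)
  for (i in seq_len(3)) {
    p <- fit$parameters$parameter[i]
    expect_lt(abs(fit$parameters$estimate[i] - truth[[p]]),
              2 * fit$parameters$se[i])
  }
  expect_gt(fit$adj_r_squared, 0.95)
})

test_that("fit is invariant to row order and equivariant under unit rescaling", {
  tab <- generate_measurements(generator_spec(seed = 6))
  fit <- fit_bulk_model(tab)
  shuffled <- measurement_table(as.data.frame(tab)[sample(nrow(tab)), ])
  fit2 <- fit_bulk_model(shuffled)
  expect_equal(sort(fit2$parameters$estimate), sort(fit$parameters$estimate),
               tolerance = 1e-5)
  ## currents in ions/us instead of ions/ns: rates scale by the same factor
  scaled <- as.data.frame(tab)
  scaled$current <- scaled$current * 1e3
  scaled$current_se <- scaled$current_se * 1e3
  fit3 <- fit_bulk_model(measurement_table(scaled))
  expect_equal(fit3$parameters$estimate, fit$parameters$estimate * 1e3,
               tolerance = 1e-6)
  expect_equal(fit3$r_squared, fit$r_squared, tolerance = 1e-8)
})

test_that("model comparison ranks the drift-fed truth above drift-only", {
  tab <- generate_measurements(generator_spec(seed = 9))
  f_drift <- fit_bulk_model(tab, "drift_fed")
  f_act <- fit_bulk_model(tab, "activated")
  f_only <- fit_bulk_model(tab, "drift_only")
  cmp <- compare_models(f_drift, f_act, f_only)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$model[1], "drift_fed")
  expect_equal(cmp$model[3], "drift_only")
  expect_true(cmp$rejected[cmp$model == "drift_only"])
  ## the activated alternative is a decent description away from the
  ## lowest voltage but pays there
  expect_gt(f_act$adj_r_squared, 0.9)
  expect_gte(cmp$low_voltage_rmse[cmp$model == "activated"],
             cmp$low_voltage_rmse[cmp$model == "drift_fed"])
  expect_error(compare_models(f_drift), "at least two")
  tab2 <- generate_measurements(generator_spec(seed = 10))
  expect_error(compare_models(f_drift, fit_bulk_model(tab2)), "identical data")
})

test_that("interpolated predictions follow the measured occupancy", {
  tab <- generate_measurements(generator_spec(seed = 12), noise = "none")
  fit <- fit_bulk_model(tab)
  pr <- predict(fit, strain = c(0, 1, 2), voltage = 1)
  d1 <- tab[tab$voltage == 1, ]
  expect_equal(pr$P2[1], d1$P2[d1$strain == 0])
  expect_equal(pr$P2[3], d1$P2[d1$strain == 2])
  ## linear interpolation between the 0 and 2 percent rows
  expect_equal(pr$P2[2], mean(c(pr$P2[1], pr$P2[3])), tolerance = 1e-12)
  expect_true(all(pr$current > 0))
})

test_that("kd extraction inverts the plateau balance", {
  ## trivial algebra with propagated errors
  one <- measurement_table(data.frame(strain = 0:1, voltage = 1,
                                      current = 1, current_se = 0.1,
                                      P2 = 0.5, P2_se = 0.05))
  kd <- extract_kd(one)
  expect_equal(kd$points$kd, c(2, 2))
  expect_equal(kd$points$kd_se, rep(2 * sqrt(0.1^2 / 1 + 0.1^2), 2),
               tolerance = 1e-12)
  ## zero-occupancy rows are excluded with a warning
  zr <- measurement_table(data.frame(strain = 0:2, voltage = 1,
                                     current = c(1, 1, 1), current_se = 0.1,
                                     P2 = c(0.5, 0, 0.25), P2_se = 0.02))
  expect_warning(kd0 <- extract_kd(zr), "excluded")
  expect_equal(nrow(kd0$points), 2)
  ## noise-free generator data: extraction is the identity on the truth
  spec <- generator_spec(seed = 3)
  tabnf <- generate_measurements(spec, noise = "none")
  kdnf <- suppressWarnings(extract_kd(tabnf))
  truth <- kd_truth(spec, kdnf$points$strain, kdnf$points$voltage)
  expect_equal(kdnf$points$kd, truth, tolerance = 1e-10)
  ## and the fitted strain law returns the generating exponent per voltage
  pv <- kdnf$per_voltage
  expect_equal(pv$exponent, rep(0.22, 4), tolerance = 1e-8)
  expect_equal(kdnf$combined$strain_exponent, 0.22, tolerance = 1e-8)
  expect_equal(kdnf$combined$voltage_exponent, 0.043, tolerance = 1e-6)
})
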