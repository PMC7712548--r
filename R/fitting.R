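## Fitting the site-eliminated chain current to (strain, voltage, current,
## P2) tables: the drift-fed bulk form kb = kb0 + kappa_b V, the activated
## alternative kb = kb0 exp(beta V), beta in kBT/V, the drift-only reduction,
## and the extraction of the dissociation rate from occupancy.

#' Measurement table of currents and occupancies
#'
#' Validates and classes a data frame of per-(strain, voltage) observables:
#' ion-counting current with standard error, pore-site occupancy P2 with
#' standard error, the rim oxygen charge and the replica count.
#'
#' @param df data frame with columns `strain` (%), `voltage` (V), `current`
#'   (ions/ns), `current_se`, `P2`, `P2_se`, and optionally `q_oxygen` (e)
#'   and `n_runs`.
#' @return The data frame with class `measurement_table`.
#' @export
measurement_table <- function(df) {
  need <- c("strain", "voltage", "current", "current_se", "P2", "P2_se")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"q_oxygen" %in% names(df)) df$q_oxygen <- NA_real_
  if (!"n_runs" %in% names(df)) df$n_runs <- NA_integer_
  if (any(df$P2 < 0 | df$P2 > 1, na.rm = TRUE))
    stop("'P2' must lie in [0, 1]", call. = FALSE)
  if (any(df$current_se < 0 | df$P2_se < 0, na.rm = TRUE))
    stop("standard errors must be non-negative", call. = FALSE)
  key <- paste(df$strain, df$voltage, df$q_oxygen)
  if (anyDuplicated(key))
    stop("duplicate (strain, voltage, q_oxygen) keys in measurement table",
         call. = FALSE)
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Read and write measurement tables
#'
#' Comma-separated text with a header row naming the columns and optional
#' `#`-prefixed comment lines.
#'
#' @param path file path.
#' @return `read_measurements()` returns a [measurement_table()].
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, comment.char = "#")
  measurement_table(df)
}

#' @rdname read_measurements
#' @param table a [measurement_table()].
#' @param comments optional character vector written as `#` header lines.
#' @export
write_measurements <- function(table, path, comments = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comments)) writeLines(paste("#", comments), con)
  write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## model prediction: I(V, P2) in ions/ns for a named parameter vector on
## the natural scale
predict_bulk_model <- function(par, voltage, P2, model, vt) {
  kb <- switch(model,
               drift_fed = par[["kb0"]] + par[["kappa_b"]] * voltage,
               activated = par[["kb0"]] * exp(par[["beta"]] * voltage),
               drift_only = par[["kappa_b"]] * voltage)
  current_from_occupancy_vec(kb, par[["ktilde_a"]], P2)
}

current_from_occupancy_vec <- function(kb, ktilde_a, P2) {
  ka_eff <- ktilde_a * (1 - P2)
  ifelse(ka_eff <= 0 | kb <= 0, 0, 1 / (1 / kb + 1 / ka_eff))
}

#' Fit the bulk-supply model to a measurement table
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of the
#' site-eliminated chain current I/q = (1/kb + 1/(ktilde_a (1-P2)))^-1
#' against measured currents, using the measured occupancies directly and
#' inverse-variance weights from the current standard errors.  Three model
#' forms for the bulk feed: `drift_fed` (kb = kb0 + kappa_b V), `activated`
#' (kb = kb0 exp(beta V), beta in kBT/V) and `drift_only` (kb0 = 0).  Rates are
#' fitted in log space so the solution is positive by construction;
#' standard errors come from the scaled covariance of the weighted fit via
#' the delta method.
#'
#' Because the measured occupancy enters the model nonlinearly, its
#' uncertainty is propagated into the weights (delta method,
#' `(dI/dP2)^2 P2_se^2` added to the current variance) and the fit is
#' iterated; this guards against attenuation of `ktilde_a` by occupancy
#' noise at near-blocked points.
#'
#' @param table a [measurement_table()] (>= 4 rows spanning >= 2 voltages).
#' @param model one of `"drift_fed"`, `"activated"`, `"drift_only"`.
#' @param cond a [conditions()] (thermal voltage for the activated form).
#' @param start optional named list of natural-scale starting values.
#' @param propagate_p2_error add the delta-method P2 contribution to the
#'   weights and re-fit (default TRUE).
#' @return An object of class `fit_result`: `parameters` (data frame of
#'   estimate/se on the natural scale), `model`, `r_squared`,
#'   `adj_r_squared`, `fitted`, `residuals`, `weighted_rss`, `n`, and the
#'   data the fit used.
#' @examples
#' spec <- generator_spec(seed = 7)
#' tab <- generate_measurements(spec)
#' fit <- fit_bulk_model(tab)
#' fit$parameters
#' @export
fit_bulk_model <- function(table, model = c("drift_fed", "activated", "drift_only"),
                           cond = conditions(), start = NULL,
                           propagate_p2_error = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(table, "data.frame"))
  d <- as.data.frame(table)
  if (nrow(d) < 4 || length(unique(d$voltage)) < 2)
    stop("fit needs >= 4 rows spanning >= 2 voltages", call. = FALSE)
  if (any(is.na(d$P2)))
    stop("fit requires measured P2 for every row", call. = FALSE)
  vt <- thermal_voltage(cond)
  w <- fit_weights(d$current_se)
  pnames <- switch(model,
                   drift_fed = c("kb0", "kappa_b", "ktilde_a"),
                   activated = c("kb0", "beta", "ktilde_a"),
                   drift_only = c("kappa_b", "ktilde_a"))
  if (is.null(start)) {
    imax <- max(d$current)
    start <- list(kb0 = max(0.5 * imax, 1e-3),
                  kappa_b = max(imax / max(d$voltage), 1e-3),
                  beta = 1,
                  ktilde_a = 5 * imax)
  }
  theta0 <- log(unlist(start)[pnames])
  can_propagate <- propagate_p2_error && all(is.finite(d$P2_se)) &&
    all(is.finite(d$current_se)) && any(d$P2_se > 0)
  n_pass <- if (can_propagate) 2L else 1L
  for (pass in seq_len(n_pass)) {
    resid_fun <- function(theta) {
      par <- exp(theta); names(par) <- pnames
      (predict_bulk_model(par, d$voltage, d$P2, model, vt) - d$current) * sqrt(w)
    }
    fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                              control = minpack.lm::nls.lm.control(maxiter = 500))
    if (fit$info == 0 || fit$info == 9)
      stop("bulk-model fit did not converge: ", fit$message, call. = FALSE)
    par <- exp(fit$par); names(par) <- pnames
    if (pass < n_pass) {
      pred <- predict_bulk_model(par, d$voltage, d$P2, model, vt)
      dIdP2 <- -pred^2 / (par[["ktilde_a"]] * (1 - d$P2)^2)
      dIdP2[!is.finite(dIdP2)] <- 0
      w <- 1 / (d$current_se^2 + (dIdP2 * d$P2_se)^2)
      theta0 <- fit$par
    }
  }
  theta <- fit$par
  n <- nrow(d); p <- length(pnames)
  rss <- sum(fit$fvec^2)
  sigma2 <- rss / (n - p)
  cov_theta <- tryCatch(sigma2 * solve(fit$hessian),
                        error = function(e) matrix(NA_real_, p, p))
  se_theta <- sqrt(pmax(0, diag(cov_theta)))
  se <- par * se_theta                      # delta method from log scale
  pred <- predict_bulk_model(par, d$voltage, d$P2, model, vt)
  res <- d$current - pred
  r2 <- weighted_r_squared(d$current, pred, w)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(parameters = data.frame(parameter = pnames, estimate = unname(par),
                                         se = unname(se)),
                 model = model, r_squared = r2, adj_r_squared = adj,
                 fitted = pred, residuals = res, weighted_rss = rss,
                 n = n, n_parameters = p, data = d,
                 weighting = if (can_propagate)
                   "inverse variance, P2 uncertainty propagated (delta method)"
                 else "inverse variance of current_se",
                 log_cov = cov_theta),
            class = "fit_result")
}

fit_weights <- function(se) {
  if (all(is.finite(se)) && all(se > 0)) 1 / se^2
  else rep(1, length(se))
}

weighted_r_squared <- function(y, pred, w) {
  mu <- weighted.mean(y, w)
  1 - sum(w * (y - pred)^2) / sum(w * (y - mu)^2)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Bulk-supply model fit (%s), n = %d\n", x$model, x$n))
  for (i in seq_len(nrow(x$parameters)))
    cat(sprintf("  %-9s %.4g +/- %.2g ions/ns%s\n", x$parameters$parameter[i],
                x$parameters$estimate[i], x$parameters$se[i],
                if (x$parameters$parameter[i] == "kappa_b") " per V"
                else if (x$parameters$parameter[i] == "beta") " (kBT/V, dimensionless rate exponent)" else ""))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f\n", x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Predict currents from a fit, interpolating occupancy in strain
#'
#' Occupancies between measured strains are obtained by linear
#' interpolation of the measured P2 within each voltage group, then fed
#' through the fitted current form.
#'
#' @param object a `fit_result`.
#' @param strain,voltage vectors of points to predict (recycled together).
#' @param cond a [conditions()].
#' @param ... unused.
#' @return Data frame with `strain`, `voltage`, `P2` (interpolated) and
#'   `current`.
#' @export
predict.fit_result <- function(object, strain, voltage, cond = conditions(), ...) {
  n <- max(length(strain), length(voltage))
  strain <- rep_len(strain, n); voltage <- rep_len(voltage, n)
  vt <- thermal_voltage(cond)
  par <- setNames(object$parameters$estimate, object$parameters$parameter)
  P2 <- numeric(n)
  for (i in seq_len(n)) {
    dv <- object$data[object$data$voltage == voltage[i], ]
    if (!nrow(dv))
      stop("no measured P2 at voltage ", voltage[i], " to interpolate", call. = FALSE)
    P2[i] <- approx(dv$strain, dv$P2, xout = strain[i], rule = 2)$y
  }
  data.frame(strain = strain, voltage = voltage, P2 = P2,
             current = predict_bulk_model(par, voltage, P2, object$model, vt))
}

#' Extract the dissociation rate from occupancy data
#'
#' On the current plateau the stage currents balance, so kd P2 = I/q and
#' each measurement yields kd = (I/q)/P2 directly (exit-site occupancy
#' taken as negligible).  Per-voltage weighted fits of the exponential
#' strain law kd = A exp(c s) and a combined fit
#' kd = B V exp(b q V / kBT + c s) are performed on the log scale, with
#' inverse-variance weights from the propagated per-point errors; when
#' those errors are available the parameter covariance uses them directly
#' (unit dispersion) instead of the short-sample residual variance.
#'
#' @param table a [measurement_table()]; rows with P2 = 0 are excluded with
#'   a warning.
#' @param cond a [conditions()].
#' @param conf_level confidence level for the prefactor interval.
#' @return An object of class `kd_extraction`: `points` (per-point kd with
#'   SE), `per_voltage` (data frame of A, c and SEs with prefactor CI per
#'   voltage), and `combined` (B, b, c with SEs and prefactor CI).
#' @examples
#' tab <- generate_measurements(generator_spec(seed = 3))
#' kd <- extract_kd(tab)
#' subset(kd$per_voltage, voltage == 1)
#' @export
extract_kd <- function(table, cond = conditions(), conf_level = 0.95) {
  d <- as.data.frame(table)
  drop <- !is.finite(d$P2) | d$P2 <= 0 | !is.finite(d$current) | d$current <= 0
  if (any(drop)) {
    warning(sum(drop), " row(s) with zero/invalid P2 or current excluded",
            call. = FALSE)
    d <- d[!drop, ]
  }
  if (!nrow(d)) stop("no usable rows for kd extraction", call. = FALSE)
  kd <- d$current / d$P2
  kd_se <- kd * sqrt((d$current_se / d$current)^2 + (d$P2_se / d$P2)^2)
  points <- data.frame(strain = d$strain, voltage = d$voltage,
                       kd = kd, kd_se = kd_se)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  log_kd <- log(kd)
  se_log <- ifelse(kd_se > 0, kd_se / kd, NA_real_)
  known_var <- all(is.finite(se_log)) && all(se_log > 0)
  w <- fit_weights(se_log)
  ## when the table carries per-point uncertainties, parameter covariance
  ## comes from those known variances ((X' W X)^-1, unit dispersion) rather
  ## than the few-degrees-of-freedom residual estimate
  wls <- function(X, y, idx) {
    fit <- lm(y[idx] ~ X[idx, ] - 1, weights = w[idx])
    cf <- unname(coef(fit))
    vc <- if (known_var) {
      Xw <- X[idx, , drop = FALSE] * sqrt(w[idx])
      solve(crossprod(Xw))
    } else unname(vcov(fit))
    list(cf = cf, vc = vc)
  }
  per_voltage <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$voltage),
    function(idx) {
      if (length(idx) < 2) return(NULL)
      f <- wls(cbind(1, d$strain), log_kd, idx)
      A <- exp(f$cf[1]); seA <- A * sqrt(f$vc[1, 1])
      data.frame(voltage = d$voltage[idx][1],
                 prefactor = A, prefactor_se = seA,
                 prefactor_lo = exp(f$cf[1] - zc * sqrt(f$vc[1, 1])),
                 prefactor_hi = exp(f$cf[1] + zc * sqrt(f$vc[1, 1])),
                 exponent = f$cf[2], exponent_se = sqrt(f$vc[2, 2]))
    }))
  rownames(per_voltage) <- NULL
  combined <- NULL
  if (length(unique(d$voltage)) >= 2) {
    vt <- thermal_voltage(cond)
    f <- wls(cbind(1, d$voltage / vt, d$strain), log_kd - log(d$voltage),
             seq_len(nrow(d)))
    combined <- list(prefactor = exp(f$cf[1]),
                     prefactor_se = exp(f$cf[1]) * sqrt(f$vc[1, 1]),
                     prefactor_lo = exp(f$cf[1] - zc * sqrt(f$vc[1, 1])),
                     prefactor_hi = exp(f$cf[1] + zc * sqrt(f$vc[1, 1])),
                     voltage_exponent = f$cf[2],
                     voltage_exponent_se = sqrt(f$vc[2, 2]),
                     strain_exponent = f$cf[3],
                     strain_exponent_se = sqrt(f$vc[3, 3]))
  }
  structure(list(points = points, per_voltage = per_voltage, combined = combined),
            class = "kd_extraction")
}

#' @export
print.kd_extraction <- function(x, ...) {
  cat(sprintf("kd extraction: %d points\n", nrow(x$points)))
  if (!is.null(x$per_voltage) && nrow(x$per_voltage)) {
    for (i in seq_len(nrow(x$per_voltage)))
      cat(sprintf("  %g V: kd = %.3g exp((%.3g +/- %.2g) s) ions/ns, prefactor CI [%.3g, %.3g]\n",
                  x$per_voltage$voltage[i], x$per_voltage$prefactor[i],
                  x$per_voltage$exponent[i], x$per_voltage$exponent_se[i],
                  x$per_voltage$prefactor_lo[i], x$per_voltage$prefactor_hi[i]))
  }
  if (!is.null(x$combined))
    cat(sprintf("  combined: kd = %.3g V exp(%.3g qV/kBT + %.3g s) ions/(V ns)\n",
                x$combined$prefactor, x$combined$voltage_exponent,
                x$combined$strain_exponent))
  invisible(x)
}

#' Rank competing bulk-supply model fits
#'
#' Ranks fits of the same data by adjusted R-squared and reports the
#' residual structure at the lowest voltage, where the drift-fed and
#' activated interpretations differ most; flags whether the drift-only
#' reduction (kb0 = 0) is rejected.
#'
#' @param ... two or more `fit_result` objects on identical data.
#' @return Data frame of class `model_comparison`, ranked best first, with
#'   columns `model`, `adj_r_squared`, `r_squared`, `low_voltage_rmse`,
#'   `parameters` (formatted) and `rejected`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "fit_result"))
    fits <- fits[[1]]
  if (length(fits) < 2) stop("supply at least two fit_result objects", call. = FALSE)
  key <- function(f) paste(f$data$strain, f$data$voltage, f$data$current,
                           collapse = ";")
  if (length(unique(vapply(fits, key, ""))) != 1)
    stop("fits were not performed on identical data", call. = FALSE)
  vmin <- min(fits[[1]]$data$voltage)
  rows <- do.call(rbind, lapply(fits, function(f) {
    low <- f$data$voltage == vmin
    data.frame(model = f$model,
               adj_r_squared = f$adj_r_squared,
               r_squared = f$r_squared,
               low_voltage_rmse = sqrt(mean(f$residuals[low]^2)),
               parameters = paste(sprintf("%s=%.3g", f$parameters$parameter,
                                          f$parameters$estimate), collapse = ", "))
  }))
  rows <- rows[order(-rows$adj_r_squared), ]
  best <- rows$adj_r_squared[1]
  rows$rejected <- rows$adj_r_squared < best - 0.01 &
    rows$low_voltage_rmse > rows$low_voltage_rmse[1]
  rownames(rows) <- NULL
  class(rows) <- c("model_comparison", "data.frame")
  rows
}
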