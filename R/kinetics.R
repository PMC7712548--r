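## The single-site and three-site one-way rate models: closed-form current,
## deterministic steady state, transient ODE solution, and the exact
## event-driven stochastic twin.
##
## Chain topology (all rates in ions/ns):
##   bulk <-> site1 (kb in, kb_out out)
##   site1 -> site2 (ka, one-way; optional ka_back)
##   site2 -> site3 (kd, one-way; optional kd_back)
##   site3 <-> bulk (kexit_out out, kexit_in in)

#' Kinetic rate set of the three-site chain
#'
#' Holds the rates of the site chain.  The bulk feed may be given directly
#' (`kb`) or through its voltage dependence: drift-fed
#' `kb = kb0 + kappa_b V`, or activated `kb = kb0 exp(beta V), beta in kBT/V`.
#' The effective association rate is `ktilde_a = ka * P1eq` with
#' `P1eq = kb / (kb + kb_out)`; supplying `ktilde_a` with `kb`/`kb_out` sets
#' `ka` implicitly.
#'
#' @param kb bulk-to-staging feed rate, ions/ns (or NULL to use kb0/kappa_b).
#' @param kb0 zero-voltage (diffusive) component of `kb`, ions/ns.
#' @param kappa_b drift-feed coefficient, ions/(V ns).
#' @param beta activation coefficient, kBT per volt (activated alternative).
#' @param kb_out staging-to-bulk return rate, ions/ns.
#' @param ka staging-to-pore association rate, ions/ns.
#' @param ktilde_a effective association rate ka * P1eq, ions/ns.
#' @param kd pore-to-exit-site dissociation rate, ions/ns.
#' @param kexit_in,kexit_out exit-site bulk exchange rates, ions/ns.
#' @param ka_back,kd_back optional backward rates (default 0: one-way pore).
#' @return An object of class `rate_set`.
#' @examples
#' r <- rate_set(kb = 0.5, kb_out = 0.5, ktilde_a = 12, kd = 20, kexit_out = 100)
#' steady_state_chain(r)
#' @export
rate_set <- function(kb = NULL, kb0 = NULL, kappa_b = NULL, beta = NULL,
                     kb_out = 0, ka = NULL, ktilde_a = NULL, kd = 0,
                     kexit_in = 0, kexit_out = 0,
                     ka_back = 0, kd_back = 0) {
  vals <- c(kb = kb, kb0 = kb0, kappa_b = kappa_b, beta = beta,
            kb_out = kb_out, ka = ka, ktilde_a = ktilde_a, kd = kd,
            kexit_in = kexit_in, kexit_out = kexit_out,
            ka_back = ka_back, kd_back = kd_back)
  if (any(vals < 0, na.rm = TRUE))
    stop("all rates must be non-negative", call. = FALSE)
  if (is.null(kb) && is.null(kb0))
    stop("supply 'kb' or its voltage form via 'kb0' (+ 'kappa_b' or 'beta')",
         call. = FALSE)
  rs <- structure(list(kb = kb, kb0 = kb0, kappa_b = kappa_b, beta = beta,
                       kb_out = kb_out, ka = ka, ktilde_a = ktilde_a, kd = kd,
                       kexit_in = kexit_in, kexit_out = kexit_out,
                       ka_back = ka_back, kd_back = kd_back),
                  class = "rate_set")
  if (!is.null(rs$ka) && !is.null(rs$ktilde_a) && !is.null(rs$kb)) {
    if (rs$ktilde_a > rs$ka + 1e-12)
      stop("'ktilde_a' cannot exceed 'ka'", call. = FALSE)
  }
  rs
}

#' @export
print.rate_set <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else sprintf("%.4g", v)
  cat("Rate set (ions/ns)\n")
  cat(sprintf("  kb: %s  (kb0: %s, kappa_b: %s /V, beta: %s kBT/V)\n",
              fmt(x$kb), fmt(x$kb0), fmt(x$kappa_b), fmt(x$beta)))
  cat(sprintf("  kb_out: %s  ka: %s  ktilde_a: %s  kd: %s\n",
              fmt(x$kb_out), fmt(x$ka), fmt(x$ktilde_a), fmt(x$kd)))
  cat(sprintf("  kexit_in: %s  kexit_out: %s  backward (ka', kd'): %s, %s\n",
              fmt(x$kexit_in), fmt(x$kexit_out), fmt(x$ka_back), fmt(x$kd_back)))
  invisible(x)
}

#' Evaluate the bulk feed rate at a voltage
#'
#' @param rates a [rate_set()].
#' @param V applied voltage, V.
#' @param cond a [conditions()] (unused by the current forms; kept for a
#'   stable interface).
#' @return `kb` in ions/ns: the stored `kb` if set, else
#'   `kb0 + kappa_b V` (drift-fed) or `kb0 exp(beta V)` (activated, `beta`
#'   in kBT/V).
#' @export
bulk_feed_rate <- function(rates, V = 0, cond = conditions()) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is.null(rates$kb)) return(rates$kb)
  if (!is.null(rates$kappa_b)) return(rates$kb0 + rates$kappa_b * V)
  ## beta in kBT per volt: the exponent beta V is the activation-barrier
  ## reduction in kBT at voltage V
  if (!is.null(rates$beta)) return(rates$kb0 * exp(rates$beta * V))
  rates$kb0
}

## resolve ka / ktilde_a / kb / kb_out into concrete chain rates
resolve_chain <- function(rates, V = 0, cond = conditions()) {
  kb <- bulk_feed_rate(rates, V, cond)
  kb_out <- rates$kb_out
  ka <- rates$ka
  if (is.null(ka)) {
    if (is.null(rates$ktilde_a))
      stop("rate set needs 'ka' or 'ktilde_a'", call. = FALSE)
    p1eq <- if (kb + kb_out > 0) kb / (kb + kb_out) else 1
    ka <- rates$ktilde_a / p1eq
  }
  list(kb = kb, kb_out = kb_out, ka = ka, kd = rates$kd,
       kexit_in = rates$kexit_in, kexit_out = rates$kexit_out,
       ka_back = rates$ka_back, kd_back = rates$kd_back)
}

#' Single-site one-way current and occupancy
#'
#' The minimal model: ions associate at `ka` and dissociate at `kd`, one
#' way.  The current is the harmonic sum I/q = (1/ka + 1/kd)^-1 and the
#' occupancy P = ka / (ka + kd), so that I/q = kd P = ka (1 - P).
#'
#' @param ka association rate, ions/ns.
#' @param kd dissociation rate, ions/ns.
#' @return List with `current` (ions/ns) and `P` (occupancy).
#' @examples
#' single_site_current(1, 3)  # current 0.75, P 0.25
#' @export
single_site_current <- function(ka, kd) {
  stopifnot(ka >= 0, kd >= 0)
  if (ka + kd == 0) stop("ka + kd must be positive", call. = FALSE)
  list(current = if (ka == 0 || kd == 0) 0 else 1 / (1 / ka + 1 / kd),
       P = ka / (ka + kd))
}

#' Closed-form chain current from the pore occupancy
#'
#' The site-eliminated form of the chain current:
#' I/q = (1/kb + 1/(ktilde_a (1 - P2)))^-1.  A fully blocked pore
#' (P2 = 1) carries zero current.
#'
#' @param kb bulk feed rate, ions/ns.
#' @param ktilde_a effective association rate, ions/ns.
#' @param P2 pore-site occupancy in `[0, 1]` (vectorised).
#' @return Current in ions/ns.
#' @examples
#' current_from_occupancy(0.72, 12, 0.999)  # blocked-pore limit
#' @export
current_from_occupancy <- function(kb, ktilde_a, P2) {
  stopifnot(kb >= 0, ktilde_a >= 0, all(P2 >= 0 & P2 <= 1))
  ka_eff <- ktilde_a * (1 - P2)
  ifelse(ka_eff == 0 | kb == 0, 0, 1 / (1 / kb + 1 / ka_eff))
}

#' Deterministic steady state of the three-site chain
#'
#' With `method = "mean_field"` (the model's rate equations), sets the
#' occupancy time derivatives to zero: the staging and exit occupancies are
#' slaved to the pore occupancy, leaving a single monotone balance equation
#' at the pore site that is solved to machine precision; at the fixed point
#' the three stage currents (bulk to staging, staging to pore, pore to
#' exit) agree to better than `tol`.  The rate equations
#' factorize the pair terms (P1 (1-P2) and so on), which is the
#' approximation the model itself makes.  `method = "exact"` instead solves
#' the stationary distribution of the underlying eight-state occupancy
#' Markov chain by linear algebra; its marginals differ from the mean-field
#' solution when blocking correlations between the staging and pore sites
#' are strong, and it is the reference the stochastic simulator
#' ([gillespie_chain()]) reproduces for any rate set.
#'
#' @param rates a [rate_set()].
#' @param V voltage at which the bulk feed is evaluated, V.
#' @param cond a [conditions()].
#' @param method `"mean_field"` (rate equations) or `"exact"`
#'   (master-equation stationary state).
#' @param tol residual tolerance on the stage currents (mean-field).
#' @param max_iter iteration cap (mean-field).
#' @return An object of class `chain_state`: occupancies `P1`, `P2`, `P3`,
#'   the `current` (ions/ns), the stage currents and the residual.
#' @examples
#' r <- rate_set(kb = 0.7, kb_out = 0.7, ka = 24, kd = 5, kexit_out = 100)
#' steady_state_chain(r)
#' steady_state_chain(r, method = "exact")
#' @export
steady_state_chain <- function(rates, V = 0, cond = conditions(),
                               method = c("mean_field", "exact"),
                               tol = 1e-12, max_iter = 20000) {
  method <- match.arg(method)
  k <- resolve_chain(rates, V, cond)
  if (method == "exact") return(exact_chain_state(k))
  ratescale <- max(1, k$kb, k$kb_out, k$ka, k$kd, k$kexit_in, k$kexit_out)
  if (k$kb == 0 && k$kexit_in == 0 && k$ka_back == 0 && k$kd_back == 0)
    return(chain_state(0, 0, 0, k))
  ## the staging and exit sites are slaved to the pore occupancy, so the
  ## fixed point reduces to a single balance equation at site 2
  P1_of <- function(P2) {
    a <- k$kb + k$ka_back * P2
    d <- a + k$kb_out + k$ka * (1 - P2)
    ifelse(d > 0, a / d, 0)
  }
  P3_of <- function(P2) {
    a <- k$kd * P2 + k$kexit_in
    d <- a + k$kexit_out + k$kd_back * (1 - P2)
    ifelse(d > 0, a / d, 0)
  }
  g <- function(P2) {
    P1 <- P1_of(P2); P3 <- P3_of(P2)
    k$ka * P1 * (1 - P2) + k$kd_back * P3 * (1 - P2) -
      k$ka_back * P2 * (1 - P1) - k$kd * P2 * (1 - P3)
  }
  P2 <- if (g(0) <= 0) 0 else if (g(1) >= 0) 1 else
    uniroot(g, c(0, 1), tol = .Machine$double.eps, maxiter = max_iter)$root
  st <- chain_state(P1_of(P2), P2, P3_of(P2), k)
  if (st$residual > tol * ratescale)
    stop(sprintf("steady_state_chain residual %.3g exceeds tolerance",
                 st$residual), call. = FALSE)
  st
}

## stationary distribution of the eight-state occupancy chain
exact_chain_state <- function(k) {
  states <- as.matrix(expand.grid(s1 = 0:1, s2 = 0:1, s3 = 0:1))
  n <- nrow(states)
  idx <- function(s) 1L + s[1] + 2L * s[2] + 4L * s[3]
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- states[i, ]
    put <- function(sn, r) if (r > 0) Q[i, idx(sn)] <<- Q[i, idx(sn)] + r
    if (!s[1])          put(c(1, s[2], s[3]), k$kb)
    if (s[1])           put(c(0, s[2], s[3]), k$kb_out)
    if (s[1] && !s[2])  put(c(0, 1, s[3]), k$ka)
    if (s[2] && !s[3])  put(c(s[1], 0, 1), k$kd)
    if (s[3])           put(c(s[1], s[2], 0), k$kexit_out)
    if (!s[3])          put(c(s[1], s[2], 1), k$kexit_in)
    if (s[2] && !s[1])  put(c(1, 0, s[3]), k$ka_back)
    if (s[3] && !s[2])  put(c(s[1], 1, 0), k$kd_back)
  }
  diag(Q) <- -rowSums(Q)
  ## solve pi Q = 0 with sum(pi) = 1: replace one balance equation
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pp <- solve(A, b)
  pp <- pmax(pp, 0); pp <- pp / sum(pp)
  P1 <- sum(pp * states[, 1]); P2 <- sum(pp * states[, 2])
  P3 <- sum(pp * states[, 3])
  J1 <- k$kb * sum(pp * (1 - states[, 1])) - k$kb_out * sum(pp * states[, 1])
  J2 <- k$ka * sum(pp * (states[, 1] * (1 - states[, 2]))) -
    k$ka_back * sum(pp * (states[, 2] * (1 - states[, 1])))
  J3 <- k$kd * sum(pp * (states[, 2] * (1 - states[, 3]))) -
    k$kd_back * sum(pp * (states[, 3] * (1 - states[, 2])))
  structure(list(P1 = P1, P2 = P2, P3 = P3,
                 current = J2,
                 stage_currents = c(bulk_in = J1, association = J2,
                                    dissociation = J3),
                 residual = max(abs(J1 - J2), abs(J2 - J3)),
                 method = "exact", distribution = pp),
            class = "chain_state")
}

chain_state <- function(P1, P2, P3, k) {
  J1 <- k$kb * (1 - P1) - k$kb_out * P1                       # bulk -> staging
  J2 <- k$ka * P1 * (1 - P2) - k$ka_back * P2 * (1 - P1)      # staging -> pore
  J3 <- k$kd * P2 * (1 - P3) - k$kd_back * P3 * (1 - P2)      # pore -> exit
  structure(list(P1 = P1, P2 = P2, P3 = P3,
                 current = J2,
                 stage_currents = c(bulk_in = J1, association = J2,
                                    dissociation = J3),
                 residual = max(abs(J1 - J2), abs(J2 - J3))),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("Chain state: P1 = %.4g, P2 = %.4g, P3 = %.4g\n",
              x$P1, x$P2, x$P3))
  cat(sprintf("  current %.6g ions/ns (stage residual %.2g)\n",
              x$current, x$residual))
  invisible(x)
}

#' Transient solution of the three-site chain
#'
#' Integrates the occupancy rate equations from an initial condition; the
#' trajectory converges to the [steady_state_chain()] fixed point.
#'
#' @param rates a [rate_set()].
#' @param P_init initial occupancies, length 3 in `[0, 1]`.
#' @param t_grid output times, ns.
#' @param V,cond voltage and conditions for the bulk feed.
#' @return Data frame with columns `time`, `P1`, `P2`, `P3`, `current`.
#' @examples
#' r <- rate_set(kb = 0.7, kb_out = 0.7, ka = 24, kd = 5, kexit_out = 100)
#' tr <- transient_chain(r, c(0, 0, 0), seq(0, 10, 0.1))
#' tail(tr, 1)
#' @export
transient_chain <- function(rates, P_init = c(0, 0, 0), t_grid = seq(0, 10, 0.1),
                            V = 0, cond = conditions()) {
  stopifnot(length(P_init) == 3, all(P_init >= 0 & P_init <= 1))
  k <- resolve_chain(rates, V, cond)
  deriv <- function(t, P, parms) {
    P1 <- P[1]; P2 <- P[2]; P3 <- P[3]
    dP1 <- k$kb * (1 - P1) - k$kb_out * P1 - k$ka * P1 * (1 - P2) +
      k$ka_back * P2 * (1 - P1)
    dP2 <- k$ka * P1 * (1 - P2) - k$kd * P2 * (1 - P3) -
      k$ka_back * P2 * (1 - P1) + k$kd_back * P3 * (1 - P2)
    dP3 <- k$kd * P2 * (1 - P3) - k$kexit_out * P3 + k$kexit_in * (1 - P3) -
      k$kd_back * P3 * (1 - P2)
    list(c(dP1, dP2, dP3))
  }
  sol <- deSolve::ode(y = P_init, times = t_grid, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", "P1", "P2", "P3")
  if (any(out[, 2:4] < -1e-8) || any(out[, 2:4] > 1 + 1e-8))
    stop("occupancy bounds violated during integration", call. = FALSE)
  out$P1 <- pmin(1, pmax(0, out$P1))
  out$P2 <- pmin(1, pmax(0, out$P2))
  out$P3 <- pmin(1, pmax(0, out$P3))
  out$current <- k$ka * out$P1 * (1 - out$P2) - k$ka_back * out$P2 * (1 - out$P1)
  out
}

#' Exact stochastic simulation of the three-site chain
#'
#' Event-driven (Gillespie) simulation of the occupancy Markov chain on
#' states \{0,1\}^3 with the one-way pore transitions.  Runs `n_replicas`
#' independent replicas; the current estimate counts pore-to-exit events
#' per unit time and the standard error across replicas is sqrt(var/n).
#'
#' @param rates a [rate_set()].
#' @param t_end simulated time per replica, ns.
#' @param seed RNG seed.
#' @param n_replicas independent replicas.
#' @param V,cond voltage and conditions for the bulk feed.
#' @param burn_in initial stretch (ns) excluded from the averages while the
#'   chain relaxes from its empty start (default a tenth of `t_end`).
#' @param record keep the event train (times and types) of each replica.
#' @param max_events cap on recorded events per replica.
#' @return An object of class `gillespie_run`: `P` (mean occupancies),
#'   `P_se`, `current`, `current_se`, per-replica tables, and the event
#'   trains when recorded.
#' @examples
#' r <- rate_set(kb = 0.7, kb_out = 0.7, ka = 24, kd = 5, kexit_out = 100)
#' g <- gillespie_chain(r, t_end = 200, seed = 1)
#' g$current
#' @export
gillespie_chain <- function(rates, t_end, seed = NULL, n_replicas = 5,
                            V = 0, cond = conditions(),
                            burn_in = 0.1 * t_end,
                            record = FALSE, max_events = 100000) {
  stopifnot(burn_in >= 0, burn_in < t_end)
  k <- resolve_chain(rates, V, cond)
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_replicas)
  for (i in seq_len(n_replicas)) {
    reps[[i]] <- cpp_gillespie(k$kb, k$kb_out, k$ka, k$kd,
                               k$kexit_in, k$kexit_out,
                               k$ka_back, k$kd_back,
                               t_end, burn_in, record, as.integer(max_events))
  }
  occ <- t(vapply(reps, function(r) c(r$P1, r$P2, r$P3), numeric(3)))
  colnames(occ) <- c("P1", "P2", "P3")
  cur <- vapply(reps, function(r) r$translocations / (t_end - burn_in),
                numeric(1))
  structure(list(P = colMeans(occ),
                 P_se = apply(occ, 2, function(x) sqrt(var(x) / length(x))),
                 current = mean(cur),
                 current_se = sqrt(var(cur) / length(cur)),
                 replica_occupancy = occ,
                 replica_current = cur,
                 events = if (record) lapply(reps, function(r)
                   data.frame(time = r$event_time, type = r$event_type)) else NULL,
                 t_end = t_end, n_replicas = n_replicas, seed = seed),
            class = "gillespie_run")
}

#' @export
print.gillespie_run <- function(x, ...) {
  cat(sprintf("Gillespie chain run: %d replicas x %g ns\n", x$n_replicas, x$t_end))
  cat(sprintf("  current %.4g +/- %.2g ions/ns\n", x$current, x$current_se))
  cat(sprintf("  P = (%.4g, %.4g, %.4g)\n", x$P[1], x$P[2], x$P[3]))
  invisible(x)
}
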