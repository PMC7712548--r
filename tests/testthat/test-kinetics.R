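test_that("single-site current follows the harmonic-sum closed form", {
  s <- single_site_current(1, 1)
  expect_equal(s$current, 0.5)
  expect_equal(s$P, 0.5)
  s2 <- single_site_current(1, 3)
  expect_equal(s2$current, 0.75)
  expect_equal(s2$P, 0.25)
  ## supply-limited regime: I -> ka when dissociation is fast
  s3 <- single_site_current(0.01, 1e6)
  expect_equal(s3$current, 0.01, tolerance = 1e-5)
  ## consistency I = kd P = ka (1 - P)
  expect_equal(s2$current, 3 * s2$P, tolerance = 1e-12)
  expect_equal(s2$current, 1 * (1 - s2$P), tolerance = 1e-12)
  expect_error(single_site_current(0, 0), "positive")
})

test_that("mean-field steady state satisfies the site-eliminated closed form", {
  ## the chain current must equal the two-parameter closed form whenever
  ## the chain's own P2 is fed back in, for any rate set (pure algebra of
  ## the elimination of sites 1 and 3)
  set.seed(202)
  for (i in 1:100) {
    r <- rand_rate_set()
    st <- steady_state_chain(r)
    ktilde <- r$ka * r$kb / (r$kb + r$kb_out)
    closed <- current_from_occupancy(r$kb, ktilde, st$P2)
    expect_equal(st$current, closed, tolerance = 1e-10)
    expect_true(all(c(st$P1, st$P2, st$P3) >= 0 &
                    c(st$P1, st$P2, st$P3) <= 1))
    expect_lt(st$residual, 1e-9)
  }
})

test_that("steady-state limits behave physically", {
  ## no feed, no current
  r0 <- rate_set(kb = 0, kb_out = 1, ka = 2, kd = 1, kexit_out = 5)
  expect_equal(steady_state_chain(r0)$current, 0)
  ## instantaneous dissociation and exit empty the pore: Eq. 9 at P2 = 0
  r <- rate_set(kb = 1, kb_out = 0.5, ka = 2, kd = 1e7, kexit_out = 1e9)
  st <- steady_state_chain(r)
  expect_lt(st$P2, 1e-5)
  expect_equal(st$current, 1 * 2 / (1 + 0.5 + 2), tolerance = 1e-4)
  ## blocked pore carries nothing
  expect_equal(current_from_occupancy(0.72, 12, 1), 0)
  ## supply-limited limit of the closed form
  expect_equal(current_from_occupancy(1e6, 12, 0.5), 12 * 0.5,
               tolerance = 1e-4)
})

test_that("current is monotone in each forward rate", {
  set.seed(77)
  for (i in 1:20) {
    r <- rand_rate_set()
    base <- steady_state_chain(r)$current
    up <- function(field, fac = 2) {
      r2 <- r; r2[[field]] <- r2[[field]] * fac
      steady_state_chain(r2)$current
    }
    expect_gte(up("kb"), base - 1e-12)
    expect_gte(up("ka"), base - 1e-12)
    expect_gte(up("kd"), base - 1e-12)
  }
})

test_that("transient solution relaxes to the steady state and stays bounded", {
  r <- rate_set(kb = 0.7, kb_out = 0.7, ka = 6, kd = 2, kexit_out = 40)
  st <- steady_state_chain(r)
  ## start at the fixed point: nothing moves
  tr0 <- transient_chain(r, c(st$P1, st$P2, st$P3), seq(0, 5, 0.5))
  expect_lt(max(abs(tr0$P2 - st$P2)), 1e-8)
  ## arbitrary start converges (horizon 100 / smallest positive rate)
  tr <- transient_chain(r, c(0.9, 0.1, 0.3), seq(0, 100 / 0.7, 1))
  last <- tr[nrow(tr), ]
  expect_lt(max(abs(c(last$P1 - st$P1, last$P2 - st$P2, last$P3 - st$P3))),
            1e-8)
  expect_true(all(tr[, c("P1", "P2", "P3")] >= 0 &
                  tr[, c("P1", "P2", "P3")] <= 1))
  ## blocked dissociation: the pore site fills monotonically
  rb <- rate_set(kb = 1, kb_out = 0.2, ka = 3, kd = 0)
  trb <- transient_chain(rb, c(0, 0, 0), seq(0, 50, 0.5))
  expect_true(all(diff(trb$P2) >= -1e-10))
  expect_gt(trb$P2[nrow(trb)], 0.999)
})

test_that("exact master-equation steady state is reproduced by the stochastic chain", {
  set.seed(99)
  for (i in 1:6) {
    r <- rand_rate_set(0.2, 5)
    ex <- steady_state_chain(r, method = "exact")
    g <- gillespie_chain(r, t_end = 800, seed = 1000 + i, n_replicas = 5)
    expect_lt(abs(g$current - ex$current), 3 * max(g$current_se, 1e-3))
    expect_lt(abs(g$P["P2"] - ex$P2), 3 * max(g$P_se["P2"], 1e-3))
  }
  ## exact solve balances its stage currents by construction
  ex <- steady_state_chain(rate_set(kb = 0.72, kb_out = 0.72, ka = 24,
                                    kd = 0.378, kexit_out = 189),
                           method = "exact")
  expect_lt(ex$residual, 1e-12)
})

test_that("mean-field and exact solutions separate when blocking correlations are strong", {
  ## the rate equations factorize P1(1-P2); with fast association and a
  ## slow pore the exact chain occupies the pore visibly less
  r <- rate_set(kb = 0.72, kb_out = 0.72, ka = 24, kd = 0.378,
                kexit_out = 189)
  mf <- steady_state_chain(r)
  ex <- steady_state_chain(r, method = "exact")
  expect_gt(mf$P2 - ex$P2, 0.1)
  ## and they agree when the pore site is fast (weak correlation)
  r2 <- rate_set(kb = 0.5, kb_out = 0.5, ka = 1, kd = 50, kexit_out = 500)
  expect_lt(abs(steady_state_chain(r2)$current -
                steady_state_chain(r2, method = "exact")$current) /
              steady_state_chain(r2)$current, 0.01)
})

test_that("the event-driven simulator is deterministic and respects blocking", {
  r <- rate_set(kb = 1, kb_out = 1, ka = 3, kd = 2, kexit_out = 20)
  g1 <- gillespie_chain(r, t_end = 50, seed = 4, n_replicas = 2, record = TRUE)
  g2 <- gillespie_chain(r, t_end = 50, seed = 4, n_replicas = 2, record = TRUE)
  expect_identical(g1$events, g2$events)
  expect_identical(g1$replica_current, g2$replica_current)
  ## kd = 0: at most one ion ever makes it to the exit side
  rb <- rate_set(kb = 2, kb_out = 1, ka = 5, kd = 0, kexit_out = 10)
  gb <- gillespie_chain(rb, t_end = 200, seed = 9, n_replicas = 3)
  expect_true(all(gb$replica_current * 200 <= 1))
})
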