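## shared fixtures: random rate sets, simple profiles, and the closed-form
## constants used as independent oracles

kB_SI <- 1.380649e-23
e_SI <- 1.602176634e-19
NA_SI <- 6.02214076e23
eps0_SI <- 8.8541878128e-12
vt298 <- kB_SI * 298 / e_SI

## log-uniform random rate set for chain consistency checks
rand_rate_set <- function(lo = 0.05, hi = 10) {
  r <- exp(runif(6, log(lo), log(hi)))
  rate_set(kb = r[1], kb_out = r[2], ka = r[3], kd = r[4],
           kexit_in = 0.1 * r[5], kexit_out = r[6])
}

## flat profile over [z_lo, z_hi]
flat_profile <- function(z_lo = -1, z_hi = 1, dz = 0.05) {
  z <- seq(z_lo, z_hi, by = dz)
  free_energy_profile(z, rep(0, length(z)))
}

## linear ramp with total drop u (kBT) from z_lo to z_hi
ramp_profile <- function(u, z_lo = -1, z_hi = 1, dz = 0.05) {
  z <- seq(z_lo, z_hi, by = dz)
  free_energy_profile(z, -u * (z - z_lo) / (z_hi - z_lo))
}

## single Gaussian barrier of given height (kBT)
barrier_profile <- function(height, sd = 0.12, z_lo = -0.8, z_hi = 0.8,
                            dz = 0.04) {
  z <- seq(z_lo, z_hi, by = dz)
  free_energy_profile(z, height * exp(-z^2 / (2 * sd^2)))
}

## brute-force extrema pairing oracle: every local minimum paired with the
## next local maximum at larger z, straight from the definition
brute_force_features <- function(z, F) {
  n <- length(F)
  is_min <- is_max <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    if (F[i] < F[i - 1] && F[i] < F[i + 1]) is_min[i] <- TRUE
    if (F[i] > F[i - 1] && F[i] > F[i + 1]) is_max[i] <- TRUE
  }
  feats <- NULL
  for (i in which(is_min)) {
    nxt <- which(is_max & seq_len(n) > i)
    nxt <- nxt[nxt < c(which(is_min), n + 1)[match(i, which(is_min)) + 1]]
    if (length(nxt)) {
      j <- nxt[1]
      feats <- rbind(feats, data.frame(
        z_min = z[i], F_min = F[i], z_max = z[j], F_max = F[j],
        gradient = (F[j] - F[i]) / (z[j] - z[i]),
        mean_position = (z[i] + z[j]) / 2))
    }
  }
  feats
}
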