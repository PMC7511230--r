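# Independent stochastic oracles used to validate the closed-form rates and
# probabilities. These deliberately avoid the package's own formulas.

# Monte-Carlo fraction of isotropic rays that hit a face-on disk of radius r
# at distance d (hit = ray crosses the disk plane inside the disk).
mc_cone_fraction <- function(d, r, n = 2e6) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  fwd <- u[, 1] > 0
  t <- d / u[fwd, 1]
  hit <- (t * u[fwd, 2])^2 + (t * u[fwd, 3])^2 <= r^2
  p <- sum(hit) / n
  list(est = p, se = sqrt(p * (1 - p) / n))
}

# Discrete-event impingement rate: microtubules nucleate isotropically at rate
# gamma, grow at Vg, and catastrophe at rate lambda (so the length reached is
# exponential with mean Vg/lambda); an impingement is a nucleation whose ray
# hits the disk and whose length reaches it. Rate = gamma * P(hit & survive).
mc_impingement <- function(d, r, gam, lam, Vg, n = 2e6) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  len <- stats::rexp(n, rate = lam / Vg)
  fwd <- u[, 1] > 0
  t <- ifelse(fwd, d / pmax(u[, 1], 1e-12), Inf)
  hit <- fwd & ((t * u[, 2])^2 + (t * u[, 3])^2 <= r^2) & (len >= t)
  p <- mean(hit)
  list(est = gam * p, se = gam * sqrt(p * (1 - p) / n))
}

# Sojourn-time Gillespie occupancy of one CFG contested by k centrosomes with
# impingement rates 'omegas' and detachment rate 'kappa' (alternating renewal:
# empty -> bound-to-i -> empty). Returns time-fraction bound to each, with a
# batch-means standard error.
gillespie_occupancy <- function(omegas, kappa, n_cycles = 2e5, n_batches = 20) {
  tot <- sum(omegas)
  tu <- stats::rexp(n_cycles, tot)
  who <- sample.int(length(omegas), n_cycles, replace = TRUE, prob = omegas / tot)
  tb <- stats::rexp(n_cycles, kappa)
  batch <- rep(seq_len(n_batches), length.out = n_cycles)
  occ <- sapply(seq_along(omegas), function(i) {
    per <- tapply(tb * (who == i), batch, sum) / tapply(tu + tb, batch, sum)
    c(mean(per), stats::sd(per) / sqrt(n_batches))
  })
  list(est = occ[1, ], se = occ[2, ])
}

# Immigration-death (M/M/infinity) population: arrivals Poisson(gamma),
# exponential lifetimes (rate lambda). Time-averaged population after burn-in,
# with a batch-means standard error.
birth_death_count <- function(gam, lam, t_total = 4000, burn = 400,
                              n_batches = 18) {
  n_arr <- stats::rpois(1, gam * t_total)
  starts <- sort(stats::runif(n_arr, 0, t_total))
  ends <- starts + stats::rexp(n_arr, lam)
  grid <- seq(burn, t_total, by = 2)
  N <- findInterval(grid, starts) - findInterval(grid, sort(ends))
  # contiguous batches (longer than the relaxation time 1/lambda) so the
  # batch means are effectively independent
  batch <- rep(seq_len(n_batches), each = ceiling(length(grid) / n_batches),
               length.out = length(grid))
  per <- tapply(N, batch, mean)
  list(est = mean(per), se = stats::sd(per) / sqrt(n_batches))
}

# Dense 6x6 linear solve of the coupled two-centrosome force balance,
# independent of the package's mode decomposition.
dense_velocities <- function(F1, F2, X1, X2, eta, nu) {
  S <- (X1 - X2) / sqrt(sum((X1 - X2)^2))
  SS <- outer(S, S)
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- diag(3) * eta + nu * SS
  A[1:3, 4:6] <- -nu * SS
  A[4:6, 4:6] <- diag(3) * eta + nu * SS
  A[4:6, 1:3] <- -nu * SS
  v <- solve(A, c(F1, F2))
  list(V1 = v[1:3], V2 = v[4:6])
}

# Monte-Carlo estimate of a half-surface area by sampling directions and
# averaging the area element rho^2/(u.n) over the hemisphere (x >= 0 times
# the sign), independent of the package quadrature.
mc_half_area <- function(geom, xsign = 1, n = 4e5) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  u <- u[u[, 1] * xsign > 0, , drop = FALSE]
  rho <- sqrt(1 / ((u[, 1] / geom$semi_axes[1])^2 +
                     (u[, 2] / geom$semi_axes[2])^2 +
                     (u[, 3] / geom$semi_axes[3])^2))
  p <- u * rho
  nrm <- implicit_and_normal(p, geom)$normal
  f <- rho^2 / rowSums(u * nrm)
  # hemisphere solid angle is 2*pi
  list(est = 2 * pi * mean(f), se = 2 * pi * stats::sd(f) / sqrt(nrow(u)))
}
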