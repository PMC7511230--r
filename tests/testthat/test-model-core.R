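test_that("steady-state microtubule statistics follow the exponential length distribution", {
  p <- motor_params()
  s <- mt_steady_state_stats(p)
  expect_equal(s$mt_count, 10000)
  expect_equal(s$density_at_zero, 500)
  # mean length against numerical quadrature of l * psi(l) / N
  psi <- function(l) p$nucleation_rate / p$growth_speed *
    exp(-l * p$catastrophe_rate / p$growth_speed)
  N <- integrate(psi, 0, Inf)$value
  ml <- integrate(function(l) l * psi(l), 0, Inf)$value / N
  expect_equal(s$mean_length, ml, tolerance = 1e-5)
  expect_equal(s$mean_length, 20)
  # doubling the catastrophe rate halves the count
  s2 <- mt_steady_state_stats(motor_params(catastrophe_rate = 0.05))
  expect_equal(s2$mt_count, 5000)
  expect_error(motor_params(catastrophe_rate = -1), "positive")
  expect_error(motor_params(nucleation_rate = 0), "positive")
})

test_that("cone fraction has the hemisphere and edge-on limits and matches ray-sampling MC", {
  # d -> 0 with face-on incidence opens to the half space
  expect_equal(cone_fraction(1e-9, 1, 1.5), 0.5, tolerance = 1e-6)
  # edge-on disk captures nothing
  expect_equal(cone_fraction(10, 0, 1.5), 0)
  # negative incidence clamps to zero
  expect_equal(cone_fraction(10, -0.5, 1.5), 0)
  # frozen Monte-Carlo value (2e7 isotropic rays): 5.5207e-3 +- 1.7e-5
  expect_equal(cone_fraction(10, 1, 1.5), 5.532e-3, tolerance = 1e-3)
  # fresh MC agreement within 3 SE
  set.seed(101)
  mc <- mc_cone_fraction(10, 1.5)
  expect_lt(abs(cone_fraction(10, 1, 1.5) - mc$est), 3 * mc$se)
  # monotone decreasing in distance
  d <- seq(2, 40, by = 2)
  expect_true(all(diff(cone_fraction(d, 1, 1.5)) < 0))
  expect_error(cone_fraction(-1, 1, 1.5), "> 0")
})

test_that("impingement rate matches its discrete-event oracle and the small-angle form", {
  p <- motor_params()
  # frozen discrete-event value at d = 10: 0.8381 +- 0.0032 (2e7 events)
  expect_equal(impingement_rate(10, 1, p), 0.8388, tolerance = 1e-3)
  expect_equal(impingement_rate(10, 1, p, form = "approx"), 0.8529, tolerance = 1e-3)
  # approx within 2% of exact at r/d = 0.15
  expect_lt(abs(impingement_rate(10, 1, p, form = "approx") /
                  impingement_rate(10, 1, p) - 1), 0.02)
  # vanishes at large distance; exact form bounded by gamma/2
  expect_lt(impingement_rate(1e4, 1, p), 1e-10)
  expect_lt(impingement_rate(1e-6, 1, p), p$nucleation_rate / 2 + 1e-9)
  # approx converges to exact as r/d -> 0 (< 1% relative error at r/d <= 0.1)
  for (d in c(15, 30, 60, 150)) {
    rel <- impingement_rate(d, 1, p, form = "approx") / impingement_rate(d, 1, p) - 1
    expect_lt(abs(rel), 0.01)
  }
  expect_error(impingement_rate(0, 1, p), "coincident")
})

test_that("exact impingement rate agrees with the stochastic oracle across parameter points", {
  set.seed(7)
  pts <- data.frame(
    d = c(5, 8, 10, 12, 15, 20, 25, 10, 10, 10),
    r = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 0.8, 2.5, 1.5),
    gam = c(250, 250, 250, 250, 250, 250, 250, 250, 250, 100),
    lam = c(0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.025, 0.05, 0.025, 0.025),
    Vg = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 1, 0.5)
  )
  for (i in seq_len(nrow(pts))) {
    q <- pts[i, ]
    p <- motor_params(nucleation_rate = q$gam, growth_speed = q$Vg,
                      catastrophe_rate = q$lam, capture_radius = q$r)
    mc <- mc_impingement(q$d, q$r, q$gam, q$lam, q$Vg)
    expect_lt(abs(impingement_rate(q$d, 1, p) - mc$est), 3 * mc$se,
              label = sprintf("point %d (d=%g, r=%g)", i, q$d, q$r))
  }
})

test_that("attachment probabilities implement quasi-steady competition", {
  # equal on/off rates occupy half the time
  expect_equal(attachment_probabilities(0.1, 0.1), 0.5)
  # frozen single- and two-centrosome values at the d = 10 impingement rate
  om <- impingement_rate(10, 1, motor_params())
  expect_equal(attachment_probabilities(om, 0.1), 0.8935, tolerance = 1e-3)
  p2 <- attachment_probabilities(c(om, om), 0.1)
  expect_equal(p2[1], p2[2])
  expect_equal(p2[1], 0.4719, tolerance = 1e-3)
  # competition reduces the single-centrosome probability
  expect_lt(p2[1], attachment_probabilities(om, 0.1))
  # total occupancy below one for any configuration
  set.seed(11)
  for (k in 1:20) {
    oms <- rexp(sample(1:4, 1), 1)
    P <- attachment_probabilities(oms, 0.1)
    expect_true(all(P >= 0 & P < 1))
    expect_lt(sum(P), 1)
  }
  expect_error(attachment_probabilities(1, 0), "positive")
})

test_that("attachment probabilities match the sojourn-time Gillespie oracle", {
  set.seed(23)
  params <- list(
    list(om = 0.84, kap = 0.1), list(om = 0.05, kap = 0.1),
    list(om = 2.5, kap = 0.1), list(om = 0.84, kap = 0.01),
    list(om = 0.84, kap = 1), list(om = c(0.84, 0.84), kap = 0.1),
    list(om = c(0.84, 0.2), kap = 0.1), list(om = c(0.1, 0.05), kap = 0.3),
    list(om = c(2, 0.5), kap = 0.05), list(om = c(0.3, 0.3), kap = 0.5)
  )
  for (q in params) {
    g <- gillespie_occupancy(q$om, q$kap, n_cycles = 3e5)
    P <- attachment_probabilities(q$om, q$kap)
    for (i in seq_along(P)) {
      expect_lt(abs(P[i] - g$est[i]), 3 * g$se[i],
                label = sprintf("omega=%s kappa=%g i=%d",
                                paste(q$om, collapse = ","), q$kap, i))
    }
  }
})

test_that("competition monotonicity: a second centrosome never raises the first's occupancy", {
  set.seed(31)
  for (k in 1:25) {
    om1 <- rexp(1, 1)
    om2 <- rexp(1, 1)
    kap <- runif(1, 0.01, 1)
    expect_lte(attachment_probabilities(c(om1, om2), kap)[1],
               attachment_probabilities(om1, kap))
  }
})

test_that("per-CFG forces respect the stoichiometric bound and the unbounded non-stoichiometric mean", {
  p <- motor_params()
  xi <- c(0, 0, 1)
  expect_equal(cfg_force(xi, p, "stoichiometric", P = 0), c(0, 0, 0))
  f <- cfg_force(xi, p, "stoichiometric", P = 0.8935)
  expect_equal(sqrt(sum(f^2)), 8.935, tolerance = 1e-9)
  expect_lte(sqrt(sum(f^2)), p$pull_force)
  # non-stoichiometric: f0 * Omega / kappa, mean bound microtubules > 1
  fn <- cfg_force(xi, p, "nonstoichiometric", omega = 0.8388)
  expect_equal(sqrt(sum(fn^2)), 83.88, tolerance = 1e-9)
  expect_gt(sqrt(sum(fn^2)), p$pull_force)
  # near contact the stoichiometric force saturates while the
  # non-stoichiometric force keeps growing
  d <- c(2, 1, 0.5, 0.25)
  om <- impingement_rate(d, 1, p)
  fs <- p$pull_force * vapply(om, attachment_probabilities, 0, kappa = p$detachment_rate)
  fns <- p$pull_force * om / p$detachment_rate
  expect_true(all(fs <= p$pull_force))
  expect_true(all(diff(fns) > 0))
  expect_gt(fns[4] / fs[4], 100)
})

test_that("net forces superpose per-CFG forces and respect layout symmetry", {
  p <- motor_params()
  # mirror-symmetric toy layout: 4 CFGs at +-y, +-z on a ring, normals outward
  lay <- data.frame(id = 1:4,
                    x = 0, y = c(15, -15, 0, 0), z = c(0, 0, 15, -15),
                    nx = 0, ny = c(1, -1, 0, 0), nz = c(0, 0, 1, -1),
                    side = "posterior")
  class(lay) <- c("cfg_layout", "data.frame")
  nf <- net_forces(matrix(c(0, 0, 0), 1), lay, p)
  expect_equal(max(abs(nf$forces)), 0, tolerance = 1e-9)
  # total equals the sum of per-CFG forces rebuilt from the attachment output
  X <- matrix(c(3, 1, -2), 1)
  nf2 <- net_forces(X, lay, p)
  manual <- colSums(nf2$attachment$P[, 1] * nf2$attachment$xi[, , 1]) * p$pull_force
  expect_equal(nf2$forces[1, ], manual, tolerance = 1e-12)
  # per-CFG occupancy bookkeeping: P_unbound + sum_i P_i = 1 exactly
  X2 <- rbind(c(-4, 0, 0), c(4, 0, 0))
  nf3 <- net_forces(X2, lay, p)
  om <- nf3$attachment$omega
  p_unbound <- p$detachment_rate / (rowSums(om) + p$detachment_rate)
  expect_equal(p_unbound + rowSums(nf3$attachment$P), rep(1, 4), tolerance = 1e-12)
  expect_error(net_forces(X, lay[0, ], p), "empty")
})

test_that("two parallel planes of CFGs pull a displaced centrosome back to the midplane", {
  prof <- run_scenario("two_plane_toy", offsets = c(-10, -5, 0, 5, 10))
  expect_equal(prof$force_z[3], 0, tolerance = 1e-9)
  # restoring: force opposes the offset
  expect_true(all(sign(prof$force_z[c(1, 2)]) == 1))
  expect_true(all(sign(prof$force_z[c(4, 5)]) == -1))
})
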