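test_that("force balance velocities solve the coupled linear system exactly", {
  mech <- mechanics_params(150, 100)
  X1 <- c(-5.5, 0, 0); X2 <- c(5.5, 0, 0)
  S <- (X1 - X2) / 11
  # opposing axial forces: separation rate 2F/(eta + 2 nu)
  v <- solve_velocities(100 * S, -100 * S, X1, X2, mech)
  expect_equal(sum((v$V1 - v$V2) * S), 2 * 100 / (150 + 2 * 100), tolerance = 1e-12)
  # against an independent dense 6x6 solve, including transverse components
  set.seed(3)
  for (k in 1:10) {
    F1 <- rnorm(3, 0, 50); F2 <- rnorm(3, 0, 50)
    ref <- dense_velocities(F1, F2, X1, X2, 150, 100)
    v <- solve_velocities(F1, F2, X1, X2, mech)
    expect_equal(v$V1, ref$V1, tolerance = 1e-10)
    expect_equal(v$V2, ref$V2, tolerance = 1e-10)
  }
  # nu = 0 decouples the drag
  v0 <- solve_velocities(c(30, 0, 0), c(0, -15, 0), X1, X2, mechanics_params(150, 0))
  expect_equal(v0$V1, c(30, 0, 0) / 150)
  expect_equal(v0$V2, c(0, -15, 0) / 150)
  # equal forces translate without elongation
  ve <- solve_velocities(c(10, 5, 0), c(10, 5, 0), X1, X2, mech)
  expect_equal(ve$V1, ve$V2)
  expect_equal(ve$V1, c(10, 5, 0) / 150)
  expect_error(solve_velocities(c(1, 0, 0), c(1, 0, 0), X1, X1, mech), "coincident")
})

test_that("parameter ramps interpolate linearly and clamp at the endpoints", {
  p <- motor_params()
  sch <- ramp_schedule("detachment_rate", 0.1, 0.02, t_start = 50, t_end = 150)
  expect_equal(apply_ramp(p, 0, sch)$detachment_rate, 0.1)
  expect_equal(apply_ramp(p, 50, sch)$detachment_rate, 0.1)
  expect_equal(apply_ramp(p, 100, sch)$detachment_rate, 0.06)
  expect_equal(apply_ramp(p, 200, sch)$detachment_rate, 0.02)
  expect_identical(apply_ramp(p, 77, NULL), p)
  expect_error(ramp_schedule("not_a_param", 1, 2, 0, 1), "unknown parameter")
  expect_error(ramp_schedule("detachment_rate", 1, 2, 5, 5), "t_end")
})

test_that("a single CFG pulls a single centrosome straight toward it", {
  g <- cell_geometry()
  lay <- data.frame(id = 1L, x = 25, y = 0, z = 0, nx = 1, ny = 0, nz = 0,
                    side = "posterior")
  class(lay) <- c("cfg_layout", "data.frame")
  cfg <- simulation_config(geometry = g, x0 = matrix(c(0, 3, 0), 1),
                           t_max = 30, record_stride = 1)
  traj <- run_simulation(cfg, layout = lay)
  # all displacement along the initial centrosome-to-CFG direction
  xi0 <- c(25, -3, 0) / sqrt(25^2 + 9)
  disp <- sweep(traj$X1, 2, traj$X1[1, ])
  along <- as.vector(disp %*% xi0)
  proj <- disp - along %o% xi0
  expect_lt(max(abs(proj)), 1e-9)
})

test_that("wild-type dynamics elongate to a stable asymmetric configuration", {
  cfg <- simulation_config(seed = 21, t_max = 600)
  traj <- run_simulation(cfg)
  expect_equal(traj$termination, "converged")
  nend <- length(traj$times)
  expect_equal(traj$L[1], 11, tolerance = 1e-9)
  expect_gt(traj$L[nend], traj$L[1])
  # posterior pole moved farther than the anterior pole
  expect_gt(abs(traj$X2[nend, 1] - 5.5), abs(traj$X1[nend, 1] + 5.5))
  # stationarity: residual net force below drag * speed tolerance
  fmag <- sqrt(rowSums(traj$forces^2))
  expect_lt(max(fmag), cfg$mechanics$centrosome_drag * cfg$speed_tolerance * 1.5)
  # deterministic rerun
  traj2 <- run_simulation(cfg)
  expect_identical(as.data.frame(traj), as.data.frame(traj2))
})

test_that("halving the time step moves the final poles by less than 0.1 um", {
  lay <- cfg_layout(seed = 33)
  t1 <- run_simulation(simulation_config(seed = 33, dt = 0.05, t_max = 600), layout = lay)
  t2 <- run_simulation(simulation_config(seed = 33, dt = 0.025, t_max = 600), layout = lay)
  d1 <- sqrt(sum((t1$X1[nrow(t1$X1), ] - t2$X1[nrow(t2$X1), ])^2))
  d2 <- sqrt(sum((t1$X2[nrow(t1$X2), ] - t2$X2[nrow(t2$X2), ])^2))
  expect_lt(max(d1, d2), 0.1)
})

test_that("explicit occupancy-ODE attachment mode reproduces the quasi-steady result", {
  lay <- cfg_layout(seed = 5)
  qs <- run_simulation(simulation_config(seed = 5, t_max = 400), layout = lay)
  od <- run_simulation(simulation_config(seed = 5, t_max = 400,
                                         attachment_dynamics = "ode"), layout = lay)
  nq <- length(qs$times); no <- length(od$times)
  expect_lt(abs(qs$L[nq] - od$L[no]), 0.3)
  expect_lt(abs(qs$center[nq, 1] - od$center[no, 1]), 0.3)
})

test_that("zero net force means a stationary state", {
  # two CFGs at opposite poles, centrosome at the centre: velocities vanish
  lay <- data.frame(id = 1:2, x = c(25, -25), y = 0, z = 0,
                    nx = c(1, -1), ny = 0, nz = 0,
                    side = c("posterior", "anterior"))
  class(lay) <- c("cfg_layout", "data.frame")
  nf <- net_forces(matrix(c(0, 0, 0), 1), lay, motor_params())
  expect_equal(max(abs(nf$forces)), 0, tolerance = 1e-12)
})

test_that("centrosome removal frees mid-cell CFGs and re-centres the survivor", {
  lay <- cfg_layout(cell_geometry(), n_total = 100, posterior_fraction = 0.5,
                    jitter_scale = 0.2, seed = 13)
  cfg <- simulation_config(layout = list(n_total = 100, posterior_fraction = 0.5,
                                         jitter_scale = 0.2),
                           seed = 13, t_max = 1500, speed_tolerance = 0.001,
                           events = list(list(time = 250,
                                              action = "remove_centrosome",
                                              which = 1)))
  # occupancy before removal, at the converged two-centrosome state
  pre <- run_simulation(simulation_config(seed = 13, t_max = 250,
                                          layout = list(n_total = 100,
                                                        posterior_fraction = 0.5,
                                                        jitter_scale = 0.2)),
                        layout = lay)
  traj <- run_simulation(cfg, layout = lay)
  expect_false(traj$active[1])
  expect_true(traj$active[2])
  # survivor's attachment probabilities at mid-cell CFGs strictly increase
  mid <- which(abs(lay$x) < 8)
  expect_true(length(mid) > 3)
  expect_true(all(traj$attachment$P[mid, 2] > pre$attachment$P[mid, 2]))
  # survivor ends within 1 um of the cell centre
  nend <- length(traj$times)
  expect_lt(sqrt(sum(traj$X2[nend, ]^2)), 1)
  # removing an already-removed centrosome errors
  st <- list(X = traj$X2[nend, , drop = FALSE], active = c(FALSE, TRUE))
  expect_error(remove_centrosome(st, 1), "already inactive")
})

test_that("trajectories round-trip through the TSV writer at 1e-9", {
  traj <- run_simulation(simulation_config(seed = 2, t_max = 60))
  path <- tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  orig <- as.data.frame(traj)
  expect_equal(names(back$data), names(orig))
  expect_equal(as.matrix(back$data), as.matrix(orig), tolerance = 1e-9)
  expect_equal(back$meta$termination, traj$termination)
  expect_equal(back$meta$seed, traj$config$seed)
  unlink(c(path, paste0(path, ".meta.yaml")))
})
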