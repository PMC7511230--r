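test_that("sigmoid fitting recovers exact parameters on noiseless curves", {
  t <- seq(0, 240, by = 1.5)
  y <- 12 + (24 - 12) / (1 + exp(-(t - 60) / 20))
  f <- fit_sigmoid(t, y, "rising")
  expect_equal(unname(coef(f)), c(12, 24, 60, 20), tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-8)
  expect_equal(predict(f, 60), 18, tolerance = 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-6)
  # falling sigmoid (centrosome-distance trace)
  d <- 10 + 6 / (1 + exp((t - 80) / 15))
  fd <- fit_sigmoid(t, d, "falling")
  expect_equal(unname(coef(fd)), c(10, 6, 80, 15), tolerance = 1e-6)
  # constant series degenerates gracefully: plateau equals baseline
  fc <- fit_sigmoid(t, rep(17, length(t)), "rising")
  expect_equal(fc$baseline, 17)
  expect_equal(fc$plateau, 17)
  expect_equal(elongation_rate(fc), 0)
  expect_error(fit_sigmoid(1:5, 1:5), "at least 8")
})

test_that("noisy sigmoid fits recover the plateau within 3 SE across replicates", {
  set.seed(77)
  t <- seq(0, 300, length.out = 200)
  truth <- c(IL = 12, FL = 24, t0 = 60, tau = 20)
  ests <- replicate(100, {
    y <- truth["IL"] + (truth["FL"] - truth["IL"]) /
      (1 + exp(-(t - truth["t0"]) / truth["tau"])) + rnorm(length(t), 0, 0.3)
    coef(fit_sigmoid(t, y, "rising"))["FL"]
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth["FL"]), 3 * se + 1e-3)
  expect_lt(sd(ests), 0.2) # individual fits are tight at this noise level
})

test_that("elongation rate equals the sigmoid derivative at the midpoint", {
  t <- seq(0, 240, by = 1)
  y <- 12 + (24 - 12) / (1 + exp(-(t - 60) / 30))
  f <- fit_sigmoid(t, y, "rising")
  expect_equal(elongation_rate(f), 0.1, tolerance = 1e-6)
  # numerical derivative of the fitted curve at t0
  h <- 1e-5
  dnum <- (predict(f, f$t_mid + h) - predict(f, f$t_mid - h)) / (2 * h)
  expect_equal(elongation_rate(f), dnum, tolerance = 1e-9)
  # doubling tau halves the rate
  y2 <- 12 + 12 / (1 + exp(-(t - 60) / 60))
  expect_equal(elongation_rate(fit_sigmoid(t, y2, "rising")),
               0.05, tolerance = 1e-6)
})

test_that("trait extraction round-trips a trajectory built from a known sigmoid", {
  # synthetic trajectory: poles separating along x following a sigmoid
  tt <- seq(0, 400, by = 2)
  L <- 11 + (24 - 11) / (1 + exp(-(tt - 90) / 25))
  traj <- structure(list(
    times = tt,
    X1 = cbind(-L / 2 + 1, 0 * tt, 0 * tt),
    X2 = cbind(L / 2 + 1, 0 * tt, 0 * tt),
    L = L,
    center = cbind(1 + 0 * tt, 0 * tt, 0 * tt),
    termination = "converged", active = c(TRUE, TRUE),
    config = list(geometry = cell_geometry())
  ), class = "spindle_trajectory")
  tr <- extract_traits(traj)
  expect_equal(tr$FL, 24, tolerance = 0.05)
  expect_equal(tr$IL, L[1], tolerance = 1e-9)
  expect_equal(tr$CL, 50)
  expect_equal(tr$CA, pi * 25 * 15, tolerance = 1e-9)
  expect_equal(tr$center_offset, 1)
  expect_true(tr$plateau_ok)
  # CD: posterior pole x -> L/2 + 1 -> 13.77..., distance from 25
  expect_equal(tr$CD, 25 - (24 / 2 + 1), tolerance = 0.1)
})

test_that("ordinary least squares association matches known lines and covers the truth", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1)
  a <- suppressWarnings(regress_traits(d, "y", "x")) # exact fit
  expect_equal(a$slope, 2, tolerance = 1e-12)
  expect_equal(a$intercept, 1, tolerance = 1e-12)
  expect_lt(a$p_value, 1e-20)
  # slope invariant under shifting y
  d$y2 <- d$y + 100
  expect_equal(suppressWarnings(regress_traits(d, "y2", "x"))$slope, 2, tolerance = 1e-12)
  expect_error(regress_traits(data.frame(x = rep(1, 10), y = 1:10), "y", "x"),
               "zero variance")
  # coverage: the 95% CI on the slope covers the truth in >= 93% of replicates
  set.seed(19)
  cover <- replicate(1000, {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100, 0, 0.7)
    a <- regress_traits(data.frame(x = x, y = y), "y", "x")
    abs(a$slope - 0.5) <= qt(0.975, 98) * a$slope_se
  })
  expect_gte(mean(cover), 0.93)
})

test_that("partial correlation removes a shared conditioner and keeps direct links", {
  set.seed(4)
  n <- 5000
  z <- rnorm(n)
  tab <- data.frame(z = z, y = z + rnorm(n), x = z + rnorm(n))
  # raw correlation positive, partial slope indistinguishable from zero
  expect_gt(regress_traits(tab, "y", "x")$slope, 0.3)
  pc <- partial_correlation(tab, "y", "x", "z")
  expect_lt(abs(pc$slope), 3 * pc$slope_se)
  # direct identity survives conditioning on an unrelated variable
  tab2 <- data.frame(x = rnorm(50), z = rnorm(50))
  tab2$y <- tab2$x
  expect_equal(suppressWarnings(partial_correlation(tab2, "y", "x", "z"))$slope,
               1, tolerance = 1e-9)
  # y, x unrelated to z: partial equals raw
  tab3 <- data.frame(x = rnorm(2000), z = rnorm(2000))
  tab3$y <- 0.7 * tab3$x + rnorm(2000, 0, 0.5)
  raw <- regress_traits(tab3, "y", "x")
  par <- partial_correlation(tab3, "y", "x", "z")
  expect_equal(par$slope, raw$slope, tolerance = 0.02)
  # constant conditioner: partial coincides with raw exactly
  tab3$c0 <- 5
  par0 <- partial_correlation(tab3, "y", "x", "c0")
  expect_equal(par0$slope, raw$slope, tolerance = 1e-12)
  expect_equal(par0$r, raw$r, tolerance = 1e-12)
  # the partial correlation coefficient is symmetric in y and x
  pc_yx <- partial_correlation(tab, "y", "x", "z")
  pc_xy <- partial_correlation(tab, "x", "y", "z")
  expect_equal(pc_yx$r, pc_xy$r, tolerance = 1e-12)
})

test_that("model signature tests flag the generating model and report diagnostics", {
  tab <- generate_trait_table("timer", n_lines = 400, seed = 8)
  v <- model_signature_tests(tab)
  expect_s3_class(v, "model_verdicts")
  expect_true(v$consistent[v$model == "Timer"])
  expect_false(v$consistent[v$model == "Boundary"])
  vb <- model_signature_tests(generate_trait_table("boundary", n_lines = 400, seed = 8))
  expect_true(vb$consistent[vb$model == "Boundary"])
  vl <- model_signature_tests(generate_trait_table("limiting_component",
                                                   n_lines = 400, seed = 8))
  expect_true(vl$consistent[vl$model == "LimitingComponent"])
  expect_error(model_signature_tests(data.frame(IL = 1:5, FL = 1:5)),
               "missing trait columns")
})
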