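#' Fit a sigmoid to a spindle-trait time series
#'
#' Rising form (spindle length):
#' \deqn{l(t) = IL + \frac{FL - IL}{1 + e^{-(t - t_0)/\tau_s}}}
#' Falling form (posterior-centrosome distance from the posterior cell edge):
#' \deqn{d(t) = CD + \frac{A}{1 + e^{(t - t_1)/\tau_C}}}
#' Fitted by Levenberg-Marquardt nonlinear least squares with data-driven
#' initialisation: baseline and plateau from the first/last decile means, the
#' midpoint from the half-range crossing, and the timescale from a quarter of
#' the 10--90\% transition interval. An essentially constant series (range
#' below \code{1e-8}) short-circuits to a degenerate fit with equal baseline
#' and plateau.
#'
#' @param times Numeric vector of time points (s), length >= 8.
#' @param values Trait values (um).
#' @param kind \code{"rising"} or \code{"falling"}.
#' @param baseline Optional fixed baseline. Recorded series that begin at the
#'   transition onset (no pre-transition plateau, as in simulated anaphase
#'   traces) do not constrain the sigmoid's lower tail; fixing the baseline at
#'   the known initial value removes that degeneracy.
#' @return An object of class \code{sigmoid_fit} with fields \code{baseline}
#'   (IL, or plateau CD for falling fits), \code{plateau} (FL for rising; for
#'   falling fits the early-time level CD + A), \code{amplitude}, \code{t_mid}
#'   (t0 / t1), \code{timescale} (tau, s), \code{residual_rms}, \code{kind},
#'   \code{converged}, and the underlying \code{nls} fit (or \code{NULL} for
#'   degenerate input).
#' @examples
#' t <- seq(0, 200, by = 1)
#' l <- 12 + (24 - 12) / (1 + exp(-(t - 60) / 20))
#' coef(fit_sigmoid(t, l))
#' @export
fit_sigmoid <- function(times, values, kind = c("rising", "falling"),
                        baseline = NULL) {
  kind <- match.arg(kind)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 8) stop("fit_sigmoid: need at least 8 finite points", call. = FALSE)
  o <- order(times)
  times <- times[o]; values <- values[o]

  n <- length(values)
  k <- max(2L, ceiling(n / 10))
  lo <- mean(values[seq_len(k)])
  hi <- mean(values[seq(n - k + 1, n)])
  rng <- range(values)
  if (diff(rng) < 1e-8) {
    fit <- structure(list(baseline = mean(values), plateau = mean(values),
                          amplitude = 0, t_mid = mean(times),
                          timescale = diff(range(times)) / 4,
                          residual_rms = stats::sd(values),
                          kind = kind, converged = TRUE, fit = NULL,
                          times = times, values = values),
                     class = "sigmoid_fit")
    return(fit)
  }
  half <- (lo + hi) / 2
  cross <- if (hi >= lo) which(values >= half) else which(values <= half)
  t0 <- if (length(cross)) times[cross[1]] else stats::median(times)
  q10 <- lo + 0.1 * (hi - lo); q90 <- lo + 0.9 * (hi - lo)
  inq <- if (hi >= lo) which(values >= q10 & values <= q90) else which(values <= q10 & values >= q90)
  tau0 <- if (length(inq) >= 2) max(diff(range(times[inq])) / 4, 1e-3) else diff(range(times)) / 8

  df <- data.frame(t = times, y = values)
  fit <- tryCatch({
    if (kind == "rising" && !is.null(baseline)) {
      df$IL0 <- baseline
      minpack.lm::nlsLM(y ~ IL0 + (FL - IL0) / (1 + exp(-(t - t0) / tau)),
                        data = df,
                        start = list(FL = hi, t0 = t0, tau = tau0),
                        lower = c(-Inf, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else if (kind == "rising") {
      minpack.lm::nlsLM(y ~ IL + (FL - IL) / (1 + exp(-(t - t0) / tau)),
                        data = df,
                        start = list(IL = lo, FL = hi, t0 = t0, tau = tau0),
                        lower = c(-Inf, -Inf, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ CD + A / (1 + exp((t - t1) / tau)),
                        data = df,
                        start = list(CD = hi, A = lo - hi, t1 = t0, tau = tau0),
                        lower = c(-Inf, -Inf, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf(paste0("fit_sigmoid: nonlinear least squares failed (%s); ",
                        "initialisation: baseline=%.4g plateau=%.4g t_mid=%.4g tau=%.4g; ",
                        "data range %.4g..%.4g"),
                 conditionMessage(fit), lo, hi, t0, tau0, rng[1], rng[2]),
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (kind == "rising" && !is.null(baseline)) cf["IL"] <- baseline
  res_rms <- sqrt(mean(stats::residuals(fit)^2))
  out <- if (kind == "rising") {
    list(baseline = unname(cf["IL"]), plateau = unname(cf["FL"]),
         amplitude = unname(cf["FL"] - cf["IL"]), t_mid = unname(cf["t0"]),
         timescale = unname(cf["tau"]))
  } else {
    list(baseline = unname(cf["CD"]), plateau = unname(cf["CD"] + cf["A"]),
         amplitude = unname(cf["A"]), t_mid = unname(cf["t1"]),
         timescale = unname(cf["tau"]))
  }
  structure(c(out, list(residual_rms = res_rms, kind = kind,
                        converged = TRUE, fit = fit,
                        times = times, values = values)),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  if (object$kind == "rising") {
    c(IL = object$baseline, FL = object$plateau, t0 = object$t_mid,
      tau_s = object$timescale)
  } else {
    c(CD = object$baseline, A = object$amplitude, t1 = object$t_mid,
      tau_C = object$timescale)
  }
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit (%s):\n", x$kind))
  print(round(coef(x), 4))
  cat(sprintf("  residual RMS: %.4g\n", x$residual_rms))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, times = object$times, ...) {
  if (object$kind == "rising") {
    object$baseline + (object$plateau - object$baseline) /
      (1 + exp(-(times - object$t_mid) / object$timescale))
  } else {
    object$baseline + object$amplitude /
      (1 + exp((times - object$t_mid) / object$timescale))
  }
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$values - predict(object)
}

#' Elongation rate at the sigmoid midpoint
#'
#' The derivative of the rising sigmoid at its midpoint \eqn{t_0},
#' \eqn{ER = (FL - IL) / (4 \tau_s)} (um/s) -- the maximum rate of spindle
#' elongation.
#'
#' @param fit A rising \code{\link{fit_sigmoid}} result.
#' @return Elongation rate (um/s).
#' @export
elongation_rate <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (fit$timescale <= 0) return(0)
  (fit$plateau - fit$baseline) / (4 * fit$timescale)
}

#' Extract spindle traits from a simulated trajectory
#'
#' Fits the rising sigmoid to spindle length L(t) for IL, FL, tau_s, t0 and
#' the elongation rate ER = (FL - IL)/(4 tau_s); fits the falling sigmoid to
#' the distance of the posterior pole from the posterior cell edge for the
#' final centrosome distance CD; and reports geometric traits: cell length
#' CL = 2 Rx, midplane cross-sectional area CA (the area of the x-y midplane
#' superellipse, an image-plane proxy for cell size), and the final
#' spindle-centre offset along x. A plateau flag records whether the final
#' 10\% of samples vary by less than 0.5 um.
#'
#' @param traj A \code{\link{run_simulation}} trajectory with two centrosomes.
#' @param geom The cell geometry (defaults to the trajectory's).
#' @return One-row data frame with columns IL, FL, ER, tau_s, t0, CD, CL, CA,
#'   center_offset, plateau_ok, termination.
#' @export
extract_traits <- function(traj, geom = traj$config$geometry) {
  stopifnot(inherits(traj, "spindle_trajectory"))
  if (all(is.na(traj$L))) {
    stop("extract_traits: trajectory has no two-centrosome spindle length record",
         call. = FALSE)
  }
  keep <- !is.na(traj$L)
  tt <- traj$times[keep]; LL <- traj$L[keep]
  n <- length(LL)
  tail_idx <- seq(max(1, ceiling(0.9 * n)), n)
  plateau_ok <- diff(range(LL[tail_idx])) < 0.5
  if (!plateau_ok) {
    warning("extract_traits: no plateau detected in the final 10% of samples")
  }
  # simulated traces start at anaphase onset: the recorded first length IS the
  # initial (metaphase) spindle length, so the baseline is fixed there
  lfit <- fit_sigmoid(tt, LL, "rising", baseline = LL[1])

  # posterior pole = the centrosome with the larger final x
  post_is_2 <- traj$X2[n, 1] >= traj$X1[n, 1]
  xpost <- if (post_is_2) traj$X2[keep, 1] else traj$X1[keep, 1]
  Rx <- geom$semi_axes[1]
  dpost <- Rx - xpost
  cdfit <- tryCatch(fit_sigmoid(tt, dpost, "falling"), error = function(e) NULL)
  CD <- if (is.null(cdfit)) mean(dpost[tail_idx]) else cdfit$baseline

  E <- geom$exponents; R <- geom$semi_axes
  CA <- 4 * R[1] * R[2] * gamma(1 + 1 / E[1]) * gamma(1 + 1 / E[2]) /
    gamma(1 + 1 / E[1] + 1 / E[2])

  data.frame(IL = lfit$baseline, FL = lfit$plateau,
             ER = elongation_rate(lfit),
             tau_s = lfit$timescale, t0 = lfit$t_mid,
             CD = CD, CL = 2 * R[1], CA = CA,
             center_offset = traj$center[n, 1],
             plateau_ok = plateau_ok,
             termination = traj$termination,
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares association between two traits
#'
#' Fits \eqn{y = m x + b} and reports the regression coefficient with its
#' standard error and the two-sided t-test p-value for m = 0, plus the Pearson
#' correlation.
#'
#' @param table Data frame of traits (one row per line/run).
#' @param y,x Column names.
#' @return An object of class \code{trait_assoc} with fields \code{slope},
#'   \code{intercept}, \code{slope_se}, \code{p_value}, \code{r}, \code{n},
#'   \code{y}, \code{x}.
#' @export
regress_traits <- function(table, y, x) {
  yy <- table[[y]]; xx <- table[[x]]
  ok <- is.finite(yy) & is.finite(xx)
  yy <- yy[ok]; xx <- xx[ok]
  n <- length(yy)
  if (n < 3) stop("regress_traits: need at least 3 complete observations", call. = FALSE)
  if (stats::var(xx) < 1e-14 * max(1, mean(xx)^2)) {
    stop("regress_traits: zero variance in '", x, "'", call. = FALSE)
  }
  fit <- stats::lm(yy ~ xx)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["xx", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["xx", "Std. Error"]),
                 p_value = unname(sm["xx", "Pr(>|t|)"]),
                 r = stats::cor(xx, yy),
                 n = n, y = y, x = x, conditioned_on = NULL),
            class = "trait_assoc")
}

#' Partial correlation between two traits conditioned on a third
#'
#' Residualises both \code{y} and \code{x} on the conditioner \code{z} by
#' ordinary least squares (\eqn{R_1 = y - m_1 z - b_1},
#' \eqn{R_2 = x - m_2 z - b_2}) and regresses the residuals on each other,
#' reporting the residual-regression slope s, intercept c, standard error and
#' p-value, and the partial correlation coefficient. If \code{z} has zero
#' variance the residualisation reduces to centring and the result coincides
#' with the raw regression.
#'
#' @param table Data frame of traits.
#' @param y,x,z Column names (response, predictor, conditioner).
#' @return A \code{trait_assoc} object (slope = residual slope s).
#' @export
partial_correlation <- function(table, y, x, z) {
  yy <- table[[y]]; xx <- table[[x]]; zz <- table[[z]]
  ok <- is.finite(yy) & is.finite(xx) & is.finite(zz)
  yy <- yy[ok]; xx <- xx[ok]; zz <- zz[ok]
  n <- length(yy)
  if (n < 4) stop("partial_correlation: need at least 4 complete observations", call. = FALSE)
  resid_on <- function(v) {
    if (stats::var(zz) < 1e-14 * max(1, mean(zz)^2)) {
      v - mean(v)
    } else {
      stats::residuals(stats::lm(v ~ zz))
    }
  }
  r1 <- resid_on(yy)
  r2 <- resid_on(xx)
  if (stats::var(r2) < 1e-20) {
    stop("partial_correlation: '", x, "' is fully explained by '", z, "'", call. = FALSE)
  }
  fit <- stats::lm(r1 ~ r2)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["r2", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["r2", "Std. Error"]),
                 p_value = unname(sm["r2", "Pr(>|t|)"]),
                 r = stats::cor(r1, r2),
                 n = n, y = y, x = x, conditioned_on = z),
            class = "trait_assoc")
}

#' @export
print.trait_assoc <- function(x, ...) {
  if (is.null(x$conditioned_on)) {
    cat(sprintf("OLS association %s ~ %s (n = %d)\n", x$y, x$x, x$n))
  } else {
    cat(sprintf("Partial association %s ~ %s | %s (n = %d)\n",
                x$y, x$x, x$conditioned_on, x$n))
  }
  cat(sprintf("  slope %.4g +- %.3g (p = %.3g), intercept %.4g, r = %.3f\n",
              x$slope, x$slope_se, x$p_value, x$intercept, x$r))
  invisible(x)
}

#' Test trait tables against the candidate size-control models
#'
#' Evaluates the correlation signatures that distinguish the three classes of
#' spindle size-control models:
#' \itemize{
#'   \item \strong{Timer}: final length is initial length plus an independent
#'     elongation, so it predicts a positive IL--FL correlation.
#'   \item \strong{Limiting Component}: spindle growth exhausts a cytoplasmic
#'     component whose amount scales with cell volume, predicting a positive
#'     partial correlation of FL with cell area (volume proxy) conditioned on
#'     cell length.
#'   \item \strong{Boundary}: centrosomes stop at a fixed distance from the
#'     cortex, predicting FL positively correlated with CL and negatively
#'     correlated with CD.
#' }
#' A model is called consistent when its predicted signature holds with the
#' stated sign at significance level \code{alpha}.
#'
#' @param table Data frame with columns IL, FL, CL, CA, CD.
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{model_verdicts}: a data frame with one row
#'   per model (columns \code{model}, \code{consistent}, \code{statistic},
#'   \code{p_value}, \code{detail}).
#' @export
model_signature_tests <- function(table, alpha = 0.05) {
  need <- c("IL", "FL", "CL", "CA", "CD")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("model_signature_tests: missing trait columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  timer <- regress_traits(table, "FL", "IL")
  lc <- partial_correlation(table, "FL", "CA", "CL")
  b1 <- regress_traits(table, "FL", "CL")
  b2 <- regress_traits(table, "FL", "CD")

  out <- data.frame(
    model = c("Timer", "LimitingComponent", "Boundary"),
    consistent = c(
      timer$slope > 0 && timer$p_value < alpha,
      lc$slope > 0 && lc$p_value < alpha,
      (b1$slope > 0 && b1$p_value < alpha) && (b2$slope < 0 && b2$p_value < alpha)
    ),
    statistic = c(timer$slope, lc$slope, b1$slope),
    p_value = c(timer$p_value, lc$p_value, max(b1$p_value, b2$p_value)),
    detail = c(
      sprintf("corr(IL, FL): slope %.3g, p %.3g", timer$slope, timer$p_value),
      sprintf("partial(FL, CA | CL): slope %.3g, p %.3g", lc$slope, lc$p_value),
      sprintf("corr(FL, CL): slope %.3g (p %.3g); corr(FL, CD): slope %.3g (p %.3g)",
              b1$slope, b1$p_value, b2$slope, b2$p_value)
    ),
    stringsAsFactors = FALSE
  )
  class(out) <- c("model_verdicts", "data.frame")
  out
}

#' @export
print.model_verdicts <- function(x, ...) {
  cat("Size-control model signatures:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %s  [%s]\n", x$model[i],
                ifelse(x$consistent[i], "CONSISTENT", "inconsistent"),
                x$detail[i]))
  }
  invisible(x)
}
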