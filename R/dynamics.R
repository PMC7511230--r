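#' Solve the overdamped force balance for centrosome velocities
#'
#' Two centrosomes experience viscous drag \eqn{\eta} and are coupled by the
#' central spindle, modelled as a viscous element of coefficient \eqn{\nu}
#' acting along the spindle axis \eqn{\hat S = (X_1 - X_2)/|X_1 - X_2|}:
#' \deqn{\eta \dot X_1 + \nu ((\dot X_1 - \dot X_2)\cdot\hat S)\hat S = F_1}
#' \deqn{\eta \dot X_2 - \nu ((\dot X_1 - \dot X_2)\cdot\hat S)\hat S = F_2}
#' The linear system decouples into a translation mode
#' \eqn{\dot X_1 + \dot X_2 = (F_1+F_2)/\eta} and a separation mode whose
#' along-axis component relaxes with \eqn{(\eta + 2\nu)^{-1}} and transverse
#' component with \eqn{\eta^{-1}}.
#'
#' @param F1,F2 Force 3-vectors (pN).
#' @param X1,X2 Centrosome positions (um); must differ.
#' @param mech A \code{\link{mechanics_params}} object.
#' @return A list with velocity 3-vectors \code{V1} and \code{V2} (um/s).
#' @export
solve_velocities <- function(F1, F2, X1, X2, mech = mechanics_params()) {
  stopifnot(inherits(mech, "mechanics_params"))
  S <- X1 - X2
  L <- sqrt(sum(S^2))
  if (L < 1e-9) stop("solve_velocities: coincident centrosomes (spindle axis undefined)",
                     call. = FALSE)
  S <- S / L
  eta <- mech$centrosome_drag
  nu <- mech$spindle_viscosity
  Vsum <- (F1 + F2) / eta
  Fd <- F1 - F2
  Vdiff <- sum(Fd * S) / (eta + 2 * nu) * S + (Fd - sum(Fd * S) * S) / eta
  list(V1 = (Vsum + Vdiff) / 2, V2 = (Vsum - Vdiff) / 2)
}

#' Simulation configuration
#'
#' Bundles geometry, CFG layout specification, kinetic and mechanical
#' parameters, initial conditions, integrator settings and timed events into
#' a validated configuration for \code{\link{run_simulation}}.
#'
#' @param geometry A \code{\link{cell_geometry}}.
#' @param layout Either a prebuilt \code{\link{cfg_layout}} or a list of
#'   arguments for \code{cfg_layout} (\code{n_total}, \code{posterior_fraction},
#'   \code{jitter_scale}); the layout seed is derived from \code{seed}.
#' @param motor A \code{\link{motor_params}}.
#' @param mechanics A \code{\link{mechanics_params}}.
#' @param mode \code{"stoichiometric"} (default) or \code{"nonstoichiometric"}.
#' @param x0 Initial centrosome positions: an n x 3 matrix (n = 1 or 2), um.
#'   Default: two centrosomes on the x axis, 11 um apart, centred on the cell
#'   centre.
#' @param dt Integrator time step (s).
#' @param t_max Maximum simulated time (s).
#' @param speed_tolerance Convergence speed threshold (um/s); the run
#'   terminates as converged when every centrosome moves slower than this for
#'   \code{quiet_time} consecutive seconds.
#' @param quiet_time Sustained-quiet interval for convergence (s).
#' @param ramp Optional \code{\link{ramp_schedule}} for a time-varying motor
#'   parameter.
#' @param events Optional list of timed events; each event is a list with
#'   \code{time} (s), \code{action = "remove_centrosome"}, and \code{which}
#'   (1 or 2).
#' @param record_stride Record every \code{record_stride}-th step (the initial
#'   and final states are always recorded).
#' @param seed Integer seed controlling layout generation (when \code{layout}
#'   is an argument list). The dynamics itself is deterministic.
#' @param attachment_dynamics \code{"quasi_steady"} (default) computes
#'   attachment probabilities from the stationary competition formula at each
#'   step; \code{"ode"} integrates the occupancy kinetics
#'   \eqn{dP_i/dt = \Omega_i(1 - \sum_j P_j) - \kappa P_i} explicitly
#'   (validation mode).
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(geometry = cell_geometry(),
                              layout = list(n_total = 100, posterior_fraction = 0.6,
                                            jitter_scale = 0.2),
                              motor = motor_params(),
                              mechanics = mechanics_params(),
                              mode = c("stoichiometric", "nonstoichiometric"),
                              x0 = NULL,
                              dt = 0.05,
                              t_max = 600,
                              speed_tolerance = 0.005,
                              quiet_time = 10,
                              ramp = NULL,
                              events = NULL,
                              record_stride = 10L,
                              seed = 1L,
                              attachment_dynamics = c("quasi_steady", "ode")) {
  mode <- match.arg(mode)
  attachment_dynamics <- match.arg(attachment_dynamics)
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(motor, "motor_params"),
            inherits(mechanics, "mechanics_params"))
  if (dt <= 0 || t_max <= 0) stop("simulation_config: dt and t_max must be > 0", call. = FALSE)
  if (is.null(x0)) x0 <- rbind(c(-5.5, 0, 0), c(5.5, 0, 0))
  x0 <- matrix(as.numeric(x0), ncol = 3)
  if (!nrow(x0) %in% c(1L, 2L)) stop("simulation_config: x0 must have 1 or 2 rows", call. = FALSE)
  inside <- implicit_and_normal(x0, geometry)$value < 0
  if (!all(inside)) stop("simulation_config: initial centrosome positions must be inside the cell",
                         call. = FALSE)
  if (!is.null(ramp)) stopifnot(inherits(ramp, "ramp_schedule"))
  if (!is.null(events)) {
    for (ev in events) {
      if (!identical(ev$action, "remove_centrosome") || !ev$which %in% c(1, 2)) {
        stop("simulation_config: events must be remove_centrosome with which in {1,2}",
             call. = FALSE)
      }
    }
  }
  structure(list(geometry = geometry, layout = layout, motor = motor,
                 mechanics = mechanics, mode = mode, x0 = x0, dt = dt,
                 t_max = t_max, speed_tolerance = speed_tolerance,
                 quiet_time = quiet_time, ramp = ramp, events = events,
                 record_stride = as.integer(record_stride), seed = as.integer(seed),
                 attachment_dynamics = attachment_dynamics),
            class = "simulation_config")
}

#' Flag a centrosome as removed (in-silico ablation)
#'
#' Marks one centrosome of a dynamical state inactive. Inactive centrosomes
#' exert no pull, are excluded from the per-CFG competition, and the
#' central-spindle coupling is dropped (single-body dynamics thereafter).
#'
#' @param state A list with elements \code{X} (n x 3 positions) and
#'   \code{active} (logical vector).
#' @param which Index of the centrosome to remove.
#' @return The state with \code{active[which]} set to \code{FALSE}.
#' @export
remove_centrosome <- function(state, which) {
  if (!state$active[which]) {
    stop("remove_centrosome: centrosome ", which, " is already inactive", call. = FALSE)
  }
  state$active[which] <- FALSE
  state
}

#' Run a centrosome-dynamics simulation
#'
#' Explicit time stepping of one or two centrosomes under stoichiometric (or
#' non-stoichiometric) cortical pulling forces. At each step the per-CFG
#' impingement rates and attachment probabilities are recomputed for the
#' current positions (quasi-steady competition by default), summed into net
#' forces, and the overdamped force balance is solved for the velocities. A
#' per-step displacement guard (0.5 um) triggers recursive step halving;
#' persistent violation aborts with a diagnostic advising a smaller \code{dt}.
#'
#' Termination: \code{"converged"} when all active centrosomes move slower
#' than \code{speed_tolerance} for \code{quiet_time} consecutive seconds;
#' \code{"t_max"} when time runs out; \code{"cortex_contact"} when an active
#' centrosome comes within one capture radius of the surface (the fate of
#' every non-stoichiometric run -- stoichiometric runs never reach it).
#'
#' @param config A \code{\link{simulation_config}}.
#' @param layout Optional prebuilt \code{\link{cfg_layout}} overriding the
#'   config's layout spec.
#' @return An object of class \code{spindle_trajectory}: a list with
#'   \code{times}, position matrices \code{X1}, \code{X2} (um; \code{X2} is
#'   all-\code{NA} for single-centrosome runs and frozen after removal),
#'   spindle length \code{L} (um, \code{NA} when fewer than two centrosomes
#'   are active), \code{center} (midpoint matrix), \code{termination},
#'   \code{active} (final activity flags), the final \code{attachment} list
#'   (per-CFG probabilities, rates, distances), the \code{layout}, and the
#'   \code{config}.
#' @examples
#' \donttest{
#' cfg <- simulation_config(t_max = 100, seed = 7)
#' traj <- run_simulation(cfg)
#' summary(traj)
#' }
#' @export
run_simulation <- function(config, layout = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  if (is.null(layout)) {
    layout <- if (inherits(config$layout, "cfg_layout")) {
      config$layout
    } else {
      do.call(cfg_layout, c(list(geom = geom, seed = config$seed,
                                 capture_radius = config$motor$capture_radius),
                            config$layout))
    }
  }
  stopifnot(inherits(layout, "cfg_layout"))

  px <- layout$x; py <- layout$y; pz <- layout$z
  nx <- layout$nx; ny <- layout$ny; nz <- layout$nz
  m <- length(px)
  stoich <- config$mode == "stoichiometric"
  ode_P <- config$attachment_dynamics == "ode"

  X <- config$x0
  nc <- nrow(X)
  active <- rep(TRUE, nc)
  eta <- config$mechanics$centrosome_drag
  nu <- config$mechanics$spindle_viscosity
  dt <- config$dt
  t_max <- config$t_max
  tol <- config$speed_tolerance
  stride <- max(1L, config$record_stride)

  events <- config$events
  ev_times <- if (is.null(events)) numeric(0) else vapply(events, `[[`, 0, "time")

  n_steps_max <- ceiling(t_max / dt) + 1L
  n_rec_max <- n_steps_max %/% stride + 3L
  rec_t <- numeric(n_rec_max)
  rec_X1 <- matrix(NA_real_, n_rec_max, 3)
  rec_X2 <- matrix(NA_real_, n_rec_max, 3)
  n_rec <- 0L

  # occupancy state for the explicit-ODE attachment mode
  Pstate <- matrix(0, m, nc)

  omega_at <- function(Xi, motor) {
    dx <- px - Xi[1]; dy <- py - Xi[2]; dz <- pz - Xi[3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    ci <- (dx * nx + dy * ny + dz * nz) / d
    ci[ci < 0] <- 0
    om <- motor$nucleation_rate * (ci / 2) *
      (1 - 1 / sqrt(1 + (motor$capture_radius / d)^2)) *
      exp(-d * motor$catastrophe_rate / motor$growth_speed)
    list(om = om, dx = dx, dy = dy, dz = dz, d = d)
  }

  compute_forces <- function(X, active, motor, Pstate) {
    g1 <- if (active[1]) omega_at(X[1, ], motor) else NULL
    g2 <- if (nc == 2 && active[2]) omega_at(X[2, ], motor) else NULL
    om1 <- if (is.null(g1)) numeric(m) else g1$om
    om2 <- if (is.null(g2)) numeric(m) else g2$om
    if (stoich) {
      if (ode_P) {
        P1 <- Pstate[, 1]
        P2 <- if (nc == 2) Pstate[, 2] else numeric(m)
        free <- 1 - P1 - P2
        kap <- motor$detachment_rate
        Pstate[, 1] <- P1 + dt * (om1 * free - kap * P1)
        if (nc == 2) Pstate[, 2] <- P2 + dt * (om2 * free - kap * P2)
        Pstate[Pstate < 0] <- 0
        w1 <- Pstate[, 1]
        w2 <- if (nc == 2) Pstate[, 2] else numeric(m)
      } else {
        den <- om1 + om2 + motor$detachment_rate
        w1 <- om1 / den
        w2 <- om2 / den
      }
    } else {
      w1 <- om1 / motor$detachment_rate
      w2 <- om2 / motor$detachment_rate
    }
    f0 <- motor$pull_force
    F1 <- if (is.null(g1)) c(0, 0, 0) else {
      a <- f0 * w1 / g1$d
      c(sum(a * g1$dx), sum(a * g1$dy), sum(a * g1$dz))
    }
    F2 <- if (is.null(g2)) c(0, 0, 0) else {
      a <- f0 * w2 / g2$d
      c(sum(a * g2$dx), sum(a * g2$dy), sum(a * g2$dz))
    }
    list(F1 = F1, F2 = F2, Pstate = Pstate)
  }

  velocities <- function(X, active, F1, F2) {
    if (nc == 2 && all(active)) {
      v <- solve_velocities(F1, F2, X[1, ], X[2, ], config$mechanics)
      rbind(v$V1, v$V2)
    } else {
      V <- matrix(0, nc, 3)
      if (active[1]) V[1, ] <- F1 / eta
      if (nc == 2 && active[2]) V[2, ] <- F2 / eta
      V
    }
  }

  cortex_hit <- function(X, active, motor) {
    for (i in seq_len(nc)) {
      if (!active[i]) next
      v <- implicit_and_normal(X[i, ], geom)$value
      if (v >= 0) return(TRUE)
      nr <- sqrt(sum(X[i, ]^2))
      if (nr > 1e-9) {
        rho <- surface_radius(X[i, ] / nr, geom)
        if (rho - nr < motor$capture_radius) return(TRUE)
      }
    }
    FALSE
  }

  record <- function(t, X) {
    n_rec <<- n_rec + 1L
    rec_t[n_rec] <<- t
    rec_X1[n_rec, ] <<- X[1, ]
    if (nc == 2) rec_X2[n_rec, ] <<- X[2, ]
  }

  # one Euler step with recursive halving under the displacement guard
  advance <- function(X, active, motor, Pstate, h, depth = 0) {
    f <- compute_forces(X, active, motor, Pstate)
    V <- velocities(X, active, f$F1, f$F2)
    disp <- V * h
    if (max(abs(disp)) > 0.5) {
      if (depth >= 8) {
        stop("run_simulation: step-size instability (displacement > 0.5 um at minimal substep); ",
             "use a smaller dt", call. = FALSE)
      }
      s1 <- advance(X, active, motor, f$Pstate, h / 2, depth + 1)
      s2 <- advance(s1$X, active, motor, s1$Pstate, h / 2, depth + 1)
      return(list(X = s2$X, Pstate = s2$Pstate, Vmax2 = max(s1$Vmax2, s2$Vmax2)))
    }
    vmax2 <- if (any(active)) max(rowSums((V[active, , drop = FALSE])^2)) else 0
    list(X = X + disp, Pstate = f$Pstate, Vmax2 = vmax2)
  }

  t <- 0
  quiet <- 0
  termination <- "t_max"
  record(t, X)
  step <- 0L
  while (t < t_max - 1e-12) {
    # apply due events
    if (length(ev_times) && any(due <- ev_times <= t + 1e-12)) {
      for (k in which(due)) {
        st <- remove_centrosome(list(X = X, active = active), events[[k]]$which)
        active <- st$active
      }
      events <- events[!due]
      ev_times <- ev_times[!due]
      quiet <- 0
    }
    motor_t <- apply_ramp(config$motor, t, config$ramp)
    stp <- advance(X, active, motor_t, Pstate, dt)
    X <- stp$X
    Pstate <- stp$Pstate
    t <- t + dt
    step <- step + 1L
    if (step %% stride == 0L) record(t, X)
    if (cortex_hit(X, active, motor_t)) {
      termination <- "cortex_contact"
      break
    }
    quiet <- if (stp$Vmax2 < tol^2) quiet + dt else 0
    if (quiet >= config$quiet_time && length(ev_times) == 0L) {
      termination <- "converged"
      break
    }
  }
  if (step %% stride != 0L || n_rec == 0L) record(t, X)

  times <- rec_t[seq_len(n_rec)]
  X1 <- rec_X1[seq_len(n_rec), , drop = FALSE]
  X2 <- rec_X2[seq_len(n_rec), , drop = FALSE]
  L <- if (nc == 2) sqrt(rowSums((X1 - X2)^2)) else rep(NA_real_, n_rec)
  center <- if (nc == 2) (X1 + X2) / 2 else X1
  # after an ablation event the removed centrosome is frozen; L is undefined
  if (nc == 2 && !all(active)) {
    rm_t <- vapply(config$events, `[[`, 0, "time")
    L[times >= min(rm_t)] <- NA_real_
  }

  final_att <- net_forces(X, layout, config$motor, mode = config$mode, active = active)

  structure(list(times = times, X1 = X1, X2 = X2, L = L, center = center,
                 termination = termination, active = active,
                 attachment = final_att$attachment, forces = final_att$forces,
                 layout = layout, config = config),
            class = "spindle_trajectory")
}

#' @export
print.spindle_trajectory <- function(x, ...) {
  nend <- length(x$times)
  cat("Spindle trajectory:", nend, "recorded states over",
      sprintf("%.1f s", x$times[nend]), "\n")
  cat("  termination:", x$termination, "\n")
  if (!is.na(x$L[nend])) {
    cat(sprintf("  final spindle length: %.2f um; center x: %.2f um\n",
                x$L[nend], x$center[nend, 1]))
  } else {
    cat(sprintf("  final centrosome position: (%.2f, %.2f, %.2f) um\n",
                x$X1[nend, 1], x$X1[nend, 2], x$X1[nend, 3]))
  }
  invisible(x)
}

#' @export
summary.spindle_trajectory <- function(object, ...) {
  nend <- length(object$times)
  out <- list(
    duration = object$times[nend],
    termination = object$termination,
    initial_length = object$L[1],
    final_length = object$L[nend],
    final_center = object$center[nend, ],
    n_cfg = nrow(object$layout),
    active = object$active
  )
  class(out) <- "summary.spindle_trajectory"
  out
}

#' @export
print.summary.spindle_trajectory <- function(x, ...) {
  cat("Simulated centrosome dynamics\n")
  cat(sprintf("  duration: %.1f s (%s)\n", x$duration, x$termination))
  if (!is.na(x$final_length)) {
    cat(sprintf("  spindle length: %.2f -> %.2f um\n", x$initial_length, x$final_length))
  }
  cat(sprintf("  final spindle center: (%.2f, %.2f, %.2f) um\n",
              x$final_center[1], x$final_center[2], x$final_center[3]))
  cat(sprintf("  %d CFGs; active centrosomes: %s\n", x$n_cfg,
              paste(which(x$active), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.spindle_trajectory <- function(x, ...) {
  data.frame(t = x$times,
             x1 = x$X1[, 1], y1 = x$X1[, 2], z1 = x$X1[, 3],
             x2 = x$X2[, 1], y2 = x$X2[, 2], z2 = x$X2[, 3],
             L = x$L,
             cx = x$center[, 1], cy = x$center[, 2], cz = x$center[, 3])
}

#' Plot spindle length and centre position over time
#' @param x A \code{spindle_trajectory}.
#' @param ... Passed to \code{plot}.
#' @export
plot.spindle_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (any(!is.na(x$L))) {
    graphics::plot(x$times, x$L, type = "l", xlab = "time (s)",
                   ylab = "spindle length (um)", main = "Elongation", ...)
  }
  graphics::plot(x$times, x$center[, 1], type = "l", xlab = "time (s)",
                 ylab = "center x (um)", main = "Positioning", ...)
  invisible(x)
}
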