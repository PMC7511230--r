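#' Kinetic and mechanical parameters of the microtubule--force-generator system
#'
#' Constructs the parameter set governing astral microtubule dynamics and
#' their interaction with cortical force generators (CFGs). Units are fixed
#' package-wide: micrometres, seconds, piconewtons.
#'
#' Defaults are the literature estimates used throughout the simulations:
#' microtubules nucleate isotropically from each centrosome at rate
#' \code{nucleation_rate}, grow at \code{growth_speed}, and disappear by
#' catastrophe at rate \code{catastrophe_rate}. A microtubule whose tip passes
#' within \code{capture_radius} of an unoccupied CFG binds it and is pulled on
#' with force \code{pull_force} along the microtubule direction until it
#' detaches at rate \code{detachment_rate}.
#'
#' @param nucleation_rate Microtubule nucleation rate per centrosome (1/s).
#' @param growth_speed Microtubule polymerisation speed (um/s).
#' @param catastrophe_rate Microtubule catastrophe rate (1/s).
#' @param detachment_rate Microtubule--CFG detachment rate (1/s).
#' @param capture_radius Effective CFG capture radius (um). A single constant
#'   that lumps the physical size of the CFG with the distance a microtubule
#'   can grow and translocate along the cortex before binding.
#' @param pull_force Force exerted on a bound microtubule (pN).
#' @return An object of class \code{motor_params}.
#' @examples
#' p <- motor_params()
#' mt_steady_state_stats(p)
#' @export
motor_params <- function(nucleation_rate = 250,
                         growth_speed = 0.5,
                         catastrophe_rate = 0.025,
                         detachment_rate = 0.1,
                         capture_radius = 1.5,
                         pull_force = 10) {
  p <- list(
    nucleation_rate = nucleation_rate,
    growth_speed = growth_speed,
    catastrophe_rate = catastrophe_rate,
    detachment_rate = detachment_rate,
    capture_radius = capture_radius,
    pull_force = pull_force
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("motor_params: '", nm, "' must be a single finite positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("Microtubule / force-generator parameters (um, s, pN):\n")
  cat(sprintf("  nucleation rate  gamma  = %g /s\n", x$nucleation_rate))
  cat(sprintf("  growth speed     Vg     = %g um/s\n", x$growth_speed))
  cat(sprintf("  catastrophe rate lambda = %g /s\n", x$catastrophe_rate))
  cat(sprintf("  detachment rate  kappa  = %g /s\n", x$detachment_rate))
  cat(sprintf("  capture radius   r      = %g um\n", x$capture_radius))
  cat(sprintf("  pull force       f0     = %g pN\n", x$pull_force))
  invisible(x)
}

#' Mechanical parameters of centrosome motion
#'
#' Drag on each centrosome and the viscosity of the central spindle, which
#' couples the two centrosomes along the spindle axis.
#'
#' @param centrosome_drag Viscous drag coefficient per centrosome (pN s/um).
#' @param spindle_viscosity Central-spindle viscous friction coefficient
#'   (pN s/um); resists the rate of change of pole-to-pole distance.
#' @return An object of class \code{mechanics_params}.
#' @export
mechanics_params <- function(centrosome_drag = 150, spindle_viscosity = 100) {
  if (!is.numeric(centrosome_drag) || length(centrosome_drag) != 1L ||
      !is.finite(centrosome_drag) || centrosome_drag <= 0) {
    stop("mechanics_params: 'centrosome_drag' must be a single finite positive number",
         call. = FALSE)
  }
  if (!is.numeric(spindle_viscosity) || length(spindle_viscosity) != 1L ||
      !is.finite(spindle_viscosity) || spindle_viscosity < 0) {
    stop("mechanics_params: 'spindle_viscosity' must be a single finite non-negative number",
         call. = FALSE)
  }
  structure(list(centrosome_drag = centrosome_drag,
                 spindle_viscosity = spindle_viscosity),
            class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat("Centrosome mechanics (pN s/um):\n")
  cat(sprintf("  centrosome drag   eta = %g\n", x$centrosome_drag))
  cat(sprintf("  spindle viscosity nu  = %g\n", x$spindle_viscosity))
  invisible(x)
}

#' Steady-state statistics of the astral microtubule population
#'
#' With constant nucleation at rate gamma, growth at speed Vg and catastrophe
#' at rate lambda, the steady-state microtubule length distribution is
#' exponential, \eqn{\psi(l) = (\gamma/V_g) e^{-l \lambda / V_g}}. This
#' returns its summary statistics.
#'
#' @param params A \code{\link{motor_params}} object.
#' @return A list with \code{mt_count} (total number of microtubules,
#'   gamma/lambda), \code{mean_length} (Vg/lambda, um), and
#'   \code{density_at_zero} (gamma/Vg, microtubules per um of length at the
#'   centrosome).
#' @examples
#' mt_steady_state_stats(motor_params())  # 10,000 microtubules, 20 um mean
#' @export
mt_steady_state_stats <- function(params) {
  stopifnot(inherits(params, "motor_params"))
  list(
    mt_count = params$nucleation_rate / params$catastrophe_rate,
    mean_length = params$growth_speed / params$catastrophe_rate,
    density_at_zero = params$nucleation_rate / params$growth_speed
  )
}

#' Detachment rate preserving attachment probability under a radius change
#'
#' In the small-angle regime the impingement rate scales as the square of the
#' capture radius at fixed centrosome--CFG distance, so the single-CFG
#' quasi-steady attachment probability \eqn{P = \Omega/(\Omega + \kappa)} is
#' left invariant under \eqn{r \to r'} by rescaling the detachment rate as
#' \eqn{\kappa' = \kappa (r'/r)^2}. Used when shrinking CFGs to pack many of
#' them on the cortex while conserving elongation dynamics.
#'
#' @param r_new New capture radius (um).
#' @param params A \code{\link{motor_params}} object supplying the baseline
#'   radius and detachment rate.
#' @return The rescaled detachment rate (1/s).
#' @examples
#' kappa_for_radius(0.1, motor_params())  # 4.44e-4 /s
#' @export
kappa_for_radius <- function(r_new, params = motor_params()) {
  stopifnot(inherits(params, "motor_params"))
  if (!is.numeric(r_new) || length(r_new) != 1L || !is.finite(r_new) || r_new <= 0) {
    stop("kappa_for_radius: 'r_new' must be a single finite positive number", call. = FALSE)
  }
  params$detachment_rate * (r_new / params$capture_radius)^2
}

#' Linear ramp schedule for a motor parameter
#'
#' Motor properties can change during anaphase; the simulator supports a
#' linear ramp of one \code{\link{motor_params}} field between two time
#' points, clamped to the endpoint values outside the ramp interval. Final
#' spindle length, position and scaling are unchanged by such ramps; they only
#' smooth the metaphase-to-anaphase transition.
#'
#' @param parameter Name of the ramped \code{motor_params} field
#'   (default \code{"detachment_rate"}, i.e. motor processivity changing over
#'   time).
#' @param start_value,end_value Parameter value before/after the ramp.
#' @param t_start,t_end Ramp interval (s); \code{t_end > t_start}.
#' @return An object of class \code{ramp_schedule}.
#' @export
ramp_schedule <- function(parameter = "detachment_rate",
                          start_value, end_value, t_start, t_end) {
  valid <- names(motor_params())
  if (!is.character(parameter) || length(parameter) != 1L || !(parameter %in% valid)) {
    stop("ramp_schedule: unknown parameter '", parameter,
         "'; must be one of: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (!(t_end > t_start)) stop("ramp_schedule: t_end must exceed t_start", call. = FALSE)
  structure(list(parameter = parameter, start_value = start_value,
                 end_value = end_value, t_start = t_start, t_end = t_end),
            class = "ramp_schedule")
}

#' Evaluate motor parameters at a time point under an optional ramp
#'
#' @param params A \code{\link{motor_params}} object (values used outside any
#'   ramp, and for all non-ramped fields).
#' @param t Time (s).
#' @param schedule A \code{\link{ramp_schedule}} or \code{NULL} (identity).
#' @return A \code{motor_params} object with the ramped field interpolated
#'   linearly and clamped outside \code{[t_start, t_end]}.
#' @export
apply_ramp <- function(params, t, schedule = NULL) {
  stopifnot(inherits(params, "motor_params"))
  if (is.null(schedule)) return(params)
  stopifnot(inherits(schedule, "ramp_schedule"))
  frac <- (t - schedule$t_start) / (schedule$t_end - schedule$t_start)
  frac <- min(1, max(0, frac))
  params[[schedule$parameter]] <-
    schedule$start_value + frac * (schedule$end_value - schedule$start_value)
  params
}
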