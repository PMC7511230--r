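#' Fraction of microtubules nucleated into the capture cone of a CFG
#'
#' A disk-shaped force generator of capture radius \code{r} at distance
#' \code{d} from the centrosome subtends a cone of nucleation directions.
#' For isotropic nucleation the fraction of microtubules inside the cone is
#' \deqn{\chi(d) = \frac{\hat\xi\cdot\hat n}{2}
#'   \left(1 - \frac{1}{\sqrt{1+(r/d)^2}}\right)}
#' where \eqn{\hat\xi\cdot\hat n} is the cosine of the angle between the
#' centrosome-to-CFG direction and the CFG's outward normal (the projected-area
#' correction for an obliquely viewed disk). Negative incidence (a CFG facing
#' away from the centrosome) is clamped to zero capture.
#'
#' @param d Centrosome--CFG distance (um), > 0. Vectorised.
#' @param cos_incidence Cosine of the incidence angle, clamped to [0, 1].
#' @param r Capture radius (um), > 0.
#' @return The cone fraction, in [0, 0.5].
#' @examples
#' cone_fraction(10, 1, 1.5)
#' @export
cone_fraction <- function(d, cos_incidence = 1, r) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("cone_fraction: distance 'd' must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("cone_fraction: capture radius 'r' must be a single finite positive number",
         call. = FALSE)
  }
  ci <- pmin(1, pmax(0, cos_incidence))
  ci / 2 * (1 - 1 / sqrt(1 + (r / d)^2))
}

#' Rate at which growing microtubules impinge on a force generator
#'
#' Combines the cone fraction with the probability that a microtubule survives
#' catastrophe long enough to span the distance:
#' \deqn{\Omega(d) = \gamma\, \chi(d)\, e^{-d\lambda/V_g}.}
#' The widely quoted small-angle approximation replaces \eqn{\chi} by
#' \eqn{(\hat\xi\cdot\hat n/4)(r/d)^2}; it is accurate for \eqn{r \ll d} but
#' diverges as \eqn{d \to 0}, whereas the exact form is bounded by
#' \eqn{\gamma/2}. Simulations use the exact form.
#'
#' @param d Centrosome--CFG distance (um), > 0. Vectorised.
#' @param cos_incidence Cosine of the incidence angle (clamped to [0, 1]).
#' @param params A \code{\link{motor_params}} object.
#' @param form \code{"exact"} (default) or \code{"approx"}.
#' @return Impingement rate (1/s).
#' @examples
#' impingement_rate(10, 1, motor_params())
#' @export
impingement_rate <- function(d, cos_incidence = 1, params = motor_params(),
                             form = c("exact", "approx")) {
  stopifnot(inherits(params, "motor_params"))
  form <- match.arg(form)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("impingement_rate: distance 'd' must be finite and > 0 (coincident points?)",
         call. = FALSE)
  }
  ci <- pmin(1, pmax(0, cos_incidence))
  chi <- if (form == "exact") {
    cone_fraction(d, ci, params$capture_radius)
  } else {
    ci / 4 * (params$capture_radius / d)^2
  }
  params$nucleation_rate * chi *
    exp(-d * params$catastrophe_rate / params$growth_speed)
}

#' Quasi-steady attachment probabilities at one CFG
#'
#' A CFG binds one microtubule at a time, so centrosomes compete for it. Given
#' the impingement rates \eqn{\Omega_i} of microtubules from each active
#' centrosome and the detachment rate \eqn{\kappa}, the stationary occupancy
#' probabilities are
#' \deqn{P_i = \frac{\Omega_i}{\sum_j \Omega_j + \kappa},}
#' the quasi-steady solution of the occupancy kinetics
#' \eqn{dP_i/dt = \Omega_i (1 - \sum_j P_j) - \kappa P_i}. With a single
#' centrosome this reduces to \eqn{\Omega/(\Omega+\kappa)}. The probability
#' that the CFG is unoccupied is \eqn{1 - \sum_i P_i > 0}.
#'
#' @param omegas Numeric vector of per-centrosome impingement rates (1/s),
#'   all >= 0.
#' @param kappa Detachment rate (1/s), > 0.
#' @return Numeric vector of attachment probabilities, same length as
#'   \code{omegas}; each in [0, 1) and summing to < 1.
#' @examples
#' attachment_probabilities(0.8388, 0.1)          # single centrosome
#' attachment_probabilities(c(0.84, 0.84), 0.1)   # two competing centrosomes
#' @export
attachment_probabilities <- function(omegas, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0) {
    stop("attachment_probabilities: 'kappa' must be a single finite positive number",
         call. = FALSE)
  }
  if (any(!is.finite(omegas)) || any(omegas < 0)) {
    stop("attachment_probabilities: impingement rates must be finite and >= 0",
         call. = FALSE)
  }
  omegas / (sum(omegas) + kappa)
}

#' Mean pulling force from one CFG on one centrosome
#'
#' Under stoichiometric binding the time-averaged force is the pull force
#' weighted by the attachment probability, \eqn{\vec F = f_0 P \hat\xi}, with
#' magnitude bounded by \eqn{f_0}. Without stoichiometric interactions every
#' impinging microtubule is pulled, so the force is proportional to the mean
#' number of bound microtubules, \eqn{\vec F = f_0 (\Omega/\kappa) \hat\xi},
#' which is unbounded as the centrosome approaches the cortex -- the
#' destabilising feedback that stoichiometric binding removes.
#'
#' @param xi_hat Unit 3-vector from the centrosome toward the CFG.
#' @param params A \code{\link{motor_params}} object (supplies \code{f0} and,
#'   in non-stoichiometric mode, \code{kappa}).
#' @param mode \code{"stoichiometric"} or \code{"nonstoichiometric"}.
#' @param P Attachment probability (stoichiometric mode).
#' @param omega Impingement rate (non-stoichiometric mode), 1/s.
#' @return Force 3-vector (pN) acting on the centrosome.
#' @export
cfg_force <- function(xi_hat, params = motor_params(),
                      mode = c("stoichiometric", "nonstoichiometric"),
                      P = NULL, omega = NULL) {
  stopifnot(inherits(params, "motor_params"))
  mode <- match.arg(mode)
  if (mode == "stoichiometric") {
    if (is.null(P)) stop("cfg_force: stoichiometric mode requires 'P'", call. = FALSE)
    if (P < 0 || P > 1) stop("cfg_force: 'P' must lie in [0, 1]", call. = FALSE)
    params$pull_force * P * xi_hat
  } else {
    if (is.null(omega)) stop("cfg_force: nonstoichiometric mode requires 'omega'", call. = FALSE)
    params$pull_force * (omega / params$detachment_rate) * xi_hat
  }
}

#' Net cortical pulling forces on the centrosomes
#'
#' Computes, for every (CFG, centrosome) pair, the distance, direction and
#' impingement rate; resolves the per-CFG competition between active
#' centrosomes into attachment probabilities; and sums the per-CFG forces into
#' a net force vector per centrosome. Inactive centrosomes (e.g. after
#' in-silico removal) are excluded from the competition and receive zero
#' force.
#'
#' @param centrosomes Numeric matrix, one row per centrosome, columns x, y, z
#'   (um).
#' @param layout A \code{\link{cfg_layout}} data frame (or any data frame with
#'   columns x, y, z, nx, ny, nz).
#' @param params A \code{\link{motor_params}} object.
#' @param mode \code{"stoichiometric"} or \code{"nonstoichiometric"}.
#' @param active Logical vector, one entry per centrosome.
#' @param form Impingement-rate form passed to \code{\link{impingement_rate}}.
#' @return A list with \code{forces} (matrix, one row per centrosome, pN) and
#'   \code{attachment}, itself a list of per-(CFG, centrosome) matrices
#'   \code{P}, \code{omega}, \code{d} and the direction array \code{xi}
#'   (n_cfg x 3 x n_centrosomes).
#' @export
net_forces <- function(centrosomes, layout, params = motor_params(),
                       mode = c("stoichiometric", "nonstoichiometric"),
                       active = rep(TRUE, nrow(centrosomes)),
                       form = c("exact", "approx")) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  stopifnot(inherits(params, "motor_params"))
  if (is.null(nrow(centrosomes))) centrosomes <- matrix(centrosomes, nrow = 1)
  nc <- nrow(centrosomes)
  if (!any(active)) stop("net_forces: need at least one active centrosome", call. = FALSE)
  if (!is.data.frame(layout) || nrow(layout) == 0) {
    stop("net_forces: empty force-generator set", call. = FALSE)
  }
  pos <- as.matrix(layout[, c("x", "y", "z")])
  nrm <- as.matrix(layout[, c("nx", "ny", "nz")])
  m <- nrow(pos)

  omega <- matrix(0, m, nc)
  dmat <- matrix(NA_real_, m, nc)
  xi <- array(NA_real_, c(m, 3, nc))
  for (i in seq_len(nc)) {
    if (!active[i]) next
    dv <- pos - matrix(centrosomes[i, ], m, 3, byrow = TRUE)
    d <- sqrt(rowSums(dv^2))
    if (any(d < 1e-9)) stop("net_forces: centrosome coincides with a CFG", call. = FALSE)
    u <- dv / d
    ci <- rowSums(u * nrm)
    omega[, i] <- impingement_rate(d, ci, params, form)
    dmat[, i] <- d
    xi[, , i] <- u
  }

  forces <- matrix(0, nc, 3)
  Pmat <- matrix(0, m, nc)
  if (mode == "stoichiometric") {
    den <- rowSums(omega) + params$detachment_rate
    for (i in seq_len(nc)) {
      if (!active[i]) next
      Pmat[, i] <- omega[, i] / den
      xim <- matrix(xi[, , i], ncol = 3)
      forces[i, ] <- params$pull_force * colSums(Pmat[, i] * xim)
    }
  } else {
    for (i in seq_len(nc)) {
      if (!active[i]) next
      nbar <- omega[, i] / params$detachment_rate
      Pmat[, i] <- nbar # mean bound microtubules, may exceed 1
      xim <- matrix(xi[, , i], ncol = 3)
      forces[i, ] <- params$pull_force * colSums(nbar * xim)
    }
  }
  list(forces = forces,
       attachment = list(P = Pmat, omega = omega, d = dmat, xi = xi))
}
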