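#' Run a canonical simulation scenario
#'
#' Reproducible experiment runners mirroring the model's headline simulations.
#' Available scenarios:
#' \describe{
#'   \item{wildtype_asymmetric}{Two centrosomes, ~100 CFGs split 60/40
#'     posterior/anterior (the posterior cortex carries ~50\% more force
#'     generators), 50 x 30 x 30 um cell, 11 um initial separation.}
#'   \item{symmetric_par6}{As wild type but with a symmetric 50/50 CFG
#'     distribution, emulating loss of anterior-posterior polarity: the
#'     spindle centres and reaches the same final length.}
#'   \item{single_centrosome}{One centrosome started off-centre with a uniform
#'     50/50 layout; it migrates to the cell centre.}
#'   \item{ablation}{Two centrosomes with a uniform layout; one is removed at
#'     \code{t_ablate} (default 250 s, after positioning), and the survivor
#'     re-centres.}
#'   \item{nonstoichiometric}{Wild-type layout without the one-microtubule-
#'     per-CFG rule; positioning is unstable and every run ends in cortex
#'     contact.}
#'   \item{two_plane_toy}{A single centrosome between two parallel planes
#'     carrying four CFGs each; returns the axial net-force profile versus
#'     centrosome offset instead of a trajectory (the force is antisymmetric
#'     and restoring).}
#'   \item{initial_condition_ensemble}{One fixed layout, \code{n_configs}
#'     random initial centrosome placements near the centre; final positions
#'     coincide.}
#' }
#'
#' @param name Scenario name (see above).
#' @param overrides Named list of \code{\link{simulation_config}} arguments to
#'   override scenario defaults (e.g. \code{dt}, \code{t_max}, \code{motor}).
#' @param n_configs Number of ensemble members (independent CFG layouts and
#'   initial-condition draws).
#' @param seed Integer master seed; per-member seeds derive from it.
#' @param t_ablate Removal time for the \code{ablation} scenario (s).
#' @param offsets Axial offsets (um) probed by \code{two_plane_toy}.
#' @return For \code{two_plane_toy}, a data frame with columns \code{offset}
#'   and \code{force_z}. Otherwise an object of class \code{scenario_result}:
#'   a list with \code{runs} (trajectories), \code{traits} (per-run trait
#'   table where applicable), \code{ensemble} (common time grid with mean and
#'   SD of spindle length and centre position), \code{name}, and \code{seed}.
#' @examples
#' \donttest{
#' res <- run_scenario("wildtype_asymmetric", n_configs = 4, seed = 1)
#' print(res)
#' }
#' @export
run_scenario <- function(name, overrides = list(), n_configs = 8, seed = 1,
                         t_ablate = 250, offsets = seq(-12, 12, by = 1)) {
  known <- c("wildtype_asymmetric", "symmetric_par6", "single_centrosome",
             "ablation", "nonstoichiometric", "two_plane_toy",
             "initial_condition_ensemble")
  if (!name %in% known) {
    stop("run_scenario: unknown scenario '", name, "'; options: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (name == "two_plane_toy") return(two_plane_force_profile(offsets, overrides))

  member_seeds <- with_seed(seed, sample.int(2^30, n_configs))
  base <- switch(name,
    wildtype_asymmetric = list(layout = list(n_total = 100, posterior_fraction = 0.6,
                                             jitter_scale = 0.2)),
    symmetric_par6 = list(layout = list(n_total = 100, posterior_fraction = 0.5,
                                        jitter_scale = 0.2)),
    # centring runs need a tight speed tolerance: the restoring force near the
    # cell centre is weak, so a looser cutoff would stall the aster early
    single_centrosome = list(layout = list(n_total = 100, posterior_fraction = 0.5,
                                           jitter_scale = 0.2),
                             x0 = c(6, 2, 0),
                             t_max = 1500, speed_tolerance = 0.001),
    ablation = list(layout = list(n_total = 100, posterior_fraction = 0.5,
                                  jitter_scale = 0.2),
                    events = list(list(time = t_ablate, action = "remove_centrosome",
                                       which = 1)),
                    t_max = 1500, speed_tolerance = 0.001),
    nonstoichiometric = list(layout = list(n_total = 100, posterior_fraction = 0.6,
                                           jitter_scale = 0.2),
                             mode = "nonstoichiometric"),
    initial_condition_ensemble = list(layout = list(n_total = 100,
                                                    posterior_fraction = 0.6,
                                                    jitter_scale = 0.2))
  )

  # one layout shared across members for the initial-condition ensemble;
  # fresh layouts otherwise
  shared_layout <- NULL
  if (name == "initial_condition_ensemble") {
    args <- utils::modifyList(base, overrides)
    motor <- if (is.null(args$motor)) motor_params() else args$motor
    geom <- if (is.null(args$geometry)) cell_geometry() else args$geometry
    shared_layout <- do.call(cfg_layout, c(list(geom = geom, seed = seed,
                                                capture_radius = motor$capture_radius),
                                           args$layout))
  }

  runs <- vector("list", n_configs)
  for (i in seq_len(n_configs)) {
    args <- utils::modifyList(base, overrides)
    args$seed <- member_seeds[i]
    if (name %in% c("wildtype_asymmetric", "symmetric_par6", "ablation",
                    "nonstoichiometric")) {
      args$x0 <- jittered_start(member_seeds[i])
    }
    if (name == "initial_condition_ensemble") {
      args$x0 <- with_seed(member_seeds[i], {
        c0 <- stats::runif(3, -3, 3) * c(1, 0.6, 0.6)
        rbind(c0 + c(-5.5, 0, 0), c0 + c(5.5, 0, 0))
      })
    }
    cfg <- do.call(simulation_config, args)
    runs[[i]] <- run_simulation(cfg, layout = shared_layout)
  }

  traits <- NULL
  if (name %in% c("wildtype_asymmetric", "symmetric_par6")) {
    traits <- do.call(rbind, lapply(runs, function(tr) {
      cbind(extract_traits(tr), seed = tr$config$seed)
    }))
  }

  structure(list(name = name, runs = runs, traits = traits,
                 ensemble = ensemble_summary(runs), seed = seed),
            class = "scenario_result")
}

# Small random displacement of the default 11-um-apart starting positions,
# reproducing run-to-run variation in metaphase spindle placement.
jittered_start <- function(seed) {
  with_seed(seed + 1L, {
    rbind(c(-5.5, 0, 0) + stats::rnorm(3, 0, 0.5),
          c(5.5, 0, 0) + stats::rnorm(3, 0, 0.5))
  })
}

# Mean and SD of L(t) and centre x(t) across runs on a common grid, holding
# each converged run at its final state beyond its termination time.
ensemble_summary <- function(runs) {
  tmax <- max(vapply(runs, function(r) max(r$times), 0))
  grid <- seq(0, tmax, length.out = 201)
  getcurve <- function(r, what) {
    v <- if (what == "L") r$L else r$center[, 1]
    ok <- !is.na(v)
    if (!any(ok)) return(rep(NA_real_, length(grid)))
    stats::approx(r$times[ok], v[ok], xout = pmin(grid, max(r$times[ok])),
                  rule = 2)$y
  }
  Lm <- sapply(runs, getcurve, what = "L")
  Cm <- sapply(runs, getcurve, what = "center")
  data.frame(t = grid,
             L_mean = rowMeans(Lm), L_sd = apply(Lm, 1, stats::sd),
             center_mean = rowMeans(Cm), center_sd = apply(Cm, 1, stats::sd))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d runs\n", x$name, length(x$runs)))
  term <- table(vapply(x$runs, function(r) r$termination, ""))
  cat("  termination:", paste(names(term), term, sep = " x ", collapse = ", "), "\n")
  nend <- nrow(x$ensemble)
  if (!is.na(x$ensemble$L_mean[nend])) {
    cat(sprintf("  final spindle length: %.2f +- %.2f um\n",
                x$ensemble$L_mean[nend], x$ensemble$L_sd[nend]))
  }
  cat(sprintf("  final center x: %.2f +- %.2f um\n",
              x$ensemble$center_mean[nend], x$ensemble$center_sd[nend]))
  invisible(x)
}

# Axial net force on a single centrosome between two parallel planes (z = +-
# half the separation), four CFGs per plane on a square grid, outward normals
# along +-z.
two_plane_force_profile <- function(offsets, overrides = list()) {
  sep <- if (is.null(overrides$separation)) 30 else overrides$separation
  spacing <- if (is.null(overrides$spacing)) 30 else overrides$spacing
  motor <- if (is.null(overrides$motor)) motor_params() else overrides$motor
  h <- sep / 2; s <- spacing / 2
  grid <- expand.grid(x = c(-s, s), y = c(-s, s))
  lay <- data.frame(
    id = 1:8,
    x = rep(grid$x, 2), y = rep(grid$y, 2),
    z = rep(c(h, -h), each = 4),
    nx = 0, ny = 0, nz = rep(c(1, -1), each = 4),
    side = rep(c("posterior", "anterior"), each = 4)
  )
  class(lay) <- c("cfg_layout", "data.frame")
  fz <- vapply(offsets, function(z0) {
    if (abs(z0) >= h) return(NA_real_)
    net_forces(matrix(c(0, 0, z0), 1), lay, motor)$forces[1, 3]
  }, 0)
  data.frame(offset = offsets, force_z = fz)
}

#' Sweep cell length at fixed CFG surface density
#'
#' Simulates spindle elongation in cells of different lengths (varying the
#' long semi-axis Rx only; Ry = Rz stay at 15 um), holding the CFG surface
#' density and the posterior/anterior asymmetry fixed at their values in the
#' 50 um baseline cell (counts per half are re-derived from the half surface
#' areas). Extracts traits per run and fits the scaling regression of final
#' spindle length on cell length.
#'
#' @param lengths Cell lengths (um), within [30, 80]; at least two distinct
#'   values are required for the scaling fit.
#' @param n_configs Runs (independent layouts) per length.
#' @param seed Integer master seed.
#' @param overrides Named list of \code{\link{simulation_config}} overrides.
#' @param baseline_n,baseline_pf CFG count and posterior fraction of the
#'   baseline 50 um cell that define the fixed density.
#' @return An object of class \code{scaling_sweep}: list with \code{traits}
#'   (per-run trait table including CL), \code{fit} (the FL-on-CL
#'   \code{\link{regress_traits}} result), and \code{per_length} summary.
#' @examples
#' \donttest{
#' sw <- cell_size_sweep(c(44, 50, 54), n_configs = 4, seed = 1)
#' sw$fit
#' }
#' @export
cell_size_sweep <- function(lengths = c(44, 46, 48, 50, 52, 54),
                            n_configs = 8, seed = 1, overrides = list(),
                            baseline_n = 100, baseline_pf = 0.6) {
  if (any(lengths < 30 | lengths > 80)) {
    stop("cell_size_sweep: lengths must lie within [30, 80] um", call. = FALSE)
  }
  base_geom <- cell_geometry(c(25, 15, 15))
  a_post <- half_surface_area(base_geom, "posterior", n_theta = 200, n_phi = 100)
  a_ant <- half_surface_area(base_geom, "anterior", n_theta = 200, n_phi = 100)
  dens_post <- baseline_n * baseline_pf / a_post
  dens_ant <- baseline_n * (1 - baseline_pf) / a_ant

  member_seeds <- with_seed(seed, matrix(sample.int(2^30, length(lengths) * n_configs),
                                         nrow = length(lengths)))
  rows <- list()
  for (li in seq_along(lengths)) {
    CL <- lengths[li]
    geom <- cell_geometry(c(CL / 2, 15, 15))
    ap <- half_surface_area(geom, "posterior", n_theta = 200, n_phi = 100)
    aa <- half_surface_area(geom, "anterior", n_theta = 200, n_phi = 100)
    n_post <- round(dens_post * ap)
    n_ant <- round(dens_ant * aa)
    for (i in seq_len(n_configs)) {
      sd_i <- member_seeds[li, i]
      args <- utils::modifyList(
        list(geometry = geom,
             layout = list(n_total = n_post + n_ant,
                           posterior_fraction = n_post / (n_post + n_ant),
                           jitter_scale = 0.2),
             x0 = jittered_start(sd_i),
             seed = sd_i),
        overrides)
      traj <- tryCatch(run_simulation(do.call(simulation_config, args)),
                       error = function(e) {
                         stop("cell_size_sweep: length ", CL, " um failed: ",
                              conditionMessage(e), call. = FALSE)
                       })
      tr <- extract_traits(traj, geom)
      tr$seed <- sd_i
      rows[[length(rows) + 1]] <- tr
    }
  }
  traits <- do.call(rbind, rows)
  fit <- regress_traits(traits, "FL", "CL")
  per_length <- do.call(rbind, lapply(split(traits, traits$CL), function(d) {
    data.frame(CL = d$CL[1], FL_mean = mean(d$FL), FL_sd = stats::sd(d$FL),
               ER_mean = mean(d$ER), center_mean = mean(d$center_offset),
               n = nrow(d))
  }))
  structure(list(traits = traits, fit = fit, per_length = per_length,
                 lengths = lengths, seed = seed),
            class = "scaling_sweep")
}

#' @export
print.scaling_sweep <- function(x, ...) {
  cat("Cell-size sweep:", nrow(x$traits), "runs over lengths",
      paste(x$lengths, collapse = ", "), "um\n")
  cat(sprintf("  scaling of final length on cell length: slope %.3f +- %.3f (p = %.3g)\n",
              x$fit$slope, x$fit$slope_se, x$fit$p_value))
  invisible(x)
}

#' Sweep the number of cortical force generators
#'
#' Tests whether stable positioning requires fewer CFGs than microtubules by
#' increasing the CFG count, optionally co-scaling other parameters to keep
#' the elongation dynamics comparable:
#' \describe{
#'   \item{force}{holds the total available force \code{N * f0} at its
#'     baseline (100 x 10 pN), so \code{f0 = 1000/N};}
#'   \item{radius_kappa}{additionally shrinks the capture radius to
#'     \code{r_new} (allowing dense packing) and rescales the detachment rate
#'     as \code{kappa (r_new/r)^2} (see \code{\link{kappa_for_radius}}), which
#'     preserves the single-CFG attachment probability;}
#'   \item{none}{changes only N (elongation speeds up but positioning stays
#'     stable).}
#' }
#'
#' @param n_values CFG counts to test.
#' @param co_scaling \code{"force"}, \code{"radius_kappa"}, or \code{"none"}.
#' @param seed Integer master seed.
#' @param n_configs Layouts per count.
#' @param r_new Capture radius used under \code{radius_kappa} co-scaling (um).
#' @param overrides \code{\link{simulation_config}} overrides (e.g. a shorter
#'   \code{t_max} for large counts).
#' @return Data frame with one row per (N, config): columns \code{n_cfg},
#'   \code{f0}, \code{kappa}, \code{r}, \code{final_length}, \code{termination},
#'   \code{stable}.
#' @export
cfg_number_sweep <- function(n_values = c(100, 1000),
                             co_scaling = c("force", "radius_kappa", "none"),
                             seed = 1, n_configs = 2, r_new = 0.1,
                             overrides = list()) {
  co_scaling <- match.arg(co_scaling)
  base_motor <- if (is.null(overrides$motor)) motor_params() else overrides$motor
  overrides$motor <- NULL
  member_seeds <- with_seed(seed, matrix(sample.int(2^30, length(n_values) * n_configs),
                                         nrow = length(n_values)))
  rows <- list()
  for (ni in seq_along(n_values)) {
    N <- n_values[ni]
    motor <- base_motor
    if (co_scaling %in% c("force", "radius_kappa")) {
      motor$pull_force <- 100 * base_motor$pull_force / N
    }
    if (co_scaling == "radius_kappa") {
      motor$detachment_rate <- kappa_for_radius(r_new, base_motor)
      motor$capture_radius <- r_new
    }
    for (i in seq_len(n_configs)) {
      sd_i <- member_seeds[ni, i]
      args <- utils::modifyList(
        list(layout = list(n_total = N, posterior_fraction = 0.6,
                           jitter_scale = 0.2),
             motor = motor, seed = sd_i),
        overrides)
      traj <- run_simulation(do.call(simulation_config, args))
      nend <- length(traj$times)
      rows[[length(rows) + 1]] <- data.frame(
        n_cfg = N, f0 = motor$pull_force, kappa = motor$detachment_rate,
        r = motor$capture_radius,
        final_length = traj$L[nend],
        termination = traj$termination,
        stable = traj$termination != "cortex_contact",
        seed = sd_i)
    }
  }
  do.call(rbind, rows)
}
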