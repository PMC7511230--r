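#' Superellipsoid cell geometry
#'
#' The embryo is modelled as a superellipsoid
#' \deqn{\left|\frac{x}{R_x}\right|^{P_x} + \left|\frac{y}{R_y}\right|^{P_y} +
#'   \left|\frac{z}{R_z}\right|^{P_z} = 1,}
#' with the long (anterior--posterior) axis along x; posterior is +x. Cell
#' length is \code{2 * Rx}. Default semi-axes 25 x 15 x 15 um (a 50 x 30 x 30
#' um cell) with exponents (2, 2, 2), i.e. an ellipsoid.
#'
#' @param semi_axes Numeric length-3 vector (Rx, Ry, Rz), um, all > 0.
#' @param exponents Numeric length-3 vector (Px, Py, Pz), all >= 2.
#' @return An object of class \code{cell_geometry}.
#' @export
cell_geometry <- function(semi_axes = c(25, 15, 15), exponents = c(2, 2, 2)) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("cell_geometry: 'semi_axes' must be three finite positive numbers", call. = FALSE)
  }
  if (length(exponents) != 3L || any(!is.finite(exponents)) || any(exponents < 2)) {
    stop("cell_geometry: 'exponents' must be three finite numbers >= 2", call. = FALSE)
  }
  structure(list(semi_axes = as.numeric(semi_axes),
                 exponents = as.numeric(exponents)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Superellipsoid cell: semi-axes (%g, %g, %g) um, exponents (%g, %g, %g)\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              x$exponents[1], x$exponents[2], x$exponents[3]))
  cat(sprintf("  cell length CL = %g um\n", 2 * x$semi_axes[1]))
  invisible(x)
}

#' Cell length of a geometry (2 Rx, um)
#' @param geom A \code{\link{cell_geometry}}.
#' @export
cell_length <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  2 * geom$semi_axes[1]
}

#' Implicit surface value and outward normal
#'
#' Evaluates \eqn{F(p) = \sum_i |p_i/R_i|^{P_i} - 1} (negative inside, zero on
#' the surface, positive outside) and the outward unit normal, the normalised
#' gradient of F.
#'
#' @param point Numeric 3-vector or n x 3 matrix (um).
#' @param geom A \code{\link{cell_geometry}}.
#' @return A list with \code{value} (length n) and \code{normal} (n x 3 matrix
#'   of unit outward normals; rows are \code{NA} where the gradient vanishes,
#'   except that a single-point evaluation at the origin is an error).
#' @export
implicit_and_normal <- function(point, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  P <- if (is.null(dim(point))) matrix(point, nrow = 1) else as.matrix(point)
  if (any(!is.finite(P))) stop("implicit_and_normal: point must be finite", call. = FALSE)
  R <- geom$semi_axes; E <- geom$exponents
  sc <- abs(sweep(P, 2, R, "/"))
  val <- sc[, 1]^E[1] + sc[, 2]^E[2] + sc[, 3]^E[3] - 1
  grad <- sapply(1:3, function(k) E[k] / R[k] * sc[, k]^(E[k] - 1) * sign(P[, k]))
  grad <- matrix(grad, ncol = 3)
  gn <- sqrt(rowSums(grad^2))
  if (nrow(P) == 1L && gn < 1e-12) {
    stop("implicit_and_normal: normal undefined at the origin (zero gradient)",
         call. = FALSE)
  }
  normal <- grad / ifelse(gn > 0, gn, NA_real_)
  list(value = val, normal = normal)
}

# Distance from the origin to the surface along unit direction(s) u (rows).
# Closed form for an all-exponents-equal superellipsoid; Newton iteration
# otherwise (F(t u) is strictly increasing in t > 0).
surface_radius <- function(u, geom) {
  U <- if (is.null(dim(u))) matrix(u, nrow = 1) else as.matrix(u)
  R <- geom$semi_axes; E <- geom$exponents
  sc <- abs(sweep(U, 2, R, "/"))
  if (length(unique(E)) == 1L) {
    p <- E[1]
    return((sc[, 1]^p + sc[, 2]^p + sc[, 3]^p)^(-1 / p))
  }
  t <- (sc[, 1]^2 + sc[, 2]^2 + sc[, 3]^2)^(-1 / 2) # ellipsoidal initial guess
  for (it in 1:60) {
    f <- (t * sc[, 1])^E[1] + (t * sc[, 2])^E[2] + (t * sc[, 3])^E[3] - 1
    df <- E[1] * t^(E[1] - 1) * sc[, 1]^E[1] + E[2] * t^(E[2] - 1) * sc[, 2]^E[2] +
      E[3] * t^(E[3] - 1) * sc[, 3]^E[3]
    step <- f / df
    t <- t - step
    if (max(abs(step)) < 1e-12) break
  }
  t
}

# Radial projection of points onto the surface (along the ray from the origin).
project_to_surface <- function(P, geom) {
  P <- if (is.null(dim(P))) matrix(P, nrow = 1) else as.matrix(P)
  nr <- sqrt(rowSums(P^2))
  u <- P / nr
  u * surface_radius(u, geom)
}

# Area-uniform random points on one half (x*xsign > 0) of the surface.
# Directions are drawn isotropically, mapped radially to the surface, and
# accepted with probability proportional to the area element
# dA = rho^2 / (u . n) dOmega.
sample_surface_uniform <- function(n, xsign, geom) {
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    m <- max(4 * n, 256)
    u <- matrix(stats::rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    u <- u[u[, 1] * xsign > 0, , drop = FALSE]
    rho <- surface_radius(u, geom)
    p <- u * rho
    nrm <- implicit_and_normal(p, geom)$normal
    w <- rho^2 / rowSums(u * nrm)
    keep <- stats::runif(nrow(p)) < w / max(w)
    pts <- rbind(pts, p[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Surface area of one half of the cell
#'
#' Numerical quadrature of the surface integral over the posterior (x > 0) or
#' anterior (x < 0) half, on a product grid of spherical directions with the
#' polar axis along x. Used to convert a fixed CFG surface density into CFG
#' counts when sweeping cell size.
#'
#' @param geom A \code{\link{cell_geometry}}.
#' @param side \code{"posterior"} or \code{"anterior"}.
#' @param n_theta,n_phi Quadrature resolution.
#' @return Area in um^2 (relative error below 1e-4 at the default resolution).
#' @examples
#' half_surface_area(cell_geometry(c(10, 10, 10)))  # 2*pi*10^2
#' @export
half_surface_area <- function(geom, side = c("posterior", "anterior"),
                              n_theta = 400, n_phi = 200) {
  stopifnot(inherits(geom, "cell_geometry"))
  side <- match.arg(side)
  # Gauss-Legendre nodes in cos(theta) on [0, 1]; x = cos(theta) * sign
  gl <- gauss_legendre(n_theta, 0, 1)
  ct <- gl$nodes; wt <- gl$weights
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-1]
  xsign <- if (side == "posterior") 1 else -1
  g <- expand.grid(i = seq_along(ct), ph = ph)
  u <- cbind(xsign * ct[g$i], st[g$i] * cos(g$ph), st[g$i] * sin(g$ph))
  rho <- surface_radius(u, geom)
  p <- u * rho
  nrm <- implicit_and_normal(p, geom)$normal
  f <- rho^2 / rowSums(u * nrm)
  sum(f * wt[g$i]) * (2 * pi / n_phi)
}

# Gauss-Legendre quadrature nodes/weights on [a, b] (Golub-Welsch).
gauss_legendre <- function(n, a = -1, b = 1) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Place cortical force generators on the cell surface
#'
#' Generates a well-spaced, area-uniform arrangement of CFGs on each half of
#' the cell surface with a prescribed posterior/anterior asymmetry, by
#' Poisson-disk (dart-throwing) sampling: candidate positions are drawn
#' area-uniformly and accepted only if they keep a minimum spacing of
#' \code{0.7 * sqrt(A_half / n_half)} from all previously accepted CFGs. This
#' yields an even distribution with unbiased surface density (no systematic
#' excess or deficit anywhere on the half, including at the equator between
#' the two halves). An optional tangential jitter displaces each CFG by
#' \code{jitter_scale} times the mean spacing and re-projects it onto the
#' surface, emulating biological randomness in motor placement. For very large
#' counts (> 2000 per half) the spacing constraint is dropped and plain
#' area-uniform sampling is used.
#'
#' @param geom A \code{\link{cell_geometry}}.
#' @param n_total Total number of CFGs (>= 1).
#' @param posterior_fraction Fraction placed on the posterior (x > 0) half;
#'   the posterior count is \code{round(n_total * posterior_fraction)}.
#' @param jitter_scale Tangential jitter magnitude as a fraction of the mean
#'   inter-CFG spacing (default 0.2; 0 disables).
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param capture_radius Capture radius used for the packing feasibility check
#'   (um).
#' @return A data frame of class \code{cfg_layout} with columns \code{id},
#'   \code{x}, \code{y}, \code{z} (um), \code{nx}, \code{ny}, \code{nz}
#'   (outward unit normal) and \code{side} ("posterior"/"anterior"), plus the
#'   geometry in attribute \code{"geometry"}.
#' @export
cfg_layout <- function(geom = cell_geometry(), n_total = 100,
                       posterior_fraction = 0.6, jitter_scale = 0.2,
                       seed = 1, capture_radius = 1.5) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (n_total < 1) stop("cfg_layout: n_total must be >= 1", call. = FALSE)
  if (posterior_fraction < 0 || posterior_fraction > 1) {
    stop("cfg_layout: posterior_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (jitter_scale < 0) stop("cfg_layout: jitter_scale must be >= 0", call. = FALSE)
  n_post <- round(n_total * posterior_fraction)
  n_ant <- n_total - n_post

  a_post <- half_surface_area(geom, "posterior", n_theta = 200, n_phi = 100)
  a_ant <- half_surface_area(geom, "anterior", n_theta = 200, n_phi = 100)
  # feasibility: disks of the capture radius must fit below hex-packing density
  for (h in list(c(n_post, a_post, "posterior"), c(n_ant, a_ant, "anterior"))) {
    nh <- as.numeric(h[1]); ah <- as.numeric(h[2])
    cover <- nh * pi * capture_radius^2 / ah
    if (cover > 0.9069) {
      stop(sprintf(paste0("cfg_layout: packing infeasible on the %s half: %d disks of ",
                          "radius %.3g um cover %.0f%% of %.4g um^2 (limit 90.69%%, ",
                          "max density %.3g CFGs/um^2)"),
                   h[3], nh, capture_radius, 100 * cover, ah,
                   0.9069 / (pi * capture_radius^2)), call. = FALSE)
    }
  }

  pts <- with_seed(seed, {
    post <- place_half(n_post, 1, geom, a_post)
    ant <- place_half(n_ant, -1, geom, a_ant, existing = post)
    P <- rbind(post, ant)
    if (nrow(P) <= 2000 && nrow(P) > 1) {
      spac <- 0.75 * sqrt(rep(c(a_post / max(1, n_post), a_ant / max(1, n_ant)),
                              c(n_post, n_ant)))
      xs_half <- rep(c(1, -1), c(n_post, n_ant))
      P <- polish_spacing(P, geom, spac, xs_half)
    }
    if (jitter_scale > 0 && nrow(P) > 0) {
      spacing <- sqrt(((a_post + a_ant) / 2) / max(1, n_total / 2))
      nrm <- implicit_and_normal(P, geom)$normal
      disp <- matrix(stats::rnorm(3 * nrow(P)), ncol = 3)
      disp <- disp - rowSums(disp * nrm) * nrm # tangent plane
      dn <- sqrt(rowSums(disp^2))
      dn[dn == 0] <- 1
      mag <- abs(stats::rnorm(nrow(P), 0, jitter_scale * spacing))
      P <- P + disp / dn * mag
      # keep each point on its assigned half, then re-project
      xs <- rep(c(1, -1), c(n_post, n_ant))
      P[, 1] <- xs * pmax(xs * P[, 1], 1e-6)
      P <- project_to_surface(P, geom)
    }
    P
  })

  nrm <- if (nrow(pts) > 0) implicit_and_normal(pts, geom)$normal else matrix(0, 0, 3)
  out <- data.frame(
    id = seq_len(nrow(pts)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    side = rep(c("posterior", "anterior"), c(n_post, n_ant)),
    stringsAsFactors = FALSE
  )
  attr(out, "geometry") <- geom
  class(out) <- c("cfg_layout", "data.frame")
  out
}

# Separate too-close pairs by symmetric pushes along their chord, re-projected
# to the surface; points stay on their assigned half. Purely local, so the
# large-scale (area-uniform) density is preserved. 'spac' is the per-point
# target minimum distance; a pair's target is the smaller of the two.
polish_spacing <- function(P, geom, spac, xs_half, iters = 40) {
  n <- nrow(P)
  for (it in seq_len(iters)) {
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    tgt <- outer(spac, spac, pmin)
    idx <- which(D < tgt & upper.tri(D), arr.ind = TRUE)
    if (nrow(idx) == 0) break
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      dv <- P[i, ] - P[j, ]
      dd <- sqrt(sum(dv^2))
      push <- 0.55 * (tgt[i, j] - dd) * dv / max(dd, 1e-9)
      P[i, ] <- P[i, ] + push
      P[j, ] <- P[j, ] - push
    }
    P[, 1] <- xs_half * pmax(xs_half * P[, 1], 1e-6)
    P <- project_to_surface(P, geom)
  }
  P
}

# Dispatch: surfaces of revolution about x (Ry = Rz, Py = Pz) get the
# area-exact randomized spiral lattice; other shapes fall back to
# Poisson-disk sampling.
place_half <- function(n, xsign, geom, area_half, existing = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  R <- geom$semi_axes; E <- geom$exponents
  if (R[2] == R[3] && E[2] == E[3]) {
    return(revolution_lattice(n, xsign, geom))
  }
  place_half_pdisk(n, xsign, geom, area_half, existing)
}

# Randomized spiral (Fibonacci) lattice on one half of a surface of
# revolution about x. Band coordinate u stratifies the cumulative surface
# area exactly (one point per equal-area stratum, with a random common
# offset), and the azimuth advances by the golden angle from a random
# rotation. Density is exactly area-uniform; spacing is blue-noise quality.
revolution_lattice <- function(n, xsign, geom) {
  R <- geom$semi_axes; E <- geom$exponents
  Rx <- R[1]; Ry <- R[2]; Px <- E[1]; Py <- E[2]
  profile <- function(x) Ry * (pmax(0, 1 - (x / Rx)^Px))^(1 / Py)
  # cumulative area from the equator (x = 0) to the tip, on a pole-refined grid
  s <- seq(0, pi / 2, length.out = 4001)
  xg <- Rx * sin(s)
  rg <- profile(xg)
  seg <- sqrt(diff(xg)^2 + diff(rg)^2)
  dA <- 2 * pi * (rg[-1] + rg[-length(rg)]) / 2 * seg
  cumA <- c(0, cumsum(dA))
  golden <- (1 + sqrt(5)) / 2
  u0 <- stats::runif(1)
  phi0 <- stats::runif(1, 0, 2 * pi)
  u <- (seq_len(n) - u0) / n
  x <- stats::approx(cumA / cumA[length(cumA)], xg, xout = u)$y
  rho <- profile(x)
  phi <- phi0 + 2 * pi * ((seq_len(n) / golden) %% 1)
  cbind(xsign * x, rho * cos(phi), rho * sin(phi))
}

# Poisson-disk sampling of n points on one half; minimum spacing
# 0.7*sqrt(A/n) against both this half's points and any 'existing' points.
place_half_pdisk <- function(n, xsign, geom, area_half, existing = NULL) {
  if (n > 2000) return(sample_surface_uniform(n, xsign, geom))
  dmin2 <- (0.7 * sqrt(area_half / n))^2
  placed <- matrix(numeric(0), 0, 3)
  attempts <- 0
  while (nrow(placed) < n) {
    cand <- sample_surface_uniform(max(64, 4 * n), xsign, geom)
    for (i in seq_len(nrow(cand))) {
      if (nrow(placed) >= n) break
      p <- cand[i, ]
      blockers <- rbind(existing, placed)
      ok <- nrow(blockers) == 0 ||
        min((blockers[, 1] - p[1])^2 + (blockers[, 2] - p[2])^2 +
              (blockers[, 3] - p[3])^2) >= dmin2
      if (ok) placed <- rbind(placed, p)
    }
    attempts <- attempts + 1
    if (attempts > 500) {
      stop(sprintf(paste0("cfg_layout: could not place %d points at minimum spacing ",
                          "%.3g um on a %.4g um^2 half (limiting density %.3g points/um^2)"),
                   n, sqrt(dmin2), area_half, n / area_half), call. = FALSE)
    }
  }
  placed
}

#' @export
print.cfg_layout <- function(x, ...) {
  cat(sprintf("CFG layout: %d force generators (%d posterior / %d anterior)\n",
              nrow(x), sum(x$side == "posterior"), sum(x$side == "anterior")))
  g <- attr(x, "geometry")
  if (!is.null(g)) {
    cat(sprintf("  on a %g x %g x %g um cell\n",
                2 * g$semi_axes[1], 2 * g$semi_axes[2], 2 * g$semi_axes[3]))
  }
  invisible(x)
}

# Evaluate an expression with a temporary RNG state seeded by 'seed',
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
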