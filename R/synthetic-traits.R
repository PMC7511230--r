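#' Generate synthetic trait tables under candidate size-control models
#'
#' Produces many-line trait tables with the statistical structure implied by
#' each class of spindle size-control model, so the discrimination logic of
#' \code{\link{model_signature_tests}} can be validated without experimental
#' data. Each "line" has latent trait values drawn from the generative model;
#' \code{n_replicates} noisy measurements per line are averaged into line
#' means (with standard errors), emulating replicate embryos per genetic line.
#'
#' Generative structures (lengths in um, near the one-cell embryo regime):
#' \itemize{
#'   \item \code{timer}: initial length IL and elongation Delta are independent
#'     draws; FL = IL + Delta. Cell size (CL, CA) varies independently of the
#'     spindle; CD follows from the geometry (CL - FL)/2 plus noise.
#'   \item \code{limiting_component}: a latent relative cell volume CV and an
#'     independent component density rho set FL ~ rho * CV; CL and CA are
#'     noisy readouts of CV (CA less noisy than CL, so area carries volume
#'     information beyond length); IL and CD vary independently.
#'   \item \code{boundary}: CL and CD are independent; FL = CL - 2 CD + noise;
#'     IL varies independently; CA tracks CL.
#'   \item \code{custom_covariance}: multivariate normal with a user covariance
#'     (dimnames name the traits).
#' }
#'
#' @param model_kind One of \code{"timer"}, \code{"limiting_component"},
#'   \code{"boundary"}, \code{"custom_covariance"}.
#' @param n_lines Number of lines (>= 10).
#' @param means,sds Named numeric vectors overriding the per-trait latent
#'   means / SDs (names among IL, Delta, CL, CD, CV, rho).
#' @param noise_sd Measurement noise SD applied to each replicate of the
#'   length-like traits (um).
#' @param n_replicates Replicates per line averaged into the line mean.
#' @param covariance Covariance matrix for \code{custom_covariance} (with
#'   dimnames), and \code{custom_means} its mean vector.
#' @param custom_means Mean vector for \code{custom_covariance}.
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return A data frame (class \code{trait_table}) with one row per line:
#'   columns \code{line}, trait means (IL, FL, CL, CA, CD for the named
#'   models), per-trait standard errors (\code{*_se}), and \code{n_rep}.
#' @examples
#' tab <- generate_trait_table("boundary", n_lines = 200, seed = 1)
#' model_signature_tests(tab)
#' @export
generate_trait_table <- function(model_kind = c("timer", "limiting_component",
                                                "boundary", "custom_covariance"),
                                 n_lines = 200,
                                 means = NULL, sds = NULL,
                                 noise_sd = 0.4,
                                 n_replicates = 5,
                                 covariance = NULL, custom_means = NULL,
                                 seed = 1) {
  model_kind <- match.arg(model_kind)
  if (n_lines < 10) stop("generate_trait_table: n_lines must be >= 10", call. = FALSE)
  mu <- c(IL = 11.5, Delta = 12.4, CL = 50, CD = 10, CV = 1, rho = 1)
  sg <- c(IL = 0.8, Delta = 1.2, CL = 2.5, CD = 1.0, CV = 0.08, rho = 0.05)
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) {
    if (any(unlist(sds) < 0)) stop("generate_trait_table: SDs must be >= 0", call. = FALSE)
    sg[names(sds)] <- sds
  }
  ca_per_cl <- pi * 15 / 2 # midplane ellipse area per unit cell length at Ry = 15

  with_seed(seed, {
    lat <- switch(model_kind,
      timer = {
        IL <- stats::rnorm(n_lines, mu["IL"], sg["IL"])
        Delta <- stats::rnorm(n_lines, mu["Delta"], sg["Delta"])
        FL <- IL + Delta
        CL <- stats::rnorm(n_lines, mu["CL"], sg["CL"])
        CA <- ca_per_cl * CL + stats::rnorm(n_lines, 0, 12)
        CD <- (CL - FL) / 2 + stats::rnorm(n_lines, 0, 0.5)
        data.frame(IL = IL, FL = FL, CL = CL, CA = CA, CD = CD)
      },
      limiting_component = {
        # cell area reads volume nearly noise-free; cell length is a looser
        # readout (shape variation), so area carries volume information beyond
        # length and the FL-CA partial correlation given CL stays positive
        CV <- stats::rnorm(n_lines, mu["CV"], sg["CV"])
        rho <- stats::rnorm(n_lines, mu["rho"], sg["rho"])
        FL <- (mu["IL"] + mu["Delta"]) * rho * CV
        CL <- mu["CL"] * (1 + 0.5 * (CV - 1) + stats::rnorm(n_lines, 0, 0.03))
        CA <- ca_per_cl * mu["CL"] * (1 + 0.9 * (CV - 1) + stats::rnorm(n_lines, 0, 0.008))
        IL <- stats::rnorm(n_lines, mu["IL"], sg["IL"])
        CD <- stats::rnorm(n_lines, mu["CD"], sg["CD"])
        data.frame(IL = IL, FL = FL, CL = CL, CA = CA, CD = CD)
      },
      boundary = {
        CL <- stats::rnorm(n_lines, mu["CL"], sg["CL"])
        CD <- stats::rnorm(n_lines, mu["CD"], sg["CD"])
        FL <- CL - 2 * CD + stats::rnorm(n_lines, 0, if (noise_sd > 0) 0.3 else 0)
        IL <- stats::rnorm(n_lines, mu["IL"], sg["IL"])
        CA <- ca_per_cl * CL + stats::rnorm(n_lines, 0, 12)
        data.frame(IL = IL, FL = FL, CL = CL, CA = CA, CD = CD)
      },
      custom_covariance = {
        if (is.null(covariance)) {
          stop("generate_trait_table: custom_covariance requires 'covariance'", call. = FALSE)
        }
        ch <- tryCatch(chol(covariance), error = function(e) {
          stop("generate_trait_table: covariance is not positive definite", call. = FALSE)
        })
        k <- ncol(covariance)
        zz <- matrix(stats::rnorm(n_lines * k), n_lines, k) %*% ch
        if (!is.null(custom_means)) zz <- sweep(zz, 2, custom_means, "+")
        zz <- as.data.frame(zz)
        names(zz) <- colnames(covariance)
        zz
      }
    )
    traits <- names(lat)
    out <- data.frame(line = paste0("L", seq_len(n_lines)))
    for (tr in traits) {
      reps <- matrix(stats::rnorm(n_lines * n_replicates, 0, noise_sd),
                     n_lines, n_replicates) + lat[[tr]]
      out[[tr]] <- rowMeans(reps)
      out[[paste0(tr, "_se")]] <- apply(reps, 1, stats::sd) / sqrt(n_replicates)
    }
    out$n_rep <- n_replicates
    class(out) <- c("trait_table", "data.frame")
    out
  })
}
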