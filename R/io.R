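#' Load a simulation configuration document
#'
#' Reads a YAML configuration file, validates it against the schema (unknown
#' keys are rejected, types checked), and fills every omitted field with the
#' package defaults -- the literature parameter table. An empty file therefore
#' yields the full default configuration.
#'
#' Schema sections: \code{motor} (nucleation_rate, growth_speed,
#' catastrophe_rate, detachment_rate, capture_radius, pull_force),
#' \code{mechanics} (centrosome_drag, spindle_viscosity), \code{geometry}
#' (semi_axes, exponents), \code{layout} (n_total, posterior_fraction,
#' jitter_scale), \code{simulation} (mode, dt, t_max, speed_tolerance,
#' quiet_time, record_stride, seed, attachment_dynamics), \code{scenario}
#' (name, n_configs), \code{schema_version}.
#'
#' @param path Path to a YAML file.
#' @return A nested list of class \code{config_document}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("load_config: no such file: ", path),
                        class = c("config_missing_file_error", "error", "condition")))
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  validate_config(doc)
}

#' @rdname load_config
#' @param doc A (possibly partial) nested configuration list.
#' @export
validate_config <- function(doc = list()) {
  defaults <- default_config()
  if (!is.list(doc)) {
    stop(errorCondition("config must be a mapping of sections",
                        class = c("config_type_error", "error", "condition")))
  }
  bad <- setdiff(names(doc), names(defaults))
  if (length(bad)) {
    stop(errorCondition(paste0("unknown config key: ", paste(bad, collapse = ", ")),
                        class = c("config_unknown_key_error", "error", "condition")))
  }
  out <- defaults
  for (sec in names(doc)) {
    if (sec == "schema_version") {
      out$schema_version <- doc$schema_version
      next
    }
    if (!is.list(doc[[sec]])) {
      stop(errorCondition(paste0("config section '", sec, "' must be a mapping"),
                          class = c("config_type_error", "error", "condition")))
    }
    badk <- setdiff(names(doc[[sec]]), names(defaults[[sec]]))
    if (length(badk)) {
      stop(errorCondition(paste0("unknown config key: ", sec, ".",
                                 paste(badk, collapse = paste0(", ", sec, "."))),
                          class = c("config_unknown_key_error", "error", "condition")))
    }
    for (k in names(doc[[sec]])) {
      v <- doc[[sec]][[k]]
      ref <- defaults[[sec]][[k]]
      if (is.numeric(ref)) {
        if (!is.numeric(v) || length(v) != length(ref)) {
          stop(errorCondition(sprintf("config key %s.%s must be numeric of length %d",
                                      sec, k, length(ref)),
                              class = c("config_type_error", "error", "condition")))
        }
      }
      out[[sec]][[k]] <- v
    }
  }
  structure(out, class = "config_document")
}

default_config <- function() {
  list(
    schema_version = 1,
    motor = unclass(motor_params()),
    mechanics = unclass(mechanics_params()),
    geometry = unclass(cell_geometry()),
    layout = list(n_total = 100, posterior_fraction = 0.6, jitter_scale = 0.2),
    simulation = list(mode = "stoichiometric", dt = 0.05, t_max = 600,
                      speed_tolerance = 0.005, quiet_time = 10,
                      record_stride = 10, seed = 1,
                      attachment_dynamics = "quasi_steady"),
    scenario = list(name = "wildtype_asymmetric", n_configs = 8)
  )
}

#' Save a configuration document as YAML
#' @param doc A \code{config_document} (or compatible list).
#' @param path Output path.
#' @export
save_config <- function(doc, path) {
  yaml::write_yaml(unclass(doc), path)
  invisible(path)
}

#' Build a \code{\link{simulation_config}} from a configuration document
#' @param doc A \code{config_document}.
#' @param ... Overrides passed on to \code{\link{simulation_config}}.
#' @export
as_simulation_config <- function(doc, ...) {
  stopifnot(inherits(doc, "config_document"))
  args <- list(
    geometry = do.call(cell_geometry, doc$geometry),
    layout = doc$layout,
    motor = do.call(motor_params, doc$motor),
    mechanics = do.call(mechanics_params, doc$mechanics),
    mode = doc$simulation$mode,
    dt = doc$simulation$dt,
    t_max = doc$simulation$t_max,
    speed_tolerance = doc$simulation$speed_tolerance,
    quiet_time = doc$simulation$quiet_time,
    record_stride = doc$simulation$record_stride,
    seed = doc$simulation$seed,
    attachment_dynamics = doc$simulation$attachment_dynamics
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' Write a trajectory as TSV with a YAML metadata sidecar
#'
#' The table holds t, x1, y1, z1, x2, y2, z2, L, cx, cy, cz at full double
#' precision (round-trip exact to 1e-9). The sidecar \code{<path>.meta.yaml}
#' records the seed, termination reason, package version and an echo of the
#' configuration.
#'
#' @param traj A \code{spindle_trajectory}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "spindle_trajectory"))
  df <- as.data.frame(traj)
  fmt <- vapply(df, function(col) sprintf("%.12g", col), character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(fmt, 1, paste, collapse = "\t"), con)
  cfg <- traj$config
  meta <- list(
    seed = cfg$seed,
    termination = traj$termination,
    package_version = as.character(utils::packageVersion("stoichspindle")),
    config = list(
      motor = unclass(cfg$motor),
      mechanics = unclass(cfg$mechanics),
      geometry = unclass(cfg$geometry),
      mode = cfg$mode,
      dt = cfg$dt, t_max = cfg$t_max,
      speed_tolerance = cfg$speed_tolerance,
      record_stride = cfg$record_stride
    )
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a trajectory TSV written by \code{\link{write_trajectory}}
#'
#' @param path TSV path.
#' @return A list with \code{data} (data frame) and \code{meta} (list, or
#'   \code{NULL} if the sidecar is absent).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) {
    stop("read_trajectory: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop("read_trajectory: parse error at line ", length(lines),
         ": file truncated (no data rows)", call. = FALSE)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncol_expect <- length(header)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != ncol_expect)) {
    bad <- which(nf != ncol_expect)[1] + 1L
    stop("read_trajectory: parse error at line ", bad, ": expected ",
         ncol_expect, " fields, found ", nf[bad - 1L], call. = FALSE)
  }
  vals <- matrix(as.numeric(unlist(rows)), ncol = ncol_expect, byrow = TRUE)
  if (anyNA(vals[, 1])) {
    stop("read_trajectory: parse error: non-numeric time values", call. = FALSE)
  }
  df <- as.data.frame(vals)
  names(df) <- header
  metafile <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(metafile)) yaml::read_yaml(metafile) else NULL
  list(data = df, meta = meta)
}

#' Write / read a trait table as TSV
#'
#' Plain tab-separated tables with a leading comment line naming the units
#' (lengths in um, rates in um/s).
#'
#' @param table A data frame (e.g. from \code{\link{generate_trait_table}} or
#'   \code{\link{cell_size_sweep}}).
#' @param path File path.
#' @return \code{path} (write) or the data frame (read).
#' @export
write_trait_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: lengths um; elongation rate um/s; areas um^2", con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("read_trait_table: no such file: ", path, call. = FALSE)
  out <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}
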