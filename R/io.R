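#' Load and validate a run configuration
#'
#' Reads a flat key-value YAML configuration, applies the package defaults
#' (`c0 = 0.01`, `H = 0.1`, `q = 1.5`, `p_bar = 1`, `rho = 1`), validates
#' every key against the schema and rejects unknown keys. Geometry keys
#' (`shift`) are only accepted for the cytosol tier.
#'
#' @param path Path to a YAML file (an empty file yields the all-defaults
#'   configuration).
#' @return A validated `run_config` (named list) including all defaults.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path) && file.size(path) > 0)
    yaml::read_yaml(path) else list()
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

config_schema <- function() {
  list(
    tier = list(default = "wellmixed",
                check = function(x) x %in% c("wellmixed", "membrane", "cytosol")),
    alpha = list(default = 10, check = function(x) is.numeric(x) && x > 0),
    b = list(default = NA_real_,
             check = function(x) is.na(x) || (is.numeric(x) && x > 0)),
    H = list(default = 0.1, check = function(x) is.numeric(x) && x > 0),
    c0 = list(default = 0.01,
              check = function(x) is.numeric(x) && x >= 0 && x <= 1),
    q = list(default = 1.5, check = function(x) is.numeric(x) && x > 1),
    p_bar = list(default = 1, check = function(x) is.numeric(x) && x > 0),
    rho = list(default = 1, check = function(x) is.numeric(x) && x > 0),
    r_n = list(default = 0.95,
               check = function(x) is.numeric(x) && x >= 0 && x < 1),
    shift = list(default = 0, check = function(x) is.numeric(x) && x >= 0,
                 tiers = "cytosol"),
    F = list(default = 0, check = function(x) is.numeric(x) && x >= 0 && x <= 1),
    i = list(default = 1, check = function(x) is.numeric(x) && x >= 1),
    t_end = list(default = 300, check = function(x) is.numeric(x) && x > 0),
    dt = list(default = 0.05, check = function(x) is.numeric(x) && x > 0),
    save_by = list(default = 1, check = function(x) is.numeric(x) && x > 0),
    n_theta = list(default = 240,
                   check = function(x) is.numeric(x) && x >= 8),
    n_r = list(default = 8, check = function(x) is.numeric(x) && x >= 2,
               tiers = "cytosol")
  )
}

config_from_list <- function(raw) {
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- lapply(names(schema), function(k)
    if (k %in% names(raw)) raw[[k]] else schema[[k]]$default)
  names(cfg) <- names(schema)
  bad <- names(schema)[!vapply(names(schema), function(k)
    isTRUE(schema[[k]]$check(cfg[[k]])), logical(1))]
  if (length(bad))
    stop("invalid configuration values for keys: ", paste(bad, collapse = ", "))
  for (k in names(schema)) {
    tiers <- schema[[k]]$tiers
    if (!is.null(tiers) && !(cfg$tier %in% tiers) && k %in% names(raw) &&
        !identical(raw[[k]], schema[[k]]$default))
      stop(sprintf("key `%s` is not applicable to tier `%s`", k, cfg$tier))
  }
  if (cfg$shift >= 1 - cfg$r_n && cfg$shift > 0)
    stop("invalid configuration: shift must be < 1 - r_n")
  structure(cfg, class = "run_config")
}

#' Model parameters from a run configuration
#'
#' @param cfg A `run_config`.
#' @return A `bcr_params` with `a` chosen by the configured tier.
#' @export
params_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  a <- if (cfg$tier == "membrane") surface_to_volume(cfg$r_n) else 1
  model_params(alpha = cfg$alpha, b = cfg$b, H = cfg$H, c0 = cfg$c0, a = a,
               rho = cfg$rho, p_bar = cfg$p_bar, q = cfg$q, r_n = cfg$r_n)
}

#' Write results with a reproducibility manifest
#'
#' Writes a table (sweep table, tidy trajectory, or any data frame) as CSV
#' and an accompanying JSON manifest recording the configuration, its hash
#' and the package version. Identical configurations hash identically, and
#' the whole pipeline is deterministic, so repeated runs produce bit-identical
#' outputs.
#'
#' @param x A data frame (e.g. a `sweep_table`) or a `bcr_trajectory` (tidied
#'   before writing).
#' @param path Output CSV path; the manifest is written next to it with
#'   extension `.manifest.json`.
#' @param config Optional `run_config` (or any list) recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(x, path, config = NULL) {
  if (inherits(x, "bcr_trajectory")) x <- generics::tidy(x)
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE)
  manifest <- list(
    path = basename(path),
    rows = nrow(x),
    columns = names(x),
    config = if (is.null(config)) NULL else unclass(config),
    config_hash = if (is.null(config)) NULL else digest::digest(unclass(config)),
    package = "bcrwave",
    version = as.character(utils::packageVersion("bcrwave")),
    time_units = "1/gamma* (seconds for gamma* = 1/s)"
  )
  jsonlite::write_json(manifest,
                       sub("\\.csv$", ".manifest.json", path, ignore.case = TRUE),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Write a receptor-density profile as CSV
#'
#' Two-column CSV (`theta_rad`, `density`) fixture describing an
#' axisymmetric receptor distribution.
#'
#' @param dist A `bcr_receptors` object.
#' @param path Output path.
#' @param n Number of angles.
#' @return The profile tibble, invisibly.
#' @export
write_receptor_profile <- function(dist, path, n = 721) {
  prof <- receptor_profile(dist, n)
  utils::write.csv(prof, path, row.names = FALSE)
  invisible(prof)
}

#' Export a meridian mesh and nodal fields as a legacy VTK file
#'
#' Writes the quadrilateral meridian mesh with any number of nodal scalar
#' fields (e.g. the final kinase field of a cytosolic run) as an ASCII legacy
#' VTK file for visualization in ParaView or similar tools. Coordinates are
#' the meridian-plane `(z, rho)` pair with zero third component.
#'
#' @param mesh A `bcr_mesh`.
#' @param path Output `.vtk` path.
#' @param ... Named numeric vectors, one value per mesh node.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, ...) {
  stopifnot(inherits(mesh, "bcr_mesh"))
  fields <- list(...)
  nn <- length(mesh$z)
  for (f in fields) stopifnot(length(f) == nn)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "bcrwave meridian mesh snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(cbind(mesh$z, mesh$rho, 0), con, row.names = FALSE,
                     col.names = FALSE)
  nq <- nrow(mesh$quads)
  writeLines(sprintf("CELLS %d %d", nq, 5 * nq), con)
  utils::write.table(cbind(4L, mesh$quads - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nq), con)
  writeLines(as.character(rep(9L, nq)), con) # VTK_QUAD
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(fields[[nm]], digits = 12), con)
    }
  }
  invisible(path)
}
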