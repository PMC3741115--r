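#' Read a simulation configuration file
#'
#' Plain-text YAML with one section per concern: `params` (any field of
#' [sim_params()]), `grid` (`n`, `spacing`, `boundary`), `protocol` (either
#' a preset `name` plus `fraction`, or explicit protocol fields) and `run`
#' (`seed`, `n_seeds`, `snapshot_times`, `probe_radii`). Unknown keys are an
#' error, so typos cannot silently fall back to defaults.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `params` ([sim_params()]), `grid`
#'   ([grid_spec()]), `protocol` ([da_protocol()]) and `run` (list).
#' @examples
#' cfg <- read_config(system.file("extdata", "config-default.yaml",
#'                                package = "dopaflux"))
#' cfg$params$uptake_rate
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_sections <- c("params", "grid", "protocol", "run")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      stop("unknown key(s) in [", section, "]: ",
           paste(bad, collapse = ", "), call. = FALSE)
    x
  }

  par_allowed <- setdiff(names(formals(sim_params)), "")
  par_args <- check_keys(raw$params %||% list(), par_allowed, "params")
  params <- do.call(sim_params, par_args)

  grid_raw <- raw$grid %||% list()
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(grid_raw)[names(grid_raw) == "FALSE"] <- "n"
  grid_args <- check_keys(grid_raw, c("n", "spacing", "boundary"), "grid")
  grid <- do.call(grid_spec, grid_args)
  if (abs(grid$shape[1] * grid$spacing - params$edge_length) > 1e-9 ||
      length(unique(grid$shape)) != 1)
    stop("grid (n * spacing) must match params$edge_length", call. = FALSE)

  proto_raw <- raw$protocol %||% list(name = "A", fraction = 0.5)
  check_keys(proto_raw, c("name", "fraction", "t_end"), "protocol")
  protocol <- do.call(da_protocol, proto_raw)

  run <- check_keys(raw$run %||% list(),
                    c("seed", "n_seeds", "snapshot_times", "probe_radii",
                      "out_dir"), "run")
  run$seed <- run$seed %||% params$seed
  run$n_seeds <- run$n_seeds %||% 10L

  list(params = params, grid = grid, protocol = protocol, run = run)
}

#' Write a release-site set to CSV
#'
#' Columns `site`, `x`, `y`, `z`, `cohort`; the placement seed, density and
#' grid are recorded as comment header lines for reproducibility.
#'
#' @param sites A `release_sites` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  stopifnot(inherits(sites, "release_sites"))
  g <- attr(sites, "grid")
  hdr <- c(sprintf("# seed: %s", format(attr(sites, "seed"))),
           sprintf("# density_per_um3: %g", attr(sites, "density")),
           sprintf("# grid: %d x %d x %d @ %g um, %s",
                   g$shape[1], g$shape[2], g$shape[3], g$spacing, g$boundary))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    as.data.frame(sites), path, sep = ",", row.names = FALSE,
    quote = FALSE, append = TRUE))
  invisible(path)
}

#' Write a field snapshot as long-format CSV
#'
#' One row per voxel (`x`, `y`, `z`, `conc_nM`) with the snapshot time in a
#' comment header — a plain-text serialization that any tool can read back.
#'
#' @param field A [da_field()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "da_field"))
  writeLines(sprintf("# time_s: %g", field_time(field)), path)
  suppressWarnings(utils::write.table(
    as.data.frame(tidy.da_field(field)), path, sep = ",", row.names = FALSE,
    quote = FALSE, append = TRUE))
  invisible(path)
}
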