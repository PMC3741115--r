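#' Simulation parameters for cortical dopamine volume transmission
#'
#' Bundles every physical constant of the model with its units and validates
#' the invariants that the engine relies on. Defaults describe layer 3 of
#' primate prefrontal area 10: sparse release sites (2 per 10,000 um^3),
#' an extracellular volume fraction of 23%, hindered diffusion at an
#' effective 322 um^2/s, and slow first-order reuptake at 1.5 /s.
#'
#' Concentrations throughout the package are expressed in nM referred to the
#' extracellular fluid volume (mol per litre of extracellular water), so a
#' single vesicle released into one 1-um^3 voxel raises that voxel by
#' `quantal_increment()` nanomolar.
#'
#' @param site_density Potential release sites per um^3 of tissue.
#' @param edge_length Side of the cubic simulation volume, um.
#' @param voxel_spacing Voxel side, um (voxel volume is `voxel_spacing^3`).
#' @param alpha Extracellular volume fraction (0 < alpha <= 1).
#' @param tortuosity Geometric hindrance factor of the neuropil
#'   (metadata; the engine uses `D_eff` directly).
#' @param D_free Free diffusion coefficient of dopamine, um^2/s.
#' @param D_eff Effective diffusion coefficient in tissue, um^2/s
#'   (approximately `D_free / tortuosity^2`).
#' @param vesicle_volume Volume of one vesicle, litres.
#' @param vesicle_conc Dopamine concentration inside a vesicle, mol/L.
#' @param quantal_moles Moles of dopamine per release event; defaults to
#'   `vesicle_volume * vesicle_conc` and must agree with it when supplied.
#' @param f_tonic Tonic (background) firing rate, Hz.
#' @param f_phasic Default phasic (burst) firing rate, Hz.
#' @param pause_rate Firing rate during a pause, Hz (normally 0).
#' @param release_prob Probability that a firing event releases one vesicle.
#' @param uptake_rate First-order reuptake rate constant k, 1/s.
#' @param uptake_block_time Time (s) after which reuptake is switched off
#'   completely, or `Inf` for never. See [blocked_uptake_variant()].
#' @param kd_high,kd_low Receptor dissociation constants for the high- and
#'   low-affinity states, nM.
#' @param dt Euler time step, s. Must satisfy the stability bound
#'   `dt <= voxel_spacing^2 / (6 * D_eff)` and, for guaranteed
#'   non-negativity, `dt * (6 * D_eff / voxel_spacing^2 + uptake_rate) <= 1`.
#' @param seed Default integer seed for site placement and release sampling.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' p$quantal_moles            # 1.625e-20 mol per vesicle
#' stability_max_dt(p$D_eff, p$voxel_spacing)
#' @export
sim_params <- function(site_density = 2e-4,
                       edge_length = 64,
                       voxel_spacing = 1,
                       alpha = 0.23,
                       tortuosity = 1.54,
                       D_free = 763,
                       D_eff = 322,
                       vesicle_volume = 6.5e-20,
                       vesicle_conc = 0.25,
                       quantal_moles = vesicle_volume * vesicle_conc,
                       f_tonic = 5.6,
                       f_phasic = 15,
                       pause_rate = 0,
                       release_prob = 0.5,
                       uptake_rate = 1.5,
                       uptake_block_time = Inf,
                       kd_high = 10,
                       kd_low = 1500,
                       dt = 5e-4,
                       seed = 1L) {
  p <- list(
    site_density = site_density, edge_length = edge_length,
    voxel_spacing = voxel_spacing, voxel_volume = voxel_spacing^3,
    alpha = alpha, tortuosity = tortuosity,
    D_free = D_free, D_eff = D_eff,
    vesicle_volume = vesicle_volume, vesicle_conc = vesicle_conc,
    quantal_moles = quantal_moles,
    f_tonic = f_tonic, f_phasic = f_phasic, pause_rate = pause_rate,
    release_prob = release_prob,
    uptake_rate = uptake_rate, uptake_block_time = uptake_block_time,
    kd_high = kd_high, kd_low = kd_low,
    dt = dt, seed = as.integer(seed))
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  num_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  if (!num_pos(p$alpha) || p$alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  for (f in c("site_density", "edge_length", "voxel_spacing", "D_free",
              "D_eff", "vesicle_volume", "vesicle_conc", "quantal_moles",
              "kd_high", "kd_low", "dt"))
    if (!num_pos(p[[f]])) stop("`", f, "` must be a positive number", call. = FALSE)
  for (f in c("f_tonic", "f_phasic", "pause_rate", "uptake_rate"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) || p[[f]] < 0)
      stop("`", f, "` must be a non-negative rate", call. = FALSE)
  if (p$release_prob < 0 || p$release_prob > 1)
    stop("`release_prob` must lie in [0, 1]", call. = FALSE)
  if (p$D_eff > p$D_free + 1e-9)
    stop("`D_eff` cannot exceed `D_free`", call. = FALSE)
  qv <- p$vesicle_volume * p$vesicle_conc
  if (abs(p$quantal_moles - qv) > 1e-6 * qv)
    stop("`quantal_moles` must equal `vesicle_volume * vesicle_conc` (",
         format(qv), " mol)", call. = FALSE)
  bound <- stability_max_dt(p$D_eff, p$voxel_spacing)
  if (p$dt > bound * (1 + 1e-12))
    stop("`dt` = ", p$dt, " s exceeds the explicit-Euler stability bound ",
         signif(bound, 4), " s", call. = FALSE)
  if (p$dt * (6 * p$D_eff / p$voxel_spacing^2 + p$uptake_rate) > 1 + 1e-12)
    stop("`dt` violates the non-negativity bound ",
         "dt * (6*D_eff/dx^2 + k) <= 1", call. = FALSE)
  if (!is.finite(p$uptake_block_time) && p$uptake_block_time != Inf)
    stop("`uptake_block_time` must be a time in seconds or Inf", call. = FALSE)
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  volume: %g um cube, %g um voxels, alpha = %g, tortuosity = %g\n",
              x$edge_length, x$voxel_spacing, x$alpha, x$tortuosity))
  cat(sprintf("  diffusion: D_free = %g, D_eff = %g um^2/s; uptake k = %g /s\n",
              x$D_free, x$D_eff, x$uptake_rate))
  cat(sprintf("  release: %g sites/um^3, Q = %.4g mol, p = %g, tonic %g Hz\n",
              x$site_density, x$quantal_moles, x$release_prob, x$f_tonic))
  cat(sprintf("  dt = %g s (stability bound %.4g s), seed = %d\n",
              x$dt, stability_max_dt(x$D_eff, x$voxel_spacing), x$seed))
  invisible(x)
}

#' Largest stable explicit-Euler time step
#'
#' The 7-point discrete Laplacian advanced with a first-order Euler step is
#' stable only for `dt <= spacing^2 / (6 * D_eff)`; the engine refuses larger
#' steps.
#'
#' @param D_eff Effective diffusion coefficient, um^2/s.
#' @param spacing Voxel side, um.
#' @return Maximum stable time step in seconds.
#' @examples
#' stability_max_dt(322, 1)   # ~5.18e-4 s
#' @export
stability_max_dt <- function(D_eff, spacing) {
  if (!is.numeric(D_eff) || any(D_eff <= 0) || !is.numeric(spacing) ||
      any(spacing <= 0))
    stop("`D_eff` and `spacing` must be positive", call. = FALSE)
  spacing^2 / (6 * D_eff)
}

#' Concentration jump from one quantal release event
#'
#' One vesicle's dopamine content, diluted into the extracellular water of a
#' single voxel, in nanomolar: `Q / (alpha * voxel_volume_litres)`.
#'
#' @param Q Moles per release event.
#' @param alpha Extracellular volume fraction.
#' @param voxel_volume Voxel volume in um^3 (1 um^3 = 1e-15 L).
#' @return Concentration increment in nM.
#' @examples
#' quantal_increment(1.625e-20, 0.23, 1)  # ~7.07e4 nM
#' @export
quantal_increment <- function(Q, alpha, voxel_volume) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    stop("`alpha` must be positive", call. = FALSE)
  if (any(Q <= 0) || any(voxel_volume <= 0))
    stop("`Q` and `voxel_volume` must be positive", call. = FALSE)
  # mol / (alpha * voxel_volume um^3 * 1e-15 L/um^3) -> mol/L; * 1e9 -> nM
  Q / (alpha * voxel_volume) * 1e24
}

#' Voxel-grid geometry
#'
#' @param n Voxels per axis (scalar or length-3).
#' @param spacing Voxel side, um.
#' @param boundary `"periodic"` (default) or `"reflecting"` (zero-flux).
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(64)            # the default 64 x 64 x 64 um volume
#' @export
grid_spec <- function(n = 64, spacing = 1,
                      boundary = c("periodic", "reflecting")) {
  boundary <- match.arg(boundary)
  n <- as.integer(n)
  if (length(n) == 1) n <- rep(n, 3L)
  if (length(n) != 3 || any(n < 2)) stop("`n` must give >= 2 voxels per axis",
                                         call. = FALSE)
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be positive",
                                                 call. = FALSE)
  structure(list(shape = n, spacing = spacing, boundary = boundary),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %g um spacing, %s boundary\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing, x$boundary))
  invisible(x)
}

#' Grid implied by a parameter set
#'
#' @param params A [sim_params()] object.
#' @param boundary Boundary condition passed to [grid_spec()].
#' @return A `grid_spec` with `shape * spacing = edge_length`.
#' @export
as_grid_spec <- function(params, boundary = "periodic") {
  n <- params$edge_length / params$voxel_spacing
  if (abs(n - round(n)) > 1e-9)
    stop("`edge_length` must be an integer multiple of `voxel_spacing`",
         call. = FALSE)
  grid_spec(round(n), params$voxel_spacing, boundary)
}

#' Switch off reuptake from a given time
#'
#' Returns a parameter set identical to `params` except that the reuptake
#' rate constant is set to zero from `block_time` onwards, emulating a
#' complete pharmacological block of the dopamine transporter while release
#' continues unchanged.
#'
#' @param params A [sim_params()] object.
#' @param block_time Time of the block in seconds (default 1 s).
#' @return A modified `sim_params` object.
#' @export
blocked_uptake_variant <- function(params, block_time = 1) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(block_time) || length(block_time) != 1 || block_time < 0)
    stop("`block_time` must be a non-negative time in seconds", call. = FALSE)
  params$uptake_block_time <- block_time
  validate_sim_params(params)
}

n_voxels <- function(grid) prod(grid$shape)

grid_volume <- function(grid) prod(grid$shape) * grid$spacing^3

# moles represented by 1 nM in the extracellular water of one voxel
mol_per_nM_voxel <- function(params) {
  params$alpha * params$voxel_volume * 1e-24
}
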