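#' Advance a concentration field by explicit-Euler diffusion and uptake
#'
#' One (or several) first-order Euler steps of Fickian diffusion on the
#' voxel grid (7-point discrete Laplacian, boundary condition taken from the
#' field's grid) combined with first-order reuptake:
#' `C <- C + dt * D_eff * lap(C) - dt * k * C`. The step is refused above the
#' stability bound, so concentrations stay finite and non-negative.
#'
#' @param field A [da_field()].
#' @param params A [sim_params()] object.
#' @param dt Time step, s.
#' @param n_steps Number of steps to take.
#' @param k Reuptake rate constant, 1/s; defaults to `params$uptake_rate`.
#' @return The advanced `da_field` (time incremented by `n_steps * dt`).
#' @examples
#' f <- da_field(100, grid_spec(16))
#' f1 <- diffuse_uptake_step(f, sim_params(), n_steps = 2000)  # ~1 s decay
#' @export
diffuse_uptake_step <- function(field, params = sim_params(),
                                dt = params$dt, n_steps = 1L,
                                k = params$uptake_rate) {
  g <- field_grid(field)
  check_dt(dt, params$D_eff, g$spacing, k)
  res <- .rd_run_cpp(as.numeric(field), g$shape, params$D_eff,
                     rep(k, n_steps), dt, g$spacing,
                     integer(n_steps + 1L), integer(0), 0,
                     integer(0), boundary_code(g), 0L, -1L,
                     integer(0), integer(0), 0L)
  new_da_field(res$final, g, field_time(field) + n_steps * dt)
}

check_dt <- function(dt, D_eff, spacing, k) {
  bound <- stability_max_dt(D_eff, spacing)
  if (dt > bound * (1 + 1e-12))
    stop("dt = ", dt, " s exceeds the stability bound ", signif(bound, 4),
         " s for D_eff = ", D_eff, ", spacing = ", spacing, call. = FALSE)
  if (dt * (6 * D_eff / spacing^2 + k) > 1 + 1e-12)
    stop("dt violates the non-negativity bound dt*(6*D_eff/dx^2 + k) <= 1",
         call. = FALSE)
  invisible(dt)
}

boundary_code <- function(grid) {
  if (grid$boundary == "periodic") 0L else 1L
}

#' Inject quantal release events into a field
#'
#' Each listed voxel is incremented by [quantal_increment()] once per
#' occurrence (a voxel listed twice receives two quanta).
#'
#' @param field A [da_field()].
#' @param voxels A data frame with columns `x`, `y`, `z` (1-based voxel
#'   indices), e.g. rows of a `release_sites` tibble or of
#'   [sample_release_events()] output.
#' @param params A [sim_params()] object.
#' @return The field with the quanta added.
#' @export
inject_quanta <- function(field, voxels, params = sim_params()) {
  g <- field_grid(field)
  if (nrow(voxels) == 0) return(field)
  xyz <- as.matrix(voxels[, c("x", "y", "z")])
  if (any(xyz < 1) || any(t(xyz) > g$shape))
    stop("voxel outside the grid", call. = FALSE)
  inc <- quantal_increment(params$quantal_moles, params$alpha, g$spacing^3)
  v <- unclass(field)
  for (i in seq_len(nrow(xyz)))
    v[xyz[i, 1], xyz[i, 2], xyz[i, 3]] <- v[xyz[i, 1], xyz[i, 2], xyz[i, 3]] + inc
  new_da_field(v, g, field_time(field))
}

#' Run a firing protocol
#'
#' The full simulation loop: per step, sample quantal release events for
#' every site from its cohort's firing rate, inject them, then advance the
#' field by one diffusion/uptake step. Records the volume-mean trace and a
#' mass ledger every step, snapshots at requested times, optional
#' shell-probe traces around the phasic sites, and an optional running time
#' average of the field.
#'
#' @param sites A `release_sites` tibble (defines positions and cohorts).
#' @param schedule A firing schedule from [firing_schedule()] covering
#'   `[t0, t_end]`.
#' @param params A [sim_params()] object. If `params$uptake_block_time` is
#'   finite, reuptake is switched off from that time onwards.
#' @param t_end End time, s.
#' @param snapshot_times Times (s) at which to keep full field snapshots;
#'   must be multiples of `dt` within `(t0, t_end]`.
#' @param seed Integer seed for the release sampling.
#' @param init Optional initial [da_field()] to continue from; its time
#'   becomes `t0`. Defaults to an empty field at `t0 = 0`.
#' @param release `"stochastic"` (Bernoulli quantal sampling, default) or
#'   `"expected"` (inject the expectation `rate * p * dt * Q` every step at
#'   every site — noise-free; requires a single common firing rate).
#' @param probe_radii Radii (um) of spherical shells around each phasic site
#'   (all sites if no phasic cohort) whose mean concentration is recorded
#'   over time, e.g. `c(1, 2, 5)`.
#' @param record_every Record probe traces every this many steps (default 20
#'   steps = 10 ms at the default `dt`).
#' @param average_window Length-2 times `c(from, to)` over which to
#'   accumulate the time-averaged field.
#' @return A `da_trajectory`: list with `final` and named `snapshots`
#'   (da_fields), `traces` (tibble: `time`, `mean_nM`, `injected_mol`,
#'   `uptaken_mol`), `probes` (tibble or NULL), `average` (da_field or
#'   NULL), `ledger`, plus the inputs needed to reproduce the run.
#' @examples
#' p <- sim_params()
#' sites <- place_sites(p, seed = 1)
#' traj <- run_protocol(sites, firing_schedule(t_end = 0.2), p,
#'                      t_end = 0.2, seed = 2)
#' glance(traj)
#' @export
run_protocol <- function(sites, schedule, params = sim_params(), t_end,
                         snapshot_times = NULL, seed = params$seed,
                         init = NULL,
                         release = c("stochastic", "expected"),
                         probe_radii = NULL, record_every = 20L,
                         average_window = NULL) {
  stopifnot(inherits(sites, "release_sites"))
  release <- match.arg(release)
  validate_schedule(schedule)
  g <- attr(sites, "grid")
  dt <- params$dt

  if (is.null(init)) {
    t0 <- 0
    f0 <- rep(0, n_voxels(g))
  } else {
    stopifnot(inherits(init, "da_field"))
    if (!identical(field_grid(init)$shape, g$shape))
      stop("`init` grid does not match the site grid", call. = FALSE)
    t0 <- field_time(init)
    f0 <- as.numeric(init)
  }
  n_steps <- round((t_end - t0) / dt)
  if (abs(t0 + n_steps * dt - t_end) > 1e-9)
    stop("`t_end` - t0 must be a multiple of `dt`", call. = FALSE)
  if (n_steps < 1) stop("nothing to simulate: t_end <= t0", call. = FALSE)
  check_dt(dt, params$D_eff, g$spacing, params$uptake_rate)

  # uptake switched off from uptake_block_time onwards, if requested
  step_t <- t0 + (seq_len(n_steps) - 1L) * dt
  k_steps <- rep(params$uptake_rate, n_steps)
  k_steps[step_t >= params$uptake_block_time - 1e-12] <- 0

  inc <- quantal_increment(params$quantal_moles, params$alpha, g$spacing^3)
  if (release == "stochastic") {
    events <- sample_release_events(sites, schedule, params, t_end,
                                    seed = seed, t0 = t0)
    counts <- tabulate(events$step, nbins = n_steps)
    ev_ptr <- c(0L, cumsum(counts))
    ev_vox <- voxel_linear_index0(events$x, events$y, events$z, g$shape)
    ev_inc <- inc
  } else {
    rates <- vapply(unique(as.character(droplevels(sites$cohort))),
                    function(co) rate_per_step(schedule, co, t0, dt, n_steps),
                    numeric(n_steps))
    rates <- unique(as.vector(rates))
    if (length(rates) != 1)
      stop("`release = \"expected\"` requires one common constant rate",
           call. = FALSE)
    events <- NULL
    ev_ptr <- as.integer(seq(0L, nrow(sites) * n_steps, by = nrow(sites)))
    ev_vox <- rep(voxel_linear_index0(sites$x, sites$y, sites$z, g$shape),
                  n_steps)
    ev_inc <- rates * params$release_prob * dt * inc
  }

  snap_steps <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_steps <- round((snapshot_times - t0) / dt)
    if (any(abs(t0 + snap_steps * dt - snapshot_times) > 1e-9))
      stop("`snapshot_times` must be multiples of `dt`", call. = FALSE)
    if (any(snap_steps < 1) || any(snap_steps > n_steps))
      stop("`snapshot_times` must lie in (t0, t_end]", call. = FALSE)
    ord <- order(snap_steps)
    snap_steps <- as.integer(snap_steps[ord])
    snapshot_times <- snapshot_times[ord]
  }

  probe_ptr <- integer(0); probe_vox <- integer(0); probe_meta <- NULL
  if (!is.null(probe_radii)) {
    ph <- sites[sites$cohort == "phasic", ]
    if (nrow(ph) == 0) ph <- sites
    shells <- shell_voxels(ph, probe_radii, g)
    probe_meta <- shells$meta
    probe_ptr <- shells$ptr
    probe_vox <- shells$voxel
  }

  avg_from <- 0L; avg_to <- -1L
  if (!is.null(average_window)) {
    avg_from <- as.integer(max(1, round((average_window[1] - t0) / dt)))
    avg_to <- as.integer(round((average_window[2] - t0) / dt))
  }

  res <- .rd_run_cpp(f0, g$shape, params$D_eff, k_steps, dt, g$spacing,
                     ev_ptr, ev_vox, ev_inc, snap_steps, boundary_code(g),
                     avg_from, avg_to, probe_ptr, probe_vox,
                     as.integer(record_every))

  mol <- mol_per_nM_voxel(params)
  traces <- tibble::tibble(
    step = seq_len(n_steps),
    time = t0 + seq_len(n_steps) * dt,
    mean_nM = res$mean_nM,
    injected_mol = res$injected_nM_voxel * mol,
    uptaken_mol = res$uptaken_nM_voxel * mol)

  snapshots <- list()
  if (length(snap_steps) > 0) {
    snapshots <- lapply(seq_along(snap_steps), function(i)
      new_da_field(res$snapshots[[i]], g, t0 + snap_steps[i] * dt))
    names(snapshots) <- vapply(snapshot_times, function(t)
      format(t, trim = TRUE), character(1))
  }

  probes <- NULL
  if (!is.null(probe_meta) && length(res$probe_steps) > 0) {
    m <- res$probe_means
    probes <- tidyr::expand_grid(
      step = res$probe_steps,
      probe = seq_len(nrow(probe_meta)))
    probes <- dplyr::mutate(probes,
      time = t0 + .data$step * dt,
      site = probe_meta$site[.data$probe],
      radius_um = probe_meta$radius[.data$probe],
      conc_nM = as.vector(t(m)))
    probes <- probes[, c("time", "site", "radius_um", "conc_nM")]
  }

  average <- NULL
  if (!is.null(res$average))
    average <- new_da_field(res$average, g, NA_real_)

  initial_nMvox <- sum(f0)
  final_nMvox <- sum(res$final)
  inj_nMvox <- sum(res$injected_nM_voxel)
  upt_nMvox <- sum(res$uptaken_nM_voxel)
  ledger <- list(
    initial_mol = initial_nMvox * mol, injected_mol = inj_nMvox * mol,
    uptaken_mol = upt_nMvox * mol, final_mol = final_nMvox * mol,
    rel_error = (final_nMvox - (initial_nMvox + inj_nMvox - upt_nMvox)) /
      max(final_nMvox, inj_nMvox, .Machine$double.eps))

  structure(list(
    final = new_da_field(res$final, g, t_end),
    snapshots = snapshots, traces = traces, probes = probes,
    average = average, ledger = ledger, events = events,
    sites = sites, schedule = schedule, params = params,
    grid = g, seed = seed, t0 = t0, t_end = t_end),
    class = "da_trajectory")
}

#' @export
print.da_trajectory <- function(x, ...) {
  cat(sprintf("<da_trajectory> t = [%g, %g] s, %d sites, seed %s\n",
              x$t0, x$t_end, nrow(x$sites), format(x$seed)))
  cat(sprintf("  final volume mean %.3g nM; %d snapshots; ledger error %.2e\n",
              mean(as.numeric(x$final)), length(x$snapshots),
              x$ledger$rel_error))
  invisible(x)
}

#' Mass ledger of a trajectory
#'
#' With periodic (or reflecting) boundaries the scheme conserves mass
#' exactly: total moles at the end equal initial + injected - uptaken. The
#' relative closure error should be at rounding level (<= 1e-6 by a wide
#' margin).
#'
#' @param traj A `da_trajectory`.
#' @return A one-row tibble with the ledger entries in mol and the relative
#'   closure error.
#' @export
mass_balance <- function(traj) {
  stopifnot(inherits(traj, "da_trajectory"))
  tibble::as_tibble(traj$ledger)
}
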