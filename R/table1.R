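#' Protocol presets
#'
#' The canonical simulation conditions. All runs start with 4 s of tonic
#' firing at 5.6 Hz (release probability 0.5) to reach steady state; the
#' presets then differ in what follows:
#'
#' * `"A"` — phasic 15 Hz for 150 ms, then a 150-ms pause (0 Hz).
#' * `"B"` — phasic 26 Hz for 150 ms.
#' * `"C"` — pause (0 Hz) for 150 ms.
#' * `"D"` — Parkinsonian-like depletion: site density 0.61e-4 /um^3
#'   (~70% fewer sites), phasic 15 Hz for 150 ms then a 150-ms pause.
#' * `"E"` — tonic only, with reuptake completely blocked from t = 1 s.
#'
#' @param name Preset letter.
#' @param fraction Fraction of sites firing phasically (ignored for `"E"`).
#' @param t_end End of the simulation, s; defaults to the end of the
#'   perturbation (3.5 s for `"E"`).
#' @return A `da_protocol` list: `name`, `site_density`, `phasic_fraction`,
#'   `phasic_rate`, `phasic_duration`, `pause_duration`, `uptake_blocked`,
#'   `block_time`, `t_tonic`, `t_end`.
#' @examples
#' da_protocol("A", fraction = 0.5)
#' @export
da_protocol <- function(name = c("A", "B", "C", "D", "E"), fraction = 0.5,
                        t_end = NULL) {
  name <- match.arg(name)
  base <- list(name = name, site_density = 2e-4, phasic_fraction = fraction,
               phasic_rate = 0, phasic_duration = 0, pause_duration = 0,
               uptake_blocked = FALSE, block_time = Inf, t_tonic = 4)
  spec <- switch(name,
    A = list(phasic_rate = 15, phasic_duration = 0.15, pause_duration = 0.15),
    B = list(phasic_rate = 26, phasic_duration = 0.15),
    C = list(phasic_rate = 0, phasic_duration = 0.15),
    D = list(site_density = 0.61e-4, phasic_rate = 15,
             phasic_duration = 0.15, pause_duration = 0.15),
    E = list(uptake_blocked = TRUE, block_time = 1, t_tonic = 3.5,
             phasic_fraction = 0))
  base[names(spec)] <- spec
  base$t_end <- t_end %||%
    (if (name == "E") 3.5 else
       base$t_tonic + base$phasic_duration + base$pause_duration)
  structure(base, class = "da_protocol")
}

#' @export
print.da_protocol <- function(x, ...) {
  cat(sprintf("<da_protocol %s> density %g /um^3, fraction %g, %g Hz x %g ms",
              x$name, x$site_density, x$phasic_fraction, x$phasic_rate,
              1000 * x$phasic_duration))
  if (x$pause_duration > 0) cat(sprintf(" + %g ms pause",
                                        1000 * x$pause_duration))
  if (x$uptake_blocked) cat(sprintf("; uptake blocked at t = %g s",
                                    x$block_time))
  cat(sprintf("; t_end %g s\n", x$t_end))
  invisible(x)
}

#' Simulate one protocol preset end to end
#'
#' Convenience wrapper: places the sites, assigns the phasic cohort, builds
#' the firing schedule and runs the engine, with snapshots at steady state
#' (t = 4 s) and at the end of the phasic window (t = 4.15 s) where
#' applicable.
#'
#' @param protocol A [da_protocol()] (or preset letter).
#' @param params A [sim_params()] object.
#' @param seed Integer seed; site placement, cohort draw and release
#'   sampling use seeds derived from it.
#' @param ... Passed on to [run_protocol()] (e.g. `probe_radii`).
#' @return A `da_trajectory`.
#' @examples
#' \donttest{
#' traj <- simulate_protocol(da_protocol("B", 0.5), seed = 1)
#' summary(difference_map(traj$snapshots[["4.15"]], traj$snapshots[["4"]]))
#' }
#' @export
simulate_protocol <- function(protocol = da_protocol("A"),
                              params = sim_params(), seed = params$seed,
                              ...) {
  if (is.character(protocol)) protocol <- da_protocol(protocol)
  stopifnot(inherits(protocol, "da_protocol"))
  params$site_density <- protocol$site_density
  if (protocol$uptake_blocked)
    params <- blocked_uptake_variant(params, protocol$block_time)
  sites <- place_sites(params, seed = seed)
  if (protocol$phasic_fraction > 0 && protocol$phasic_duration > 0)
    sites <- assign_phasic_cohort(sites, protocol$phasic_fraction,
                                  seed = seed + 1L)
  sched <- firing_schedule(
    t_end = protocol$t_end, f_tonic = params$f_tonic,
    t_tonic = protocol$t_tonic, phasic_rate = protocol$phasic_rate,
    phasic_duration = protocol$phasic_duration,
    pause_duration = protocol$pause_duration, pause_rate = params$pause_rate)
  snaps <- unique(pmin(c(protocol$t_tonic,
                         protocol$t_tonic + protocol$phasic_duration),
                       protocol$t_end))
  snaps <- snaps[snaps > 0]
  run_protocol(sites, sched, params, t_end = protocol$t_end,
               snapshot_times = snaps, seed = seed + 2L, ...)
}

# derived sub-seeds; kept well below 2^31
sub_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 1009 + i * 131071 + j * 7919) %% 2147483629)
}

#' Per-seed simulation of the protocol summary grid
#'
#' Runs the tonic baseline once per seed and branches into each phasic
#' condition from the common steady-state snapshot (the branches are
#' conditionally independent continuations), at normal and depleted site
#' density. This is the machinery behind [build_table1()].
#'
#' Absolute difference maps compare the two instantaneous snapshots at
#' t = 4 s and t = 4.15 s; relative difference maps express that change as a
#' percentage of the steady-state level, estimated per voxel as the time
#' average of the tonic field over the last second of the tonic epoch.
#'
#' @param params A [sim_params()] object.
#' @param n_seeds Number of independent replicate simulations.
#' @param seed Base seed; replicate r uses seeds derived from `seed` and `r`.
#' @param rates Phasic rates (Hz) for the normal-density grid.
#' @param fractions Phasic fractions for both grids.
#' @param mptp_density Depleted site density (NULL to skip); probed at 15 Hz.
#' @param rel_threshold Baseline (nM) below which relative changes are
#'   excluded (see [difference_map()]).
#' @return A long tibble with one row per (seed, density, condition,
#'   fraction): volume statistics of the post-phasic field and of the
#'   absolute and relative difference maps.
#' @export
simulate_table1 <- function(params = sim_params(), n_seeds = 10,
                            seed = params$seed, rates = c(15, 26, 0),
                            fractions = c(.1, .25, .5),
                            mptp_density = 0.61e-4, rel_threshold = 0.01) {
  densities <- c(normal = params$site_density)
  if (!is.null(mptp_density)) densities <- c(densities, mptp = mptp_density)
  t_tonic <- 4; t_phasic <- 0.15
  out <- list()
  for (r in seq_len(n_seeds)) {
    for (d in seq_along(densities)) {
      p <- params
      p$site_density <- densities[[d]]
      dens <- names(densities)[d]
      drates <- if (dens == "mptp") rates[rates == 15] else rates
      sites <- place_sites(p, seed = sub_seed(seed, r, d))
      tonic <- run_protocol(sites, firing_schedule(t_end = t_tonic,
                                                   f_tonic = p$f_tonic),
                            p, t_end = t_tonic, seed = sub_seed(seed, r, d + 10),
                            average_window = c(t_tonic - 1, t_tonic))
      pre <- tonic$final
      baseline <- tonic$average
      vs <- volume_stats(pre)
      out[[length(out) + 1]] <- tibble::tibble(
        seed_rep = r, density = dens, condition = "tonic",
        fraction = NA_real_, value_mean = vs$mean, value_sd = vs$sd,
        value_min = vs$min, value_max = vs$max,
        abs_mean = NA_real_, abs_sd = NA_real_, abs_min = NA_real_,
        abs_max = NA_real_, rel_mean = NA_real_, rel_sd = NA_real_,
        rel_min = NA_real_, rel_max = NA_real_)
      cond_grid <- expand.grid(rate = drates, fraction = fractions)
      for (i in seq_len(nrow(cond_grid))) {
        co <- assign_phasic_cohort(sites, cond_grid$fraction[i],
                                   seed = sub_seed(seed, r, d + 20 + i))
        sched <- firing_schedule(t_end = t_tonic + t_phasic,
                                 f_tonic = p$f_tonic, t_tonic = t_tonic,
                                 phasic_rate = cond_grid$rate[i],
                                 phasic_duration = t_phasic)
        br <- run_protocol(co, sched, p, t_end = t_tonic + t_phasic,
                           seed = sub_seed(seed, r, d + 40 + i), init = pre)
        post <- br$final
        dm <- difference_map(post, pre, baseline = baseline,
                             rel_threshold = rel_threshold)
        sv <- volume_stats(post)
        sm <- summary(dm)
        out[[length(out) + 1]] <- tibble::tibble(
          seed_rep = r, density = dens,
          condition = paste0(cond_grid$rate[i], " Hz"),
          fraction = cond_grid$fraction[i],
          value_mean = sv$mean, value_sd = sv$sd, value_min = sv$min,
          value_max = sv$max,
          abs_mean = sm$mean[1], abs_sd = sm$sd[1], abs_min = sm$min[1],
          abs_max = sm$max[1],
          rel_mean = sm$mean[2], rel_sd = sm$sd[2], rel_min = sm$min[2],
          rel_max = sm$max[2])
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Summary table of the simulated protocol grid
#'
#' Aggregates [simulate_table1()] across seeds into one row per condition:
#' the across-seed mean of each per-seed statistic (mean/sd/min/max of the
#' concentration values, of the absolute change, and of the relative change
#' in percent). The per-seed results are attached as
#' `attr(, "per_seed")` so Monte-Carlo spread (standard errors) can be
#' computed.
#'
#' @inheritParams simulate_table1
#' @param ... Passed to [simulate_table1()].
#' @return A tibble of class `da_table1`, one row per (density, condition,
#'   fraction).
#' @examples
#' \donttest{
#' tab <- build_table1(n_seeds = 2, fractions = 0.5)
#' }
#' @export
build_table1 <- function(params = sim_params(), n_seeds = 10,
                         seed = params$seed, ...) {
  per_seed <- simulate_table1(params, n_seeds = n_seeds, seed = seed, ...)
  agg <- dplyr::summarise(
    dplyr::group_by(per_seed, .data$density, .data$condition, .data$fraction),
    dplyr::across(dplyr::all_of(c("value_mean", "value_sd", "value_min",
                                  "value_max", "abs_mean", "abs_sd",
                                  "abs_min", "abs_max", "rel_mean", "rel_sd",
                                  "rel_min", "rel_max")),
                  ~ mean(.x)),
    n_seeds = dplyr::n(), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$density,
                        match(.data$condition,
                              c("tonic", "15 Hz", "26 Hz", "0 Hz")),
                        .data$fraction)
  attr(agg, "per_seed") <- per_seed
  class(agg) <- c("da_table1", class(agg))
  agg
}

#' Fit the post-block accumulation slope
#'
#' Runs the blocked-reuptake protocol (tonic release throughout, reuptake
#' switched off at `block_time`) and fits a straight line to the post-block
#' volume-mean trace. With lossless boundaries the accumulation is linear at
#' the mean-field rate `rho * f * p * Q / alpha` (~39 nM/s at default
#' parameters), reaching micromolar levels within tens of seconds.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param block_time Time of the block, s.
#' @param t_end End of the run, s.
#' @param fit_from Start of the fit window, s (allows a settling margin
#'   after the block).
#' @return A one-row tibble: `slope_nM_per_s`, `r_squared`, the projected
#'   time from the tonic steady state to 1 uM, and the seed.
#' @export
blocked_uptake_slope_fit <- function(params = sim_params(),
                                     seed = params$seed, block_time = 1,
                                     t_end = 3.5, fit_from = 1.5) {
  p <- blocked_uptake_variant(params, block_time)
  sites <- place_sites(p, seed = seed)
  traj <- run_protocol(sites, firing_schedule(t_end = t_end,
                                              f_tonic = p$f_tonic),
                       p, t_end = t_end, seed = seed + 1L)
  tr <- traj$traces[traj$traces$time >= fit_from, ]
  fit <- stats::lm(mean_nM ~ time, data = tr)
  slope <- unname(stats::coef(fit)[2])
  css <- mf_steady_state(params,
                         site_density = nrow(sites) / grid_volume(traj$grid))
  tibble::tibble(slope_nM_per_s = slope,
                 r_squared = summary(fit)$r.squared,
                 t_to_1uM_s = (1000 - css) / slope,
                 seed = seed)
}

#' Recompute the headline results of the model
#'
#' Runs the full study from scratch — tonic steady state, the phasic
#' protocol grid, the depleted (Parkinsonian-like) condition and the
#' blocked-reuptake ramp — and reports the headline quantities, each
#' averaged over `n_seeds` independent replicates where stochastic:
#'
#' * tonic steady-state volume mean (nM) and its mean-field prediction;
#' * mean absolute change after 150 ms of 15/26/0 Hz at 50% synchrony and
#'   15 Hz at 25% (nM);
#' * depleted-density steady state (nM) and its 15 Hz / 50% change;
#' * mean relative change after 15 Hz / 50% (percent);
#' * blocked-reuptake accumulation slope (nM/s) and the projected time to
#'   1 uM.
#'
#' @param seed Base seed.
#' @param n_seeds Replicates for the stochastic quantities.
#' @param params A [sim_params()] object.
#' @return A tibble: `metric`, `value`, `n`, `units`.
#' @export
reproduce_headline_results <- function(seed = 1, n_seeds = 10,
                                       params = sim_params()) {
  per_seed <- simulate_table1(params, n_seeds = n_seeds, seed = seed,
                              rates = c(15, 26, 0),
                              fractions = c(0.1, 0.25, 0.5))
  cell <- function(dens, cond, frac) {
    r <- per_seed[per_seed$density == dens & per_seed$condition == cond &
                    (is.na(frac) | per_seed$fraction == frac), ]
    r
  }
  m <- function(x) mean(x)
  tonic <- cell("normal", "tonic", NA)
  mtonic <- cell("mptp", "tonic", NA)
  vol <- grid_volume(as_grid_spec(params))
  rho52 <- round(params$site_density * vol) / vol
  rho16 <- round(0.61e-4 * vol) / vol
  slopes <- purrr::map_dfr(seq_len(n_seeds), function(r)
    blocked_uptake_slope_fit(params, seed = sub_seed(seed, r, 99L)))

  out <- tibble::tibble(
    metric = c("tonic_steady_state_sim", "tonic_steady_state_oracle",
               "abs_diff_15Hz_50", "abs_diff_26Hz_50", "abs_diff_0Hz_50",
               "abs_diff_15Hz_25", "mptp_steady_state_oracle",
               "mptp_steady_state_sim", "mptp_abs_diff_15Hz_50",
               "rel_diff_15Hz_50_pct", "blocked_slope_sim",
               "blocked_slope_oracle", "blocked_t_to_1uM_s"),
    value = c(m(tonic$value_mean),
              mf_steady_state(params, site_density = rho52),
              m(cell("normal", "15 Hz", 0.5)$abs_mean),
              m(cell("normal", "26 Hz", 0.5)$abs_mean),
              m(cell("normal", "0 Hz", 0.5)$abs_mean),
              m(cell("normal", "15 Hz", 0.25)$abs_mean),
              mf_steady_state(params, site_density = rho16),
              m(mtonic$value_mean),
              m(cell("mptp", "15 Hz", 0.5)$abs_mean),
              m(cell("normal", "15 Hz", 0.5)$rel_mean),
              m(slopes$slope_nM_per_s),
              mf_blocked_slope(params, site_density = rho52),
              m(slopes$t_to_1uM_s)),
    n = c(n_seeds, 1, rep(n_seeds, 4), 1, rep(n_seeds, 3), n_seeds, 1,
          n_seeds),
    units = c("nM", "nM", rep("nM", 4), "nM", "nM", "nM", "%", "nM/s",
              "nM/s", "s"))
  attr(out, "per_seed") <- per_seed
  attr(out, "slopes") <- slopes
  out
}
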