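#' Place release sites uniformly at random on the voxel grid
#'
#' Each potential release site occupies exactly one voxel (dopaminergic
#' boutons are ~0.9 um across, i.e. one 1-um voxel). The number of sites is
#' `round(density * volume)`; with the default density of 2e-4 /um^3 a 64-um
#' cube holds 52 sites. Positions are drawn without replacement, so sites are
#' distinct; the draw is deterministic given `seed`.
#'
#' @param params A [sim_params()] object (supplies the default density and
#'   seed).
#' @param grid A [grid_spec()]; defaults to the grid implied by `params`.
#' @param density Sites per um^3 of tissue.
#' @param seed Integer seed.
#' @return A tibble of class `release_sites` with columns `site`, `x`, `y`,
#'   `z` (1-based voxel indices) and `cohort` (all `"tonic"` until
#'   [assign_phasic_cohort()] is applied). The grid, density and seed are
#'   attached as attributes.
#' @examples
#' sites <- place_sites(sim_params(), seed = 1)
#' nrow(sites)                       # 52
#' nearest_neighbour_stats(sites)    # mean NN distance ~9.5 um
#' @export
place_sites <- function(params = sim_params(), grid = as_grid_spec(params),
                        density = params$site_density, seed = params$seed) {
  stopifnot(inherits(grid, "grid_spec"))
  vol <- grid_volume(grid)
  n_sites <- round(density * vol)
  if (n_sites < 1)
    stop("`density` * volume gives fewer than one site", call. = FALSE)
  nv <- n_voxels(grid)
  if (n_sites > nv)
    stop("`density` too high: more sites than voxels", call. = FALSE)
  lin <- withr::with_seed(seed, sample.int(nv, n_sites, replace = FALSE))
  sh <- grid$shape
  lin0 <- lin - 1L
  out <- tibble::tibble(
    site = seq_len(n_sites),
    x = lin0 %% sh[1] + 1L,
    y = (lin0 %/% sh[1]) %% sh[2] + 1L,
    z = lin0 %/% (sh[1] * sh[2]) + 1L,
    cohort = factor(rep("tonic", n_sites), levels = c("tonic", "phasic")))
  new_release_sites(out, grid, density, seed)
}

new_release_sites <- function(df, grid, density, seed) {
  structure(df, grid = grid, density = density, seed = seed,
            class = c("release_sites", class(tibble::tibble())))
}

#' Label a random subset of sites as the phasic cohort
#'
#' Phasic firing after an unexpected (or omitted) reward is carried by a
#' synchronous subset of release sites; the remainder stay tonic. The cohort
#' size is `round(fraction * n)` and the subset is drawn uniformly at random,
#' deterministically given `seed`.
#'
#' @param sites A `release_sites` tibble from [place_sites()].
#' @param fraction Fraction of sites in the phasic cohort (0-1).
#' @param seed Integer seed.
#' @return The sites tibble with its `cohort` column updated.
#' @examples
#' place_sites(seed = 1) |> assign_phasic_cohort(0.5, seed = 2)
#' @export
assign_phasic_cohort <- function(sites, fraction, seed = 1L) {
  stopifnot(inherits(sites, "release_sites"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  n <- nrow(sites)
  n_ph <- round(fraction * n)
  cohort <- rep("tonic", n)
  if (n_ph > 0) {
    pick <- withr::with_seed(seed, sample.int(n, n_ph))
    cohort[pick] <- "phasic"
  }
  sites$cohort <- factor(cohort, levels = c("tonic", "phasic"))
  attr(sites, "phasic_fraction") <- fraction
  attr(sites, "cohort_seed") <- seed
  sites
}

#' Nearest-neighbour distance statistics of a site set
#'
#' Exact all-pairs nearest-neighbour distances between site centres
#' (Euclidean, in um). For a homogeneous random placement at density rho the
#' expected mean is `0.554 * rho^(-1/3)`, which is 9.5 um at the default
#' cortical density — the sparseness that drives the local heterogeneity of
#' the dopamine landscape.
#'
#' @param sites A `release_sites` tibble with at least two sites.
#' @param periodic Use minimum-image (wrap-around) distances. Default `FALSE`,
#'   matching how nearest neighbours are measured in a bounded tissue block.
#' @return A tibble with `n`, `mean_um`, `sd_um`, `min_um`, `max_um`.
#' @export
nearest_neighbour_stats <- function(sites, periodic = FALSE) {
  stopifnot(inherits(sites, "release_sites"))
  if (nrow(sites) < 2)
    stop("need at least two sites for nearest-neighbour distances",
         call. = FALSE)
  g <- attr(sites, "grid")
  xyz <- as.matrix(sites[, c("x", "y", "z")]) * g$spacing
  d <- as.matrix(stats::dist(xyz))
  if (periodic) {
    ext <- g$shape * g$spacing
    d2 <- matrix(0, nrow(xyz), nrow(xyz))
    for (a in 1:3) {
      dd <- abs(outer(xyz[, a], xyz[, a], "-"))
      dd <- pmin(dd, ext[a] - dd)
      d2 <- d2 + dd^2
    }
    d <- sqrt(d2)
  }
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  tibble::tibble(n = nrow(xyz), mean_um = mean(nn), sd_um = stats::sd(nn),
                 min_um = min(nn), max_um = max(nn))
}

#' Piecewise-constant firing schedule
#'
#' A schedule assigns each cohort a contiguous sequence of
#' (t_start, t_end, rate) segments. Helper for building the protocol
#' schedules: all simulations begin with tonic firing at `f_tonic`; the
#' phasic cohort then switches to `phasic_rate` for `phasic_duration`,
#' optionally pauses at `pause_rate`, and returns to tonic.
#'
#' @param t_end End of the schedule, s.
#' @param f_tonic Tonic rate, Hz.
#' @param t_tonic Duration of the initial tonic epoch, s.
#' @param phasic_rate Phasic cohort rate during the burst window, Hz.
#' @param phasic_duration Burst duration, s (0 for none).
#' @param pause_duration Pause duration after the burst, s.
#' @param pause_rate Rate during the pause, Hz.
#' @return A tibble with columns `cohort`, `t_start`, `t_end`, `rate`.
#' @examples
#' firing_schedule(t_end = 4.3, phasic_rate = 15,
#'                 phasic_duration = 0.15, pause_duration = 0.15)
#' @export
firing_schedule <- function(t_end, f_tonic = 5.6, t_tonic = 4,
                            phasic_rate = f_tonic, phasic_duration = 0,
                            pause_duration = 0, pause_rate = 0) {
  stopifnot(t_end > 0, t_tonic >= 0, phasic_duration >= 0,
            pause_duration >= 0, f_tonic >= 0, phasic_rate >= 0,
            pause_rate >= 0)
  seg <- list(tibble::tibble(cohort = "tonic", t_start = 0, t_end = t_end,
                             rate = f_tonic))
  if (phasic_duration > 0 || pause_duration > 0) {
    br <- c(0, t_tonic, t_tonic + phasic_duration,
            t_tonic + phasic_duration + pause_duration, t_end)
    rates <- c(f_tonic, phasic_rate, pause_rate, f_tonic)
    keep <- which(diff(br) > 1e-12)
    seg <- c(seg, list(tibble::tibble(cohort = "phasic",
                                      t_start = br[keep],
                                      t_end = br[keep + 1],
                                      rate = rates[keep])))
  }
  out <- dplyr::bind_rows(seg)
  validate_schedule(out)
  out
}

validate_schedule <- function(schedule) {
  stopifnot(all(c("cohort", "t_start", "t_end", "rate") %in% names(schedule)))
  if (any(schedule$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  for (co in unique(schedule$cohort)) {
    s <- schedule[schedule$cohort == co, ]
    s <- s[order(s$t_start), ]
    if (any(s$t_end <= s$t_start))
      stop("schedule segments must have positive duration", call. = FALSE)
    if (nrow(s) > 1 && any(abs(s$t_start[-1] - s$t_end[-nrow(s)]) > 1e-9))
      stop("schedule segments must be contiguous and non-overlapping",
           call. = FALSE)
  }
  invisible(schedule)
}

# firing rate of one cohort at the start of each step
rate_per_step <- function(schedule, cohort, t0, dt, n_steps) {
  s <- schedule[schedule$cohort == cohort, ]
  if (nrow(s) == 0)
    stop("schedule has no segments for cohort '", cohort, "'", call. = FALSE)
  s <- s[order(s$t_start), ]
  t <- t0 + (seq_len(n_steps) - 1L) * dt
  idx <- findInterval(t + 1e-12, s$t_start)
  if (any(idx == 0) || any(t > s$t_end[pmin(idx, nrow(s))] + 1e-9))
    stop("schedule does not cover the simulated interval for cohort '",
         cohort, "'", call. = FALSE)
  s$rate[idx]
}

#' Sample quantal release events
#'
#' Each site releases independently in each time step as a Bernoulli trial
#' with probability `rate(t) * release_prob * dt`, so the expected event
#' count per site over an interval at constant rate is
#' `rate * release_prob * duration`.
#'
#' @param sites A `release_sites` tibble.
#' @param schedule A firing schedule covering `[t0, t_end]` for every cohort
#'   present in `sites`.
#' @param params A [sim_params()] object (supplies `release_prob` and `dt`).
#' @param t_end End time, s.
#' @param seed Integer seed.
#' @param t0 Start time, s.
#' @return A tibble with one row per release event: `step`, `time`, `site`,
#'   `x`, `y`, `z`.
#' @examples
#' sites <- place_sites(seed = 1)
#' sched <- firing_schedule(t_end = 1)
#' ev <- sample_release_events(sites, sched, sim_params(), t_end = 1, seed = 2)
#' @export
sample_release_events <- function(sites, schedule, params = sim_params(),
                                  t_end, seed = params$seed, t0 = 0) {
  stopifnot(inherits(sites, "release_sites"))
  validate_schedule(schedule)
  dt <- params$dt
  n_steps <- round((t_end - t0) / dt)
  if (n_steps < 1) stop("`t_end` must exceed `t0` by at least one step",
                        call. = FALSE)
  p <- params$release_prob
  cohorts <- levels(droplevels(sites$cohort))
  withr::with_seed(seed, {
    pieces <- lapply(cohorts, function(co) {
      members <- which(sites$cohort == co)
      if (length(members) == 0) return(NULL)
      rates <- rate_per_step(schedule, co, t0, dt, n_steps)
      prob <- rates * p * dt
      if (any(prob >= 1))
        stop("rate * release_prob * dt >= 1: `dt` too large for this rate",
             call. = FALSE)
      hit <- which(stats::runif(length(members) * n_steps) <
                     rep(prob, each = length(members)))
      if (length(hit) == 0) return(NULL)
      step <- (hit - 1L) %/% length(members) + 1L
      site <- members[(hit - 1L) %% length(members) + 1L]
      tibble::tibble(step = step, site = site)
    })
    ev <- dplyr::bind_rows(pieces)
  })
  if (nrow(ev) == 0)
    return(tibble::tibble(step = integer(), time = numeric(),
                          site = integer(), x = integer(), y = integer(),
                          z = integer()))
  ev <- ev[order(ev$step, ev$site), ]
  tibble::tibble(step = ev$step, time = t0 + ev$step * dt, site = ev$site,
                 x = sites$x[ev$site], y = sites$y[ev$site],
                 z = sites$z[ev$site])
}
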