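#' Volume statistics of a concentration field
#'
#' Mean, standard deviation, minimum and maximum over all voxels (1-um^3
#' resolution by default).
#'
#' @param field A [da_field()].
#' @return A one-row tibble: `time`, `n_voxels`, `mean`, `sd`, `min`, `max`
#'   (nM).
#' @export
volume_stats <- function(field) {
  stopifnot(inherits(field, "da_field"))
  v <- as.numeric(field)
  tibble::tibble(time = field_time(field), n_voxels = length(v),
                 mean = mean(v), sd = stats::sd(v), min = min(v),
                 max = max(v))
}

#' Absolute and relative per-voxel difference maps
#'
#' The spatial fingerprint of a phasic episode: `abs = post - pre` (nM) and
#' `rel = 100 * (post - pre) / baseline` (%) per voxel. By default the
#' baseline is `pre` itself; for the protocol statistics the package passes
#' the time-averaged steady-state field instead, so that the relative change
#' is expressed as a percentage of the steady-state level rather than of one
#' stochastic snapshot (an instantaneous denominator is noisy near release
#' sites and biases the volume-mean relative change upwards). Voxels whose
#' baseline is below `rel_threshold` are flagged undefined (`NA`) in the
#' relative map and excluded from its summary statistics.
#'
#' @param post,pre Two [da_field()]s on the same grid (after/before).
#' @param baseline Reference field for the relative map (defaults to `pre`);
#'   typically the tonic steady-state time average (see the
#'   `average_window` argument of [run_protocol()]).
#' @param rel_threshold Baseline concentration (nM) below which the relative
#'   change is undefined.
#' @return A `da_diff` object: list with `abs` (da_field-like array, nM),
#'   `rel` (array, %, possibly with NAs), the threshold, and the snapshot
#'   times.
#' @examples
#' f <- da_field(10, grid_spec(8)); g <- da_field(12, grid_spec(8))
#' summary(difference_map(g, f))
#' @export
difference_map <- function(post, pre, baseline = pre, rel_threshold = 0.01) {
  stopifnot(inherits(post, "da_field"), inherits(pre, "da_field"))
  g <- field_grid(pre)
  if (!identical(g$shape, field_grid(post)$shape))
    stop("`post` and `pre` must share a grid", call. = FALSE)
  if (!identical(g$shape, dim(unclass(baseline))))
    stop("`baseline` must share the grid of `pre`", call. = FALSE)
  a <- unclass(post) - unclass(pre)
  bl <- unclass(baseline)
  r <- 100 * a / bl
  r[bl < rel_threshold] <- NA_real_
  structure(list(abs = structure(a, grid = g), rel = structure(r, grid = g),
                 rel_threshold = rel_threshold,
                 t_pre = field_time(pre), t_post = field_time(post)),
            class = "da_diff")
}

#' @export
summary.da_diff <- function(object, ...) {
  stat_row <- function(v, map) {
    v <- v[is.finite(v)]
    tibble::tibble(map = map, mean = mean(v), sd = stats::sd(v),
                   min = min(v), max = max(v))
  }
  dplyr::bind_rows(stat_row(as.numeric(object$abs), "abs_nM"),
                   stat_row(as.numeric(object$rel), "rel_pct"))
}

#' @export
print.da_diff <- function(x, ...) {
  cat(sprintf("<da_diff> t = %g s vs %g s\n", x$t_post, x$t_pre))
  print(summary(x))
  invisible(x)
}

#' Sample a field along a straight line
#'
#' Nearest-voxel concentrations at unit voxel steps along an axis-aligned or
#' diagonal direction, as plotted along "sample lines" through the volume.
#'
#' @param field A [da_field()].
#' @param start Length-3 integer voxel index (1-based) where the line starts.
#' @param direction Length-3 step vector with entries in -1/0/1, e.g.
#'   `c(1, 0, 0)` or `c(1, 1, 0)`.
#' @param n_steps Number of steps; defaults to as many as fit in the grid.
#' @param wrap Wrap around the periodic boundary instead of stopping at the
#'   edge (default `FALSE`; out-of-grid without wrapping is an error).
#' @return A tibble: `step`, `distance_um`, `x`, `y`, `z`, `conc_nM`.
#' @export
line_sample <- function(field, start, direction, n_steps = NULL,
                        wrap = FALSE) {
  stopifnot(inherits(field, "da_field"))
  g <- field_grid(field)
  start <- as.integer(start); direction <- as.integer(direction)
  if (length(start) != 3 || any(start < 1) || any(start > g$shape))
    stop("`start` must be a voxel inside the grid", call. = FALSE)
  if (length(direction) != 3 || all(direction == 0) ||
      any(abs(direction) > 1))
    stop("`direction` must be a nonzero vector of -1/0/1 steps", call. = FALSE)
  if (is.null(n_steps)) {
    room <- ifelse(direction > 0, g$shape - start,
                   ifelse(direction < 0, start - 1L, Inf))
    n_steps <- if (wrap) max(g$shape) - 1L else min(room)
  }
  k <- 0:n_steps
  xyz <- outer(k, direction) + rep(start, each = length(k))
  if (wrap) {
    xyz <- sweep(xyz - 1L, 2, g$shape, "%%") + 1L
  } else if (any(xyz < 1) || any(sweep(xyz, 2, g$shape, ">"))) {
    stop("line leaves the grid; use `wrap = TRUE` on a periodic grid",
         call. = FALSE)
  }
  v <- unclass(field)[cbind(xyz[, 1], xyz[, 2], xyz[, 3])]
  tibble::tibble(step = k,
                 distance_um = k * sqrt(sum(direction^2)) * g$spacing,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], conc_nM = v)
}

# voxels whose centre lies in the shell [r - 0.5, r + 0.5) * spacing around
# each site; minimum-image distances on a periodic grid. Returns CSR lists
# plus a meta tibble (site, radius).
shell_voxels <- function(sites, radii, grid) {
  sh <- grid$shape
  periodic <- grid$boundary == "periodic"
  rmax <- max(radii) + 0.5
  off <- seq.int(-ceiling(rmax), ceiling(rmax))
  offs <- expand.grid(dx = off, dy = off, dz = off)
  d <- sqrt(offs$dx^2 + offs$dy^2 + offs$dz^2)
  meta <- list(); vox <- list(); clipped <- FALSE
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    for (r in radii) {
      sel <- d >= r - 0.5 & d < r + 0.5
      x <- sites$x[i] + offs$dx[sel]
      y <- sites$y[i] + offs$dy[sel]
      z <- sites$z[i] + offs$dz[sel]
      if (periodic) {
        x <- (x - 1L) %% sh[1] + 1L
        y <- (y - 1L) %% sh[2] + 1L
        z <- (z - 1L) %% sh[3] + 1L
      } else {
        keep <- x >= 1 & x <= sh[1] & y >= 1 & y <= sh[2] & z >= 1 &
          z <= sh[3]
        if (!all(keep)) clipped <- TRUE
        x <- x[keep]; y <- y[keep]; z <- z[keep]
      }
      k <- k + 1L
      meta[[k]] <- tibble::tibble(site = sites$site[i], radius = r)
      vox[[k]] <- voxel_linear_index0(x, y, z, sh)
    }
  }
  if (clipped)
    warning("probe shell clipped at the reflecting boundary", call. = FALSE)
  lens <- vapply(vox, length, integer(1))
  list(meta = dplyr::bind_rows(meta),
       ptr = as.integer(c(0L, cumsum(lens))),
       voxel = as.integer(unlist(vox)))
}

#' Shell-averaged concentrations at fixed distances from sites
#'
#' Mean concentration over the spherical shell `[r - 0.5, r + 0.5)` um
#' around each site, for a single field snapshot.
#'
#' @param field A [da_field()].
#' @param sites A `release_sites` tibble (all rows are used).
#' @param radii Distances in um, e.g. `c(1, 2, 5)`.
#' @return A tibble: `site`, `radius_um`, `conc_nM`.
#' @export
radial_profile <- function(field, sites, radii = c(1, 2, 5)) {
  g <- field_grid(field)
  shells <- shell_voxels(sites, radii, g)
  v <- as.numeric(field)
  n <- nrow(shells$meta)
  conc <- vapply(seq_len(n), function(i) {
    ix <- shells$voxel[(shells$ptr[i] + 1):shells$ptr[i + 1]] + 1L
    mean(v[ix])
  }, numeric(1))
  tibble::tibble(site = shells$meta$site, radius_um = shells$meta$radius,
                 conc_nM = conc)
}

#' Concentration time course at fixed distances from the phasic sites
#'
#' Reduces a trajectory's probe recordings to the mean and standard
#' deviation, across release sites, of the shell-averaged concentration at
#' each distance — the quantity plotted as distance-resolved traces (solid
#' mean, dashed sd) for 1, 2 and 5 um.
#'
#' @param traj A `da_trajectory` run with `probe_radii` set (see
#'   [run_protocol()]), or one with dense snapshots.
#' @param radii Radii to report (subset of the recorded ones).
#' @return A tibble of class `da_distance_trace`: `time`, `radius_um`,
#'   `mean_nM`, `sd_nM`, `n_sites`.
#' @export
distance_timeseries <- function(traj, radii = NULL) {
  stopifnot(inherits(traj, "da_trajectory"))
  pr <- traj$probes
  if (is.null(pr)) {
    if (length(traj$snapshots) == 0)
      stop("trajectory has no probe recordings; rerun with `probe_radii`",
           call. = FALSE)
    ph <- traj$sites[traj$sites$cohort == "phasic", ]
    if (nrow(ph) == 0) ph <- traj$sites
    pr <- purrr::map_dfr(traj$snapshots, function(sn) {
      out <- radial_profile(sn, ph, radii %||% c(1, 2, 5))
      out$time <- field_time(sn)
      out
    })
    names(pr)[names(pr) == "radius"] <- "radius_um"
  }
  if (!is.null(radii)) pr <- pr[pr$radius_um %in% radii, ]
  out <- dplyr::summarise(
    dplyr::group_by(pr, .data$time, .data$radius_um),
    mean_nM = mean(.data$conc_nM), sd_nM = stats::sd(.data$conc_nM),
    n_sites = dplyr::n(), .groups = "drop")
  class(out) <- c("da_distance_trace", class(out))
  out
}

#' Equilibrium receptor occupancy of a field
#'
#' Single-site equilibrium binding probability per voxel,
#' `p = C / (C + Kd)`. At the tonic baseline (~26 nM) the high-affinity
#' state (Kd ~ 10 nM) is ~70% occupied while the low-affinity state
#' (Kd ~ 1-2 uM) is essentially unbound — the regime in which relative
#' changes of the dopamine level can be read out as changes in binding
#' probability.
#'
#' @param field A [da_field()] (nM).
#' @param kd Dissociation constant, nM.
#' @return A `da_occupancy` object: 3-D array of binding probabilities in
#'   `[0, 1)` with the `kd` used attached.
#' @examples
#' receptor_occupancy(da_field(26.2, grid_spec(4)), kd = 10)[1, 1, 1]
#' @export
receptor_occupancy <- function(field, kd = sim_params()$kd_high) {
  stopifnot(inherits(field, "da_field"))
  if (!is.numeric(kd) || kd <= 0) stop("`kd` must be positive", call. = FALSE)
  v <- unclass(field)
  structure(v / (v + kd), grid = field_grid(field), kd = kd,
            time = field_time(field), class = "da_occupancy")
}

#' @export
print.da_occupancy <- function(x, ...) {
  cat(sprintf("<da_occupancy> Kd = %g nM; occupancy %.3f-%.3f (mean %.3f)\n",
              attr(x, "kd"), min(x), max(x), mean(x)))
  invisible(x)
}
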