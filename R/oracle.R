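#' Well-mixed (mean-field) predictions
#'
#' Closed-form balance of total release flux against total uptake. With
#' sites at density rho firing at f Hz, release probability p and quantal
#' content Q, the volume-mean source is `rho * f * p * Q` mol/(um^3 s) of
#' tissue; referred to the extracellular water (fraction alpha) and balanced
#' against first-order uptake at rate k, the steady-state volume mean is
#'
#'   `C_ss = rho * f * p * Q / (alpha * k)`  (in nM).
#'
#' These formulas ignore diffusion entirely. That is exact for volume means
#' on a periodic grid (diffusion only redistributes mass), so they serve as
#' an independent oracle for the simulated volume-mean values — but they say
#' nothing about local concentrations, which vary by more than an order of
#' magnitude around the sparse sites.
#'
#' @param params A [sim_params()] object supplying defaults.
#' @param site_density Sites per um^3. For comparison against a concrete
#'   placement use the realized density `n_sites / volume` (e.g. 52/64^3).
#' @param f_tonic Tonic firing rate, Hz.
#' @return `mf_steady_state()`: the steady-state volume mean in nM.
#' @examples
#' p <- sim_params()
#' mf_steady_state(p, site_density = 52 / 64^3)   # ~26.2 nM
#' mf_blocked_slope(p, site_density = 52 / 64^3)  # ~39.2 nM/s
#' @export
mf_steady_state <- function(params = sim_params(),
                            site_density = params$site_density,
                            f_tonic = params$f_tonic) {
  if (params$uptake_rate <= 0)
    stop("no steady state without uptake (k = 0): the mean grows without ",
         "bound at the blocked-uptake slope", call. = FALSE)
  mf_blocked_slope(params, site_density, f_tonic) / params$uptake_rate
}

#' @rdname mf_steady_state
#' @return `mf_blocked_slope()`: the growth rate of the volume mean when
#'   uptake is completely blocked while tonic release continues,
#'   `rho * f * p * Q / alpha`, in nM/s.
#' @export
mf_blocked_slope <- function(params = sim_params(),
                             site_density = params$site_density,
                             f_tonic = params$f_tonic) {
  site_density * f_tonic * params$release_prob * params$quantal_moles /
    params$alpha * 1e24
}

#' @rdname mf_steady_state
#' @param fraction Fraction of sites firing phasically (0-1).
#' @param phasic_rate Phasic firing rate, Hz.
#' @param duration Duration of the phasic episode, s.
#' @return `mf_phasic_delta()`: the change of the volume mean after
#'   `duration` seconds of phasic firing by `fraction` of the sites,
#'   `fraction * (f_phasic - f_tonic)/f_tonic * C_ss * (1 - exp(-k*T))`, in
#'   nM (negative for a pause).
#' @examples
#' mf_phasic_delta(p, site_density = 52 / 64^3, fraction = 0.5,
#'                 phasic_rate = 15, duration = 0.15)   # ~4.4 nM
#' @export
mf_phasic_delta <- function(params = sim_params(), fraction,
                            phasic_rate = params$f_phasic, duration = 0.15,
                            site_density = params$site_density,
                            f_tonic = params$f_tonic) {
  if (f_tonic <= 0)
    stop("`f_tonic` must be positive for a relative phasic change",
         call. = FALSE)
  if (params$uptake_rate <= 0) stop("k must be positive", call. = FALSE)
  if (duration < 0) stop("`duration` must be >= 0", call. = FALSE)
  css <- mf_steady_state(params, site_density, f_tonic)
  fraction * (phasic_rate - f_tonic) / f_tonic * css *
    (1 - exp(-params$uptake_rate * duration))
}

#' Mean-field reconstruction of the protocol summary table
#'
#' Tabulates the predicted volume-mean concentration and its phasic change
#' for the full protocol grid: tonic baseline plus 15/26/0 Hz episodes at
#' 10/25/50% synchrony, at normal and Parkinsonian-like (depleted) site
#' density. Nominal fractions are used (the mean-field limit does not round
#' to whole sites).
#'
#' @param params A [sim_params()] object.
#' @param densities Named vector of site densities (tissue labels).
#' @param rates Phasic rates, Hz.
#' @param fractions Phasic fractions.
#' @param duration Phasic duration, s.
#' @param realized Use the realized density of the rounded site count (e.g.
#'   52/64^3 instead of 2e-4) as a finite placement does. Default `TRUE`.
#' @return A tibble: `density`, `condition`, `fraction`, `value_mean_nM`
#'   (baseline + change) and `abs_diff_mean_nM`.
#' @export
oracle_table1 <- function(params = sim_params(),
                          densities = c(normal = params$site_density,
                                        mptp = 0.61e-4),
                          rates = c(15, 26, 0), fractions = c(.1, .25, .5),
                          duration = 0.15, realized = TRUE) {
  vol <- (params$edge_length / params$voxel_spacing)^3 * params$voxel_volume
  rows <- list()
  for (d in seq_along(densities)) {
    rho <- densities[d]
    if (realized) rho <- round(rho * vol) / vol
    css <- mf_steady_state(params, site_density = rho)
    rows[[length(rows) + 1]] <- tibble::tibble(
      density = names(densities)[d], condition = "tonic", fraction = NA_real_,
      value_mean_nM = css, abs_diff_mean_nM = NA_real_)
    grid <- expand.grid(rate = rates, fraction = fractions)
    # the depleted condition was only probed with the 15 Hz protocol
    if (names(densities)[d] == "mptp") grid <- grid[grid$rate == 15, ]
    for (i in seq_len(nrow(grid))) {
      delta <- mf_phasic_delta(params, fraction = grid$fraction[i],
                               phasic_rate = grid$rate[i],
                               duration = duration, site_density = rho)
      rows[[length(rows) + 1]] <- tibble::tibble(
        density = names(densities)[d],
        condition = paste0(grid$rate[i], " Hz"), fraction = grid$fraction[i],
        value_mean_nM = css + delta, abs_diff_mean_nM = delta)
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$density, match(.data$condition,
                 c("tonic", "15 Hz", "26 Hz", "0 Hz")), .data$fraction)
}

#' Screened point-source solution around a single release site
#'
#' The continuum steady state around one site releasing `S = f * p * Q`
#' mol/s into a porous medium with effective diffusivity D, extracellular
#' fraction alpha and first-order uptake k is the screened-Poisson Green's
#' function
#'
#'   `C(r) = S / (4 pi D alpha r) * exp(-r / lambda)`,  `lambda = sqrt(D/k)`
#'
#' (lambda ~ 14.7 um at the default parameters). On a periodic box the
#' solution is the sum of this kernel over the periodic images; `images`
#' controls how many shells of images are added (they matter at the ~5-20%
#' level for r beyond ~5 um in a 64-um box).
#'
#' @param r Distances from the site, um.
#' @param params A [sim_params()] object.
#' @param f_rate Source firing rate, Hz.
#' @param box Periodic box edge, um (NULL for free space).
#' @param images Number of image shells per axis (ignored for free space).
#' @return Concentrations in nM at `r`.
#' @export
point_source_profile <- function(r, params = sim_params(),
                                 f_rate = params$f_tonic,
                                 box = params$edge_length, images = 2) {
  S <- f_rate * params$release_prob * params$quantal_moles   # mol/s
  lambda <- sqrt(params$D_eff / params$uptake_rate)
  kern <- function(d) S / (4 * pi * params$D_eff * params$alpha * d) *
    exp(-d / lambda) * 1e24            # mol/um^3 ec -> nM
  if (is.null(box)) return(kern(r))
  off <- seq.int(-images, images) * box
  offs <- expand.grid(x = off, y = off, z = off)
  vapply(r, function(ri) {
    d <- sqrt((ri + offs$x)^2 + offs$y^2 + offs$z^2)
    sum(kern(d))
  }, numeric(1))
}
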