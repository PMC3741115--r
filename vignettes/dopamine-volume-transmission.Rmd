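---
title: "Modelling non-synaptic dopamine transmission in prefrontal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-synaptic dopamine transmission in prefrontal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopaflux)
```

## The model

Dopaminergic axons in primate prefrontal cortex rarely form conventional
synapses. Vesicle-filled varicosities release dopamine directly into the
extracellular space, and the transmitter reaches its receptors by diffusing
through the neuropil — *volume transmission*. dopaflux simulates this
process in an idealized block of cortex (layer 3 of frontopolar area 10) and
asks what concentration landscape the sparse release sites generate, how far
a phasic firing episode is felt, and what happens when release sites are
depleted or reuptake is blocked.

The model has four ingredients on a cubic voxel grid (64 µm per side, 1-µm³
compartments, periodic boundary by default):

1. **Quantal release.** Potential release sites occur at density
   $\rho = 2 \times 10^{-4}\,\mu m^{-3}$ (52 sites in the volume, mean
   nearest-neighbour spacing ≈ 9.5 µm). Each site occupies one voxel — a
   bouton is ~0.9 µm across. In each time step a site releases one vesicle
   with probability $f(t)\,p\,\Delta t$, where $f$ is its cohort's firing
   rate and $p = 0.5$ the release probability per spike. A vesicle carries
   $Q = V_v C_v = 6.5\times10^{-20}\,\mathrm{L} \times 0.25\,\mathrm{M} =
   1.625\times10^{-20}$ mol, which raises the release voxel's extracellular
   water — the fraction $\alpha = 0.23$ of each voxel — by
   $Q/(\alpha V) \approx 7.1 \times 10^{4}$ nM.

2. **Hindered diffusion.** Dopamine diffuses with the effective coefficient
   $D = 322\ \mu m^2/s$, the free coefficient (763 µm²/s) divided by the
   squared tortuosity of the neuropil (1.54² — the sources also quote 1.6;
   we use the effective value directly, which is self-consistent with
   763/1.54²). Diffusion is advanced by an explicit first-order Euler step
   of Fick's law with the 7-point discrete Laplacian.

3. **Linear reuptake.** Transporters are sparse and far from release sites
   in cortex, so uptake is modelled as spatially uniform and first order,
   $-k\,C$ with $k = 1.5\,s^{-1}$ — a tenth of the striatal rate.

4. **Receptor read-out.** Receptors are two-state: a high-affinity
   conformation ($K_d \approx 10$ nM) and a low-affinity one
   ($K_d \approx 1\text{–}2\ \mu M$). Occupancy is the equilibrium binding
   probability $C/(C + K_d)$ per voxel.

All concentrations in the package are nM referred to extracellular fluid
volume. With that convention release and uptake balance exactly as in the
well-mixed limit below.

## The well-mixed oracle

Because the dynamics are linear and the boundary is lossless, the volume
mean obeys a closed-form balance that ignores diffusion entirely:

$$ C_{ss} = \frac{\rho\, f\, p\, Q}{\alpha\, k}, \qquad
   \left.\frac{d\bar C}{dt}\right|_{k=0} = \frac{\rho\, f\, p\, Q}{\alpha}, $$

and a phasic episode of duration $T$ by a fraction $\varphi$ of sites at
rate $f_{ph}$ shifts the mean by
$\varphi\,(f_{ph}-f)/f \cdot C_{ss}\,(1 - e^{-kT})$.

At the default parameters (realized density 52/64³):

```{r oracle}
p <- sim_params()
rho <- 52 / 64^3
c(steady_state = mf_steady_state(p, site_density = rho),
  blocked_slope = mf_blocked_slope(p, site_density = rho),
  delta_15Hz_50 = mf_phasic_delta(p, 0.5, 15, 0.15, site_density = rho))
```

These predictions — 26 nM at steady state, ~39 nM/s accumulation under a
complete reuptake block, and the grid of phasic changes tabulated by
`oracle_table1()` — are what the stochastic simulation must reproduce in its
volume means, and they are asserted against the simulation in the test
suite. The oracle says nothing about *local* concentrations, which vary by
more than an order of magnitude around the sparse sites; that heterogeneity
is the point of running the full grid.

Note the density convention: the nominal density $2\times10^{-4}$ gives
52.43 sites; a concrete placement rounds to 52 sites, whose realized density
reproduces the published means. The tabulated 10/25/50% synchrony fractions
are likewise nominal; a cohort of 52 sites rounds to 5/13/26.

## Numerical scheme and its tolerances

* **Time step.** Explicit Euler is stable for
  $\Delta t \le \Delta x^2 / 6D \approx 5.18\times10^{-4}$ s; the default
  $\Delta t = 5\times10^{-4}$ s sits just under the bound and divides the
  protocol durations exactly. The engine additionally refuses any step with
  $\Delta t\,(6D/\Delta x^2 + k) > 1$, the condition that guarantees
  non-negative concentrations with uptake included.
* **Boundary.** The sources do not state one. We default to periodic: every
  published volume mean matches the *lossless* balance above, whereas an
  absorbing boundary would depress the means noticeably, since the uptake
  screening length $\sqrt{D/k} \approx 14.7\ \mu m$ is not small against the
  64-µm box. A reflecting (zero-flux) boundary is available and is equally
  lossless.
* **Operation order.** Events are injected at the start of a step, before
  diffusion and uptake; uptake acts on every voxel including release voxels.
  The ordering matters only at $O(\Delta t)$.
* **Mass ledger.** Each run tracks injected and removed moles exactly as the
  scheme sees them; the ledger closes to rounding error (≲ 10⁻¹², asserted
  at 10⁻⁶), which is the cheapest global correctness check on the stencil.
* **Uptake accuracy.** The scheme decays a uniform field as
  $(1-k\Delta t)^n$ — exactly exponential in time, with rate
  $-\ln(1-k\Delta t)/\Delta t$, which differs from $k$ by
  $k^2\Delta t/2 \approx 4\times10^{-4}$ relative. Tests assert exactness
  against the discrete form and first-order agreement with $e^{-kt}$.
* **Deterministic release mode.** `run_protocol(..., release = "expected")`
  injects the Bernoulli expectation $f\,p\,\Delta t\,Q$ at every site each
  step. By linearity its field equals the expectation of the stochastic
  model, so it verifies spatial profiles without Monte-Carlo noise. The
  single-site steady profile matches the screened point-source solution
  $C(r) = S\,e^{-r/\lambda} / (4\pi D \alpha r)$, $\lambda=\sqrt{D/k}$,
  summed over periodic images (`point_source_profile()`), within 15% for
  $r \in [2, 10]$ µm — the residual is 7-point-stencil discretization near
  the source.

## Design choices that were genuinely open

* **Bernoulli per step, not Poisson thinning.** At the maximal rate (26 Hz)
  the per-step release probability is 6.5 × 10⁻³; the distributions are
  indistinguishable at that resolution, and per-step Bernoulli draws keep
  the event stream bit-reproducible per seed.
* **Independent sites.** Inter-bouton correlation along shared axonal arbors
  is unknown in this tissue; sites fire independently. Phasic cohorts
  (10/25/50% of sites in synchrony) are re-drawn per replicate.
* **Cohort rounding.** The phasic cohort size is `round(fraction * n)`.
* **Snapshot convention.** "Steady state" is operationalized as t = 4 s of
  tonic firing (six uptake time constants); the phasic snapshot is taken at
  t = 4.15 s, the end of the 150-ms episode. No convergence detection.
* **Relative changes are referred to the steady-state level.** The absolute
  difference map compares the two instantaneous snapshots. The relative map
  divides that change by the steady-state baseline, estimated per voxel as
  the time average of the tonic field over [3, 4] s, not by the t = 4 s
  snapshot. An instantaneous denominator fluctuates strongly near sites
  (a voxel's value depends on the age of its last quantum) and that noise
  biases the volume-mean relative change upwards by several percentage
  points; the steady-state level is the quantity a receptor integrating over
  tens of milliseconds actually sees. `difference_map()` exposes the
  `baseline` argument so either convention can be computed. Voxels whose
  baseline is below 0.01 nM are excluded from relative summaries
  (configurable; at the default parameters no voxel is near that floor).
* **Shell-averaged distance sampling.** Concentration "at distance r from a
  site" is the mean over voxels whose centres fall in the spherical shell
  [r − 0.5, r + 0.5) µm, which tames single-voxel discretization noise; the
  spread shown across sites is the standard deviation over sites.
* **Site placement measure.** Nearest-neighbour statistics default to plain
  Euclidean distances, as one would measure in a bounded tissue block; this
  is inflated ~10% by box edges relative to the unbounded Poisson
  expectation $0.554\rho^{-1/3} = 9.5$ µm. The `periodic = TRUE` option
  (minimum-image distances) removes the edge effect and is what the
  placement-model tests compare against.

## What the simulation reproduces, and what it does not

The volume-mean observables are reproduced quantitatively and are
cross-checked by the oracle: the 26 nM tonic steady state; the grid of mean
phasic changes (e.g. +4.4 nM after 150 ms of 15 Hz at 50% synchrony,
+9.6 nM at 26 Hz, −2.6 nM for a pause); the Parkinsonian-like condition
(site density 0.61 × 10⁻⁴ µm⁻³, 16 sites) settling at 8 nM with a phasic
response of only ~1.4 nM; the ~39 nM/s linear ramp once reuptake is blocked,
which projects from baseline to micromolar levels in ~25 s; and the ~14%
mean relative increase after the 15 Hz/50% episode.

Local, instantaneous statistics (per-voxel standard deviation, minima,
maxima of snapshots) are a different matter. With truly instantaneous 1-µm³
quanta, a snapshot's extremes are dominated by the age of the most recent
event — a voxel that fired a millisecond ago holds thousands of nM for a few
steps. Published local ranges for this system (e.g. a tonic maximum of
~250 nM) are consistent with fields smoothed over roughly ten milliseconds,
not with raw instantaneous snapshots; our time-averaged tonic field (sd
≈ 7 nM, max ≈ 160 nM) is the closer analogue. We therefore treat snapshot
std/min/max as loose, convention-dependent quantities and do not anchor any
quantitative claim to them.

The generator also idealizes in ways worth keeping in mind when carrying
conclusions to tissue: uptake is linear (no transporter saturation, though
Michaelis–Menten behaviour matters above ~1 µM, precisely the blocked-uptake
regime), α and tortuosity are uniform, release probability has no
depression or facilitation, receptor binding does not buffer free dopamine,
and the affinity states are fixed rather than regulated.

## Problem sizes

The default study conditions are the full 64³ grid, Δt = 5 × 10⁻⁴ s, 4 s of
tonic equilibration plus 150-ms episodes. One replicate of the complete
protocol grid is ~25,000 steps. The test suite runs the protocol grid over
10 replicates (seed 1); the reproduction script defaults to 32 replicates.
Every mean phasic-change cell carries a shared per-replicate Monte-Carlo
noise of roughly 1 nM — the stochastic imbalance between tonic release and
uptake over the 150-ms window — so 32 replicates put each cell's standard
error near 0.18 nM. Unit tests exercise the same physics on 16³ grids.

## A worked pipeline

```{r pipeline, eval = FALSE}
p <- sim_params()

# one replicate of the 26-Hz burst protocol, with distance probes
traj <- simulate_protocol(da_protocol("B", fraction = 0.5), p, seed = 1,
                          probe_radii = c(1, 2, 5))
glance(traj)

# how far is the burst felt?
distance_timeseries(traj) |> autoplot()

# the spatial fingerprint of the episode
dm <- difference_map(traj$snapshots[["4.15"]], traj$snapshots[["4"]])
summary(dm)

# receptor's view: high-affinity occupancy before the burst
receptor_occupancy(traj$snapshots[["4"]], kd = p$kd_high) |>
  tidy() |>
  dplyr::summarise(mean_occupancy = mean(occupancy))

# the full protocol table over 10 replicates (minutes of compute)
tab <- build_table1(p, n_seeds = 10)
```
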