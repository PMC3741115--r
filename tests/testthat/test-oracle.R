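# realized densities of the rounded site counts in the 64-um cube
rho52 <- 52 / 64^3
rho16 <- 16 / 64^3

test_that("well-mixed steady state matches the flux balance", {
  p <- sim_params()
  expect_equal(mf_steady_state(p, site_density = rho52), 26.16,
               tolerance = 1e-3)
  expect_equal(mf_steady_state(p, site_density = rho16), 8.05,
               tolerance = 1e-2)
  expect_equal(mf_steady_state(p, f_tonic = 0), 0)
  pk0 <- p; pk0$uptake_rate <- 0
  expect_error(mf_steady_state(pk0), "no steady state")
})

test_that("blocked-uptake slope and the identity slope = k * steady state", {
  p <- sim_params()
  expect_equal(mf_blocked_slope(p, site_density = rho52), 39.24,
               tolerance = 1e-3)
  expect_equal(mf_blocked_slope(p, site_density = 2 * rho52),
               2 * mf_blocked_slope(p, site_density = rho52))
  p0 <- sim_params(release_prob = 0)
  expect_equal(mf_blocked_slope(p0), 0)
  expect_equal(mf_steady_state(p, site_density = rho52) * p$uptake_rate,
               mf_blocked_slope(p, site_density = rho52))
})

test_that("phasic delta formula reproduces the protocol changes", {
  p <- sim_params()
  expect_equal(mf_phasic_delta(p, 0.5, 15, 0.15, site_density = rho52),
               4.424, tolerance = 1e-3)
  expect_equal(mf_phasic_delta(p, 0.5, 26, 0.15, site_density = rho52),
               9.602, tolerance = 1e-3)
  expect_equal(mf_phasic_delta(p, 0.5, 0, 0.15, site_density = rho52),
               -2.635, tolerance = 1e-3)
  expect_equal(mf_phasic_delta(p, 0, 15, 0.15), 0)
  expect_equal(mf_phasic_delta(p, 0.5, 15, 0), 0)
  # T -> Inf limit: full proportional rescaling of the contribution
  css <- mf_steady_state(p, site_density = rho52)
  expect_equal(mf_phasic_delta(p, 0.5, 15, 1e9, site_density = rho52),
               0.5 * (15 - 5.6) / 5.6 * css, tolerance = 1e-9)
  expect_error(mf_phasic_delta(p, 0.5, 15, 0.15, f_tonic = 0), "f_tonic")
})

test_that("oracle table matches the printed protocol summary", {
  tab <- oracle_table1()
  expect_equal(nrow(tab), 14)   # tonic + 9 cells, MPTP tonic + 3 cells
  # printed mean absolute differences (nM): 15/26/0 Hz x 10/25/50%
  printed <- tibble::tribble(
    ~condition, ~fraction, ~abs_printed, ~value_printed,
    "15 Hz", 0.10,  0.9, 27,
    "15 Hz", 0.25,  2.2, 28,
    "15 Hz", 0.50,  4.5, 30.5,
    "26 Hz", 0.10,  1.9, 28,
    "26 Hz", 0.25,  5.0, 31,
    "26 Hz", 0.50,  9.6, 36,
    "0 Hz",  0.10, -0.5, 25.6,
    "0 Hz",  0.25, -1.3, 24.8,
    "0 Hz",  0.50, -2.6, 23.5)
  for (i in seq_len(nrow(printed))) {
    row <- tab[tab$density == "normal" & tab$condition == printed$condition[i] &
                 tab$fraction == printed$fraction[i], ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$abs_diff_mean_nM - printed$abs_printed[i]),
              0.05 + 0.05 * abs(printed$abs_printed[i]))
    expect_lt(abs(row$value_mean_nM - printed$value_printed[i]), 0.5)
  }
  # tonic baseline and the depleted 50% cell
  expect_lt(abs(tab$value_mean_nM[tab$density == "normal" &
                                    tab$condition == "tonic"] - 26), 0.5)
  mptp50 <- tab[tab$density == "mptp" & tab$condition == "15 Hz" &
                  tab$fraction == 0.5, ]
  expect_lt(abs(mptp50$abs_diff_mean_nM - 1.4), 0.1)
})

test_that("screened point-source profile has the expected scale and decay", {
  p <- sim_params()
  # free-space kernel: closed form at r = 2
  S <- p$f_tonic * p$release_prob * p$quantal_moles
  lambda <- sqrt(p$D_eff / p$uptake_rate)
  c2 <- S / (4 * pi * p$D_eff * p$alpha * 2) * exp(-2 / lambda) * 1e24
  expect_equal(point_source_profile(2, p, box = NULL), c2, tolerance = 1e-12)
  # periodic images only add concentration
  expect_gt(point_source_profile(10, p), point_source_profile(10, p, box = NULL))
  # monotone decay over the probed range
  prof <- point_source_profile(2:10, p)
  expect_true(all(diff(prof) < 0))
})
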