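test_that("volume statistics summarize a field", {
  f <- da_field(5, grid_spec(8))
  vs <- volume_stats(f)
  expect_equal(unlist(vs[c("mean", "sd", "min", "max")]),
               c(mean = 5, sd = 0, min = 5, max = 5))
  v <- array(0, c(8, 8, 8)); v[2, 3, 4] <- 10
  vs <- volume_stats(da_field(v, grid_spec(8)))
  expect_equal(vs$max, 10)
  expect_equal(vs$min, 0)
  expect_equal(vs$mean, 10 / 512)
})

test_that("difference maps compare snapshots and flag undefined voxels", {
  g <- grid_spec(8)
  f <- da_field(10, g)
  expect_equal(sum(abs(unclass(difference_map(f, f)$abs))), 0)
  d2 <- difference_map(da_field(20, g), f)
  expect_equal(as.numeric(d2$rel)[1], 100)
  expect_equal(summary(d2)$mean, c(10, 100))
  # a zero-baseline voxel is excluded from the relative map
  v <- array(10, c(8, 8, 8)); v[1, 1, 1] <- 0
  d3 <- difference_map(da_field(v * 2, g), da_field(v, g))
  expect_true(is.na(unclass(d3$rel)[1, 1, 1]))
  expect_equal(summary(d3)$mean[2], 100)   # NA voxel excluded
  # an explicit baseline field changes only the relative map
  bl <- da_field(50, g)
  d4 <- difference_map(da_field(20, g), f, baseline = bl)
  expect_equal(as.numeric(d4$abs)[1], 10)
  expect_equal(as.numeric(d4$rel)[1], 20)
  expect_error(difference_map(da_field(1, grid_spec(4)), f), "grid")
})

test_that("line samples walk the grid at voxel resolution", {
  g <- grid_spec(16)
  f <- da_field(7, g)
  ls <- line_sample(f, c(1, 1, 1), c(1, 0, 0))
  expect_equal(nrow(ls), 16)
  expect_true(all(ls$conc_nM == 7))
  expect_equal(ls$distance_um, 0:15)
  # diagonal steps advance sqrt(2) um
  ld <- line_sample(f, c(1, 1, 1), c(1, 1, 0), n_steps = 5)
  expect_equal(ld$distance_um, (0:5) * sqrt(2))
  expect_equal(line_sample(da_field(0, g), c(1, 1, 1), c(0, 0, 1))$conc_nM,
               rep(0, 16))
  expect_error(line_sample(f, c(16, 1, 1), c(1, 0, 0), n_steps = 5), "grid")
  lw <- line_sample(f, c(16, 1, 1), c(1, 0, 0), n_steps = 5, wrap = TRUE)
  expect_equal(lw$x, c(16L, 1L, 2L, 3L, 4L, 5L))
})

test_that("a release site is a local maximum along a line through it", {
  p <- small_params()
  g <- grid_spec(16)
  f <- inject_quanta(da_field(0, g), tibble::tibble(x = 8L, y = 8L, z = 8L), p)
  f <- diffuse_uptake_step(f, p, n_steps = 40, k = 0)
  prof <- line_sample(f, c(1, 8, 8), c(1, 0, 0))
  expect_equal(which.max(prof$conc_nM), 8)
  expect_true(all(diff(prof$conc_nM[1:8]) > 0))
  expect_true(all(diff(prof$conc_nM[8:16]) < 0))
})

test_that("shell averages at increasing distance decrease around one source", {
  # one site, deterministic expected release: time-stationary profile
  p <- sim_params(edge_length = 32, site_density = 1 / 32^3)
  sites <- place_sites(p, seed = 3)
  traj <- run_protocol(sites, firing_schedule(t_end = 1.5), p, t_end = 1.5,
                       seed = 4, release = "expected")
  rp <- radial_profile(traj$final, sites, radii = c(1, 2, 5))
  expect_equal(nrow(rp), 3)
  expect_true(all(diff(rp$conc_nM) < 0))
})

test_that("distance time series aggregate probe shells across sites", {
  p <- small_params()
  g <- grid_spec(16)
  sites <- place_sites(p, seed = 6)
  silent <- firing_schedule(t_end = 0.05, f_tonic = 0)
  traj <- run_protocol(sites, silent, small_params(uptake_rate = 0),
                       init = da_field(40, g), t_end = 0.05, seed = 7,
                       probe_radii = c(1, 2), record_every = 20L)
  dt_tr <- distance_timeseries(traj)
  # a uniform field reports the uniform value at every radius, sd 0
  expect_true(all(abs(dt_tr$mean_nM - 40) < 1e-9))
  expect_true(all(dt_tr$sd_nM < 1e-9))
  expect_setequal(unique(dt_tr$radius_um), c(1, 2))
  expect_equal(unique(dt_tr$n_sites), nrow(sites))
  # no probes recorded and no snapshots -> informative error
  bare <- run_protocol(sites, silent, small_params(uptake_rate = 0),
                       init = da_field(1, g), t_end = 0.05, seed = 7)
  expect_error(distance_timeseries(bare), "probe")
})

test_that("receptor occupancy follows single-site equilibrium binding", {
  g <- grid_spec(4)
  expect_equal(as.numeric(receptor_occupancy(da_field(10, g), kd = 10))[1],
               0.5)
  expect_equal(as.numeric(receptor_occupancy(da_field(26.2, g), kd = 10))[1],
               0.724, tolerance = 1e-3)
  expect_equal(as.numeric(receptor_occupancy(da_field(26.2, g),
                                             kd = 1500))[1],
               0.0172, tolerance = 1e-2)
  expect_equal(as.numeric(receptor_occupancy(da_field(0, g), kd = 10))[1], 0)
  # strictly increasing in concentration, bounded in [0, 1)
  cs <- seq(0, 500, by = 25)
  occ <- cs / (cs + 10)
  got <- vapply(cs, function(ci)
    as.numeric(receptor_occupancy(da_field(ci, g), kd = 10))[1], numeric(1))
  expect_equal(got, occ)
  expect_true(all(diff(got) > 0) && all(got < 1))
  expect_error(receptor_occupancy(da_field(1, g), kd = 0), "positive")
})

test_that("tidiers return long tibbles aligned with the arrays", {
  g <- grid_spec(4)
  v <- array(seq_len(64), c(4, 4, 4))
  f <- da_field(v, g)
  td <- tidy(f)
  expect_equal(nrow(td), 64)
  expect_equal(td$conc_nM, as.vector(v))
  expect_equal(td$x[2], 2L)   # column-major: x varies fastest
  oc <- tidy(receptor_occupancy(f, kd = 10))
  expect_equal(oc$occupancy, as.vector(v / (v + 10)))
  dd <- tidy(difference_map(f, f))
  expect_true(all(dd$abs_nM == 0))
})
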