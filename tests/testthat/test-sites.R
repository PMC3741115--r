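test_that("site count follows round(density * volume)", {
  p <- sim_params()
  expect_equal(nrow(place_sites(p, seed = 1)), 52)
  expect_equal(nrow(place_sites(p, density = 0.61e-4, seed = 1)), 16)
  expect_equal(nrow(place_sites(p, density = 1 / 64^3, seed = 1)), 1)
  expect_error(place_sites(p, density = 1e-9), "fewer than one")
  expect_error(place_sites(sim_params(edge_length = 4), density = 2), "more sites")
})

test_that("placement is distinct, in-grid and deterministic per seed", {
  p <- sim_params()
  s1 <- place_sites(p, seed = 11)
  s2 <- place_sites(p, seed = 11)
  s3 <- place_sites(p, seed = 12)
  expect_identical(s1[, c("x", "y", "z")], s2[, c("x", "y", "z")])
  expect_false(identical(s1$x, s3$x))
  expect_equal(anyDuplicated(s1[, c("x", "y", "z")]), 0)
  expect_true(all(s1$x >= 1 & s1$x <= 64 & s1$y >= 1 & s1$y <= 64 &
                    s1$z >= 1 & s1$z <= 64))
})

test_that("nearest-neighbour distances reproduce geometric oracles", {
  g <- grid_spec(64)
  # 3-4-5 right triangle: both sites are each other's nearest neighbour at 5 um
  tri <- manual_sites(rbind(c(1, 1, 1), c(4, 5, 1)), g)
  st <- nearest_neighbour_stats(tri)
  expect_equal(st$mean_um, 5)
  expect_equal(st$sd_um, 0)
  # a 16-um cubic lattice has nearest-neighbour distance 16 everywhere
  lat <- as.matrix(expand.grid(x = seq(1, 64, 16), y = seq(1, 64, 16),
                               z = seq(1, 64, 16)))
  st <- nearest_neighbour_stats(manual_sites(lat, g))
  expect_equal(st$mean_um, 16)
  expect_equal(st$min_um, 16)
  single <- manual_sites(rbind(c(1, 1, 1)), g)
  expect_error(nearest_neighbour_stats(single), "two sites")
})

test_that("random placement matches the Poisson nearest-neighbour expectation", {
  # unbounded expectation 0.554 * rho^(-1/3) = 9.5 um at 52 sites / 64^3;
  # minimum-image distances remove the box-edge inflation
  p <- sim_params()
  m <- vapply(1:20, function(s)
    nearest_neighbour_stats(place_sites(p, seed = s),
                            periodic = TRUE)$mean_um, numeric(1))
  expect_gt(mean(m), 9.0)
  expect_lt(mean(m), 10.0)
  # the bounded measure is systematically larger (edge effect)
  mb <- vapply(1:20, function(s)
    nearest_neighbour_stats(place_sites(p, seed = s))$mean_um, numeric(1))
  expect_gt(mean(mb), mean(m))
})

test_that("phasic cohort size follows the rounding rule and partitions sites", {
  p <- sim_params()
  sites <- place_sites(p, seed = 3)
  for (fr_n in list(c(0.5, 26), c(0.25, 13), c(0.1, 5), c(0, 0))) {
    co <- assign_phasic_cohort(sites, fr_n[1], seed = 9)
    expect_equal(sum(co$cohort == "phasic"), fr_n[2])
    expect_equal(sum(co$cohort == "tonic") + sum(co$cohort == "phasic"),
                 nrow(sites))
  }
  c1 <- assign_phasic_cohort(sites, 0.5, seed = 4)
  c2 <- assign_phasic_cohort(sites, 0.5, seed = 4)
  expect_identical(c1$cohort, c2$cohort)
  expect_error(assign_phasic_cohort(sites, 1.5), "fraction")
})

test_that("release events follow rate * p * dt Bernoulli statistics", {
  p <- small_params()   # 20 sites in a 16-um box
  sites <- place_sites(p, seed = 2)
  sched <- firing_schedule(t_end = 4, f_tonic = 5.6)
  ev <- sample_release_events(sites, sched, p, t_end = 4, seed = 5)
  # expectation 5.6 * 0.5 * 4 = 11.2 events per site
  n_exp <- nrow(sites) * 11.2
  expect_lt(abs(nrow(ev) - n_exp), 4 * sqrt(n_exp))
  expect_true(all(ev$step >= 1 & ev$step <= 8000))
  # silent schedule produces nothing
  ev0 <- sample_release_events(sites, firing_schedule(t_end = 1, f_tonic = 0),
                               p, t_end = 1, seed = 5)
  expect_equal(nrow(ev0), 0)
  # determinism
  ev2 <- sample_release_events(sites, sched, p, t_end = 4, seed = 5)
  expect_identical(ev, ev2)
  # dt too coarse for the requested rate
  fast <- firing_schedule(t_end = 0.01, f_tonic = 5000)
  expect_error(sample_release_events(sites, fast, p, t_end = 0.01, seed = 1),
               "dt")
})

test_that("phasic segments change the event rate only for the phasic cohort", {
  p <- small_params()
  sites <- assign_phasic_cohort(place_sites(p, seed = 2), 0.5, seed = 3)
  sched <- firing_schedule(t_end = 1.15, t_tonic = 1, phasic_rate = 26,
                           phasic_duration = 0.15)
  ev <- sample_release_events(sites, sched, p, t_end = 1.15, seed = 6)
  late <- ev[ev$time > 1, ]
  ph_sites <- sites$site[sites$cohort == "phasic"]
  n_ph <- sum(late$site %in% ph_sites)
  n_to <- sum(!late$site %in% ph_sites)
  # expectations: phasic 26 * 0.5 * 0.15 = 1.95/site; tonic 0.42/site
  expect_lt(abs(n_ph - 1.95 * length(ph_sites)),
            4 * sqrt(1.95 * length(ph_sites)))
  expect_lt(abs(n_to - 0.42 * (nrow(sites) - length(ph_sites))),
            4 * sqrt(0.42 * (nrow(sites) - length(ph_sites))) + 1)
})

test_that("schedules are validated", {
  expect_error(validate_schedule <- firing_schedule(t_end = -1), "t_end")
  bad <- tibble::tibble(cohort = "tonic", t_start = c(0, 2), t_end = c(1, 3),
                        rate = 5)
  sites <- place_sites(small_params(), seed = 1)
  expect_error(sample_release_events(sites, bad, small_params(), t_end = 3,
                                     seed = 1), "contiguous")
})
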