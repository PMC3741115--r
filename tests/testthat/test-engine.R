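test_that("a uniform field without uptake is a fixed point", {
  p <- small_params()
  f <- da_field(50, grid_spec(16))
  f1 <- diffuse_uptake_step(f, p, n_steps = 100, k = 0)
  expect_equal(as.numeric(f1), rep(50, 16^3), tolerance = 1e-12)
  expect_equal(attr(f1, "time"), 100 * p$dt)
})

test_that("uptake-only decay is exponential", {
  p <- small_params()
  f <- da_field(100, grid_spec(16))
  n <- 2000L                                   # 1 s at dt = 5e-4
  f1 <- diffuse_uptake_step(f, p, n_steps = n)
  # exact closed form of the scheme
  expect_equal(as.numeric(f1)[1], 100 * (1 - p$uptake_rate * p$dt)^n,
               tolerance = 1e-9)
  # continuous-time exponential to first order in dt
  expect_equal(as.numeric(f1)[1], 100 * exp(-1.5), tolerance = 2e-3)
  expect_equal(max(as.numeric(f1)) - min(as.numeric(f1)), 0)
})

test_that("diffusion conserves mass on periodic and reflecting grids", {
  p <- small_params()
  for (bnd in c("periodic", "reflecting")) {
    g <- grid_spec(16, boundary = bnd)
    v <- array(0, g$shape); v[3, 4, 5] <- 1000
    f <- da_field(v, g)
    f1 <- diffuse_uptake_step(f, p, n_steps = 400, k = 0)
    expect_equal(sum(as.numeric(f1)), 1000, tolerance = 1e-9)
    expect_gte(min(as.numeric(f1)), 0)
  }
})

test_that("quantal injection increments exactly the listed voxels", {
  p <- sim_params()
  g <- grid_spec(16)
  f <- da_field(0, g)
  inc <- quantal_increment(p$quantal_moles, p$alpha, 1)
  f1 <- inject_quanta(f, tibble::tibble(x = 5L, y = 5L, z = 5L), p)
  expect_equal(unclass(f1)[5, 5, 5], inc)
  expect_equal(sum(as.numeric(f1)), inc)
  # two events in the same voxel stack
  f2 <- inject_quanta(f, tibble::tibble(x = c(5L, 5L), y = c(5L, 5L),
                                        z = c(5L, 5L)), p)
  expect_equal(unclass(f2)[5, 5, 5], 2 * inc)
  # empty event list is a no-op; out-of-grid voxels are refused
  expect_identical(inject_quanta(f, tibble::tibble(x = integer(),
                                                   y = integer(),
                                                   z = integer()), p), f)
  expect_error(inject_quanta(f, tibble::tibble(x = 17L, y = 1L, z = 1L), p),
               "outside")
})

test_that("the engine refuses unstable time steps", {
  p <- small_params()
  f <- da_field(1, grid_spec(16))
  expect_error(diffuse_uptake_step(f, p, dt = 6e-4), "stability")
  sites <- place_sites(p, seed = 1)
  pbad <- p; pbad$dt <- 6e-4     # bypass the constructor check
  expect_error(run_protocol(sites, firing_schedule(t_end = 0.12), pbad,
                            t_end = 0.12, seed = 1), "stability")
})

test_that("the mass ledger closes for a stochastic run", {
  p <- small_params()
  sites <- place_sites(p, seed = 4)
  traj <- run_protocol(sites, firing_schedule(t_end = 0.5), p, t_end = 0.5,
                       seed = 5)
  expect_lt(abs(traj$ledger$rel_error), 1e-9)
  expect_gte(min(as.numeric(traj$final)), 0)
  mb <- mass_balance(traj)
  expect_equal(mb$final_mol,
               mb$initial_mol + mb$injected_mol - mb$uptaken_mol,
               tolerance = 1e-9)
})

test_that("concentrations scale linearly in the quantal content", {
  p1 <- small_params()
  p2 <- small_params(vesicle_conc = 0.5)   # doubled Q
  sites <- place_sites(p1, seed = 7)
  t1 <- run_protocol(sites, firing_schedule(t_end = 0.3), p1, t_end = 0.3,
                     seed = 8)
  t2 <- run_protocol(sites, firing_schedule(t_end = 0.3), p2, t_end = 0.3,
                     seed = 8)
  expect_identical(nrow(t1$events), nrow(t2$events))  # same event stream
  expect_equal(as.numeric(t2$final), 2 * as.numeric(t1$final),
               tolerance = 1e-12)
})

test_that("runs are bit-reproducible given the seed", {
  p <- small_params()
  sites <- place_sites(p, seed = 10)
  a <- run_protocol(sites, firing_schedule(t_end = 0.2), p, t_end = 0.2,
                    seed = 11, snapshot_times = 0.1)
  b <- run_protocol(sites, firing_schedule(t_end = 0.2), p, t_end = 0.2,
                    seed = 11, snapshot_times = 0.1)
  expect_identical(as.numeric(a$final), as.numeric(b$final))
  expect_identical(a$traces, b$traces)
  expect_identical(as.numeric(a$snapshots[["0.1"]]),
                   as.numeric(b$snapshots[["0.1"]]))
})

test_that("a trajectory can be continued from a snapshot", {
  p <- small_params()
  sites <- place_sites(p, seed = 12)
  a <- run_protocol(sites, firing_schedule(t_end = 0.2), p, t_end = 0.2,
                    seed = 13)
  b <- run_protocol(sites, firing_schedule(t_end = 0.4), p, t_end = 0.4,
                    seed = 14, init = a$final)
  expect_equal(b$t0, 0.2)
  expect_equal(attr(b$final, "time"), 0.4)
  wrong <- da_field(0, grid_spec(8))
  expect_error(run_protocol(sites, firing_schedule(t_end = 0.4), p,
                            t_end = 0.4, seed = 1, init = wrong), "grid")
})

test_that("blocking uptake mid-run freezes the decay", {
  p <- small_params(uptake_block_time = 0.05)
  g <- grid_spec(16)
  sites <- place_sites(p, seed = 1)
  silent <- firing_schedule(t_end = 0.1, f_tonic = 0)
  traj <- run_protocol(sites, silent, p, t_end = 0.1, seed = 2,
                       init = da_field(100, g))
  # 100 decaying steps, then flat
  expect_equal(mean(as.numeric(traj$final)),
               100 * (1 - p$uptake_rate * p$dt)^100, tolerance = 1e-9)
  late <- traj$traces$mean_nM[traj$traces$time > 0.05 + 1e-9]
  expect_equal(max(late) - min(late), 0, tolerance = 1e-12)
})

test_that("expected-release mode reaches the well-mixed steady state", {
  p <- small_params()
  sites <- place_sites(p, seed = 20)
  traj <- run_protocol(sites, firing_schedule(t_end = 4), p, t_end = 4,
                       seed = 21, release = "expected")
  rho <- nrow(sites) / 16^3
  pred <- mf_steady_state(p, site_density = rho) * (1 - exp(-6))
  expect_equal(mean(as.numeric(traj$final)), pred, tolerance = 5e-3)
  # mixed rates are not representable in expected mode
  mixed <- assign_phasic_cohort(sites, 0.5, seed = 1)
  sched <- firing_schedule(t_end = 0.3, t_tonic = 0.1, phasic_rate = 26,
                           phasic_duration = 0.1)
  expect_error(run_protocol(mixed, sched, p, t_end = 0.3, seed = 1,
                            release = "expected"), "common constant rate")
})
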