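test_that("surrogate energy/gradient: minimum, finite differences, symmetry", {
  ## diatomic Morse: energy -De and zero gradient at re
  t2 <- chm_typing(list(H = 1:2), c(H = 0.5), 1L, c(H = 1))
  pes2 <- chm_surrogate_pes(t2, pair = list(HH = list(De = 0.1, a = 1.5,
                                                      re = 0.8)))
  cfg <- chm_config(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.8)))
  eg <- surrogate_energy_gradient(pes2, cfg)
  expect_equal(eg$energy, -0.1, tolerance = 1e-12)
  expect_equal(max(abs(eg$gradient)), 0, tolerance = 1e-10)

  pes <- surrogate_h3()
  for (seed in 1:5) {
    cfg <- random_config(c("H", "H", "H"), seed = seed, min_sep = 0.6)
    eg <- surrogate_energy_gradient(pes, cfg)
    expect_equal(eg$gradient, oracle_fd_gradient(pes, cfg),
                 tolerance = 1e-6)
    ## permutation invariance of the energy
    perm <- random_class_perm(typing_h3p(), seed + 10)
    pc <- apply_permutation(cfg, perm, typing_h3p())
    expect_equal(surrogate_energy_gradient(pes, pc)$energy, eg$energy,
                 tolerance = 1e-12)
  }
})

test_that("NVE: stationary start, determinism, drift, 2nd-order timestep", {
  pes <- surrogate_h3()
  eq <- config_h3p(0.9)
  ## zero kinetic energy at an exact minimum: frames do not move
  ## (pure pairwise Morse so the equilateral geometry is stationary)
  pes_pair <- chm_surrogate_pes(typing_h3p(),
                                pair = list(HH = list(De = 0.15, a = 1.8,
                                                      re = 0.9)))
  spec0 <- chm_trajectory_spec(eq, ekin = 0, timestep = 0.5, steps = 50,
                               stride = 10, seed = 1)
  run0 <- run_nve(pes_pair, spec0)
  for (f in run0$configs)
    expect_equal(f$coords, eq$coords, tolerance = 1e-8)

  spec <- chm_trajectory_spec(eq, ekin = 3000, timestep = 0.2, steps = 400,
                              stride = 4, seed = 3)
  runa <- run_nve(pes, spec)
  runb <- run_nve(pes, spec)
  expect_identical(runa$energies, runb$energies)   # same seed, same frames
  expect_equal(length(runa$configs), 100)
  ## drift bound at a well-resolved timestep
  spec_fine <- chm_trajectory_spec(eq, ekin = 3000, timestep = 0.005,
                                   steps = 2000, stride = 400, seed = 3)
  expect_lt(attr(run_nve(pes, spec_fine), "drift_fraction"), 1e-5)
  ## halving the timestep reduces drift ~4x (2nd-order integrator);
  ## compare the same physical time span
  d1 <- attr(run_nve(pes, chm_trajectory_spec(eq, 3000, 0.4, 250,
                                              250, seed = 3)), "drift")
  d2 <- attr(run_nve(pes, chm_trajectory_spec(eq, 3000, 0.2, 500,
                                              500, seed = 3)), "drift")
  expect_gt(d1 / d2, 2.0)
  expect_lt(d1 / d2, 8.0)
})

test_that("restrained dynamics: k = 0 degenerates to NVE, large k pins r0", {
  pes <- surrogate_h3()
  eq <- config_h3p(0.9)
  spec <- chm_trajectory_spec(eq, ekin = 2000, timestep = 0.2, steps = 300,
                              stride = 3, seed = 5,
                              restraints = list(chm_restraint(c(1, 2),
                                                              1.4, 0)))
  r0 <- run_restrained(pes, spec)
  spec_plain <- spec; spec_plain$restraints <- list()
  expect_equal(r0$energies, run_nve(pes, spec_plain)$energies,
               tolerance = 1e-12)
  ## stiff restraint keeps the pair near its target
  specs <- chm_trajectory_spec(eq, ekin = 500, timestep = 0.1, steps = 2000,
                               stride = 2, seed = 6,
                               restraints = list(chm_restraint(c(1, 2),
                                                               1.3, 2.0)))
  runs <- run_restrained(pes, specs)
  r12 <- vapply(runs$configs, function(cf)
    as.numeric(compute_distances(cf))[1], 1)
  expect_lt(abs(mean(r12) - 1.3) / 1.3, 0.02)
  ## stored energies are the bare-surface energies
  expect_equal(runs$energies[1],
               surrogate_energy_gradient(pes, runs$configs[[1]])$energy,
               tolerance = 1e-12)
})

test_that("presets carry the published sampling parameters", {
  b2a <- chm_preset("basin2A")
  expect_equal(b2a$restraints[[1]]$r0, 2)
  expect_equal(b2a$restraints[[1]]$k, 0.5)
  expect_equal(b2a$ekin, 5000)
  expect_equal(b2a$steps, 4000)
  expect_equal(b2a$stride, 4)
  expect_equal(chm_preset("basin1")$steps, 50000)
  expect_equal(chm_preset("basin1")$stride, 5)
  expect_equal(chm_preset("ts12_tight")$restraints[[1]]$r0, 1.337)
  expect_error(chm_preset("nope"), "unknown preset")
})

test_that("grid_and_midpoint_split edge cases and spacing", {
  sp <- grid_and_midpoint_split(1, 2, 2)
  expect_equal(sp$train, c(1, 2))
  expect_equal(sp$test, 1.5)
  sp2 <- grid_and_midpoint_split(0.225, 3, 100)
  expect_equal(length(sp2$test), 99)
  expect_true(all(sp2$test > min(sp2$train) & sp2$test < max(sp2$train)))
  expect_equal(unique(round(diff(sp2$test) - diff(sp2$train)[1], 12)), 0)
  expect_error(grid_and_midpoint_split(2, 1, 10), "invalid")
})

test_that("prune_select stratifies energies and avoids duplicates", {
  set.seed(9)
  configs <- lapply(1:60, function(k)
    random_config(c("H", "H", "H"), seed = 400 + k, min_sep = 0.6))
  energies <- runif(60)
  idx <- prune_select(configs, energies, n_target = 60)
  expect_equal(idx, 1:60)                       # identity when keeping all
  idx2 <- prune_select(configs, energies, n_target = 20, n_bins = 5,
                       seed = 2)
  expect_equal(length(idx2), 20)
  ## every nonempty input bin is represented
  bins <- findInterval(energies, seq(min(energies), max(energies),
                                     length.out = 6),
                       rightmost.closed = TRUE)
  expect_setequal(unique(bins[idx2]), unique(bins))
  ## duplicates never chosen together while distinct points remain
  dup_configs <- c(configs[1:10], configs[1])   # config 11 == config 1
  e2 <- c(energies[1:10], energies[1])
  idx3 <- prune_select(dup_configs, e2, n_target = 10, n_bins = 1, seed = 3)
  expect_false(all(c(1, 11) %in% idx3))
  expect_error(prune_select(list(), numeric(0), 1), "empty")
})

test_that("qc_adapter caches and errors usefully", {
  cfg <- chm_config(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 0.79)))
  e1 <- qc_adapter("fci2e", cfg, "HF", "sto-3g", charge = 1)
  e2 <- qc_adapter("fci2e", cfg, "HF", "sto-3g", charge = 1)
  expect_identical(e1, e2)
  expect_error(qc_adapter("missing_engine", cfg, "HF", "sto-3g"),
               "not available")
  ## rotation invariance of the engine energy
  R <- random_rotation(5)
  rot <- chm_config(cfg$elements, cfg$coords %*% t(R))
  e3 <- qc_adapter("fci2e", rot, "HF", "sto-3g", charge = 1, cache = FALSE)
  expect_equal(e3, e1, tolerance = 1e-8)
})
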