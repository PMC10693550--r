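ff <- forcefield_params()

two_bead_topology <- function() {
  # minimal bonded pair: a construct is overkill, so reuse a single S1h
  # coil and keep only its first two beads' interactions relevant
  sys <- build_system("(S1h)1", seed = 1)
  system_topology(sys)
}

test_that("minimization finds the harmonic bond minimum and is idempotent", {
  topo <- two_bead_topology()
  # straight rod with every bond stretched to 2 x r0
  pos <- matrix(0, 21, 3)
  pos[, 1] <- (0:20) * 2 * ff$bond_r0
  cfg <- structure(list(pos = pos + 5, vel = matrix(0, 21, 3),
                        box = c(30, 30, 30), topology = topo),
                   class = "cc_config")
  out <- minimize_config(cfg, ff, max_steps = 5000, force_tol = 1)
  bl <- sqrt(rowSums((out$pos[-1, ] - out$pos[-21, ])^2))
  expect_true(all(abs(bl - ff$bond_r0) < 1e-3))
  expect_lte(attr(out, "energy"), total_energy_forces(cfg, ff)$energy)

  # idempotence: minimizing again moves (essentially) nothing
  out2 <- minimize_config(out, ff, max_steps = 5000, force_tol = 1)
  expect_lt(max(abs(out2$pos - out$pos)), 1e-2)
})

test_that("minimizing a packed random box removes overlaps", {
  sys <- build_system(c("(S1h-S3h)1-gs", "(S2h)1", "(S4h)1"))
  topo <- system_topology(sys)
  cfg <- initial_config(topo, c(6, 6, 6), seed = 9)
  e0 <- total_energy_forces(cfg, ff)$energy
  out <- minimize_config(cfg, ff)
  expect_lte(attr(out, "energy"), e0)
  dmin <- coilsim:::cpp_min_pair_distance(out$pos, out$box,
                                          coilsim:::topo_cpp(topo))
  expect_gt(dmin, 0.5 * ff$sigma_rep)
})

test_that("identical seeds give bitwise-identical trajectories", {
  cfg <- random_small_config(seed = 2)
  t1 <- run_langevin(cfg, ff, 310, n_steps = 3000, save_interval = 200,
                     seed = 77, gamma = 0.25)
  t2 <- run_langevin(cfg, ff, 310, n_steps = 3000, save_interval = 200,
                     seed = 77, gamma = 0.25)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final$vel, t2$final$vel)
  # different seed diverges
  t3 <- run_langevin(cfg, ff, 310, n_steps = 3000, save_interval = 200,
                     seed = 78, gamma = 0.25)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("the thermostat holds the kinetic temperature within 3%", {
  sys <- build_system(c("(S1h-S3h)2-gs", "(S2h-S4h)2-gs"))
  topo <- system_topology(sys)
  cfg <- initial_config(topo, c(10, 10, 10), seed = 4)
  cfg <- minimize_config(cfg, ff)
  trj <- run_langevin(cfg, ff, 310, n_steps = 25000, save_interval = 100,
                      seed = 5, gamma = 0.5)
  tk <- kinetic_temperature(trj, ff)
  n <- dim(trj$frames)[2]
  # correct for the three centre-of-mass degrees of freedom removed
  tk_mean <- mean(tk[-(1:50)]) * n / (n - 1)
  expect_lt(abs(tk_mean - 310) / 310, 0.03)
})

test_that("gamma = 0 reduces to symplectic NVE with bounded energy drift", {
  cfg <- random_small_config(seed = 6)
  # thermalize, then switch the thermostat off
  warm <- run_langevin(cfg, ff, 310, n_steps = 2000, save_interval = 500,
                       seed = 7, gamma = 0.25)
  nve <- run_langevin(warm$final, ff, 310, n_steps = 60000,
                      save_interval = 500, seed = 8, gamma = 0)
  etot <- nve$pe + nve$ke
  drift <- abs(etot[length(etot)] - etot[1]) / abs(etot[1])
  expect_lt(drift, 0.005)
})

test_that("free beads diffuse at the Einstein rate kT/(m*gamma)", {
  # an ideal gas of free beads: every bead is an independent realization of
  # free Langevin dynamics, giving the statistics the 5% check needs
  n <- 1000
  topo <- ideal_gas_topology(n)
  side <- 60
  pts <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:10))[seq_len(n), ]
  cfg <- structure(list(pos = pts * 5, vel = matrix(0, n, 3),
                        box = rep(side, 3), topology = topo),
                   class = "cc_config")
  ff0 <- forcefield_params(epsilon_rep = 0)
  gamma <- 1
  trj <- run_langevin(cfg, ff0, 310, n_steps = 80000, save_interval = 100,
                      seed = 3, gamma = gamma, remove_com = FALSE)
  dif <- msd_diffusion(trj, window = seq_len(dim(trj$frames)[1]),
                       n_bootstrap = 50, seed = 1)
  d_expected <- trj$meta$kT / (ff0$mass * gamma) * 1e-2  # cm^2/s
  expect_lt(abs(dif$D_cm2_s - d_expected) / d_expected, 0.05)
})

test_that("an unconstrained linker behaves as a freely jointed chain", {
  # (S1h-S3h) with a 40-residue gs linker; S1h/S3h are orthogonal so with
  # repulsion off the linker is an ideal chain: <R^2> over its k bonds is
  # k times the squared bond length
  sys <- build_system("(S1h-S3h)1-gs40", seed = 1)
  topo <- system_topology(sys)
  ff0 <- forcefield_params(epsilon_rep = 0)
  cfg <- initial_config(topo, c(60, 60, 60), seed = 3)
  cfg <- minimize_config(cfg, ff0)
  trj <- run_langevin(cfg, ff0, 310, n_steps = 100000, save_interval = 100,
                      seed = 4, gamma = 0.25)
  b <- topo$beads
  first_link <- min(which(b$segment_class == "linker"))
  last_link <- max(which(b$segment_class == "linker"))
  i0 <- first_link - 1   # last bead of the first coil
  i1 <- last_link + 1    # first bead of the second coil
  nf <- dim(trj$frames)[1]
  r2 <- vapply(seq(nf / 2, nf), function(f) {
    sum((trj$frames[f, i1, ] - trj$frames[f, i0, ])^2)
  }, 0)
  k_bonds <- i1 - i0
  b2 <- ff0$bond_r0^2 + 3 * trj$meta$kT / ff0$bond_k  # bond-length variance
  expect_lt(abs(mean(r2) - k_bonds * b2) / (k_bonds * b2), 0.10)
})

test_that("box resizing conserves molecules and bond geometry", {
  sys <- build_system(c("(S1h-S3h)1-gs", "(S2h-S4h)1-gs"), copies = 5)
  topo <- system_topology(sys)
  cfg <- initial_config(topo, c(10, 10, 40), seed = 5)
  cfg <- minimize_config(cfg, ff)

  # expansion leaves every coordinate, hence every bond length, untouched
  ex <- resize_box(cfg, "z", scale = 10, mode = "box_only")
  expect_equal(ex$box[3], cfg$box[3] * 10)
  expect_identical(ex$pos, cfg$pos)

  # compression to a target length is exact
  cm <- resize_box(cfg, "z", target_length = 17.3, mode = "molecule")
  expect_equal(cm$box[3], 17.3, tolerance = 1e-6)
  # molecule mode: internal geometry rigid, so bond lengths unchanged
  bl <- function(cc) {
    i <- topo$bonds[, 1]; j <- topo$bonds[, 2]
    sqrt(rowSums((cc$pos[i, ] - cc$pos[j, ])^2))
  }
  expect_equal(bl(cm), bl(cfg), tolerance = 1e-9)

  # number density scales with the inverse volume ratio
  dens <- function(cc) topo$n_beads / prod(cc$box)
  expect_equal(dens(cm) / dens(cfg), prod(cfg$box) / prod(cm$box),
               tolerance = 1e-12)
})

test_that("centre-of-mass motion removal keeps net momentum at zero", {
  cfg <- random_small_config(seed = 8)
  trj <- run_langevin(cfg, ff, 310, n_steps = 5000, save_interval = 100,
                      seed = 9, gamma = 0.25, remove_com = TRUE)
  p <- colSums(trj$final$vel) * ff$mass
  expect_lt(sqrt(sum(p^2)) / nrow(cfg$pos), 1e-8)
})

test_that("dynamics blow-up is detected and aborts with a diagnostic", {
  cfg <- random_small_config(seed = 10)
  cfg$vel[] <- 1e7  # absurd velocities: first step exceeds half the box
  expect_error(
    run_langevin(cfg, ff, 310, n_steps = 100, save_interval = 10, seed = 1,
                 gamma = 0),
    "blew up"
  )
})

test_that("extended XYZ trajectories round-trip", {
  cfg <- random_small_config(seed = 11)
  trj <- run_langevin(cfg, ff, 310, n_steps = 1000, save_interval = 200,
                      seed = 12, gamma = 0.25)
  path <- tempfile(fileext = ".xyz")
  write_xyz(trj, path)
  back <- read_xyz(path, topology = trj$topology)
  expect_equal(dim(back$frames), dim(trj$frames))
  expect_equal(back$frames, trj$frames, tolerance = 1e-9)
  expect_equal(back$times, trj$times, tolerance = 1e-9)
  expect_equal(back$box, trj$box, tolerance = 1e-9)
  unlink(path)
})
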