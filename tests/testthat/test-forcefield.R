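ff <- forcefield_params()

test_that("sticky pair energy follows the truncated-shifted 12-6 form", {
  sig <- ff$sigma_sticky
  eps <- ff$epsilon_sticky
  rmin <- 2^(1 / 6) * sig
  # closed-form: shifted minimum is -eps plus the (positive) tail magnitude
  shift <- 4 * eps * ((sig / ff$cutoff_sticky)^12 - (sig / ff$cutoff_sticky)^6)
  e <- sticky_pair_energy(rmin, 5, 5, 21, 21, "parallel", ff, strength = 1)
  expect_equal(e, -eps - shift, tolerance = 1e-12)
  expect_lt(shift, 0)  # attractive tail at 2.5 sigma
  # zero beyond the cutoff and for the none rule
  expect_equal(sticky_pair_energy(ff$cutoff_sticky + 0.01, 5, 5, 21, 21,
                                  "parallel", ff), 0)
  expect_equal(sticky_pair_energy(rmin, 5, 5, 21, 21, "none", ff), 0)
  # strength multiplier scales the well linearly
  e2 <- sticky_pair_energy(rmin, 5, 5, 21, 21, "parallel", ff,
                           strength = 0.5)
  expect_equal(e2, e / 2, tolerance = 1e-12)
  expect_error(sticky_pair_energy(-1, 5, 5, 21, 21, "parallel", ff),
               "positive")
})

test_that("registry complementarity enforces the dimer orientation", {
  rmin <- 2^(1 / 6) * ff$sigma_sticky
  # parallel: equal registries only
  expect_lt(sticky_pair_energy(rmin, 7, 7, 21, 21, "parallel", ff), 0)
  expect_equal(sticky_pair_energy(rmin, 7, 8, 21, 21, "parallel", ff), 0)
  # antiparallel: reversed registries, equal lengths required
  expect_lt(sticky_pair_energy(rmin, 1, 21, 21, 21, "antiparallel", ff), 0)
  expect_equal(sticky_pair_energy(rmin, 1, 1, 21, 21, "antiparallel", ff), 0)
  expect_equal(sticky_pair_energy(rmin, 1, 28, 21, 28, "antiparallel", ff), 0)
})

test_that("excluded volume is WCA: repulsive, shifted, capped", {
  expect_equal(excluded_volume_energy(ff$cutoff_rep, ff), 0)
  expect_equal(excluded_volume_energy(ff$cutoff_rep + 0.2, ff), 0)
  expect_equal(excluded_volume_energy(ff$sigma_rep, ff), ff$epsilon_rep,
               tolerance = 1e-12)
  # monotonically non-increasing in r
  r <- seq(ff$r_floor, ff$cutoff_rep, length.out = 50)
  v <- excluded_volume_energy(r, ff)
  expect_true(all(diff(v) <= 1e-9))
  # capped below the floor: large but finite
  expect_equal(excluded_volume_energy(1e-6, ff),
               excluded_volume_energy(ff$r_floor, ff))
  expect_true(is.finite(excluded_volume_energy(1e-6, ff)))
})

test_that("forces are the negative gradient of the energy", {
  cfg <- random_small_config(seed = 3)
  ef <- total_energy_forces(cfg, ff, all_pairs = TRUE)
  h <- 1e-6
  set.seed(42)
  picks <- sample(nrow(cfg$pos), 12)
  worst <- 0
  for (i in picks) {
    for (k in 1:3) {
      cp <- cfg; cp$pos[i, k] <- cp$pos[i, k] + h
      cm <- cfg; cm$pos[i, k] <- cm$pos[i, k] - h
      num <- -(total_energy_forces(cp, ff, TRUE)$energy -
                 total_energy_forces(cm, ff, TRUE)$energy) / (2 * h)
      rel <- abs(num - ef$forces[i, k]) / max(abs(ef$forces[i, k]), 1)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("energy matches the independent brute-force oracle", {
  cfg <- random_small_config(seed = 7)
  ef <- total_energy_forces(cfg, ff, all_pairs = TRUE)
  or <- oracle_energy(cfg, ff)
  expect_equal(ef$e_bond, or$e_bond, tolerance = 1e-9)
  expect_equal(ef$e_angle, or$e_angle, tolerance = 1e-9)
  expect_equal(ef$e_rep, or$e_rep, tolerance = 1e-9)
  expect_equal(ef$e_sticky, or$e_sticky, tolerance = 1e-9)
})

test_that("energy is translation-invariant and zero for isolated beads", {
  cfg <- random_small_config(seed = 5)
  e0 <- total_energy_forces(cfg, ff, TRUE)$energy
  cfg2 <- cfg
  cfg2$pos <- cfg2$pos + matrix(rep(c(1.7, -0.9, 2.3), each = nrow(cfg$pos)),
                                ncol = 3)
  expect_equal(total_energy_forces(cfg2, ff, TRUE)$energy, e0,
               tolerance = 1e-9)
  # lattice translation (periodicity)
  cfg3 <- cfg
  cfg3$pos[, 1] <- cfg3$pos[, 1] + cfg$box[1]
  expect_equal(total_energy_forces(cfg3, ff, TRUE)$energy, e0,
               tolerance = 1e-9)

  # two chains far apart: all nonbonded terms vanish
  topo <- single_coil_topology(2, c("S1h", "S2h"))
  pos <- matrix(0, 42, 3)
  pos[1:21, 1] <- (0:20) * ff$bond_r0
  pos[22:42, 1] <- (0:20) * ff$bond_r0
  pos[22:42, 2] <- 10
  cfg4 <- structure(list(pos = pos + 20, vel = matrix(0, 42, 3),
                         box = c(50, 50, 50), topology = topo),
                    class = "cc_config")
  ef <- total_energy_forces(cfg4, ff, TRUE)
  expect_equal(ef$e_rep, 0)
  expect_equal(ef$e_sticky, 0)
  expect_equal(ef$e_bond, 0, tolerance = 1e-9)  # bonds at r0 exactly
})

test_that("neighbour-list energies equal all-pairs computation", {
  sys <- build_system(c("(S1h-S3h)1-gs", "(S2h-S4h)1-gs"), copies = 2)
  topo <- system_topology(sys)
  cfg <- initial_config(topo, c(8, 8, 8), seed = 11)
  cfg <- minimize_config(cfg, ff)
  trj <- run_langevin(cfg, ff, 310, n_steps = 1500, save_interval = 500,
                      seed = 13, gamma = 0.25)
  cfg <- trj$final
  e_list <- total_energy_forces(cfg, ff, all_pairs = FALSE)
  e_all <- total_energy_forces(cfg, ff, all_pairs = TRUE)
  expect_equal(e_list$energy, e_all$energy, tolerance = 1e-9)
  expect_equal(e_list$forces, e_all$forces, tolerance = 1e-9)
})

test_that("only the designed coil pairs attract (orthogonality)", {
  # one single-coil chain of each Sh type, forced pairwise side by side
  topo <- single_coil_topology(4, c("S1h", "S2h", "S3h", "S4h"))
  b <- topo$beads
  sticky_between <- function(t1, t2) {
    pos <- matrix(0, topo$n_beads, 3)
    for (ch in 1:4) {
      idx <- which(b$chain == ch)
      pos[idx, 1] <- (0:20) * 0.38
      pos[idx, 2] <- 30 * ch  # far apart
    }
    # bring the two chains under test together
    i1 <- which(b$chain == t1); i2 <- which(b$chain == t2)
    pos[i2, 2] <- pos[i1, 2] + 0.64
    pos[i2, 1] <- pos[i1, 1]
    cfg <- structure(list(pos = pos + 10, vel = matrix(0, topo$n_beads, 3),
                          box = c(200, 200, 200), topology = topo),
                     class = "cc_config")
    total_energy_forces(cfg, ff, TRUE)$e_sticky
  }
  expect_lt(sticky_between(1, 2), -50)   # S1h-S2h bind
  expect_lt(sticky_between(3, 4), -50)   # S3h-S4h bind
  expect_equal(sticky_between(1, 3), 0)  # all cross pairs inert
  expect_equal(sticky_between(1, 4), 0)
  expect_equal(sticky_between(2, 3), 0)
  expect_equal(sticky_between(2, 4), 0)
})

test_that("the orientation gate zeroes wrong-orientation homodimer contacts", {
  place_pair <- function(type, antialign) {
    topo <- single_coil_topology(2, c(type, type))
    pos <- matrix(0, 42, 3)
    pos[1:21, 1] <- (0:20) * 0.38
    if (antialign) {
      pos[22:42, 1] <- rev((0:20) * 0.38)  # N->C reversed: antiparallel
    } else {
      pos[22:42, 1] <- (0:20) * 0.38
    }
    pos[22:42, 2] <- 0.64
    cfg <- structure(list(pos = pos + 10, vel = matrix(0, 42, 3),
                          box = c(40, 40, 40), topology = topo),
                     class = "cc_config")
    total_energy_forces(cfg, ff, TRUE)$e_sticky
  }
  # GCNh3 is a parallel homodimer: aligned axes bind, anti-aligned do not
  expect_lt(place_pair("GCNh3", antialign = FALSE), -50)
  expect_equal(place_pair("GCNh3", antialign = TRUE), 0)
  # APHh3 is antiparallel: the reverse holds
  expect_equal(place_pair("APHh3", antialign = FALSE), 0)
  expect_lt(place_pair("APHh3", antialign = TRUE), -50)
})

test_that("dimer binding is effectively one-to-one", {
  # two complementary pairs in a dilute box: after equilibration the
  # fraction of coil beads touching complementary beads on more than one
  # distinct chain stays below 5%
  sys <- build_system(list("(S1h)1", "(S2h)1", "(S1h)1", "(S2h)1"), seed = 1)
  topo <- system_topology(sys)
  cfg <- initial_config(topo, c(14, 14, 14), seed = 2)
  cfg <- minimize_config(cfg, ff)
  trj <- run_langevin(cfg, ff, 310, n_steps = 40000, save_interval = 400,
                      seed = 3, gamma = 0.15)
  b <- topo$beads
  cutoff <- 1.5 * ff$sigma_sticky
  nf <- dim(trj$frames)[1]
  multi <- 0; total <- 0
  for (f in seq(nf / 2, nf)) {
    pos <- trj$frames[f, , ]
    mi <- function(d) d - trj$box * round(d / trj$box)
    for (i in which(b$type > 0)) {
      partners <- integer(0)
      for (j in which(b$type > 0)) {
        if (b$chain[i] == b$chain[j]) next
        ti <- topo$types[b$type[i]]; tj <- topo$types[b$type[j]]
        if (topo$pair_code[ti, tj] == 1 && b$registry[i] == b$registry[j] &&
            sqrt(sum(mi(pos[i, ] - pos[j, ])^2)) < cutoff) {
          partners <- union(partners, b$chain[j])
        }
      }
      total <- total + 1
      if (length(partners) > 1) multi <- multi + 1
    }
  }
  expect_lt(multi / total, 0.05)
})
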