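ff <- forcefield_params()

# 8 single-coil chains alternating S1h/S2h, for synthetic-frame tests
mini_topo <- single_coil_topology(8, rep(c("S1h", "S2h"), 4))

place_chains <- function(z_coms, box, topo = mini_topo, x = NULL, y = NULL,
                         spread = TRUE) {
  # straight rods along x at given chain z positions
  nch <- length(z_coms)
  pos <- matrix(0, topo$n_beads, 3)
  for (ch in seq_len(nch)) {
    idx <- which(topo$beads$chain == ch)
    pos[idx, 1] <- (0:20) * 0.38 +
      if (is.null(x)) (ch %% 3) * 2 else x[ch]
    pos[idx, 2] <- if (is.null(y)) (ch %% 4) * 2 else y[ch]
    pos[idx, 3] <- z_coms[ch]
  }
  pos
}

test_that("density profile of a uniform gas is flat within Poisson noise", {
  set.seed(31)
  nch <- 24
  gas_topo <- single_coil_topology(nch, rep(c("S1h", "S2h"), nch / 2))
  box <- c(10, 10, 60)
  frames <- lapply(1:60, function(f) {
    place_chains(runif(nch, 0, box[3]), box, topo = gas_topo,
                 x = runif(nch, 0, 8), y = runif(nch, 0, 8))
  })
  trj <- synthetic_traj(frames, box, gas_topo)
  dp <- density_profile(trj, window = 1:60, n_bins = 12)
  # normalization: integral of the profile recovers the chain count
  expect_equal(sum(dp$density) * attr(dp, "bin_volume"), nch,
               tolerance = 1e-9)
  counts_per_bin <- dp$density * attr(dp, "bin_volume") * 60
  lambda <- nch * 60 / 12
  expect_true(all(abs(counts_per_bin - lambda) < 3 * sqrt(lambda)))
})

test_that("a single dense slab yields near-zero dilute density", {
  box <- c(10, 10, 80)
  set.seed(32)
  frames <- lapply(1:30, function(f) {
    place_chains(40 + runif(8, -2, 2), box,
                 x = runif(8, 0, 8), y = runif(8, 0, 8))
  })
  trj <- synthetic_traj(frames, box, mini_topo)
  dp <- density_profile(trj, window = 1:30, n_bins = 40)
  expect_equal(attr(dp, "dilute_density"), 0, tolerance = 1e-12)
  expect_gt(attr(dp, "contrast"), 5)
  # recentring: the dense region sits at z = 0 in profile coordinates
  expect_lt(abs(dp$z[which.max(dp$density)]), 4)
})

test_that("the empty analysis window errors", {
  box <- c(10, 10, 20)
  trj <- synthetic_traj(lapply(1:12, function(f)
    place_chains(rep(10, 8), box)), box, mini_topo)
  expect_error(density_profile(trj, window = integer(0)), "window")
  expect_error(cluster_distribution(trj, contact_cutoff = -1), "positive")
})

test_that("cluster components match the brute-force oracle", {
  box <- c(12, 12, 12)
  set.seed(33)
  for (rep in 1:5) {
    pos <- place_chains(runif(8, 2, 10), box,
                        x = runif(8, 0, 6), y = runif(8, 0, 10))
    trj <- synthetic_traj(list(pos), box, mini_topo)
    for (edge in c("engaged", "any")) {
      cl <- cluster_distribution(trj, window = 1, edge = edge)
      sizes_pkg <- local({
        # reconstruct the per-frame multiset from the report
        s <- cl$sizes
        sort(rep(s$size, s$n), decreasing = TRUE)
      })
      sizes_oracle <- oracle_clusters(pos, box, mini_topo,
                                      1.5 * ff$sigma_sticky, edge = edge)
      expect_equal(sizes_pkg, sort(sizes_oracle, decreasing = TRUE),
                   label = paste("edge", edge, "rep", rep))
    }
  }
})

test_that("cluster sizes partition the chain set in every frame", {
  box <- c(12, 12, 12)
  set.seed(34)
  frames <- lapply(1:10, function(f)
    place_chains(runif(8, 2, 10), box, x = runif(8, 0, 6),
                 y = runif(8, 0, 10)))
  trj <- synthetic_traj(frames, box, mini_topo)
  cl <- cluster_distribution(trj, window = 1:10)
  # per-frame largest*n_clusters bounds; full partition via sizes table
  expect_equal(sum(cl$sizes$size * cl$sizes$n), 8 * 10)
  expect_true(all(cl$per_frame$largest_fraction <= 1))
})

test_that("isolated, paired and fully-bound layouts classify as expected", {
  box <- c(12, 12, 40)
  # all chains far apart -> all singletons
  pos_far <- place_chains(seq(2, 37, by = 5), box, x = rep(0, 8),
                          y = rep(c(0, 6), 4))
  trj <- synthetic_traj(rep(list(pos_far), 12), box, mini_topo)
  cl <- cluster_distribution(trj, window = 1:12)
  expect_equal(cl$sizes$size, 1L)
  expect_equal(cl$dimer_dominance, 0)

  # exactly one bound pair among the 8 chains -> sizes {2,1,1,...}
  pos_pair <- pos_far
  i1 <- which(mini_topo$beads$chain == 1)
  i2 <- which(mini_topo$beads$chain == 2)
  pos_pair[i2, ] <- pos_pair[i1, ]
  pos_pair[i2, 2] <- pos_pair[i2, 2] + 0.64
  trj <- synthetic_traj(rep(list(pos_pair), 12), box, mini_topo)
  cl <- cluster_distribution(trj, window = 1:12)
  expect_equal(max(cl$per_frame$largest), 2)
  expect_equal(cl$per_frame$n_clusters[1], 7)

  # all four complementary pairs bound -> dimer dominance 1
  pos_all <- pos_far
  for (k in c(1, 3, 5, 7)) {
    ia <- which(mini_topo$beads$chain == k)
    ib <- which(mini_topo$beads$chain == k + 1)
    pos_all[ib, ] <- pos_all[ia, ]
    pos_all[ib, 2] <- pos_all[ib, 2] + 0.64
  }
  trj <- synthetic_traj(rep(list(pos_all), 12), box, mini_topo)
  cl <- cluster_distribution(trj, window = 1:12)
  expect_equal(cl$dimer_dominance, 1)
  expect_equal(cl$largest_cluster_fraction, 2 / 8)
})

test_that("dominant-species ties break toward the larger size", {
  # 2 dimers (4 chains) + 1 tetramer (4 chains): tie on chain mass
  box <- c(12, 12, 60)
  pos <- place_chains(seq(2, 37, by = 5), box, x = rep(0, 8),
                      y = rep(c(0, 6), 4))
  link <- function(pos, a, b) {
    ia <- which(mini_topo$beads$chain == a)
    ib <- which(mini_topo$beads$chain == b)
    pos[ib, ] <- pos[ia, ]
    pos[ib, 2] <- pos[ib, 2] + 0.64
    pos
  }
  pos <- link(pos, 1, 2)          # dimer
  pos <- link(pos, 3, 4)          # dimer
  pos <- link(pos, 5, 6)          # tetramer: 5-6, 6-7, 7-8 chained
  ia <- which(mini_topo$beads$chain == 6)
  ib <- which(mini_topo$beads$chain == 7)
  pos[ib, ] <- pos[ia, ]; pos[ib, 2] <- pos[ib, 2] + 0.64
  ia <- which(mini_topo$beads$chain == 7)
  ib <- which(mini_topo$beads$chain == 8)
  pos[ib, ] <- pos[ia, ]; pos[ib, 2] <- pos[ib, 2] + 0.64
  trj <- synthetic_traj(list(pos), box, mini_topo)
  cl <- cluster_distribution(trj, window = 1)
  expect_equal(cl$per_frame$dominant_size, 4)
  expect_equal(cl$dimer_dominance, 0)
})

test_that("phase classification follows the declared thresholds", {
  fake_density <- function(contrast) {
    structure(tibble::tibble(z = 0, density = 1),
              class = c("cc_density_profile", "tbl_df", "tbl", "data.frame"),
              dense_density = contrast, dilute_density = 1,
              contrast = contrast)
  }
  fake_clusters <- function(lcf, dd) {
    structure(list(largest_cluster_fraction = lcf, dimer_dominance = dd),
              class = "cc_cluster_report")
  }
  expect_equal(classify_phase(fake_density(10), fake_clusters(0.9, 0))$label,
               "condensate")
  expect_equal(classify_phase(fake_density(10), fake_clusters(0.5, 0.7))$label,
               "dimer")
  expect_equal(classify_phase(fake_density(2), fake_clusters(0.9, 0.2))$label,
               "diffuse")
  expect_equal(classify_phase(fake_density(2), fake_clusters(0.1, 0.9))$label,
               "dimer")
  # boundary values are inclusive
  expect_equal(classify_phase(fake_density(5), fake_clusters(0.8, 0))$label,
               "condensate")
  # deterministic: same inputs, same call
  a <- classify_phase(fake_density(7), fake_clusters(0.85, 0.1))
  b <- classify_phase(fake_density(7), fake_clusters(0.85, 0.1))
  expect_identical(tidy(a), tidy(b))
})

test_that("MSD diffusion recovers a known random walk and flags frozen", {
  set.seed(35)
  box <- c(50, 50, 50)
  sigma <- 0.15
  nch <- 24
  nf <- 250
  walk_topo <- single_coil_topology(nch, rep(c("S1h", "S2h"), nch / 2))
  # chain COM random walk: every bead of a chain moves identically
  base <- place_chains(runif(nch, 10, 40), box, topo = walk_topo,
                       x = runif(nch, 5, 45), y = runif(nch, 5, 45))
  frames <- vector("list", nf)
  cur <- base
  for (f in seq_len(nf)) {
    step <- matrix(rnorm(nch * 3, sd = sigma), nch, 3)
    for (ch in seq_len(nch)) {
      idx <- which(walk_topo$beads$chain == ch)
      cur[idx, ] <- sweep(cur[idx, , drop = FALSE], 2, step[ch, ], "+")
    }
    frames[[f]] <- cur
  }
  trj <- synthetic_traj(frames, box, walk_topo, dt_frame = 1)
  dif <- msd_diffusion(trj, window = seq_len(nf), n_bootstrap = 100, seed = 2)
  d_expected <- sigma^2 / 2 * 1e-2  # nm^2/ps -> cm^2/s
  expect_lt(abs(dif$D_cm2_s - d_expected) / d_expected, 0.25)
  expect_false(dif$subdiffusive)
  expect_gt(dif$D_sd, 0)

  # frozen configuration: D = 0, flagged subdiffusive, bootstrap SD = 0
  trj0 <- synthetic_traj(rep(list(base), 60), box, walk_topo)
  dif0 <- msd_diffusion(trj0, window = 1:60, n_bootstrap = 50, seed = 3)
  expect_equal(dif0$D_cm2_s, 0)
  expect_true(dif0$subdiffusive)
  expect_equal(dif0$D_sd, 0)
})

test_that("bootstrap uncertainty shrinks with more chains", {
  set.seed(36)
  sigma <- 0.2
  make_walk <- function(nch, nf) {
    topo <- single_coil_topology(nch, rep("S1h", nch))
    frames <- vector("list", nf)
    cur <- matrix(0, topo$n_beads, 3)
    for (ch in seq_len(nch)) {
      idx <- which(topo$beads$chain == ch)
      cur[idx, 1] <- (0:20) * 0.38
      cur[idx, 3] <- ch * 2
    }
    for (f in seq_len(nf)) {
      step <- matrix(rnorm(nch * 3, sd = sigma), nch, 3)
      for (ch in seq_len(nch)) {
        idx <- which(topo$beads$chain == ch)
        cur[idx, ] <- sweep(cur[idx, , drop = FALSE], 2, step[ch, ], "+")
      }
      frames[[f]] <- cur
    }
    synthetic_traj(frames, c(100, 100, 100), topo)
  }
  d_small <- msd_diffusion(make_walk(4, 80), window = 1:80,
                           n_bootstrap = 120, seed = 4)
  d_large <- msd_diffusion(make_walk(24, 80), window = 1:80,
                           n_bootstrap = 120, seed = 4)
  expect_lt(d_large$D_sd, d_small$D_sd)
})

test_that("coil engagement separates permanent dimers from free chains", {
  box <- c(12, 12, 40)
  pos <- place_chains(seq(2, 37, by = 5), box, x = rep(0, 8),
                      y = rep(c(0, 6), 4))
  # chains 1-2 permanently bound, the rest never in contact
  i1 <- which(mini_topo$beads$chain == 1)
  i2 <- which(mini_topo$beads$chain == 2)
  pos[i2, ] <- pos[i1, ]
  pos[i2, 2] <- pos[i2, 2] + 0.64
  trj <- synthetic_traj(rep(list(pos), 20), box, mini_topo)
  eng <- coil_engagement(trj, window = 1:20)
  expect_equal(eng$engaged_fraction[eng$chain == 1], 1)
  expect_equal(eng$unique_partners[eng$chain == 1], 1)
  expect_true(all(eng$engaged_fraction[eng$chain >= 3] == 0))
  expect_true(all(eng$unique_partners[eng$chain >= 3] == 0))
})
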