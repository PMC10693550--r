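# Independent R oracles and small fixtures. Everything here is written from
# the definitions, not by calling the package's compute paths, so the tests
# compare two independent routes.

# brute-force total energy: direct double loop over all bead pairs
oracle_energy <- function(config, ff) {
  topo <- config$topology
  b <- topo$beads
  pos <- config$pos
  box <- config$box
  n <- nrow(pos)

  mi <- function(d) d - box * round(d / box)

  e_bond <- 0
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[k, 1]; j <- topo$bonds[k, 2]
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    e_bond <- e_bond + 0.5 * ff$bond_k * (r - ff$bond_r0)^2
  }

  e_angle <- 0
  for (k in seq_len(nrow(topo$angles))) {
    i <- topo$angles[k, 1]; j <- topo$angles[k, 2]; l <- topo$angles[k, 3]
    va <- pos[i, ] - pos[j, ]; vb <- pos[l, ] - pos[j, ]
    ct <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
    e_angle <- e_angle + ff$angle_k * (1 + ct)
  }

  # segment axes for the orientation gate
  segs <- topo$segments
  axes <- matrix(NA_real_, nrow(segs), 3)
  for (s in seq_len(nrow(segs))) {
    if (segs$class[s] != "coil") next
    v <- pos[segs$last[s], ] - pos[segs$first[s], ]
    axes[s, ] <- v / sqrt(sum(v^2))
  }
  smoothstep <- function(x, lo, hi) {
    if (x <= lo) return(0)
    if (x >= hi) return(1)
    u <- (x - lo) / (hi - lo)
    u^2 * (3 - 2 * u)
  }

  shift <- local({
    sr6 <- (ff$sigma_sticky / ff$cutoff_sticky)^6
    4 * ff$epsilon_sticky * (sr6^2 - sr6)
  })

  e_rep <- 0; e_sticky <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (b$chain[i] == b$chain[j] && abs(i - j) == 1) next  # bonded
      d <- mi(pos[i, ] - pos[j, ])
      r <- sqrt(sum(d^2))
      re <- max(r, ff$r_floor)
      fat <- b$type[i] > 0 && b$type[j] > 0 &&
        b$segment_global[i] != b$segment_global[j] &&
        topo$pair_code[topo$types[b$type[i]], topo$types[b$type[j]]] == 0
      sig_r <- if (fat) ff$sigma_fat else ff$sigma_rep
      rc_r <- 2^(1 / 6) * sig_r
      if (r < rc_r) {
        sr6 <- (sig_r / re)^6
        e_rep <- e_rep + 4 * ff$epsilon_rep * (sr6^2 - sr6) + ff$epsilon_rep
      }
      if (b$type[i] > 0 && b$type[j] > 0 &&
          b$segment_global[i] != b$segment_global[j]) {
        ti <- topo$types[b$type[i]]; tj <- topo$types[b$type[j]]
        code <- topo$pair_code[ti, tj]
        s <- topo$pair_strength[ti, tj]
        compl <- (code == 1 && b$registry[i] == b$registry[j]) ||
          (code == 2 && b$coil_len[i] == b$coil_len[j] &&
             b$registry[j] == b$coil_len[i] + 1 - b$registry[i])
        sticky_active <- code > 0 && s > 0 && compl
        if (!sticky_active && ti == tj &&
            b$registry[i] == b$registry[j] &&
            r < 1.3 * ff$sigma_ex) {
          # competitor exclusion; gated on parallel alignment for
          # homodimeric types
          g_ex <- if (topo$pair_code[ti, ti] > 0) {
            dd <- sum(axes[b$segment_global[i], ] * axes[b$segment_global[j], ])
            smoothstep(dd, ff$gate_lo, ff$gate_hi)
          } else 1
          rc_ex <- 1.3 * ff$sigma_ex
          e_rep <- e_rep +
            g_ex * ff$epsilon_ex * (1 + cos(pi * r / rc_ex))
        }
        if (sticky_active && r < ff$cutoff_sticky) {
          dd <- sum(axes[b$segment_global[i], ] * axes[b$segment_global[j], ])
          g <- if (code == 1) smoothstep(dd, ff$gate_lo, ff$gate_hi) else
            smoothstep(-dd, ff$gate_lo, ff$gate_hi)
          if (g > 0) {
            sr6 <- (ff$sigma_sticky / re)^6
            e_sticky <- e_sticky +
              g * s * (4 * ff$epsilon_sticky * (sr6^2 - sr6) - shift)
          }
        }
      }
    }
  }
  list(e_bond = e_bond, e_angle = e_angle, e_rep = e_rep,
       e_sticky = e_sticky, energy = e_bond + e_angle + e_rep + e_sticky)
}

# brute-force chain clusters from one frame, from the criterion definition
oracle_clusters <- function(pos, box, topo, cutoff, edge = "engaged") {
  b <- topo$beads
  nch <- topo$n_chains
  mi <- function(d) d - box * round(d / box)
  adj <- matrix(FALSE, nch, nch)
  coil <- which(b$type > 0)
  contact_count <- new.env()
  for (i in coil) {
    for (j in coil) {
      if (j <= i || b$segment_global[i] == b$segment_global[j]) next
      ti <- topo$types[b$type[i]]; tj <- topo$types[b$type[j]]
      code <- topo$pair_code[ti, tj]
      if (code == 0 || topo$pair_strength[ti, tj] <= 0) next
      compl <- (code == 1 && b$registry[i] == b$registry[j]) ||
        (code == 2 && b$coil_len[i] == b$coil_len[j] &&
           b$registry[j] == b$coil_len[i] + 1 - b$registry[i])
      if (!compl) next
      if (sqrt(sum(mi(pos[i, ] - pos[j, ])^2)) < cutoff) {
        if (edge == "any") {
          if (b$chain[i] != b$chain[j]) adj[b$chain[i], b$chain[j]] <-
              adj[b$chain[j], b$chain[i]] <- TRUE
        } else {
          key <- paste(b$segment_global[i], b$segment_global[j])
          cur <- contact_count[[key]]
          regs <- if (is.null(cur)) integer(0) else cur
          contact_count[[key]] <- union(regs, b$registry[i])
        }
      }
    }
  }
  if (edge == "engaged") {
    for (key in ls(contact_count)) {
      segs <- as.integer(strsplit(key, " ")[[1]])
      La <- topo$segments$coil_len[topo$segments$segment == segs[1]]
      ca <- topo$segments$chain[topo$segments$segment == segs[1]]
      cb <- topo$segments$chain[topo$segments$segment == segs[2]]
      if (ca != cb && length(contact_count[[key]]) >= ceiling(La / 2)) {
        adj[ca, cb] <- adj[cb, ca] <- TRUE
      }
    }
  }
  # connected components by BFS
  comp <- rep(0L, nch)
  cid <- 0L
  for (s in seq_len(nch)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  sort(as.integer(table(comp)), decreasing = TRUE)
}

# a small thermalized multi-chain configuration for force tests
random_small_config <- function(seed = 1, box = c(6, 6, 6)) {
  sys <- build_system(c("(S1h)1", "(S2h)1"), seed = seed)
  topo <- system_topology(sys)
  ff <- forcefield_params()
  cfg <- initial_config(topo, box, seed = seed)
  cfg <- minimize_config(cfg, ff)
  trj <- run_langevin(cfg, ff, 310, n_steps = 2000, save_interval = 1000,
                      seed = seed + 5, gamma = 0.25)
  cfg <- trj$final
  cfg$vel[] <- 0
  cfg
}

# hand-built trajectory from a list of position matrices
synthetic_traj <- function(frames_list, box, topology, dt_frame = 1) {
  nf <- length(frames_list)
  n <- nrow(frames_list[[1]])
  arr <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames_list[[f]]
  structure(
    list(frames = arr, times = seq_len(nf) * dt_frame, box = box,
         topology = topology, pe = rep(0, nf), ke = rep(0, nf),
         final = NULL, meta = list(dt = dt_frame)),
    class = "cc_traj"
  )
}

# topology of k single-coil chains (all the same coil type by default)
single_coil_topology <- function(k, types = rep("S1h", k)) {
  sys <- build_system(as.list(paste0("(", types, ")1")), seed = 1)
  system_topology(sys)
}
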