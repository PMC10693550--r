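#' Create a configuration for a system topology
#'
#' Generates starting coordinates for every chain as a persistent random
#' walk at the C-alpha bond length, then places chains (grouped into
#' stoichiometric units) on a jittered grid with random rigid rotations.
#' Coordinates are kept unwrapped throughout the package; the minimum-image
#' convention is applied to nonbonded pair distances only, so chains never
#' need re-wrapping across stages.
#'
#' @param topology A `cc_topology`.
#' @param box Length-3 box in nm.
#' @param seed Integer seed.
#' @param persistence Direction correlation of the generating walk (0-1).
#' @return A `cc_config`: list with `pos` (n x 3), `vel` (n x 3, zero),
#'   `box`, `topology`.
#' @export
initial_config <- function(topology, box, seed = 1L, persistence = 0.85) {
  stopifnot(inherits(topology, "cc_topology"), length(box) == 3)
  rng <- local_rng(seed)
  n <- topology$n_beads
  pos <- matrix(0, n, 3)
  for (ch in seq_len(topology$n_chains)) {
    idx <- which(topology$beads$chain == ch)
    pos[idx, ] <- chain_walk(length(idx), 0.38, persistence, rng)
  }
  # group chains into units of one copy per component
  units <- chain_units(topology)
  n_units <- length(units)
  grid <- unit_grid(n_units, box)
  for (u in seq_len(n_units)) {
    chains <- units[[u]]
    # chains of a unit sit side by side, 1.2 nm apart, before rotation
    for (ki in seq_along(chains)) {
      idx <- which(topology$beads$chain == chains[ki])
      com <- colMeans(pos[idx, , drop = FALSE])
      off <- c(0, (ki - (length(chains) + 1) / 2) * 1.2, 0)
      pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, com - off)
    }
    idx <- which(topology$beads$chain %in% chains)
    com <- colMeans(pos[idx, , drop = FALSE])
    rot <- random_rotation(rng)
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, com) %*% t(rot)
    jit <- (runif_rng(rng, 3) - 0.5) * 0.3
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, grid[u, ] + jit, "+")
  }
  structure(list(pos = pos, vel = matrix(0, n, 3), box = as.numeric(box),
                 topology = topology),
            class = "cc_config")
}

#' @export
print.cc_config <- function(x, ...) {
  cat("<cc_config> ", nrow(x$pos), " beads, box ",
      paste(round(x$box, 2), collapse = " x "), " nm\n", sep = "")
  invisible(x)
}

# --- internal deterministic RNG helpers (isolated from the global RNG) ----
local_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  env
}

runif_rng <- function(rng, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(rng$state)
  out <- stats::runif(n + 1)
  rng$state <- as.integer(floor(out[n + 1] * 2147483646)) + 1L
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  out[seq_len(n)]
}

chain_walk <- function(n, step, persistence, rng) {
  u <- matrix(runif_rng(rng, 3 * n), n, 3) - 0.5
  pos <- matrix(0, n, 3)
  dir <- c(1, 0, 0)
  for (i in 2:n) {
    dir <- persistence * dir + (1 - persistence) * u[i, ] /
      max(sqrt(sum(u[i, ]^2)), 1e-12)
    dir <- dir / sqrt(sum(dir^2))
    pos[i, ] <- pos[i - 1, ] + step * dir
  }
  pos
}

random_rotation <- function(rng) {
  # rotation from a random unit quaternion
  q <- stats::qnorm(pmin(pmax(runif_rng(rng, 4), 1e-12), 1 - 1e-12))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

chain_units <- function(topology) {
  comp <- topology$beads %>%
    dplyr::distinct(.data$chain, .data$component) %>%
    dplyr::arrange(.data$chain)
  k <- length(unique(comp$component))
  # single-component systems are packed as homodimeric pairs (the locally
  # equilibrated species), mirroring the pair packing of two-component
  # systems; odd copy counts fall back to single-chain units
  if (k == 1 && nrow(comp) %% 2 == 0) k <- 2
  split(comp$chain, ceiling(seq_along(comp$chain) / k))
}

unit_grid <- function(n_units, box) {
  # near-cubic grid cells filling the box
  nx <- max(1, round((n_units * box[1]^2 / (box[2] * box[3]))^(1 / 3)))
  ny <- max(1, round((n_units * box[2]^2 / (box[1] * box[3]))^(1 / 3)))
  nz <- ceiling(n_units / (nx * ny))
  pts <- expand.grid(
    x = (seq_len(nx) - 0.5) / nx * box[1],
    y = (seq_len(ny) - 0.5) / ny * box[2],
    z = (seq_len(nz) - 0.5) / nz * box[3]
  )
  as.matrix(pts[seq_len(n_units), , drop = FALSE])
}

#' Energy-minimize a configuration
#'
#' Steepest descent with adaptive step size and a displacement cap;
#' deterministic for given inputs. Terminates when the largest per-bead
#' force magnitude falls below `force_tol` or after `max_steps`.
#'
#' @param config A `cc_config`.
#' @param ff [forcefield_params()].
#' @param max_steps Maximum iterations.
#' @param force_tol Force tolerance, kJ/mol/nm.
#' @param max_disp Per-step displacement cap, nm.
#' @return The relaxed `cc_config`, with attributes `energy`, `max_force`,
#'   `converged`.
#' @export
minimize_config <- function(config, ff = forcefield_params(),
                            max_steps = 2000, force_tol = 50,
                            max_disp = 0.02) {
  stopifnot(inherits(config, "cc_config"))
  res <- cpp_minimize(config$pos, config$box, topo_cpp(config$topology),
                      unclass(ff), as.integer(max_steps), force_tol, max_disp)
  if (!is.finite(res$energy)) {
    rlang::abort("minimization produced a non-finite energy")
  }
  out <- config
  out$pos <- res$pos
  attr(out, "energy") <- res$energy
  attr(out, "max_force") <- res$max_force
  attr(out, "converged") <- res$converged
  out
}

#' Integrate Langevin dynamics
#'
#' BAOAB Langevin integration at the effective thermostat temperature
#' `kB * temperature * temperature_scale`. With `gamma = 0` the integrator
#' reduces to velocity Verlet (NVE). Trajectories are bitwise reproducible
#' for a given seed.
#'
#' @param config Starting `cc_config` (velocities drawn from the
#'   Maxwell-Boltzmann distribution if all zero and `gamma > 0`).
#' @param ff [forcefield_params()].
#' @param temperature Nominal temperature, K.
#' @param dt Time step, ps.
#' @param gamma Friction, 1/ps.
#' @param n_steps Number of steps.
#' @param save_interval Steps between saved frames.
#' @param seed Integer seed for the thermostat noise.
#' @param remove_com Remove centre-of-mass motion every 100 steps.
#' @return A `cc_traj`: `frames` array (n_frames x n_beads x 3, unwrapped),
#'   `times` (ps), `box`, `topology`, per-frame `pe`/`ke`, `final`
#'   (`cc_config`), and `meta` (temperature, gamma, dt, seed, kT).
#' @export
run_langevin <- function(config, ff = forcefield_params(), temperature = 310,
                         dt = 0.02, gamma = 1, n_steps = 10000,
                         save_interval = 100, seed = 1L, remove_com = TRUE) {
  stopifnot(inherits(config, "cc_config"), dt > 0, gamma >= 0,
            temperature > 0)
  kT <- kT_effective(temperature, ff)
  vel <- config$vel
  if (all(vel == 0) && gamma > 0) {
    rng <- local_rng(seed + 104729L)
    u <- pmin(pmax(runif_rng(rng, length(vel)), 1e-12), 1 - 1e-12)
    vel <- matrix(stats::qnorm(u) * sqrt(kT / ff$mass), nrow(vel), 3)
  }
  res <- cpp_langevin(config$pos, vel, config$box,
                      topo_cpp(config$topology), unclass(ff),
                      dt, gamma, kT, as.integer(n_steps),
                      as.integer(save_interval), as.numeric(seed),
                      if (remove_com) 100L else 0L, 0)
  if (res$blowup) {
    rlang::abort(paste0("dynamics blew up at step ", res$blowup_step,
                        " (per-step displacement exceeded half the box)"))
  }
  nf <- res$n_saved
  n <- nrow(config$pos)
  frames <- aperm(array(res$frames[seq_len(nf * n * 3)], c(3, n, nf)),
                  c(3, 2, 1))
  final <- config
  final$pos <- res$pos
  final$vel <- res$vel
  structure(
    list(frames = frames, times = res$times[seq_len(nf)], box = config$box,
         topology = config$topology,
         pe = res$pe[seq_len(nf)], ke = res$ke[seq_len(nf)], final = final,
         meta = list(temperature = temperature, gamma = gamma, dt = dt,
                     seed = seed, kT = kT, n_steps = n_steps,
                     save_interval = save_interval)),
    class = "cc_traj"
  )
}

#' @export
print.cc_traj <- function(x, ...) {
  cat("<cc_traj> ", dim(x$frames)[1], " frames x ", dim(x$frames)[2],
      " beads, ", max(x$times), " ps, T = ", x$meta$temperature, " K\n",
      sep = "")
  invisible(x)
}

#' Kinetic temperature of a trajectory
#'
#' Instantaneous kinetic temperatures on the nominal Kelvin scale
#' (i.e. divided by the force field's `temperature_scale`).
#'
#' @param traj A `cc_traj`.
#' @param ff The force field used to generate it.
#' @return Numeric vector, one value per saved frame.
#' @export
kinetic_temperature <- function(traj, ff = forcefield_params()) {
  n <- dim(traj$frames)[2]
  2 * traj$ke / (3 * n * KB * ff$temperature_scale)
}

#' Resize the simulation box along one axis
#'
#' Two modes: `"molecule"` rescales chain centres of mass affinely
#' (internal coordinates rigid; used during slab compression, with
#' re-equilibration between stages standing in for pressure coupling), and
#' `"box_only"` changes the box length leaving all coordinates fixed (used
#' for the slab expansion, which creates the vacuum region; bond lengths
#' are untouched by construction).
#'
#' @param config A `cc_config`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param scale Multiplicative factor for the box length (or give
#'   `target_length`).
#' @param target_length Absolute new box length in nm.
#' @param mode `"molecule"` or `"box_only"`.
#' @return The rescaled `cc_config`.
#' @export
resize_box <- function(config, axis = "z", scale = NULL, target_length = NULL,
                       mode = c("molecule", "box_only")) {
  stopifnot(inherits(config, "cc_config"))
  mode <- match.arg(mode)
  k <- match(axis, c("x", "y", "z"))
  if (is.na(k)) rlang::abort("axis must be x, y or z")
  if (is.null(scale)) {
    if (is.null(target_length)) rlang::abort("give scale or target_length")
    scale <- target_length / config$box[k]
  }
  if (scale <= 0) rlang::abort("scale must be positive")
  out <- config
  out$box[k] <- config$box[k] * scale
  if (mode == "molecule") {
    ch <- config$topology$beads$chain
    com <- rowsum(config$pos[, k], ch) / tabulate(ch)[sort(unique(ch))]
    shift <- (scale - 1) * com[ch]
    out$pos[, k] <- config$pos[, k] + shift
  }
  out
}

# ------------------------------------------------------------- XYZ I/O ----

#' Write a trajectory as extended XYZ
#'
#' Multi-frame extended XYZ; the comment line carries `Lattice=`,
#' `Properties=species:S:1:pos:R:3` and `Time=`. Bead species are the
#' segment names. Round-trips losslessly through [read_xyz()].
#'
#' @param traj A `cc_traj`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "cc_traj"))
  nf <- dim(traj$frames)[1]
  n <- dim(traj$frames)[2]
  species <- traj$topology$beads$segment_name
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    lat <- sprintf("%.10g 0 0 0 %.10g 0 0 0 %.10g",
                   traj$box[1], traj$box[2], traj$box[3])
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3 Time=%.10g', lat,
      traj$times[f]), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", species,
                       traj$frames[f, , 1], traj$frames[f, , 2],
                       traj$frames[f, , 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path File written by [write_xyz()].
#' @param topology Optional `cc_topology` to attach.
#' @return A `cc_traj` (without velocities or energies).
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  box <- NULL
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    latv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                                " ")[[1]])
    box <- latv[c(1, 5, 9)]
    tm <- regmatches(hdr, regexpr("Time=[-0-9.eE+]+", hdr))
    times <- c(times, as.numeric(sub("Time=", "", tm)))
    rows <- lines[(i + 2):(i + 1 + n)]
    mat <- do.call(rbind, strsplit(rows, " ", fixed = TRUE))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(mat[, 2:4]), n, 3)
    i <- i + 2 + n
  }
  nf <- length(frames)
  n <- nrow(frames[[1]])
  arr <- array(0, c(nf, n, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  structure(
    list(frames = arr, times = times, box = box, topology = topology,
         pe = rep(NA_real_, nf), ke = rep(NA_real_, nf), final = NULL,
         meta = list()),
    class = "cc_traj"
  )
}
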