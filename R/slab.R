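#' Slab phase-coexistence protocol parameters
#'
#' The slab workflow runs, in order: a single-unit stage (one copy of each
#' component, started from an idealized in-register side-by-side
#' construction and relaxed by dynamics, so that complementary chains enter
#' the slab as the pre-paired species single-molecule dynamics converges
#' to), packing of the box with rotated copies of the relaxed unit, energy
#' minimization, staged z-compression to the target bead density with
#' re-equilibration between stages (a deterministic stand-in for barostat
#' coupling), a z-expansion by `expansion_factor` leaving coordinates fixed
#' (creating the vacuum region), and NVT production.
#'
#' Two presets are provided. `"desk"` is the package's working scale
#' (tens of chains, 10^4-10^5 production steps, reduced friction so that
#' chain diffusion is observable within the run); `"full"` records the
#' original protocol durations (150 ns compression, 20 us production,
#' friction 1/ps) and is retained for completeness rather than routine use.
#'
#' @param scale `"desk"` or `"full"`.
#' @param ... Overrides of individual fields.
#' @return A `cc_protocol` list.
#' @export
slab_protocol <- function(scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  p <- if (scale == "desk") {
    list(
      scale = "desk",
      dt = 0.02,                 # ps
      gamma = 0.05,              # 1/ps; reduced friction, desk-scale mobility
      n_single_steps = 20000,
      packing_density = 1.0,     # beads/nm^3: packed directly at slab density
      target_density = 1.0,      # beads/nm^3 held through the NPT-analogue
      box_xy = 9,                # nm, cross-section of the slab
      pre_equil_steps = 2000,
      compression_stages = 1,
      compression_steps = 4000,  # density hold standing in for the NPT run
      expansion_factor = 10,
      production_steps = 120000,
      save_interval = 300,
      equilibrated_fraction = 0.5,
      replicates = 3
    )
  } else {
    list(
      scale = "full",
      dt = 0.02,
      gamma = 1,
      n_single_steps = 5e5,
      packing_density = 0.25,
      target_density = 1.0,
      box_xy = 15,
      pre_equil_steps = 1e5,
      compression_stages = 10,
      compression_steps = 750000,   # 10 x 15 ns = 150 ns compression
      expansion_factor = 10,
      production_steps = 1e9,       # 20 us at dt = 0.02 ps
      save_interval = 1e5,
      equilibrated_fraction = 0.5,
      replicates = 3
    )
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown protocol field '", unknown[1], "'"))
  }
  p[names(dots)] <- dots
  stopifnot(p$expansion_factor > 1, p$replicates >= 1)
  structure(p, class = "cc_protocol")
}

#' Run the slab phase-coexistence workflow
#'
#' Executes the full protocol for one or more replicate seeds and returns
#' the production trajectory of each replicate together with stage
#' provenance. Chain and bead counts are conserved across all stages.
#'
#' @param system A `cc_system` (box, if `NULL`, is sized from the bead
#'   count: cross-section `box_xy^2`, packing length from
#'   `packing_density`).
#' @param protocol A `cc_protocol`.
#' @param seeds Integer vector, one production replicate per seed.
#' @param temperature Nominal temperature in K (default: the system's).
#' @param ff [forcefield_params()].
#' @param verbose Print stage progress.
#' @return A `cc_slab_result`: list with `replicates` (list of production
#'   `cc_traj`), `system`, `protocol`, `temperature`, `stages` (tibble of
#'   stage metadata per replicate).
#' @export
run_slab <- function(system, protocol = slab_protocol(), seeds = NULL,
                     temperature = NULL, ff = forcefield_params(),
                     verbose = FALSE) {
  stopifnot(inherits(system, "cc_system"), inherits(protocol, "cc_protocol"))
  if (is.null(seeds)) seeds <- system$seed
  if (is.null(temperature)) temperature <- system$temperature
  topo <- system_topology(system)
  n <- topo$n_beads

  box_xy <- protocol$box_xy
  z_pack <- n / (protocol$packing_density * box_xy^2)
  z_slab <- n / (protocol$target_density * box_xy^2)
  box_pack <- c(box_xy, box_xy, max(z_pack, z_slab))

  say <- function(...) if (verbose) message(sprintf(...))
  replicates <- list()
  stages <- list()

  for (r in seq_along(seeds)) {
    seed <- as.integer(seeds[r])
    t_stage <- function(nm) stages[[length(stages) + 1]] <<-
      tibble::tibble(replicate = r, seed = seed, stage = nm,
                     n_beads = n, n_chains = topo$n_chains)

    # 1. single-unit stage: one copy of every component, built as straight
    # in-register side-by-side chains (the zipped state that long
    # single-molecule dynamics converges to), then relaxed by MD. Matched
    # arrangements close all their coils here; mismatched arrangements are
    # left with free valences by the designs themselves.
    say("replicate %d: single-unit stage", r)
    unit_copies <- if (length(system$components) == 1 &&
                       system$copies[1] %% 2 == 0) 2L else 1L
    unit_sys <- build_system(system$components, copies = unit_copies,
                             temperature = temperature, seed = seed)
    unit_topo <- system_topology(unit_sys)
    span <- 0.38 * max(tabulate(unit_topo$beads$chain)) + 6
    ucfg <- straight_unit_config(unit_topo, rep(span, 3))
    ucfg <- minimize_config(ucfg, ff)
    utrj <- run_langevin(ucfg, ff, temperature, dt = protocol$dt,
                         gamma = protocol$gamma,
                         n_steps = protocol$n_single_steps,
                         save_interval = max(protocol$n_single_steps, 1),
                         seed = seed * 7L + 1L)
    unit_pos <- utrj$final$pos
    t_stage("single_unit")

    # 2. pack rotated copies of the relaxed unit
    say("replicate %d: packing %d chains", r, topo$n_chains)
    cfg <- pack_units(topo, unit_topo, unit_pos, box_pack, seed * 11L + 3L)
    t_stage("packing")

    # 3. minimize
    cfg <- minimize_config(cfg, ff)
    t_stage("minimize")

    # 4. pre-equilibration + staged compression to the slab density
    trj <- run_langevin(cfg, ff, temperature, dt = protocol$dt,
                        gamma = protocol$gamma,
                        n_steps = protocol$pre_equil_steps,
                        save_interval = max(protocol$pre_equil_steps, 1),
                        seed = seed * 13L + 5L)
    cfg <- trj$final
    fac <- (z_slab / cfg$box[3])^(1 / protocol$compression_stages)
    for (st in seq_len(protocol$compression_stages)) {
      cfg <- resize_box(cfg, "z", scale = fac, mode = "molecule")
      cfg <- minimize_config(cfg, ff, max_steps = 300)
      trj <- run_langevin(cfg, ff, temperature, dt = protocol$dt,
                          gamma = protocol$gamma,
                          n_steps = protocol$compression_steps,
                          save_interval = max(protocol$compression_steps, 1),
                          seed = seed * 17L + st)
      cfg <- trj$final
    }
    t_stage("compression")

    # 5. expansion: box only, coordinates fixed
    cfg <- resize_box(cfg, "z", scale = protocol$expansion_factor,
                      mode = "box_only")
    t_stage("expansion")

    # 6. production
    say("replicate %d: production (%d steps)", r, protocol$production_steps)
    prod <- run_langevin(cfg, ff, temperature, dt = protocol$dt,
                         gamma = protocol$gamma,
                         n_steps = protocol$production_steps,
                         save_interval = protocol$save_interval,
                         seed = seed * 19L + 7L)
    prod$meta$scale <- protocol$scale
    prod$meta$replicate <- r
    prod$meta$stage_seed <- seed
    replicates[[r]] <- prod
    t_stage("production")
  }

  structure(
    list(replicates = replicates, system = system, protocol = protocol,
         temperature = temperature, ff = ff,
         stages = dplyr::bind_rows(stages)),
    class = "cc_slab_result"
  )
}

#' @export
print.cc_slab_result <- function(x, ...) {
  cat("<cc_slab_result> ", length(x$replicates), " replicate(s), T = ",
      x$temperature, " K, scale = ", x$protocol$scale, "\n", sep = "")
  invisible(x)
}

# idealized unit start: every chain laid straight along x at the C-alpha
# spacing, chains stacked 0.75 nm apart in y, N termini aligned; puts
# complementary coils of a unit in register and parallel
straight_unit_config <- function(topo, box) {
  b <- topo$beads
  pos <- matrix(0, nrow(b), 3)
  for (ch in sort(unique(b$chain))) {
    idx <- which(b$chain == ch)
    pos[idx, 1] <- (seq_along(idx) - 1) * 0.38
    pos[idx, 2] <- (ch - 1) * 0.75
  }
  pos <- sweep(pos, 2, colMeans(pos))
  pos <- sweep(pos, 2, box / 2, "+")
  structure(list(pos = pos, vel = matrix(0, nrow(pos), 3),
                 box = as.numeric(box), topology = topo),
            class = "cc_config")
}

# place rotated copies of the relaxed unit on a grid in the packing box
pack_units <- function(topo, unit_topo, unit_pos, box, seed) {
  rng <- local_rng(seed)
  units <- chain_units(topo)
  n_units <- length(units)
  grid <- unit_grid(n_units, box)
  pos <- matrix(0, topo$n_beads, 3)
  ucom <- colMeans(unit_pos)
  centered <- sweep(unit_pos, 2, ucom)
  for (u in seq_len(n_units)) {
    idx <- which(topo$beads$chain %in% units[[u]])
    rot <- random_rotation(rng)
    jit <- (runif_rng(rng, 3) - 0.5) * 0.4
    pos[idx, ] <- centered %*% t(rot)
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, grid[u, ] + jit, "+")
  }
  structure(list(pos = pos, vel = matrix(0, topo$n_beads, 3),
                 box = as.numeric(box), topology = topo),
            class = "cc_config")
}

#' Estimate the dimer dissociation constant of a coil pair
#'
#' Places exactly two single-coil chains in a cubic box and measures the
#' bound-state occupancy theta (a frame counts as bound when at least half
#' of the first coil's beads are within the contact cutoff of
#' registry-complementary beads of the second). With one molecule of each
#' species at box concentration `C = 1/(NA V)`, `Kd = (1 - theta)^2 * C /
#' theta`. The confidence interval comes from block averaging (5 blocks).
#' Trajectories that never or always show the bound state are flagged
#' out-of-range and carry no point estimate.
#'
#' @param pair Character length-2, coil type names (e.g. `c("S1h","S2h")`).
#' @param box_length Cubic box edge, nm.
#' @param temperature Nominal temperature, K.
#' @param n_steps Production steps per seed.
#' @param seeds Integer seeds; frames are pooled over seeds (binding events
#'   are rare enough that several independent runs stabilize the occupancy
#'   estimate).
#' @param ff [forcefield_params()].
#' @param contact_cutoff Contact distance, nm (default `1.5 * sigma_sticky`).
#' @param dt,gamma,save_interval Integration settings (low friction speeds
#'   up the binding/unbinding kinetics without changing the equilibrium).
#' @param matrix Interaction matrix.
#' @return A tibble with `pair`, `theta`, `kd_molar`, `kd_lo`, `kd_hi`,
#'   `flag` (`"ok"`, `"never_bound"` or `"always_bound"`), `n_frames`.
#' @export
estimate_dimer_kd <- function(pair, box_length = 12, temperature = 310,
                              n_steps = 1000000, seeds = 1:3,
                              ff = forcefield_params(),
                              contact_cutoff = NULL, dt = 0.02, gamma = 0.1,
                              save_interval = 100,
                              matrix = interaction_matrix()) {
  stopifnot(length(pair) == 2)
  if (is.null(contact_cutoff)) contact_cutoff <- 1.5 * ff$sigma_sticky
  box <- rep(box_length, 3)
  bound <- c()
  for (seed in as.integer(seeds)) {
    sys <- build_system(as.list(paste0("(", pair, ")1")),
                        temperature = temperature, seed = seed)
    topo <- system_topology(sys, matrix = matrix)
    if (topo$n_chains != 2) rlang::abort("expected exactly two chains")
    cfg <- initial_config(topo, box, seed = seed)
    cfg <- minimize_config(cfg, ff)
    trj <- run_langevin(cfg, ff, temperature, dt = dt, gamma = gamma,
                        n_steps = n_steps, save_interval = save_interval,
                        seed = seed * 23L + 11L)
    # equilibrated window: drop the first 10%
    bf <- bound_frames(trj, contact_cutoff)
    nf <- length(bf)
    bound <- c(bound, bf[seq(floor(nf * 0.1) + 1, nf)])
  }
  theta <- mean(bound)
  conc <- 1 / (NAVO * prod(box) * 1e-24)  # molar; nm^3 -> L
  flag <- if (theta == 0) "never_bound" else if (theta == 1) "always_bound"
          else "ok"
  kd <- if (flag == "ok") (1 - theta)^2 * conc / theta else NA_real_
  # block averaging on theta
  blocks <- split(bound, cut(seq_along(bound), 5, labels = FALSE))
  th_b <- vapply(blocks, mean, 0)
  th_se <- stats::sd(th_b) / sqrt(length(th_b))
  th_lo <- max(min(th_b), theta - 2 * th_se, 1 / length(bound))
  th_hi <- min(max(th_b), theta + 2 * th_se, 1 - 1 / length(bound))
  kd_of <- function(th) (1 - th)^2 * conc / th
  tibble::tibble(
    pair = paste(pair, collapse = ":"),
    theta = theta,
    kd_molar = kd,
    kd_lo = if (flag == "ok") kd_of(th_hi) else NA_real_,
    kd_hi = if (flag == "ok") kd_of(th_lo) else NA_real_,
    flag = flag,
    n_frames = length(bound),
    box_conc_molar = conc,
    temperature = temperature
  )
}

# frames in which chain 1's coil is engaged with chain 2's (>= half beads)
bound_frames <- function(traj, contact_cutoff) {
  cm <- traj_contacts(traj, contact_cutoff)
  segs <- traj$topology$segments
  coilsegs <- segs$segment[segs$class == "coil"]
  L <- segs$coil_len[segs$class == "coil"][1]
  nf <- dim(traj$frames)[1]
  bound <- rep(FALSE, nf)
  if (nrow(cm) > 0) {
    hits <- cm[cm[, "seg_a"] %in% coilsegs & cm[, "seg_b"] %in% coilsegs &
                 cm[, "n_contact"] >= ceiling(L / 2), , drop = FALSE]
    bound[unique(hits[, "frame"])] <- TRUE
  }
  bound
}

#' Printed dimer-affinity calibration targets
#'
#' Experimentally measured (ITC) dissociation constants of the designed
#' coil pairs, used to anchor the simulation temperature scale.
#'
#' @return A tibble with `pair`, `kd_molar`, `kd_sd_molar`.
#' @export
calibration_targets <- function() {
  tibble::tibble(
    pair = c("P5f:P6f", "P13f:P14f", "S1h:S2h", "S3h:S4h"),
    kd_molar = c(5.9e-6, 2.3e-6, 2.3e-3, 0.34e-3),
    kd_sd_molar = c(0.5e-6, 0.2e-6, 1.5e-3, 0.07e-3)
  )
}

#' Calibrate the simulation temperature scale against dimer affinities
#'
#' For each target coil pair, estimates the simulated dissociation constant
#' over a grid of nominal temperatures and reports the grid temperature
#' whose estimate is closest to the experimental value in log space,
#' together with the residual. The mapping is approximate by construction;
#' no exact correspondence is claimed.
#'
#' @param targets Tibble as from [calibration_targets()].
#' @param temperatures Numeric temperature grid, K.
#' @param estimator Function `(pair, temperature, seed)` returning a tibble
#'   like [estimate_dimer_kd()]; injectable for testing. The default runs
#'   [estimate_dimer_kd()] with the remaining arguments.
#' @param seed Integer seed.
#' @param ... Passed to [estimate_dimer_kd()].
#' @return A tibble with one row per target: `pair`, `kd_molar`
#'   (experimental), `best_temperature`, `kd_sim_molar`, `log10_residual`,
#'   plus a `grid` list-column of all grid estimates.
#' @export
calibrate_temperature_scale <- function(targets = calibration_targets(),
                                        temperatures = c(280, 298, 310, 325),
                                        estimator = NULL, seed = 1L, ...) {
  stopifnot(nrow(targets) >= 1)
  if (length(temperatures) == 0) rlang::abort("empty temperature grid")
  if (is.null(estimator)) {
    estimator <- function(pair, temperature, seed) {
      estimate_dimer_kd(pair, temperature = temperature, seeds = seed, ...)
    }
  }
  purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    pr <- strsplit(targets$pair[i], ":", fixed = TRUE)[[1]]
    grid <- purrr::map_dfr(temperatures, function(tt) {
      est <- estimator(pr, tt, seed)
      est$grid_temperature <- tt
      est
    })
    ok <- grid[grid$flag == "ok" & is.finite(grid$kd_molar), , drop = FALSE]
    if (nrow(ok) == 0) {
      return(tibble::tibble(
        pair = targets$pair[i], kd_molar = targets$kd_molar[i],
        best_temperature = NA_real_, kd_sim_molar = NA_real_,
        log10_residual = NA_real_, status = "out_of_range",
        grid = list(grid)
      ))
    }
    res <- abs(log10(ok$kd_molar) - log10(targets$kd_molar[i]))
    j <- which.min(res)
    tibble::tibble(
      pair = targets$pair[i], kd_molar = targets$kd_molar[i],
      best_temperature = ok$grid_temperature[j],
      kd_sim_molar = ok$kd_molar[j],
      log10_residual = log10(ok$kd_molar[j]) - log10(targets$kd_molar[i]),
      status = "ok",
      grid = list(grid)
    )
  })
}
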