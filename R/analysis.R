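#' Chain centre-of-mass trajectory
#'
#' Per-frame centres of mass of every chain (uniform bead mass).
#' Coordinates are unwrapped by construction, so the result is directly
#' usable for displacement analysis.
#'
#' @param traj A `cc_traj`.
#' @return Array `n_frames x n_chains x 3`.
#' @export
chain_com <- function(traj) {
  ch <- traj$topology$beads$chain
  nch <- max(ch)
  counts <- tabulate(ch, nch)
  nf <- dim(traj$frames)[1]
  out <- array(0, c(nf, nch, 3))
  for (k in 1:3) {
    out[, , k] <- t(rowsum(t(traj$frames[, , k, drop = FALSE][, , 1]),
                           ch) / counts)
  }
  out
}

# equilibrated frame indices (default: final 50%)
equilibrated_window <- function(traj, fraction = 0.5, window = NULL) {
  nf <- dim(traj$frames)[1]
  if (!is.null(window)) {
    window <- window[window >= 1 & window <= nf]
    if (length(window) == 0) rlang::abort("empty equilibrated window")
    return(window)
  }
  seq(floor(nf * (1 - fraction)) + 1, nf)
}

#' Molecule number density profile along z
#'
#' Histogram of chain centres of mass along z, computed per frame on
#' wrapped coordinates, re-centred per frame on the circular mean of the
#' chain positions (the dense slab's centre) and averaged. The integral of
#' the profile times the bin volume recovers the chain count.
#'
#' Dense- and dilute-phase estimates: bins at or above half the (smoothed)
#' maximum form the dense region; bins outside that region, expanded by a
#' two-bin margin, form the dilute region.
#'
#' @param traj A `cc_traj`.
#' @param window Frame indices to use (default: final 50%).
#' @param n_bins Number of z bins.
#' @return A `cc_density_profile`: tibble of `z` (bin centres, nm, slab
#'   centre at 0) and `density` (chains/nm^3), with attributes
#'   `dense_density`, `dilute_density`, `contrast`, `n_chains`,
#'   `bin_volume`.
#' @export
density_profile <- function(traj, window = NULL, n_bins = 60) {
  frames <- equilibrated_window(traj, window = window)
  if (length(frames) < 10) rlang::abort("need at least 10 equilibrated frames")
  com <- chain_com(traj)
  lz <- traj$box[3]
  binw <- lz / n_bins
  vol_bin <- traj$box[1] * traj$box[2] * binw
  counts <- matrix(0, length(frames), n_bins)
  for (fi in seq_along(frames)) {
    z <- com[frames[fi], , 3] %% lz
    ang <- 2 * pi * z / lz
    sbar <- mean(sin(ang)); cbar <- mean(cos(ang))
    # mean resultant length: near 1 for a slab, ~n^-1/2 for a uniform gas;
    # recentre only when a dense region actually exists, so a uniform
    # system is not folded onto its own fluctuations
    if (sqrt(sbar^2 + cbar^2) > 0.5) {
      centre <- atan2(sbar, cbar) * lz / (2 * pi)
    } else {
      centre <- lz / 2
    }
    zc <- ((z - centre + lz / 2) %% lz)      # slab centre at lz/2
    bins <- pmin(floor(zc / binw) + 1, n_bins)
    counts[fi, ] <- tabulate(bins, n_bins)
  }
  dens <- colMeans(counts) / vol_bin
  sm <- stats::filter(c(dens[n_bins], dens, dens[1]), rep(1 / 3, 3))[
    2:(n_bins + 1)]
  dense_mask <- sm >= 0.5 * max(sm)
  margin <- dense_mask
  for (s in c(-2, -1, 1, 2)) {
    margin <- margin | dense_mask[((seq_len(n_bins) - 1 + s) %% n_bins) + 1]
  }
  dense <- mean(dens[dense_mask])
  dilute <- if (all(margin)) dense else mean(dens[!margin])
  nch <- dim(com)[2]
  floor_d <- 0.5 / (traj$box[1] * traj$box[2] * lz)  # half a chain per box
  out <- tibble::tibble(z = (seq_len(n_bins) - 0.5) * binw - lz / 2,
                        density = dens)
  structure(out, class = c("cc_density_profile", class(out)),
            dense_density = dense, dilute_density = dilute,
            contrast = dense / max(dilute, floor_d),
            n_chains = nch, bin_volume = vol_bin, n_frames = length(frames))
}

# segment-pair complementary contact counts for every frame
traj_contacts <- function(traj, contact_cutoff) {
  if (contact_cutoff <= 0) rlang::abort("contact cutoff must be positive")
  nf <- dim(traj$frames)[1]
  n <- dim(traj$frames)[2]
  flat <- as.numeric(aperm(traj$frames, c(3, 2, 1)))
  cpp_traj_contacts(flat, nf, n, traj$box, topo_cpp(traj$topology),
                    contact_cutoff)
}

#' Molecular cluster-size distribution
#'
#' Two chains are connected in a frame when a coiled-coil crosslink joins
#' them; clusters are the connected components of that graph. With the
#' default `edge = "engaged"`, a crosslink requires at least half the beads
#' of one coil to sit within `contact_cutoff` of registry-complementary
#' beads of a partner coil on the other chain (a formed CC dimer
#' interface); `edge = "any"` counts a single complementary bead contact as
#' a link (more permissive; transient single-bead encounters then bridge
#' otherwise separate molecules). Reports the per-frame size distribution,
#' the dominant species per frame (the cluster-size class holding the
#' plurality of chains, ties broken toward the larger size), the
#' dimer-dominance fraction (fraction of frames whose dominant species is
#' the size-2 cluster) and the mean largest-cluster mass fraction.
#'
#' @param traj A `cc_traj`.
#' @param contact_cutoff Contact distance, nm (default `1.5 *
#'   sigma_sticky`).
#' @param window Frame indices (default: final 50%).
#' @param edge `"engaged"` (default) or `"any"`: the crosslink criterion.
#' @return A `cc_cluster_report`: `per_frame` tibble (`frame`, `largest`,
#'   `largest_fraction`, `dominant_size`, `n_clusters`), `sizes` tibble
#'   (`size`, `n`, weight over all frames), and scalars `dimer_dominance`,
#'   `largest_cluster_fraction`, `n_chains`.
#' @export
cluster_distribution <- function(traj, contact_cutoff = NULL, window = NULL,
                                 edge = c("engaged", "any")) {
  if (is.null(contact_cutoff)) {
    contact_cutoff <- 1.5 * forcefield_params()$sigma_sticky
  }
  edge <- match.arg(edge)
  frames <- equilibrated_window(traj, window = window)
  cm <- traj_contacts(traj, contact_cutoff)
  if (edge == "engaged") {
    L <- traj$topology$segments$coil_len[cm[, "seg_a"]]
    cm <- cm[cm[, "n_contact"] >= ceiling(L / 2), , drop = FALSE]
  }
  seg2chain <- traj$topology$segments$chain
  nch <- traj$topology$n_chains

  per_frame <- vector("list", length(frames))
  size_tab <- list()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- cm[cm[, "frame"] == f, , drop = FALSE]
    ca <- seg2chain[rows[, "seg_a"]]
    cb <- seg2chain[rows[, "seg_b"]]
    keep <- ca != cb
    labels <- union_find(nch, ca[keep], cb[keep])
    sizes <- tabulate(labels, nch)
    sizes <- sizes[sizes > 0]
    # dominant species: size class with the plurality of chains
    mass_by_size <- tapply(sizes, sizes, sum)
    best <- max(mass_by_size)
    dominant <- max(as.integer(names(mass_by_size)[mass_by_size == best]))
    per_frame[[fi]] <- tibble::tibble(
      frame = f, largest = max(sizes),
      largest_fraction = max(sizes) / nch,
      dominant_size = dominant, n_clusters = length(sizes)
    )
    size_tab[[fi]] <- sizes
  }
  per_frame <- dplyr::bind_rows(per_frame)
  all_sizes <- unlist(size_tab)
  sizes <- tibble::as_tibble(table(size = all_sizes)) %>%
    dplyr::mutate(size = as.integer(.data$size),
                  weight = .data$size * .data$n /
                    (nch * length(frames)))
  structure(
    list(per_frame = per_frame, sizes = sizes,
         dimer_dominance = mean(per_frame$dominant_size == 2),
         largest_cluster_fraction = mean(per_frame$largest_fraction),
         n_chains = nch, contact_cutoff = contact_cutoff,
         n_frames = length(frames)),
    class = "cc_cluster_report"
  )
}

#' @export
print.cc_cluster_report <- function(x, ...) {
  cat("<cc_cluster_report> ", x$n_frames, " frames, ", x$n_chains,
      " chains\n  dimer dominance ", round(x$dimer_dominance, 3),
      ", largest-cluster fraction ", round(x$largest_cluster_fraction, 3),
      "\n", sep = "")
  invisible(x)
}

union_find <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, 1L)
}

#' Classify the phase of a simulated system
#'
#' Labels a run `condensate` when the dense/dilute density contrast is at
#' least `r_min` and the mean largest-cluster mass fraction is at least
#' `f_min` (nearly all chains in one cluster); otherwise `dimer` when the
#' dimer-dominance fraction is at least `d_min`; otherwise `diffuse`.
#'
#' @param density A `cc_density_profile`.
#' @param clusters A `cc_cluster_report` from the same equilibrated window.
#' @param r_min,f_min,d_min Declared thresholds.
#' @return A `cc_phase_call`: list with `label` and an `evidence` tibble.
#' @export
classify_phase <- function(density, clusters, r_min = 5, f_min = 0.8,
                           d_min = 0.5) {
  contrast <- attr(density, "contrast")
  lcf <- clusters$largest_cluster_fraction
  dd <- clusters$dimer_dominance
  label <- if (contrast >= r_min && lcf >= f_min) {
    "condensate"
  } else if (dd >= d_min) {
    "dimer"
  } else {
    "diffuse"
  }
  structure(
    list(label = label,
         evidence = tibble::tibble(
           density_contrast = contrast,
           largest_cluster_fraction = lcf,
           dimer_dominance = dd,
           r_min = r_min, f_min = f_min, d_min = d_min
         )),
    class = "cc_phase_call"
  )
}

#' @export
print.cc_phase_call <- function(x, ...) {
  ev <- x$evidence
  cat("<cc_phase_call> ", x$label,
      sprintf(" (contrast %.2f, largest fraction %.2f, dimer dominance %.2f)",
              ev$density_contrast, ev$largest_cluster_fraction,
              ev$dimer_dominance), "\n", sep = "")
  invisible(x)
}

#' Effective diffusion from mean squared displacement
#'
#' Chain centre-of-mass MSD averaged over all time origins and chains,
#' fitted linearly over the lag window 10-50% of the maximum lag;
#' `D = slope / 6`, converted to cm^2/s. The standard deviation comes from
#' bootstrap resampling of chains. A fit with R^2 below 0.9 is flagged
#' subdiffusive (D is still reported); negative fitted slopes are clamped
#' to zero.
#'
#' @param traj A `cc_traj`.
#' @param window Frame indices (default: final 50%).
#' @param n_bootstrap Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param chains Optional chain indices to restrict the analysis to (e.g.
#'   [droplet_chains()] for the mobility of chains inside the dense
#'   phase); default all chains.
#' @param relative Measure displacements relative to the per-frame centre
#'   of mass of the selected chains. For small simulated droplets the
#'   collective drift of the droplet dominates absolute chain MSD; the
#'   relative MSD isolates mobility *within* the droplet, which is the
#'   quantity that distinguishes liquid from frozen condensates.
#' @return A `cc_diffusion`: list with `D_cm2_s`, `D_sd`, `msd` tibble
#'   (`lag_ps`, `msd_nm2`), `fit` (slope, intercept, r_squared),
#'   `subdiffusive` flag.
#' @export
msd_diffusion <- function(traj, window = NULL, n_bootstrap = 200, seed = 1L,
                          chains = NULL, relative = FALSE) {
  frames <- equilibrated_window(traj, window = window)
  if (length(frames) < 20) rlang::abort("need at least 20 frames for MSD")
  com <- chain_com(traj)[frames, , , drop = FALSE]
  if (!is.null(chains)) {
    if (length(chains) < 2) rlang::abort("need at least 2 chains for MSD")
    com <- com[, chains, , drop = FALSE]
  }
  if (relative) {
    for (k in 1:3) {
      mk <- com[, , k, drop = FALSE][, , 1]
      if (is.null(dim(mk))) mk <- matrix(mk, dim(com)[1], dim(com)[2])
      com[, , k] <- mk - rowMeans(mk)
    }
  }
  times <- traj$times[frames]
  nf <- length(frames)
  nch <- dim(com)[2]
  max_lag <- nf - 1
  lags <- seq_len(max_lag)

  # per-chain MSD(lag) averaged over origins
  msd_chain <- matrix(0, max_lag, nch)
  cx <- com[, , 1, drop = FALSE][, , 1]
  cy <- com[, , 2, drop = FALSE][, , 1]
  cz <- com[, , 3, drop = FALSE][, , 1]
  if (is.null(dim(cx))) {
    cx <- matrix(cx, nf, nch); cy <- matrix(cy, nf, nch)
    cz <- matrix(cz, nf, nch)
  }
  for (lag in lags) {
    i2 <- (1 + lag):nf
    i1 <- 1:(nf - lag)
    d2 <- (cx[i2, , drop = FALSE] - cx[i1, , drop = FALSE])^2 +
      (cy[i2, , drop = FALSE] - cy[i1, , drop = FALSE])^2 +
      (cz[i2, , drop = FALSE] - cz[i1, , drop = FALSE])^2
    msd_chain[lag, ] <- colMeans(d2)
  }
  lag_ps <- times[1 + lags] - times[1]
  fit_window <- lags >= max(1, floor(0.1 * max_lag)) &
    lags <= ceiling(0.5 * max_lag)

  fit_D <- function(msd_vec) {
    fit <- stats::lm(msd_vec[fit_window] ~ lag_ps[fit_window])
    slope <- unname(coef(fit)[2])
    r2 <- summary(fit)$r.squared
    list(slope = slope, intercept = unname(coef(fit)[1]), r2 = r2)
  }
  msd_mean <- rowMeans(msd_chain)
  f <- fit_D(msd_mean)
  D <- max(f$slope / 6, 0) * 1e-2  # nm^2/ps -> cm^2/s

  rng <- local_rng(seed)
  boots <- vapply(seq_len(n_bootstrap), function(b) {
    pick <- ceiling(runif_rng(rng, nch) * nch)
    fb <- fit_D(rowMeans(msd_chain[, pick, drop = FALSE]))
    max(fb$slope / 6, 0) * 1e-2
  }, 0)

  structure(
    list(D_cm2_s = D, D_sd = stats::sd(boots),
         msd = tibble::tibble(lag_ps = lag_ps, msd_nm2 = msd_mean),
         fit = list(slope = f$slope, intercept = f$intercept,
                    r_squared = f$r2),
         subdiffusive = is.na(f$r2) || f$r2 < 0.9,
         n_chains = nch, n_frames = nf, n_bootstrap = n_bootstrap),
    class = "cc_diffusion"
  )
}

#' @export
print.cc_diffusion <- function(x, ...) {
  cat(sprintf("<cc_diffusion> D = %.3g +/- %.2g cm^2/s (R^2 %.3f%s)\n",
              x$D_cm2_s, x$D_sd, x$fit$r_squared,
              if (x$subdiffusive) ", subdiffusive" else ""))
  invisible(x)
}

#' Coil engagement statistics
#'
#' A coil is engaged in a frame when at least half of its beads are within
#' `contact_cutoff` of registry-complementary beads of a single partner
#' coil. Reports the engaged-time fraction over the equilibrated window
#' and the number of distinct partner coils per coil.
#'
#' @param traj A `cc_traj`.
#' @param contact_cutoff Contact distance, nm (default `1.5 *
#'   sigma_sticky`).
#' @param window Frame indices (default: final 50%).
#' @return A tibble with one row per coil segment: `segment`, `chain`,
#'   `coil_type`, `engaged_fraction`, `unique_partners`.
#' @export
coil_engagement <- function(traj, contact_cutoff = NULL, window = NULL) {
  if (is.null(contact_cutoff)) {
    contact_cutoff <- 1.5 * forcefield_params()$sigma_sticky
  }
  frames <- equilibrated_window(traj, window = window)
  cm <- traj_contacts(traj, contact_cutoff)
  cm <- cm[cm[, "frame"] %in% frames, , drop = FALSE]
  segs <- traj$topology$segments
  coil <- segs[segs$class == "coil", ]

  eng <- tibble::tibble(
    frame = cm[, "frame"], seg_a = cm[, "seg_a"], seg_b = cm[, "seg_b"],
    n_contact = cm[, "n_contact"]
  ) %>%
    dplyr::left_join(
      tibble::tibble(seg_a = coil$segment, L = coil$coil_len),
      by = "seg_a"
    ) %>%
    dplyr::filter(.data$n_contact >= ceiling(.data$L / 2))

  summ <- eng %>%
    dplyr::group_by(.data$seg_a) %>%
    dplyr::summarise(engaged_frames = dplyr::n_distinct(.data$frame),
                     unique_partners = dplyr::n_distinct(.data$seg_b),
                     .groups = "drop")

  coil %>%
    dplyr::transmute(segment = .data$segment, chain = .data$chain,
                     coil_type = .data$name) %>%
    dplyr::left_join(summ, by = c(segment = "seg_a")) %>%
    dplyr::mutate(
      engaged_fraction = dplyr::coalesce(.data$engaged_frames, 0L) /
        length(frames),
      unique_partners = dplyr::coalesce(.data$unique_partners, 0L)
    ) %>%
    dplyr::select(-"engaged_frames")
}

#' Analyze a slab run and call the phase
#'
#' Runs the density-profile, cluster and (optionally) diffusion analyses on
#' each production replicate of a slab result and combines replicate phase
#' calls by majority vote (ties resolved toward the non-condensate label).
#'
#' @param slab A `cc_slab_result`.
#' @param r_min,f_min,d_min Thresholds for [classify_phase()].
#' @param diffusion Also compute [msd_diffusion()] per replicate.
#' @param n_bins Bins for the density profile.
#' @return A `cc_phase_summary`: list with `label` (majority), `calls`
#'   (tibble of per-replicate evidence), and `replicates` (list of
#'   per-replicate analysis objects).
#' @export
analyze_slab <- function(slab, r_min = 5, f_min = 0.8, d_min = 0.5,
                         diffusion = FALSE, n_bins = 60) {
  stopifnot(inherits(slab, "cc_slab_result"))
  per <- purrr::map(seq_along(slab$replicates), function(r) {
    trj <- slab$replicates[[r]]
    dens <- density_profile(trj, n_bins = n_bins)
    clus <- cluster_distribution(trj)
    call <- classify_phase(dens, clus, r_min, f_min, d_min)
    dif <- if (diffusion) msd_diffusion(trj, seed = r) else NULL
    list(density = dens, clusters = clus, call = call, diffusion = dif)
  })
  calls <- purrr::map_dfr(seq_along(per), function(r) {
    ev <- per[[r]]$call$evidence
    tibble::tibble(replicate = r, label = per[[r]]$call$label,
                   density_contrast = ev$density_contrast,
                   largest_cluster_fraction = ev$largest_cluster_fraction,
                   dimer_dominance = ev$dimer_dominance,
                   D_cm2_s = if (!is.null(per[[r]]$diffusion))
                     per[[r]]$diffusion$D_cm2_s else NA_real_)
  })
  tab <- sort(table(calls$label), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  label <- if (length(top) == 1) top else
    if (any(top != "condensate")) setdiff(top, "condensate")[1] else top[1]
  structure(list(label = label, calls = calls, replicates = per),
            class = "cc_phase_summary")
}

#' @export
print.cc_phase_summary <- function(x, ...) {
  cat("<cc_phase_summary> majority label: ", x$label, " (",
      paste(x$calls$label, collapse = ", "), ")\n", sep = "")
  invisible(x)
}


#' Chains belonging to the dense cluster
#'
#' Identifies the chains that sit in the largest molecular cluster in at
#' least `fraction` of the equilibrated frames — the chains whose mobility
#' characterizes the droplet interior rather than the dilute phase.
#'
#' @param traj A `cc_traj`.
#' @param window Frame indices (default: final 50%).
#' @param fraction Minimum fraction of frames a chain must spend in the
#'   largest cluster.
#' @param contact_cutoff Contact distance, nm (default `1.5 *
#'   sigma_sticky`).
#' @return Integer chain indices (all chains if none qualify).
#' @export
droplet_chains <- function(traj, window = NULL, fraction = 0.5,
                           contact_cutoff = NULL) {
  if (is.null(contact_cutoff)) {
    contact_cutoff <- 1.5 * forcefield_params()$sigma_sticky
  }
  frames <- equilibrated_window(traj, window = window)
  cm <- traj_contacts(traj, contact_cutoff)
  L <- traj$topology$segments$coil_len[cm[, "seg_a"]]
  cm <- cm[cm[, "n_contact"] >= ceiling(L / 2), , drop = FALSE]
  seg2chain <- traj$topology$segments$chain
  nch <- traj$topology$n_chains
  in_largest <- rep(0L, nch)
  for (f in frames) {
    rows <- cm[cm[, "frame"] == f, , drop = FALSE]
    ca <- seg2chain[rows[, "seg_a"]]
    cb <- seg2chain[rows[, "seg_b"]]
    keep <- ca != cb
    labels <- union_find(nch, ca[keep], cb[keep])
    sizes <- tabulate(labels, nch)
    big <- which.max(sizes)
    in_largest[labels == big] <- in_largest[labels == big] + 1L
  }
  out <- which(in_largest >= fraction * length(frames))
  if (length(out) < 2) seq_len(nch) else out
}
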