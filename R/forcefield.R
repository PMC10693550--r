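#' Force-field parameters
#'
#' Parameters of the coarse-grained energy function, in molecular-dynamics
#' units (nm, ps, kJ/mol, K, amu):
#'
#' * sticky attraction between registry-complementary coil beads: 12-6
#'   Lennard-Jones with `sigma_sticky` = 0.570 nm and `epsilon_sticky` =
#'   7.5 kJ/mol, truncated at 2.5 sigma and shifted to zero at the cutoff;
#' * excluded volume between all nonbonded beads: purely repulsive WCA
#'   (12-6 truncated at the minimum, `2^(1/6) sigma_rep`, shifted up by
#'   `epsilon_rep`). Coil beads whose segment types do not form a designed
#'   dimer pair repel at the larger steric diameter `sigma_fat` of a
#'   coiled-coil: a chain cannot thread between formed interfaces, which
#'   is what frustrates loop-back self-closure of mismatched arrangements;
#' * harmonic bonds between consecutive beads at the C-alpha spacing
#'   `bond_r0` = 0.38 nm;
#' * a rod-stiffening bending term `angle_k * (1 + cos theta)` on
#'   coil-internal bead triplets (harmonic in the deviation from 180
#'   degrees near the minimum); linkers carry no bending term and remain
#'   fully flexible;
#' * a competitor-exclusion term: two beads of the same coil type at the
#'   same registry index compete for the same binding site, and repel
#'   through a soft WCA potential (`sigma_ex`, `epsilon_ex`). This keeps
#'   the coiled-coil interface effectively one-to-one: without it a bound
#'   coil pair admits a third helix on its open face, which real dimeric
#'   coiled coils do not;
#' * an orientation gate: sticky attraction between two coils is switched
#'   on only when their end-to-end axes are aligned (parallel pairs) or
#'   anti-aligned (antiparallel pairs) within a 60-degree tolerance band,
#'   smoothly ramped between `gate_lo` and `gate_hi` on the axis dot
#'   product so that forces stay continuous.
#'
#' `temperature_scale` multiplies the thermostat kT: the model's reduced
#' energy scale is anchored by calibrating simulated single coil-pair
#' dissociation constants to the measured values, so nominal Kelvin labels
#' (298/310 K) map onto the model's own temperature scale (see the methods
#' vignette).
#'
#' @param ... Overrides of any default parameter.
#' @return Named list of parameters (class `cc_forcefield`).
#' @export
#' @examples
#' forcefield_params()$epsilon_sticky  # 7.5 kJ/mol
forcefield_params <- function(...) {
  p <- list(
    sigma_sticky = 0.570,
    epsilon_sticky = 7.5,
    cutoff_sticky = 2.5 * 0.570,
    sigma_rep = 0.40,
    epsilon_rep = 10,
    cutoff_rep = 2^(1 / 6) * 0.40,
    sigma_fat = 0.65,
    bond_r0 = 0.38,
    bond_k = 8000,
    angle_k = 200,
    mass = 110,
    r_floor = 0.06,
    sigma_ex = 1.25,
    epsilon_ex = 12,
    gate_lo = cos(80 * pi / 180),
    gate_hi = cos(60 * pi / 180),
    skin = 0.7,
    temperature_scale = 2.45
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown force-field parameter '", unknown[1], "'"))
  }
  p[names(dots)] <- dots
  stopifnot(p$cutoff_sticky >= p$sigma_sticky,
            all(unlist(p[c("sigma_sticky", "sigma_rep", "bond_r0")]) > 0))
  structure(p, class = "cc_forcefield")
}

#' @export
print.cc_forcefield <- function(x, ...) {
  cat("<cc_forcefield>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

# effective thermostat kT in kJ/mol for a nominal temperature
kT_effective <- function(temperature, ff) {
  KB * temperature * ff$temperature_scale
}

#' Sticky pair energy between two coil beads
#'
#' Scalar reference form of the registry-specific attraction. Returns zero
#' beyond the cutoff, whenever the pair rule is `"none"`, or when the two
#' registry indices are not complementary under the rule's orientation
#' (parallel: equal registries; antiparallel: `reg_j == L_j + 1 - reg_i`,
#' defined only for equal coil lengths). For complementary registries the
#' unshifted minimum is `-strength * epsilon_sticky` at `2^(1/6) *
#' sigma_sticky`; the truncation shift raises the returned value by the
#' (positive) magnitude of the Lennard-Jones tail at the cutoff.
#'
#' The orientation gate multiplier (default 1, fully aligned) scales the
#' energy; the simulation engine computes it from the segment axes.
#'
#' @param r Distance in nm (> 0).
#' @param reg_i,reg_j Registry indices within each coil.
#' @param L_i,L_j Coil lengths in beads.
#' @param pair_rule `"none"`, `"parallel"` or `"antiparallel"`.
#' @param params [forcefield_params()].
#' @param strength Pair strength multiplier.
#' @param gate Orientation gate in `[0, 1]`.
#' @return Energy in kJ/mol.
#' @export
sticky_pair_energy <- function(r, reg_i, reg_j, L_i, L_j,
                               pair_rule = "parallel",
                               params = forcefield_params(),
                               strength = 1, gate = 1) {
  if (any(r <= 0)) rlang::abort("r must be positive")
  if (pair_rule == "none") return(rep(0, length(r)))
  compl <- switch(pair_rule,
    parallel = reg_i == reg_j,
    antiparallel = (L_i == L_j) && (reg_j == L_j + 1 - reg_i),
    rlang::abort("pair_rule must be none, parallel or antiparallel")
  )
  if (!isTRUE(compl)) return(rep(0, length(r)))
  sig <- params$sigma_sticky
  eps <- params$epsilon_sticky
  rc <- params$cutoff_sticky
  lj <- function(rr) {
    sr6 <- (sig / rr)^6
    4 * eps * (sr6^2 - sr6)
  }
  v <- ifelse(r < rc, strength * gate * (lj(pmax(r, params$r_floor)) - lj(rc)),
              0)
  v
}

#' Excluded-volume (WCA) pair energy
#'
#' Purely repulsive 12-6 potential truncated at its minimum
#' (`2^(1/6) sigma_rep`) and shifted to zero there; equals `epsilon_rep`
#' at `r = sigma_rep`. Below `r_floor` the energy is capped at its value
#' at the floor.
#'
#' @inheritParams sticky_pair_energy
#' @return Energy in kJ/mol (>= 0).
#' @export
excluded_volume_energy <- function(r, params = forcefield_params()) {
  if (any(r <= 0)) rlang::abort("r must be positive")
  rc <- params$cutoff_rep
  re <- pmax(r, params$r_floor)
  sr6 <- (params$sigma_rep / re)^6
  ifelse(r < rc, 4 * params$epsilon_rep * (sr6^2 - sr6) + params$epsilon_rep,
         0)
}

#' Total energy and forces of a configuration
#'
#' Assembles all energy terms (bonds, bending, excluded volume, gated
#' sticky attraction) under the minimum-image convention and returns the
#' per-bead force vectors (the negative gradient of the energy).
#'
#' @param config A `cc_config` from [initial_config()] or a simulation.
#' @param ff [forcefield_params()].
#' @param all_pairs Use an exhaustive pair loop instead of the neighbour
#'   list (for verification).
#' @return List with `energy`, `forces` (n x 3 matrix), and per-term
#'   components `e_bond`, `e_angle`, `e_rep`, `e_sticky`.
#' @export
total_energy_forces <- function(config, ff = forcefield_params(),
                                all_pairs = FALSE) {
  stopifnot(inherits(config, "cc_config"))
  if (any(!is.finite(config$pos))) rlang::abort("non-finite positions")
  cpp_energy_forces(config$pos, config$box, topo_cpp(config$topology),
                    unclass(ff), all_pairs)
}
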