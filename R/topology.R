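#' Define a simulation system
#'
#' A system is a set of constructs with copy numbers in a periodic
#' orthorhombic box at a nominal temperature. Multi-component systems are
#' replicated unit-wise (one copy of every component per unit) so that the
#' slab protocol can pack pre-equilibrated units, mirroring the 1:1
#' stoichiometry used for protein pairs.
#'
#' @param components Character vector of construct strings (or list of
#'   `cc_construct`s).
#' @param copies Integer vector of copy numbers (recycled to match
#'   `components`).
#' @param box Numeric length-3 box lengths in nm, or `NULL` to let
#'   [run_slab()] size the box from the bead count.
#' @param temperature Nominal temperature in K.
#' @param seed Integer seed recorded with the system.
#' @return A `cc_system` list.
#' @export
build_system <- function(components, copies = 1L, box = NULL,
                         temperature = 310, seed = 1L) {
  if (is.character(components)) components <- as.list(components)
  components <- lapply(components, function(cc) {
    if (is.character(cc)) parse_construct(cc) else cc
  })
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "cc_construct")))
  copies <- as.integer(rep_len(copies, length(components)))
  if (any(copies < 1)) rlang::abort("copy_number must be >= 1")
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(
    list(components = components, copies = copies, box = box,
         temperature = temperature, seed = as.integer(seed)),
    class = "cc_system"
  )
}

#' @export
print.cc_system <- function(x, ...) {
  cat("<cc_system> ", length(x$components), " component(s)\n", sep = "")
  for (i in seq_along(x$components)) {
    cat("  ", x$copies[i], " x ", x$components[[i]]$name, "\n", sep = "")
  }
  if (!is.null(x$box)) cat("  box:", paste(round(x$box, 2), collapse = " x "),
                           "nm\n")
  cat("  T:", x$temperature, "K  seed:", x$seed, "\n")
  invisible(x)
}

#' Build the bead-level topology of a system
#'
#' Concatenates all chains (unit-wise: one copy of each component per unit),
#' assigns global bead, chain and segment indices, generates harmonic bonds
#' between consecutive beads and bending triplets inside coil segments, and
#' attaches the coil-pair interaction matrix.
#'
#' @param system A `cc_system` or a single construct/construct string.
#' @param matrix Interaction matrix from [interaction_matrix()].
#' @return A `cc_topology`: `beads` tibble (with `chain`, `component`,
#'   `segment` global segment id, `type` integer coil type or 0,
#'   `registry`, `coil_len`), `bonds`/`angles` integer matrices, `segments`
#'   tibble, `types`, `pair_code`, `pair_strength`, `n_beads`, `n_chains`.
#' @export
system_topology <- function(system, matrix = interaction_matrix()) {
  if (is.character(system) || inherits(system, "cc_construct")) {
    system <- build_system(list(if (is.character(system))
      parse_construct(system) else system))
  }
  stopifnot(inherits(system, "cc_system"))
  n_units <- unique(system$copies)
  chains_per_unit <- length(system$components)
  if (length(n_units) == 1) {
    unit_plan <- rep(seq_len(chains_per_unit), n_units)
  } else {
    # unequal stoichiometry: emit components in proportion, units ragged
    unit_plan <- unlist(lapply(seq_along(system$components),
                               function(i) rep(i, system$copies[i])))
  }

  per_chain <- lapply(system$components, build_chain)
  beads_l <- vector("list", length(unit_plan))
  for (ci in seq_along(unit_plan)) {
    comp <- unit_plan[ci]
    b <- per_chain[[comp]]
    b$chain <- ci
    b$component <- comp
    beads_l[[ci]] <- b
  }
  beads <- dplyr::bind_rows(beads_l)
  # globalize bead + segment ids
  beads$bead <- seq_len(nrow(beads))
  seg_key <- paste(beads$chain, beads$segment)
  beads$segment_global <- as.integer(factor(seg_key, levels = unique(seg_key)))

  types <- matrix$types
  beads$type <- ifelse(beads$segment_class == "coil",
                       match(beads$segment_name, types), 0L)
  beads$type[is.na(beads$type)] <- 0L

  # bonds: consecutive beads within a chain
  same_chain <- beads$chain[-1] == beads$chain[-nrow(beads)]
  bi <- which(same_chain)
  bonds <- cbind(bi, bi + 1L)

  # bending triplets: interior bead of three consecutive beads in one coil seg
  segg <- beads$segment_global
  idx <- seq_len(nrow(beads) - 2)
  in_coil <- beads$segment_class == "coil"
  ok <- segg[idx] == segg[idx + 1] & segg[idx + 1] == segg[idx + 2] &
    in_coil[idx]
  ai <- idx[ok]
  angles <- cbind(ai, ai + 1L, ai + 2L)

  segments <- beads %>%
    dplyr::group_by(.data$segment_global) %>%
    dplyr::summarise(
      chain = .data$chain[1], component = .data$component[1],
      class = .data$segment_class[1], name = .data$segment_name[1],
      first = min(.data$bead), last = max(.data$bead),
      coil_len = .data$coil_len[1], .groups = "drop"
    ) %>%
    dplyr::rename(segment = "segment_global")

  structure(
    list(
      beads = beads, bonds = bonds, angles = angles, segments = segments,
      types = types, pair_code = matrix$code, pair_strength = matrix$strength,
      n_beads = nrow(beads), n_chains = max(beads$chain),
      system = system
    ),
    class = "cc_topology"
  )
}

#' @export
print.cc_topology <- function(x, ...) {
  cat("<cc_topology> ", x$n_beads, " beads, ", x$n_chains, " chains, ",
      nrow(x$segments), " segments\n", sep = "")
  invisible(x)
}

# internal: topology in the form the C++ core expects
topo_cpp <- function(topology) {
  b <- topology$beads
  list(
    chain = as.integer(b$chain),
    seg = as.integer(b$segment_global),
    type = as.integer(b$type),
    reg = as.integer(b$registry),
    clen = as.integer(b$coil_len),
    bonds = topology$bonds,
    angles = topology$angles,
    pair_code = topology$pair_code,
    pair_strength = topology$pair_strength
  )
}

#' Export / import a topology as JSON
#'
#' Lossless plain-text round trip of the bead table, bonds, angles and
#' interaction matrices.
#'
#' @param topology A `cc_topology`.
#' @param path Output (input) file path.
#' @return `read_topology_json()` returns a `cc_topology`;
#'   `write_topology_json()` returns `path` invisibly.
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "cc_topology"))
  obj <- list(
    beads = topology$beads,
    bonds = unclass(topology$bonds),
    angles = unclass(topology$angles),
    segments = topology$segments,
    types = topology$types,
    pair_code = topology$pair_code,
    pair_strength = topology$pair_strength
  )
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beads <- tibble::as_tibble(obj$beads)
  code <- as.matrix(obj$pair_code)
  strength <- as.matrix(obj$pair_strength)
  dimnames(code) <- dimnames(strength) <- list(obj$types, obj$types)
  structure(
    list(
      beads = beads,
      bonds = matrix(as.integer(obj$bonds), ncol = 2),
      angles = matrix(as.integer(obj$angles), ncol = 3),
      segments = tibble::as_tibble(obj$segments),
      types = obj$types,
      pair_code = code, pair_strength = strength,
      n_beads = nrow(beads), n_chains = max(beads$chain),
      system = NULL
    ),
    class = "cc_topology"
  )
}

#' Ideal-gas validation topology
#'
#' `n` independent single-bead chains with no bonds, bending or sticky
#' identity (linker-class beads). Used to validate the integrator against
#' analytic references: each bead obeys free Langevin dynamics with
#' diffusion coefficient `kT / (mass * gamma)`.
#'
#' @param n Number of free beads.
#' @return A `cc_topology`.
#' @export
ideal_gas_topology <- function(n) {
  beads <- tibble::tibble(
    bead = seq_len(n),
    segment = 1L,
    segment_class = "linker",
    segment_name = "gs",
    registry = 0L,
    coil_len = 0L,
    chain = seq_len(n),
    component = 1L,
    segment_global = seq_len(n),
    type = 0L
  )
  m <- interaction_matrix()
  segments <- tibble::tibble(
    segment = seq_len(n), chain = seq_len(n), component = 1L,
    class = "linker", name = "gs", first = seq_len(n), last = seq_len(n),
    coil_len = 0L
  )
  structure(
    list(beads = beads,
         bonds = matrix(integer(0), ncol = 2),
         angles = matrix(integer(0), ncol = 3),
         segments = segments, types = m$types, pair_code = m$code,
         pair_strength = m$strength, n_beads = n, n_chains = n,
         system = NULL),
    class = "cc_topology"
  )
}
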