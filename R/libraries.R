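#' Coil segment library
#'
#' The designed coiled-coil (CC) dimer-forming segments available to
#' constructs. Three families are covered: the helicity-enhanced 3-heptad
#' heterodimeric set (`Sh`: S1h-S4h, where S1h pairs with S2h and S3h with
#' S4h), the 4-heptad heterodimeric set (`Pf`: P5f/P6f and P13f/P14f), and
#' two 3-heptad homodimeric coils used for single-chain designs: `APHh3`
#' (pairs with itself in an antiparallel orientation, letter code `A`) and
#' `GCNh3` (parallel homodimer, letter code `P`). Coils are coarse-grained
#' to one bead per residue, 7 residues per heptad.
#'
#' @return A tibble with one row per coil type: `name`, `set_id`, `heptads`,
#'   `residues`, `partner` (name of the unique binding partner; homodimeric
#'   coils list themselves), `orientation` (`"parallel"` or `"antiparallel"`
#'   with respect to that partner), `homodimeric`, and `letter` (single-letter
#'   code used in orientation strings, `NA` for heterodimeric coils).
#' @seealso [linker_library()], [interaction_matrix()], [parse_construct()]
#' @export
#' @examples
#' coil_library()
coil_library <- function() {
  tibble::tibble(
    name = c("S1h", "S2h", "S3h", "S4h",
             "P5f", "P6f", "P13f", "P14f",
             "APHh3", "GCNh3"),
    set_id = c(rep("Sh", 4), rep("Pf", 4), "homo", "homo"),
    heptads = c(rep(3L, 4), rep(4L, 4), 3L, 3L),
    partner = c("S2h", "S1h", "S4h", "S3h",
                "P6f", "P5f", "P14f", "P13f",
                "APHh3", "GCNh3"),
    orientation = c(rep("parallel", 8), "antiparallel", "parallel"),
    homodimeric = c(rep(FALSE, 8), TRUE, TRUE),
    letter = c(rep(NA_character_, 8), "A", "P")
  ) %>%
    dplyr::mutate(residues = 7L * .data$heptads, .after = "heptads")
}

#' Linker segment library
#'
#' Flexible glycine/serine/proline spacers joining consecutive coil
#' segments: the standard `gs` linker (8 residues) and the long `gs40`
#' variant (40 residues).
#'
#' @return A tibble with columns `name` and `residues`.
#' @export
linker_library <- function() {
  tibble::tibble(name = c("gs", "gs40"), residues = c(8L, 40L))
}

#' Coil-pair interaction matrix
#'
#' Symmetric specificity table over coil types. Complementary pairs attract
#' with a defined dimer orientation; all other pairs are inert (excluded
#' volume only). Per-pair strength multipliers rescale the common sticky
#' well depth `epsilon_sticky`; they encode the relative dimer stabilities
#' of the designed pairs and are fixed by calibrating simulated single-pair
#' dissociation constants against the measured (ITC) values (see the
#' methods vignette).
#'
#' @param strengths Named numeric vector of per-pair strength multipliers,
#'   names like `"S1h:S2h"`. Defaults to the calibrated values.
#' @return A list with `types` (character vector), `code` (integer matrix,
#'   0 = none, 1 = parallel, 2 = antiparallel) and `strength` (numeric
#'   matrix), both symmetric with dimnames.
#' @export
#' @examples
#' m <- interaction_matrix()
#' m$code["S1h", "S2h"]  # parallel
#' m$code["S1h", "S3h"]  # orthogonal -> 0
interaction_matrix <- function(strengths = NULL) {
  lib <- coil_library()
  types <- lib$name
  nt <- length(types)
  code <- matrix(0L, nt, nt, dimnames = list(types, types))
  strength <- matrix(0, nt, nt, dimnames = list(types, types))

  default_strengths <- c(
    "S1h:S2h" = 1.045, "S3h:S4h" = 1.12,
    "P5f:P6f" = 1.10, "P13f:P14f" = 1.13,
    "APHh3:APHh3" = 1.09, "GCNh3:GCNh3" = 1.09
  )
  if (is.null(strengths)) strengths <- default_strengths

  for (nm in names(strengths)) {
    pq <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(pq) != 2 || !all(pq %in% types)) {
      rlang::abort(paste0("unknown coil pair '", nm, "'"))
    }
    orient <- lib$orientation[lib$name == pq[1]]
    code[pq[1], pq[2]] <- code[pq[2], pq[1]] <-
      if (orient == "parallel") 1L else 2L
    strength[pq[1], pq[2]] <- strength[pq[2], pq[1]] <- strengths[[nm]]
  }
  list(types = types, code = code, strength = strength)
}
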