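#' The designed-construct truth-table panel
#'
#' Every simulated design combination from the study behind the package,
#' with its experimentally observed phase outcome. Entries cover the
#' two-chain heterodimeric designs (arrangement mismatch vs match, 3- vs
#' 4-heptad coils), the single-chain orientation-patterned homodimer
#' designs, and the three-chain inhibition (blind-challenge) combinations
#' in which a short clustered polypeptide can poison condensation by
#' saturating a partner's stickers.
#'
#' Copy numbers are the package's desk-scale study conditions (see the
#' methods vignette); `expected` uses the closed label vocabulary
#' `condensate` / `dimer` / `diffuse`, and `expected_llps` is the binary
#' outcome the truth table is scored on.
#'
#' @param copies_pair Copies per component for two-component systems.
#' @param copies_single Copies for single-component systems.
#' @param copies_triple Copies per component for three-component systems.
#' @return A tibble with `id`, `components` (list of construct strings),
#'   `copies` (list), `expected`, `expected_llps`, `note`.
#' @export
#' @examples
#' design_panel()[, c("id", "expected")]
design_panel <- function(copies_pair = 6L, copies_single = 6L,
                         copies_triple = 4L) {
  entry <- function(id, components, copies, expected, note) {
    tibble::tibble(id = id, components = list(components),
                   copies = list(as.integer(copies)), expected = expected,
                   expected_llps = expected == "condensate", note = note)
  }
  dplyr::bind_rows(
    entry("mismatch_3h", c("(S1h-S3h)3-gs", "(S2h)3(S4h)3-gs"),
          rep(copies_pair, 2), "condensate",
          "3-heptad pair, mismatched arrangement: free valences build a network"),
    entry("matched_3h", c("(S1h-S3h)3-gs", "(S2h-S4h)3-gs"),
          rep(copies_pair, 2), "dimer",
          "same sequential arrangement: chains zip into closed molecular dimers"),
    entry("mismatch_4h", c("(P5f-P13f)3-gs", "(P6f)3(P14f)3-gs"),
          rep(copies_pair, 2), "condensate",
          "4-heptad pair, mismatched arrangement: condensate with low mobility"),
    entry("appap", "APPAP-gs", copies_single, "diffuse",
          "5 orientation-patterned homodimer coils: below the valency needed"),
    entry("ppppppaaaa", "PPPPPPAAAA-gs", copies_single, "dimer",
          "segregated orientation pattern: hairpins + in-register dimers satisfy all coils"),
    entry("appapappap", "APPAPAPPAP-gs", copies_single, "condensate",
          "10 coils, frustrated orientation pattern: single-chain condensate"),
    entry("triple_s1_block",
          c("(S1h-S3h)3-gs", "(S2h)3(S4h)3-gs", "(S1h)4-gs"),
          rep(copies_triple, 3), "dimer",
          "clustered S1h tetramer saturates the S2h block: condensation poisoned"),
    entry("pair_s2_tetramer", c("(S1h-S3h)3-gs", "(S2h)4-gs"),
          rep(copies_pair, 2), "condensate",
          "alternating chain + clustered S2h tetramer: valences stay open"),
    entry("pair_p6_tetramer", c("(P5f-P13f)3-gs", "(P6f)4-gs"),
          rep(copies_pair, 2), "condensate",
          "4-heptad analogue of the open-valence pairing"),
    entry("matched_p_block_p5", c("(P6f)3(P14f)3-gs", "(P5f)4-gs"),
          rep(copies_pair, 2), "dimer",
          "clustered P5f tetramer saturates the P6f block"),
    entry("triple_p_dimer",
          c("(P5f-P13f)3-gs", "(P5f)4-gs", "(P6f)4-gs"),
          rep(copies_triple, 3), "dimer",
          "the two short chains dimerize, stranding the long chain")
  )
}

#' Build the system for one panel entry
#'
#' @param entry One row of [design_panel()].
#' @param temperature Nominal temperature, K.
#' @param seed Integer seed.
#' @return A `cc_system`.
#' @export
panel_system <- function(entry, temperature = 310, seed = 1L) {
  build_system(entry$components[[1]], copies = entry$copies[[1]],
               temperature = temperature, seed = seed)
}
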