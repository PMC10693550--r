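#' Parse a construct string into an ordered segment specification
#'
#' Construct strings describe a polypeptide as coil segments joined by
#' flexible linkers, using the compact naming scheme of the design study:
#'
#' * repeat groups: `"(S1h-S3h)3"` expands to `S1h,S3h,S1h,S3h,S1h,S3h`;
#' * run groups: `"(S2h)3(S4h)3"` expands to three S2h then three S4h;
#' * orientation strings over the homodimeric coils: `"APPAPAPPAP"` maps
#'   `A` to APHh3 (antiparallel homodimer) and `P` to GCNh3 (parallel);
#' * a linker suffix `-gs` (default, 8 residues) or `-gs40` (40 residues);
#' * fluorescent-tag prefixes (`Cit-`, `BFP-`, `mCit-`, `TagBFP-`) are
#'   accepted and dropped: tags are not part of the coarse-grained model.
#'
#' A linker is interposed between every pair of consecutive coils; no
#' terminal linkers are added.
#'
#' @param spec_string Construct string, e.g. `"Cit-(S1h-S3h)3-gs"`.
#' @return A `cc_construct`: list with `name` (canonical rendering),
#'   `coils` (character vector of coil type names in order), `linker`
#'   (linker type name), `coil_count`, `arrangement` (comma-joined coil
#'   names) and `segments` (tibble of all segments in chain order with
#'   `class`, `name`, `residues`).
#' @seealso [build_chain()], [render_construct()]
#' @export
#' @examples
#' parse_construct("Cit-(S1h-S3h)3-gs")$coil_count   # 6
#' parse_construct("APPAPAPPAP-gs")$arrangement
parse_construct <- function(spec_string) {
  if (!is.character(spec_string) || length(spec_string) != 1 ||
      is.na(spec_string) || !nzchar(trimws(spec_string))) {
    rlang::abort("empty construct string")
  }
  s <- trimws(spec_string)

  # drop fluorescent-tag prefixes
  s <- sub("^(Cit|mCit|mCitrine|BFP|TagBFP)-", "", s)

  # linker suffix
  linker <- "gs"
  if (grepl("-gs40$", s)) {
    linker <- "gs40"
    s <- sub("-gs40$", "", s)
  } else if (grepl("-gs$", s)) {
    s <- sub("-gs$", "", s)
  }
  if (!nzchar(s)) rlang::abort("construct has no coil segments")

  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (n_open != n_close) rlang::abort("unbalanced parentheses in construct")

  lib <- coil_library()
  coils <- character(0)

  if (grepl("^[AP]+$", s)) {
    letters_map <- stats::setNames(lib$name[!is.na(lib$letter)],
                                   lib$letter[!is.na(lib$letter)])
    coils <- unname(letters_map[strsplit(s, "")[[1]]])
  } else {
    # sequence of groups "(tokens)n" or bare tokens separated by '-'
    rest <- s
    while (nzchar(rest)) {
      m <- regexpr("^\\(([^()]*)\\)(\\d*)", rest)
      if (m == 1) {
        grp <- regmatches(rest, m)
        inner <- sub("^\\(([^()]*)\\)(\\d*)$", "\\1", grp)
        reps <- sub("^\\(([^()]*)\\)(\\d*)$", "\\2", grp)
        reps <- if (nzchar(reps)) as.integer(reps) else 1L
        toks <- strsplit(inner, "-", fixed = TRUE)[[1]]
        toks <- toks[nzchar(toks)]
        if (length(toks) == 0) rlang::abort("empty group in construct")
        coils <- c(coils, rep(toks, reps))
        rest <- substring(rest, attr(m, "match.length") + 1)
      } else if (grepl("^[^()]+$", rest)) {
        toks <- strsplit(rest, "-", fixed = TRUE)[[1]]
        toks <- toks[nzchar(toks)]
        coils <- c(coils, toks)
        rest <- ""
      } else {
        rlang::abort(paste0("cannot parse construct near '", rest, "'"))
      }
    }
  }

  unknown <- setdiff(unique(coils), lib$name)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown coil token '", unknown[1], "'"))
  }
  if (length(coils) == 0) rlang::abort("construct has no coil segments")

  llib <- linker_library()
  coil_res <- lib$residues[match(coils, lib$name)]
  link_res <- llib$residues[llib$name == linker]

  n <- length(coils)
  seg_class <- rep("coil", 2 * n - 1)
  seg_name <- rep(NA_character_, 2 * n - 1)
  seg_class[seq(2, length.out = n - 1, by = 2)] <- "linker"
  seg_name[seq(1, by = 2, length.out = n)] <- coils
  seg_name[seg_class == "linker"] <- linker
  seg_res <- ifelse(seg_class == "coil",
                    coil_res[cumsum(seg_class == "coil")], link_res)

  out <- structure(
    list(
      name = NA_character_,
      coils = coils,
      linker = linker,
      coil_count = n,
      arrangement = paste(coils, collapse = ","),
      segments = tibble::tibble(class = seg_class, name = seg_name,
                                residues = as.integer(seg_res))
    ),
    class = "cc_construct"
  )
  out$name <- render_construct(out)
  out
}

#' Render a construct back to its canonical string form
#'
#' The canonical form uses an orientation letter string when every coil is
#' homodimeric, a repeat group `"(a-b)n"` when the coil sequence is a whole
#' number of repeats of a multi-coil unit, and run-length groups
#' `"(X)n(Y)m"` otherwise, followed by the linker suffix.
#'
#' @param construct A `cc_construct`.
#' @return Canonical construct string.
#' @export
render_construct <- function(construct) {
  stopifnot(inherits(construct, "cc_construct"))
  lib <- coil_library()
  coils <- construct$coils
  homo <- lib$homodimeric[match(coils, lib$name)]
  if (all(homo)) {
    body <- paste(lib$letter[match(coils, lib$name)], collapse = "")
  } else {
    body <- NULL
    n <- length(coils)
    for (ulen in seq_len(n)) {           # smallest whole-sequence repeat unit
      if (n %% ulen != 0 || ulen == n) next
      unit <- coils[seq_len(ulen)]
      if (identical(rep(unit, n / ulen), coils) && ulen > 1 &&
          length(unique(unit)) > 1) {
        body <- paste0("(", paste(unit, collapse = "-"), ")", n / ulen)
        break
      }
    }
    if (is.null(body)) {                 # run-length encoding
      r <- rle(coils)
      body <- paste0("(", r$values, ")", r$lengths, collapse = "")
    }
  }
  paste0(body, "-", construct$linker)
}

#' @export
print.cc_construct <- function(x, ...) {
  cat("<cc_construct> ", x$name, "\n", sep = "")
  cat("  coils: ", x$coil_count, " (", x$arrangement, ")\n", sep = "")
  cat("  residues:", sum(x$segments$residues), "\n")
  invisible(x)
}

#' Build the bead chain for a construct
#'
#' Expands a construct into its C-alpha-level bead records, one bead per
#' residue. Coil beads carry a registry index (1..7*heptads, numbered from
#' the N terminus); linker beads have registry 0.
#'
#' @param construct A `cc_construct` (or a construct string, parsed first).
#' @return A tibble with one row per bead: `bead`, `segment` (ordinal within
#'   the chain), `segment_class`, `segment_name`, `registry`, `coil_len`.
#' @export
#' @examples
#' nrow(build_chain("(S1h-S3h)3-gs"))  # 166 beads
build_chain <- function(construct) {
  if (is.character(construct)) construct <- parse_construct(construct)
  stopifnot(inherits(construct, "cc_construct"))
  seg <- construct$segments
  purrr::imap_dfr(seq_len(nrow(seg)), function(i, ...) {
    nres <- seg$residues[i]
    tibble::tibble(
      segment = i,
      segment_class = seg$class[i],
      segment_name = seg$name[i],
      registry = if (seg$class[i] == "coil") seq_len(nres) else rep(0L, nres),
      coil_len = if (seg$class[i] == "coil") nres else 0L
    )
  }) %>%
    dplyr::mutate(bead = dplyr::row_number(), .before = 1)
}
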