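#' Tile Cas13b gRNA spacers across a target adenosine
#'
#' Designs the spacer series used to screen editing guides: each spacer is
#' the reverse complement of a window of the sense-strand reference, except
#' that the base opposite the target adenosine is replaced by `C`, creating
#' the A-C mismatch that directs ADAR to deaminate the target. Guides differ
#' by mismatch distance `d`, the number of spacer nucleotides (inclusive)
#' from the mismatched base to the scaffold-proximal end of the spacer. With
#' the direct repeat appended 3' of the spacer (the PspCas13b-family
#' default), `d` counts from the spacer's 3' end, so the covered reference
#' window for a spacer of length `L` is `[target - d + 1, target - d + L]`.
#' Names follow the `"<L> nt-<d>"` screening convention (e.g. `50 nt-36`).
#'
#' @param ref An [amplicon_ref()].
#' @param spacer_length Spacer length in nt, 30 or 50.
#' @param d_min,d_max Mismatch-distance range to tile (inclusive).
#' @param step Tiling step in nt.
#' @param orthologue Cas13b orthologue label, one of
#'   `"PspCas13b"`, `"PspCas13b-del"`, `"Cas13bt1"`, `"Cas13bt3"`, `"Cas13bt5"`.
#' @return A data.frame of class `guide_set` with one row per emitted guide:
#'   `name`, `spacer` (DNA, cloning-oligo sense), `spacer_length`,
#'   `mismatch_distance`, `orthologue`, `window_start`, `window_end`
#'   (1-based closed reference coordinates), `has_direct_repeat` (FALSE
#'   until [attach_scaffold()]), `full_sequence`. Mismatch distances whose
#'   window overruns the reference are skipped; skipped `d` values are
#'   recorded in the `"skipped_d"` attribute and reported with a warning.
#' @export
tile_guides <- function(ref, spacer_length = 50L, d_min = 18L, d_max = 42L,
                        step = 6L, orthologue = "PspCas13b") {
  stopifnot(inherits(ref, "amplicon_ref"))
  spacer_length <- as.integer(spacer_length)
  if (!spacer_length %in% c(30L, 50L)) {
    stop("spacer_length must be 30 or 50")
  }
  orthologue <- match.arg(
    orthologue,
    c("PspCas13b", "PspCas13b-del", "Cas13bt1", "Cas13bt3", "Cas13bt5")
  )
  if (d_min > d_max) stop("d_min must be <= d_max")
  ds <- seq(as.integer(d_min), as.integer(d_max), by = as.integer(step))
  n <- nchar(ref$sequence)
  rows <- list()
  skipped <- integer(0)
  for (d in ds) {
    win_start <- ref$target_pos - d + 1L
    win_end <- win_start + spacer_length - 1L
    if (win_start < 1L || win_end > n || d > spacer_length) {
      skipped <- c(skipped, d)
      next
    }
    window <- substr(ref$sequence, win_start, win_end)
    spacer <- revcomp(window)
    # spacer position opposite the target A, counted from the 5' end:
    # the target is the d-th window base, i.e. position L - d + 1 of the
    # reverse complement
    mm_pos <- spacer_length - d + 1L
    stopifnot(substr(spacer, mm_pos, mm_pos) == "T")
    substr(spacer, mm_pos, mm_pos) <- "C"
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("%d nt-%d", spacer_length, d),
      spacer = spacer,
      spacer_length = spacer_length,
      mismatch_distance = d,
      orthologue = orthologue,
      window_start = win_start,
      window_end = win_end,
      has_direct_repeat = FALSE,
      full_sequence = spacer,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning(
      "skipped mismatch distances with out-of-bounds windows: ",
      paste(skipped, collapse = ", ")
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      name = character(), spacer = character(), spacer_length = integer(),
      mismatch_distance = integer(), orthologue = character(),
      window_start = integer(), window_end = integer(),
      has_direct_repeat = logical(), full_sequence = character(),
      stringsAsFactors = FALSE
    )
  }
  attr(out, "skipped_d") <- skipped
  class(out) <- c("guide_set", "data.frame")
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Example direct-repeat scaffold table
#'
#' Placeholder scaffold sequences for each supported orthologue so the
#' design workflow can be exercised end to end. These are synthetic stand-in
#' sequences, not the published direct repeats: supply your own table (named
#' character vector, orthologue -> DR sequence) for cloning-grade output.
#'
#' @return Named character vector of synthetic direct-repeat sequences.
#' @export
example_scaffold_table <- function() {
  c(
    "PspCas13b"     = "GTTGTGGAAGGTCCAGTTTTGAGGGGCTATTACAAC",
    "PspCas13b-del" = "GTTGTGGAAGGTCCAGTTTTGAGGGGCTATTACAAC",
    "Cas13bt1"      = "GTTGGAACTGCTCTCATTTTGGAGGGTAAAGCAAC",
    "Cas13bt3"      = "GTTGGAGACTGCCTTCATTTTGGAAGGCAGAGCAAC",
    "Cas13bt5"      = "GTTGGAATTGCTCGTCATTTTGGACGGGCAAGCAAC"
  )
}

#' Attach (or omit) the direct-repeat scaffold
#'
#' Appends the orthologue's direct repeat to each spacer. For
#' PspCas13b-family guides the DR is appended 3' of the spacer by default;
#' the side is configurable because scaffold placement differs among Cas13
#' families. `include_dr = FALSE` yields spacer-only control guides, the
#' scaffold-less controls used to show editing is Cas13-gRNA mediated.
#'
#' @param guides A `guide_set` from [tile_guides()] (or one row of it).
#' @param scaffold_table Named character vector mapping orthologue to DR
#'   sequence; see [example_scaffold_table()].
#' @param include_dr Attach the DR (`TRUE`) or emit spacer-only controls.
#' @param side `"3prime"` (default) or `"5prime"`.
#' @return The `guide_set` with `full_sequence` and `has_direct_repeat` set.
#' @export
attach_scaffold <- function(guides, scaffold_table = example_scaffold_table(),
                            include_dr = TRUE, side = c("3prime", "5prime")) {
  side <- match.arg(side)
  stopifnot(is.data.frame(guides))
  if (!include_dr) {
    guides$full_sequence <- guides$spacer
    guides$has_direct_repeat <- FALSE
    return(guides)
  }
  unknown <- setdiff(unique(guides$orthologue), names(scaffold_table))
  if (length(unknown)) {
    stop(
      "unknown orthologue(s): ", paste(unknown, collapse = ", "),
      "; scaffold_table knows: ", paste(names(scaffold_table), collapse = ", ")
    )
  }
  dr <- scaffold_table[guides$orthologue]
  guides$full_sequence <- if (side == "3prime") {
    paste0(guides$spacer, dr)
  } else {
    paste0(dr, guides$spacer)
  }
  guides$has_direct_repeat <- TRUE
  guides
}

#' Design a non-targeting control spacer
#'
#' Draws a random spacer with no exact match of `min_match` nt or longer to
#' any forbidden reference or its reverse complement, for use as the
#' non-targeting control guide in editing screens.
#'
#' @param spacer_length Spacer length in nt.
#' @param forbidden List of [amplicon_ref()] objects or character sequences
#'   the spacer must not match.
#' @param seed Integer seed; deterministic.
#' @param min_match Minimum exact-match length to exclude (default 15).
#' @param max_attempts Attempts before giving up.
#' @return A one-row `guide_set`-shaped data.frame (no mismatch distance,
#'   `NA` window).
#' @export
nontargeting_guide <- function(spacer_length = 50L, forbidden, seed = 1L,
                               min_match = 15L, max_attempts = 100L) {
  if (missing(forbidden) || length(forbidden) == 0L) {
    stop("at least one forbidden reference is required")
  }
  seqs <- vapply(forbidden, function(f) {
    if (inherits(f, "amplicon_ref")) f$sequence else toupper(as.character(f))
  }, character(1))
  kmers <- function(s, k) {
    if (nchar(s) < k) return(character(0))
    starts <- seq_len(nchar(s) - k + 1L)
    substring(s, starts, starts + k - 1L)
  }
  forbidden_kmers <- unique(unlist(lapply(
    c(seqs, vapply(seqs, revcomp, character(1))),
    kmers, k = min_match
  )))
  withr_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      spacer <- paste(
        sample(c("A", "C", "G", "T"), spacer_length, replace = TRUE),
        collapse = ""
      )
      if (!any(kmers(spacer, min_match) %in% forbidden_kmers)) {
        out <- data.frame(
          name = sprintf("NT-%d nt", spacer_length),
          spacer = spacer,
          spacer_length = as.integer(spacer_length),
          mismatch_distance = NA_integer_,
          orthologue = NA_character_,
          window_start = NA_integer_,
          window_end = NA_integer_,
          has_direct_repeat = FALSE,
          full_sequence = spacer,
          stringsAsFactors = FALSE
        )
        class(out) <- c("guide_set", "data.frame")
        return(out)
      }
    }
    stop(sprintf(
      "no non-targeting spacer found in %d attempts", max_attempts
    ))
  })
}

#' Write a guide set as FASTA plus a TSV manifest
#'
#' @param guides A `guide_set`.
#' @param fasta_path Output FASTA of `full_sequence` entries.
#' @param manifest_path Output TSV manifest.
#' @param rna If `TRUE`, transliterate T to U in the FASTA output.
#' @return Invisibly, a list of the two paths.
#' @export
write_guides <- function(guides, fasta_path, manifest_path, rna = FALSE) {
  seqs <- guides$full_sequence
  if (rna) seqs <- chartr("T", "U", seqs)
  x <- Biostrings::BStringSet(seqs)
  names(x) <- guides$name
  Biostrings::writeXStringSet(x, fasta_path)
  utils::write.table(
    guides[, c(
      "name", "mismatch_distance", "spacer_length", "orthologue",
      "window_start", "window_end", "has_direct_repeat"
    )],
    manifest_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(fasta = fasta_path, manifest = manifest_path))
}
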