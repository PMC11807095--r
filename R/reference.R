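#' Amplicon reference for an editable adenosine
#'
#' Container for the mutant-allele (A-containing) target sequence of an
#' RNA base-editing experiment, given on the sense strand. The editable
#' adenosine (the G>A premature-stop position) and the window covered by
#' the gRNA duplex are annotated, and all reference adenosines are indexed
#' so that per-site editing rates can be labelled `A_k` by their sense-strand
#' ordinal, as is conventional for bystander-editing figures.
#'
#' All coordinates are 1-based and intervals are closed, following the
#' Biostrings/GenomicRanges convention.
#'
#' @param name Sequence name (used as the FASTA header).
#' @param sequence Character scalar, uppercase DNA (`A`/`C`/`G`/`T` only),
#'   sense strand of the mutant allele.
#' @param target_pos 1-based position of the editable adenosine; the base at
#'   this position must be `A`.
#' @param guide_window Integer vector `c(start, end)`, 1-based closed
#'   interval covered by the gRNA duplex; must contain `target_pos`.
#'
#' @return An object of class `amplicon_ref`: a list with fields `name`,
#'   `sequence`, `target_pos`, `guide_window`, `adenosine_positions` (sorted
#'   1-based offsets of every reference `A`), and `site_labels` (the `A_k`
#'   label of each adenosine, `k` being its sense-strand ordinal).
#' @export
amplicon_ref <- function(name, sequence, target_pos, guide_window) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence may contain only A/C/G/T")
  }
  target_pos <- as.integer(target_pos)
  guide_window <- as.integer(guide_window)
  if (length(guide_window) != 2L || guide_window[1] > guide_window[2]) {
    stop("guide_window must be c(start, end) with start <= end")
  }
  if (guide_window[1] < 1L || guide_window[2] > n) {
    stop(sprintf(
      "guide_window [%d, %d] outside reference [1, %d]",
      guide_window[1], guide_window[2], n
    ))
  }
  if (target_pos < 1L || target_pos > n) {
    stop(sprintf("target_pos %d outside reference [1, %d]", target_pos, n))
  }
  if (substr(sequence, target_pos, target_pos) != "A") {
    stop(sprintf(
      "base at target_pos %d is '%s', expected 'A'",
      target_pos, substr(sequence, target_pos, target_pos)
    ))
  }
  if (target_pos < guide_window[1] || target_pos > guide_window[2]) {
    stop("target_pos must lie within guide_window")
  }
  a_pos <- which(strsplit(sequence, "")[[1]] == "A")
  structure(
    list(
      name = as.character(name),
      sequence = sequence,
      target_pos = target_pos,
      guide_window = guide_window,
      adenosine_positions = a_pos,
      site_labels = paste0("A", seq_along(a_pos))
    ),
    class = "amplicon_ref"
  )
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf(
    "amplicon_ref '%s': %d bp, target A at %d (%s), guide window [%d, %d], %d adenosines\n",
    x$name, nchar(x$sequence), x$target_pos,
    x$site_labels[match(x$target_pos, x$adenosine_positions)],
    x$guide_window[1], x$guide_window[2], length(x$adenosine_positions)
  ))
  invisible(x)
}

#' Label of the target adenosine
#'
#' @param ref An [amplicon_ref()].
#' @return The `A_k` label of the editable adenosine.
#' @export
target_label <- function(ref) {
  stopifnot(inherits(ref, "amplicon_ref"))
  ref$site_labels[match(ref$target_pos, ref$adenosine_positions)]
}

#' Generate a random amplicon reference
#'
#' Emulates the ~200 bp amplicon surrounding a G>A premature-stop mutation:
#' a uniform-composition random sequence with the target position forced to
#' `A` and a gRNA window of `guide_span` bases placed so the target sits at
#' mismatch distance `mismatch_distance` from the window start (the position
#' that faces the scaffold-proximal end of a tiled spacer). Deterministic
#' under `seed`.
#'
#' @param length Amplicon length in bases (default 200).
#' @param target_pos 1-based position of the editable adenosine.
#' @param guide_span gRNA duplex width in bases (default 50).
#' @param seed Integer seed.
#' @param mismatch_distance Distance (in nt, inclusive of the mismatched
#'   base) from the target adenosine to the guide-window start; defaults to
#'   `round(guide_span / 2)`, centring the window on the target.
#' @param name Reference name.
#' @return An [amplicon_ref()].
#' @export
make_reference <- function(length = 200L, target_pos = 100L, guide_span = 50L,
                           seed = 1L, mismatch_distance = NULL,
                           name = "synthetic_amplicon") {
  length <- as.integer(length)
  target_pos <- as.integer(target_pos)
  guide_span <- as.integer(guide_span)
  if (target_pos < 1L || target_pos > length) {
    stop(sprintf("target_pos %d outside reference [1, %d]", target_pos, length))
  }
  if (is.null(mismatch_distance)) mismatch_distance <- round(guide_span / 2)
  d <- as.integer(mismatch_distance)
  win_start <- target_pos - d + 1L
  win_end <- win_start + guide_span - 1L
  if (win_start < 1L || win_end > length) {
    stop(sprintf(
      "guide window [%d, %d] does not fit in reference [1, %d]",
      win_start, win_end, length
    ))
  }
  seq_chr <- withr_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
  substr(seq_chr, target_pos, target_pos) <- "A"
  amplicon_ref(name, seq_chr, target_pos, c(win_start, win_end))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Write an amplicon reference to FASTA
#'
#' @param ref An [amplicon_ref()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "amplicon_ref"))
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an amplicon reference from FASTA plus annotation
#'
#' The FASTA carries only the sequence; the target position and guide window
#' are supplied by the caller (typically from a run config).
#'
#' @param path FASTA path (first record used).
#' @inheritParams amplicon_ref
#' @return An [amplicon_ref()].
#' @export
read_reference_fasta <- function(path, target_pos, guide_window) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  amplicon_ref(names(x)[1], as.character(x[[1]]), target_pos, guide_window)
}
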