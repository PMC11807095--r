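#' Quality-filter amplicon reads
#'
#' Applies the two read-quality rules used for amplicon editing analysis:
#' reads whose arithmetic mean Phred quality is not strictly greater than
#' `min_avg_q` are discarded, and in retained reads every base whose Phred
#' quality is not strictly greater than `min_base_q` is masked (excluded
#' from allele counting, not discarded with the read).
#'
#' @param reads A `QualityScaledDNAStringSet` (see [read_fastq()]).
#' @param min_avg_q Minimum mean read quality, strict (default 30).
#' @param min_base_q Minimum single-base quality, strict (default 20).
#' @return A list with `seqs` (`DNAStringSet` of retained reads), `mask`
#'   (a `LogicalList`, `TRUE` where a base is quality-masked), and `report`
#'   (counts `n_input`, `n_fail_avg_quality`, `n_retained`, `bases_masked`).
#' @export
filter_reads <- function(reads, min_avg_q = 30, min_base_q = 20) {
  n_input <- length(reads)
  if (n_input == 0L) {
    return(list(
      seqs = Biostrings::DNAStringSet(),
      mask = IRanges::LogicalList(),
      report = list(
        n_input = 0L, n_fail_avg_quality = 0L,
        n_retained = 0L, bases_masked = 0L
      )
    ))
  }
  quals <- methods::as(Biostrings::quality(reads), "IntegerList")
  avg <- vapply(quals, mean, numeric(1))
  keep <- avg > min_avg_q
  mask <- quals[keep] <= min_base_q
  list(
    seqs = methods::as(reads[keep], "DNAStringSet"),
    mask = mask,
    report = list(
      n_input = n_input,
      n_fail_avg_quality = sum(!keep),
      n_retained = sum(keep),
      bases_masked = sum(sum(mask))
    )
  )
}

# Scoring used for read-to-amplicon alignment.
align_scoring <- function() {
  list(
    mat = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE
    ),
    gap_opening = 5, gap_extension = 1
  )
}

#' Align reads to the amplicon and extract per-position base calls
#'
#' Each read is aligned globally to the sense-strand reference in both
#' orientations and the higher-scoring orientation kept. Full-length reads
#' are first compared ungapped in both orientations; when the better
#' ungapped identity is at least `fast_identity` that gapless alignment is
#' already optimal under the scoring (a substitution costs less than any
#' gap pair) and the dynamic program is skipped. Alignments with identity
#' below `min_identity` over alignment columns are rejected. Reference
#' columns carrying a read gap, and columns within one position of any gap,
#' are masked to protect A>G counting from indel artefacts; quality-masked
#' bases are masked likewise.
#'
#' @param filtered Output of [filter_reads()].
#' @param ref An [amplicon_ref()].
#' @param min_identity Minimum alignment identity to keep a read
#'   (default 0.8).
#' @param fast_identity Ungapped-identity threshold above which full-length
#'   reads skip the dynamic program (default 0.9).
#' @return A list with `calls` (character matrix, retained reads x reference
#'   positions; entries `A`/`C`/`G`/`T`, `N` for masked bases, `-` for gap
#'   or gap-adjacent columns, `NA` outside read coverage), `orientation`
#'   (`"+"`/`"-"`), `identity`, and `n_fail_alignment`.
#' @export
align_reads <- function(filtered, ref, min_identity = 0.8,
                        fast_identity = 0.9) {
  seqs <- filtered$seqs
  mask <- filtered$mask
  L <- nchar(ref$sequence)
  n <- length(seqs)
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  calls <- matrix(NA_character_, nrow = n, ncol = L)
  orientation <- rep(NA_character_, n)
  identity <- rep(NA_real_, n)
  ok <- logical(n)
  if (n == 0L) {
    return(list(
      calls = calls, orientation = orientation,
      identity = identity, n_fail_alignment = 0L
    ))
  }
  mask_list <- as.list(mask)
  need_dp <- integer(0)

  full <- which(Biostrings::width(seqs) == L)
  if (length(full)) {
    m_f <- as.matrix(seqs[full])
    m_r <- as.matrix(Biostrings::reverseComplement(seqs[full]))
    ref_rep <- matrix(ref_chars, length(full), L, byrow = TRUE)
    mm_f <- rowSums(m_f != ref_rep)
    mm_r <- rowSums(m_r != ref_rep)
    use_rev <- mm_r < mm_f
    best_mm <- ifelse(use_rev, mm_r, mm_f)
    id <- 1 - best_mm / L
    fast <- id >= fast_identity
    need_dp <- full[!fast]
    idx <- full[fast]
    if (length(idx)) {
      sel <- which(fast)
      chosen <- m_f[sel, , drop = FALSE]
      if (any(use_rev[sel])) {
        rsel <- sel[use_rev[sel]]
        chosen[use_rev[sel], ] <- m_r[rsel, , drop = FALSE]
      }
      # map quality masks through the chosen orientation
      for (k in seq_along(idx)) {
        i <- idx[k]
        mk <- mask_list[[i]]
        if (use_rev[sel[k]]) mk <- rev(mk)
        if (any(mk)) chosen[k, mk] <- "N"
      }
      calls[idx, ] <- chosen
      orientation[idx] <- ifelse(use_rev[sel], "-", "+")
      identity[idx] <- id[fast]
      ok[idx] <- TRUE
    }
  }
  need_dp <- c(need_dp, which(Biostrings::width(seqs) != L))

  if (length(need_dp)) {
    sc <- align_scoring()
    ref_dna <- Biostrings::DNAString(ref$sequence)
    for (i in need_dp) {
      res <- align_one_read(
        seqs[[i]], mask_list[[i]], ref_dna, L, sc, min_identity
      )
      if (is.null(res)) next
      calls[i, ] <- res$calls
      orientation[i] <- res$orientation
      identity[i] <- res$identity
      ok[i] <- TRUE
    }
  }
  keep <- ok & !is.na(identity) & identity >= min_identity
  list(
    calls = calls[keep, , drop = FALSE],
    orientation = orientation[keep],
    identity = identity[keep],
    n_fail_alignment = sum(!keep)
  )
}

# Full dynamic-program alignment of one read (both orientations); returns
# per-reference-position calls with gap and gap-adjacent columns masked,
# or NULL if the read cannot be aligned at min_identity.
align_one_read <- function(seq1, qmask, ref_dna, L, sc, min_identity) {
  type <- if (length(seq1) == L) "global" else "global-local"
  rc <- Biostrings::reverseComplement(seq1)
  pa_f <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(list(seq1)), ref_dna,
    type = type, substitutionMatrix = sc$mat,
    gapOpening = sc$gap_opening, gapExtension = sc$gap_extension
  )
  pa_r <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(list(rc)), ref_dna,
    type = type, substitutionMatrix = sc$mat,
    gapOpening = sc$gap_opening, gapExtension = sc$gap_extension
  )
  use_rev <- Biostrings::score(pa_r) > Biostrings::score(pa_f)
  pa <- if (use_rev) pa_r else pa_f
  if (use_rev) qmask <- rev(qmask)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncols <- length(pat)
  ident <- sum(pat == sub & pat != "-") / ncols
  if (ident < min_identity) return(NULL)
  sub_gap <- sub == "-"
  pat_gap <- pat == "-"
  ref_offset <- if (type == "global") 0L else {
    as.integer(Biostrings::start(Biostrings::subject(pa))) - 1L
  }
  refpos <- ref_offset + cumsum(!sub_gap)
  readpos <- cumsum(!pat_gap)
  calls <- rep(NA_character_, L)
  covered <- which(!sub_gap)
  calls[refpos[covered]] <- pat[covered]
  # quality masking (only where the read contributes a base)
  base_cols <- covered[!pat_gap[covered]]
  if (any(qmask)) {
    masked_cols <- base_cols[qmask[readpos[base_cols]]]
    calls[refpos[masked_cols]] <- "N"
  }
  # gap columns and their +-1 reference neighbours are excluded
  gap_ref <- unique(c(
    refpos[covered][pat_gap[covered]],           # deletion columns
    refpos[which(sub_gap)], refpos[which(sub_gap)] + 1L  # insertion flanks
  ))
  gap_ref <- unique(c(gap_ref - 1L, gap_ref, gap_ref + 1L))
  gap_ref <- gap_ref[gap_ref >= 1L & gap_ref <= L & !is.na(calls[gap_ref])]
  calls[gap_ref] <- "-"
  list(
    calls = calls,
    orientation = if (use_rev) "-" else "+",
    identity = ident
  )
}

#' Count alleles at every reference adenosine
#'
#' Tallies the aligned read base at each reference adenosine into A, G,
#' other (C/T) and masked (quality-masked bases, gap and gap-adjacent
#' columns) counts, and computes the editing rate
#' `rate = n_G / (n_A + n_G)`. Non-A/G bases are excluded from the rate
#' denominator: the rate is an A-vs-G quantity.
#'
#' @param aligned Output of [align_reads()].
#' @param ref An [amplicon_ref()].
#' @param sample_id Sample label carried into the table.
#' @return A `site_counts` data.frame with one row per reference adenosine:
#'   `sample_id`, `position` (1-based), `label` (`A_k` ordinal), `is_target`,
#'   `n_A`, `n_G`, `n_other`, `n_masked`, `depth` (`n_A + n_G + n_other`),
#'   `rate` (`NA` when `n_A + n_G == 0`).
#' @export
count_alleles <- function(aligned, ref, sample_id = "sample") {
  pos <- ref$adenosine_positions
  calls <- aligned$calls[, pos, drop = FALSE]
  n_A <- colSums(calls == "A", na.rm = TRUE)
  n_G <- colSums(calls == "G", na.rm = TRUE)
  n_other <- colSums(calls == "C" | calls == "T", na.rm = TRUE)
  n_masked <- colSums(calls == "N" | calls == "-", na.rm = TRUE)
  denom <- n_A + n_G
  out <- data.frame(
    sample_id = sample_id,
    position = pos,
    label = ref$site_labels,
    is_target = pos == ref$target_pos,
    n_A = as.integer(n_A),
    n_G = as.integer(n_G),
    n_other = as.integer(n_other),
    n_masked = as.integer(n_masked),
    depth = as.integer(n_A + n_G + n_other),
    rate = ifelse(denom > 0, n_G / denom, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Quantify per-adenosine editing in one sample
#'
#' Composition of [filter_reads()], [align_reads()] and [count_alleles()]:
#' FASTQ in, per-site A/G count table and filter report out. Deterministic
#' for fixed input.
#'
#' @param fastq Path to a FASTQ file, or a `QualityScaledDNAStringSet`.
#' @param ref An [amplicon_ref()].
#' @param sample_id Sample label (defaults to the FASTQ basename).
#' @param min_avg_q,min_base_q Quality thresholds, see [filter_reads()].
#' @param min_identity Alignment identity threshold, see [align_reads()].
#' @param keep_calls Keep the per-read base-call matrix in the result
#'   (needed for [read_precision()]; default `TRUE`).
#' @return An object of class `edit_sample`: list with `sites` (a
#'   `site_counts` table), `report` (a filter report: `n_input`,
#'   `n_fail_avg_quality`, `n_fail_alignment`, `n_analyzed`,
#'   `bases_masked`), and optionally `calls`.
#' @export
quantify_sample <- function(fastq, ref, sample_id = NULL,
                            min_avg_q = 30, min_base_q = 20,
                            min_identity = 0.8, keep_calls = TRUE) {
  if (is.character(fastq)) {
    if (is.null(sample_id)) {
      sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
    }
    fastq <- read_fastq(fastq)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  filtered <- filter_reads(fastq, min_avg_q, min_base_q)
  aligned <- align_reads(filtered, ref, min_identity)
  sites <- count_alleles(aligned, ref, sample_id)
  report <- list(
    n_input = filtered$report$n_input,
    n_fail_avg_quality = filtered$report$n_fail_avg_quality,
    n_fail_alignment = aligned$n_fail_alignment,
    n_analyzed = nrow(aligned$calls),
    bases_masked = filtered$report$bases_masked
  )
  out <- list(sites = sites, report = report, sample_id = sample_id)
  if (keep_calls) out$calls <- aligned$calls
  class(out) <- "edit_sample"
  out
}

#' @export
print.edit_sample <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "edit_sample '%s': %d reads in, %d failed quality, %d failed alignment, %d analyzed\n",
    x$sample_id, r$n_input, r$n_fail_avg_quality,
    r$n_fail_alignment, r$n_analyzed
  ))
  tgt <- x$sites[x$sites$is_target, ]
  cat(sprintf(
    "  on-target %s rate: %.4f%% (depth %d)\n",
    tgt$label, 100 * tgt$rate, tgt$depth
  ))
  invisible(x)
}

#' Write per-site counts and the filter report
#'
#' @param sample An `edit_sample` (or a `site_counts` data.frame).
#' @param sites_path Output TSV for the per-site table.
#' @param report_path Optional JSON path for the filter report.
#' @return Invisibly, the site TSV path.
#' @export
write_site_tsv <- function(sample, sites_path, report_path = NULL) {
  sites <- if (inherits(sample, "edit_sample")) sample$sites else sample
  utils::write.table(
    sites, sites_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(report_path) && inherits(sample, "edit_sample")) {
    jsonlite::write_json(sample$report, report_path, auto_unbox = TRUE)
  }
  invisible(sites_path)
}

#' Read a per-site count TSV
#'
#' @param path TSV written by [write_site_tsv()].
#' @return A `site_counts` data.frame.
#' @export
read_site_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}
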