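#' Generative model for synthetic amplicon reads
#'
#' Configuration of the read simulator. The editing model is an engagement
#' model: each transcript (read) is independently engaged by the
#' Cas13b-ADAR complex with probability `engagement_prob`. Engaged
#' transcripts carry the target A>G edit with probability
#' `on_target_prob_given_engaged` and, independently, each non-target
#' adenosine `j` is edited with its bystander probability `bystander_probs[j]`.
#' Unengaged transcripts are edited at each adenosine with the baseline
#' probability `baseline_probs[j]` (ADAR activity not mediated by the guide;
#' 0 by default). After editing, every base suffers a uniform substitution
#' error with probability `seq_error` (to one of the three other bases), and
#' Phred qualities are drawn from a truncated normal. Bystander edits
#' therefore co-occur on engaged transcripts, which is what makes per-read
#' bystander-free precision lower than independence alone would predict.
#'
#' @param n_reads Number of reads per sample.
#' @param read_length Read length in bases; defaults to the full amplicon
#'   (`NULL`). Shorter reads start at position 1.
#' @param engagement_prob Probability a transcript is complex-engaged.
#' @param on_target_prob_given_engaged Probability an engaged transcript
#'   carries the target A>G edit (default 1).
#' @param bystander_probs Named numeric vector of per-adenosine edit
#'   probabilities for engaged transcripts; names are 1-based reference
#'   positions (target position ignored if present). Default: none.
#' @param baseline_probs Named numeric vector of per-adenosine edit
#'   probabilities for unengaged transcripts. Default: none.
#' @param seq_error Per-base substitution error probability (<= 0.1).
#' @param qual_mean,qual_sd Mean and spread of the Phred quality model
#'   (truncated to `[0, 41]`). Defaults 37 and 3.
#' @param orientation_mixed If `TRUE`, every second read is emitted
#'   reverse-complemented, emulating an unmerged paired-end library.
#' @param seed Integer seed; identical config plus reference gives
#'   byte-identical FASTQ output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 20000L,
                       read_length = NULL,
                       engagement_prob = 0,
                       on_target_prob_given_engaged = 1,
                       bystander_probs = numeric(0),
                       baseline_probs = numeric(0),
                       seq_error = 0.001,
                       qual_mean = 37,
                       qual_sd = 3,
                       orientation_mixed = FALSE,
                       seed = 1L) {
  probs <- c(
    engagement_prob, on_target_prob_given_engaged,
    bystander_probs, baseline_probs
  )
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (seq_error < 0 || seq_error > 0.1) stop("seq_error must lie in [0, 0.1]")
  structure(
    list(
      n_reads = as.integer(n_reads),
      read_length = if (is.null(read_length)) NULL else as.integer(read_length),
      engagement_prob = engagement_prob,
      on_target_prob_given_engaged = on_target_prob_given_engaged,
      bystander_probs = bystander_probs,
      baseline_probs = baseline_probs,
      seq_error = seq_error,
      qual_mean = qual_mean,
      qual_sd = qual_sd,
      orientation_mixed = isTRUE(orientation_mixed),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Expected observed A>G rate at a site
#'
#' Closed form for the rate the quantification pipeline estimates at an
#' adenosine whose pre-error edit probability is `p` under uniform
#' substitution error `error`: G is observed with probability
#' `p(1-error) + (1-p) error/3`, and an A-or-G call (the rate denominator)
#' with probability `1 - 2 error/3`.
#'
#' @param p Pre-error per-read edit probability at the site.
#' @param error Per-base substitution error rate.
#' @return Expected observed rate `n_G / (n_A + n_G)`.
#' @export
expected_observed_rate <- function(p, error) {
  (p * (1 - error) + (1 - p) * error / 3) / (1 - 2 * error / 3)
}

#' Calibrate an edit probability to a desired observed rate
#'
#' Inverts [expected_observed_rate()]: returns the pre-error per-read edit
#' probability whose expected observed A>G rate equals `rate` under
#' substitution error `error`. Reported editing rates from sequencing data
#' are observed quantities that include the sequencing-error floor, so
#' generative truths pegged to reported rates should be set on this scale.
#'
#' @param rate Desired expected observed rate (fraction, not percent).
#' @param error Per-base substitution error rate.
#' @return Edit probability in `[0, 1]`.
#' @export
calibrate_edit_prob <- function(rate, error) {
  p <- (rate * (1 - 2 * error / 3) - error / 3) / (1 - 4 * error / 3)
  if (any(p < 0)) {
    stop("requested rate is below the sequencing-error floor error/3")
  }
  if (any(p > 1)) stop("requested rate implies edit probability > 1")
  p
}

# Expand a named per-position probability vector to all adenosines.
expand_site_probs <- function(probs, ref, exclude_target = FALSE) {
  out <- stats::setNames(
    numeric(length(ref$adenosine_positions)),
    as.character(ref$adenosine_positions)
  )
  if (length(probs)) {
    if (is.null(names(probs))) {
      stop("site probability vectors must be named by reference position")
    }
    bad <- setdiff(names(probs), names(out))
    if (length(bad)) {
      stop(
        "probability keys outside the reference adenosine set: ",
        paste(bad, collapse = ", ")
      )
    }
    out[names(probs)] <- probs
  }
  if (exclude_target) out[as.character(ref$target_pos)] <- 0
  out
}

#' Simulate amplicon sequencing reads
#'
#' Draws `cfg$n_reads` reads from the engagement model described in
#' [sim_config()] against an [amplicon_ref()] and returns them as a
#' `QualityScaledDNAStringSet` ready for FASTQ export (Phred+33).
#'
#' @param ref An [amplicon_ref()].
#' @param cfg A [sim_config()]; `bystander_probs`/`baseline_probs` must be
#'   keyed by reference adenosine positions.
#' @return A `Biostrings::QualityScaledDNAStringSet` with read names
#'   `read1 ... readN`.
#' @export
simulate_reads <- function(ref, cfg) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(cfg, "sim_config"))
  L <- if (is.null(cfg$read_length)) nchar(ref$sequence) else cfg$read_length
  if (L > nchar(ref$sequence)) stop("read_length exceeds the amplicon length")
  n <- cfg$n_reads
  bases <- c("A", "C", "G", "T")
  ref_chars <- strsplit(substr(ref$sequence, 1L, L), "")[[1]]
  # per-adenosine edit probabilities, engaged and unengaged
  q_eng <- expand_site_probs(cfg$bystander_probs, ref, exclude_target = TRUE)
  q_base <- expand_site_probs(cfg$baseline_probs, ref)
  a_pos <- ref$adenosine_positions[ref$adenosine_positions <= L]
  q_eng <- q_eng[as.character(a_pos)]
  q_base <- q_base[as.character(a_pos)]

  withr_seed(cfg$seed, {
    m <- matrix(rep(ref_chars, each = n), nrow = n, ncol = L)
    engaged <- stats::runif(n) < cfg$engagement_prob
    # target edit on engaged transcripts (draw order fixed: target first,
    # then bystanders left to right, then error, then qualities)
    if (ref$target_pos <= L) {
      hit <- engaged & (stats::runif(n) < cfg$on_target_prob_given_engaged)
      m[hit, ref$target_pos] <- "G"
    }
    for (k in seq_along(a_pos)) {
      j <- a_pos[k]
      if (j == ref$target_pos) {
        flip <- !engaged & (stats::runif(n) < q_base[k])
      } else {
        u <- stats::runif(n)
        flip <- ifelse(engaged, u < q_eng[k], u < q_base[k])
      }
      m[flip, j] <- "G"
    }
    # uniform substitution error to a different base
    if (cfg$seq_error > 0) {
      err <- which(matrix(stats::runif(n * L) < cfg$seq_error, n, L))
      if (length(err)) {
        shift <- sample.int(3L, length(err), replace = TRUE)
        old <- match(m[err], bases)
        m[err] <- bases[((old - 1L + shift) %% 4L) + 1L]
      }
    }
    quals <- matrix(
      pmax(0L, pmin(41L, as.integer(round(
        stats::rnorm(n * L, cfg$qual_mean, cfg$qual_sd)
      )))),
      n, L
    )
    seqs <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
    reads <- Biostrings::DNAStringSet(seqs)
    if (cfg$orientation_mixed) {
      rc <- seq_len(n) %% 2L == 0L
      reads[rc] <- Biostrings::reverseComplement(reads[rc])
      quals[rc, ] <- quals[rc, L:1, drop = FALSE]
    }
    names(reads) <- paste0("read", seq_len(n))
    qual_strings <- vapply(
      seq_len(n),
      function(i) rawToChar(as.raw(quals[i, ] + 33L)),
      character(1)
    )
    Biostrings::QualityScaledDNAStringSet(
      reads, Biostrings::PhredQuality(qual_strings)
    )
  })
}

#' Write simulated reads to FASTQ
#'
#' @param reads A `QualityScaledDNAStringSet` (e.g. from [simulate_reads()]).
#' @param path Output FASTQ path (Phred+33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Read a FASTQ file as quality-scaled DNA
#'
#' @param path FASTQ path (Phred+33, `.gz` transparent).
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns that it drops its own internal metadata columns while
  # assembling the quality-scaled set; nothing of the record is lost.
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  S4Vectors::mcols(x) <- NULL
  x
}
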