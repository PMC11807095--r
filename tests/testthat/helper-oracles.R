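# Independent oracles and tiny fixtures used across the suite.

# Exhaustive two-sided Fisher p: enumerate the full hypergeometric support
# with fixed margins and sum probabilities <= observed (relative tie
# tolerance as in the conventional two-sided definition).
fisher_enum_oracle <- function(case_g, case_a, ctrl_g, ctrl_a) {
  m <- case_g + case_a + ctrl_g + ctrl_a
  k <- case_g + ctrl_g # total G
  n1 <- case_g + case_a # case margin
  support <- max(0L, k - (ctrl_g + ctrl_a)):min(k, n1)
  probs <- stats::dhyper(support, k, m - k, n1)
  p_obs <- stats::dhyper(case_g, k, m - k, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct step-up BH definition.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Minimal quadratic global aligner with linear gap penalty; returns the
# per-reference-position read base (or "-") for a toy pair. Independent of
# the package's Biostrings-backed alignment path.
nw_oracle <- function(read, ref, match = 2, mismatch = -1, gap = -6) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  n <- length(r)
  m <- length(s)
  sc <- matrix(0, n + 1, m + 1)
  sc[, 1] <- gap * 0:n
  sc[1, ] <- gap * 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- sc[i, j] + if (r[i] == s[j]) match else mismatch
      sc[i + 1, j + 1] <- max(d, sc[i, j + 1] + gap, sc[i + 1, j] + gap)
    }
  }
  calls <- rep(NA_character_, m)
  i <- n
  j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
      sc[i + 1, j + 1] == sc[i, j] + (if (r[i] == s[j]) match else mismatch)) {
      calls[j] <- r[i]
      i <- i - 1
      j <- j - 1
    } else if (i > 0 && sc[i + 1, j + 1] == sc[i, j + 1] + gap) {
      i <- i - 1
    } else {
      calls[j] <- "-"
      j <- j - 1
    }
  }
  calls
}

# Tiny hand-checkable reference: target A (position 11) inside TTAGC[A]GCTAA.
tiny_ref <- function() {
  #          1234567890123456789012345
  seq_chr <- "CCGGTTAGCTAGCAGCTAACCGGTT"
  amplicon_ref("tiny", seq_chr, target_pos = 14, guide_window = c(6, 20))
}

# site_counts-shaped table from raw vectors (positions default A ordinals).
make_counts <- function(n_g, n_a, positions = seq_along(n_g),
                        target = positions[1], sample_id = "s") {
  out <- data.frame(
    sample_id = sample_id,
    position = positions,
    label = paste0("A", seq_along(positions)),
    is_target = positions == target,
    n_A = as.integer(n_a),
    n_G = as.integer(n_g),
    n_other = 0L,
    n_masked = 0L,
    depth = as.integer(n_a + n_g),
    rate = ifelse(n_a + n_g > 0, n_g / (n_a + n_g), NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_counts", "data.frame")
  out
}

# Reads object from explicit base strings and integer qualities.
make_reads <- function(seqs, quals = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (length(seqs)) names(x) <- paste0("r", seq_along(seqs))
  if (is.null(quals)) {
    quals <- lapply(nchar(seqs), function(L) rep(37L, L))
  }
  qstr <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
  Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(qstr))
}
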