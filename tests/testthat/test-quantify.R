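test_that("read-quality filtering uses strict thresholds and masks single bases", {
  ref <- tiny_ref()
  L <- nchar(ref$sequence)
  reads <- make_reads(
    rep(ref$sequence, 3),
    quals = list(
      rep(37L, L),                 # retained, untouched
      rep(c(29L, 30L), length.out = L), # mean 29.5 <= 30 -> discarded
      c(15L, rep(35L, L - 1L))     # retained, first base masked
    )
  )
  f <- filter_reads(reads)
  expect_identical(f$report$n_input, 3L)
  expect_identical(f$report$n_fail_avg_quality, 1L)
  expect_identical(f$report$n_retained, 2L)
  # brute-force recount of masked bases in retained reads
  kept_quals <- list(rep(37L, L), c(15L, rep(35L, L - 1L)))
  expect_identical(
    f$report$bases_masked,
    sum(vapply(kept_quals, function(q) sum(q <= 20L), integer(1)))
  )
  expect_identical(as.list(f$mask)[[1]], rep(FALSE, L))
  expect_true(as.list(f$mask)[[2]][1])
  # a read with mean exactly 30 is discarded (strict > 30)
  f30 <- filter_reads(make_reads(ref$sequence, quals = list(rep(30L, L))))
  expect_identical(f30$report$n_retained, 0L)
  # empty input gives an empty, balanced report
  f0 <- filter_reads(make_reads(character(0)))
  expect_identical(f0$report$n_input, 0L)
})

test_that("exact and reverse-complement reads align with full identity", {
  ref <- make_reference(seed = 6)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ref$sequence))
  )
  reads <- make_reads(c(ref$sequence, rc))
  aligned <- align_reads(filter_reads(reads), ref)
  expect_identical(aligned$orientation, c("+", "-"))
  expect_equal(aligned$identity, c(1, 1))
  # strand symmetry: both rows carry identical sense-strand calls
  expect_identical(aligned$calls[1, ], aligned$calls[2, ])
})

test_that("reverse-complementing every read changes no allele count", {
  ref <- make_reference(seed = 6)
  cfg <- sim_config(
    n_reads = 200, engagement_prob = 0.3, seq_error = 0.01, seed = 5
  )
  reads <- simulate_reads(ref, cfg)
  seqs <- methods::as(reads, "DNAStringSet")
  quals <- as.list(methods::as(Biostrings::quality(reads), "IntegerList"))
  flipped <- make_reads(
    as.character(Biostrings::reverseComplement(seqs)),
    quals = lapply(quals, rev)
  )
  s1 <- quantify_sample(reads, ref)
  s2 <- quantify_sample(flipped, ref)
  expect_identical(s1$sites$n_A, s2$sites$n_A)
  expect_identical(s1$sites$n_G, s2$sites$n_G)
  expect_identical(s1$sites$n_other, s2$sites$n_other)
})

test_that("a single substitution is placed where the quadratic DP oracle puts it", {
  ref <- tiny_ref()
  mutated <- ref$sequence
  substr(mutated, 14, 14) <- "G" # the target adenosine, edited
  reads <- make_reads(mutated)
  aligned <- align_reads(filter_reads(reads), ref)
  expect_equal(aligned$identity, 1 - 1 / nchar(ref$sequence))
  oracle <- nw_oracle(mutated, ref$sequence)
  expect_identical(aligned$calls[1, ], oracle)
  expect_identical(aligned$calls[1, 14], "G")
})

test_that("indel-bearing reads are aligned with gap-adjacent columns masked", {
  ref <- make_reference(seed = 9)
  # delete base 50 and add ~6% substitutions so the gapless fast path
  # cannot win and the affine DP runs
  chars <- strsplit(ref$sequence, "")[[1]]
  del <- paste(chars[-50], collapse = "")
  reads <- make_reads(del)
  aligned <- align_reads(filter_reads(reads), ref)
  expect_identical(nrow(aligned$calls), 1L)
  calls <- aligned$calls[1, ]
  # the deleted column and its neighbours are excluded from counting
  expect_true(all(calls[49:51] == "-"))
  expect_identical(calls[40], chars[40])
  # low-identity junk is rejected and counted
  junk <- make_reads(paste(rep("ACGT", 50), collapse = ""))
  a2 <- align_reads(filter_reads(junk), make_reference(seed = 10))
  expect_identical(a2$n_fail_alignment, 1L)
})

test_that("allele counting follows the documented denominator rules", {
  ref <- tiny_ref()
  apos <- ref$adenosine_positions
  L <- nchar(ref$sequence)
  # synthetic call matrix: 4 reads, hand-set bases at the first adenosine
  calls <- matrix(
    rep(strsplit(ref$sequence, "")[[1]], each = 4), nrow = 4, ncol = L
  )
  j <- apos[1]
  calls[, j] <- c("A", "G", "C", "N")
  tab <- count_alleles(list(calls = calls), ref)
  row <- tab[tab$position == j, ]
  expect_identical(row$n_A, 1L)
  expect_identical(row$n_G, 1L)
  expect_identical(row$n_other, 1L)
  expect_identical(row$n_masked, 1L)
  expect_equal(row$rate, 0.5) # C and N excluded from the denominator
  # 50/25/25 A/G/C mix -> rate 25/75
  calls2 <- matrix(
    rep(strsplit(ref$sequence, "")[[1]], each = 100), nrow = 100, ncol = L
  )
  calls2[, j] <- rep(c("A", "G", "C"), times = c(50, 25, 25))
  tab2 <- count_alleles(list(calls = calls2), ref)
  expect_equal(tab2$rate[tab2$position == j], 25 / 75)
  # a site covered only by masked bases has an undefined rate
  calls2[, apos[2]] <- "N"
  tab3 <- count_alleles(list(calls = calls2), ref)
  expect_true(is.na(tab3$rate[tab3$position == apos[2]]))
  # count conservation at every site
  expect_true(all(tab$n_A + tab$n_G + tab$n_other + tab$n_masked == 4L))
  expect_true(all(tab2$n_A + tab2$n_G + tab2$n_other + tab2$n_masked == 100L))
  expect_true(all(tab3$n_A + tab3$n_G + tab3$n_other + tab3$n_masked == 100L))
})

test_that("estimated rates are unbiased over a grid of generative truths", {
  ref <- make_reference(seed = 11)
  n <- 20000
  for (truth in c(0.001, 0.005, 0.02, 0.05, 0.2, 0.8)) {
    cfg <- sim_config(
      n_reads = n, engagement_prob = truth, seq_error = 0,
      seed = round(truth * 1e4) + 1
    )
    s <- quantify_sample(simulate_reads(ref, cfg), ref, keep_calls = FALSE)
    r <- s$sites$rate[s$sites$is_target]
    expect_lt(abs(r - truth), 4 * sqrt(truth * (1 - truth) / n))
  }
})

test_that("quantification recovers the generative on-target rate", {
  ref <- make_reference(seed = 12)
  n <- 20000
  cfg <- sim_config(n_reads = n, engagement_prob = 0.05, seq_error = 0, seed = 2)
  s <- quantify_sample(simulate_reads(ref, cfg), ref, keep_calls = FALSE)
  r <- s$sites$rate[s$sites$is_target]
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(r - 0.05), half)
  expect_identical(
    s$report$n_input,
    s$report$n_fail_avg_quality + s$report$n_fail_alignment +
      s$report$n_analyzed
  )
})

test_that("FASTQ round trip and re-quantification are deterministic", {
  ref <- make_reference(seed = 13)
  cfg <- sim_config(
    n_reads = 300, engagement_prob = 0.1, seq_error = 0.005,
    orientation_mixed = TRUE, seed = 3
  )
  tf <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(ref, cfg), tf)
  s1 <- quantify_sample(tf, ref)
  s2 <- quantify_sample(tf, ref)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$sample_id, sub("\\.fastq$", "", basename(tf)))
  # all-reads-fail input: empty table, balanced report
  bad <- make_reads(
    ref$sequence,
    quals = list(rep(10L, nchar(ref$sequence)))
  )
  s3 <- quantify_sample(bad, ref)
  expect_identical(s3$report$n_analyzed, 0L)
  expect_true(all(s3$sites$depth == 0L))
})
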