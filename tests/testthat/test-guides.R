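test_that("tiling emits the requested mismatch-distance series of 50 nt spacers", {
  ref <- make_reference(length = 200, target_pos = 100, seed = 1)
  guides <- tile_guides(ref, spacer_length = 50, d_min = 18, d_max = 42, step = 6)
  expect_identical(guides$mismatch_distance, c(18L, 24L, 30L, 36L, 42L))
  expect_identical(nrow(guides), 5L)
  expect_true(all(nchar(guides$spacer) == 50L))
  expect_identical(guides$name[4], "50 nt-36")
})

test_that("every spacer differs from the window reverse complement at exactly one C", {
  ref <- make_reference(length = 200, target_pos = 100, seed = 2)
  for (len in c(30L, 50L)) {
    guides <- tile_guides(ref, spacer_length = len, d_min = 18, d_max = 28, step = 2)
    for (i in seq_len(nrow(guides))) {
      window <- substr(ref$sequence, guides$window_start[i], guides$window_end[i])
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(window)))
      diffs <- which(strsplit(guides$spacer[i], "")[[1]] != strsplit(rc, "")[[1]])
      expect_length(diffs, 1L)
      expect_identical(substr(guides$spacer[i], diffs, diffs), "C")
      # the mismatch faces the target adenosine...
      expect_identical(
        guides$window_start[i] + (len - diffs + 1L) - 1L, ref$target_pos
      )
      # ...at distance d (inclusive) from the scaffold-proximal 3' end
      expect_identical(len - diffs + 1L, guides$mismatch_distance[i])
      # restoring the complement of the target A makes it an exact revcomp
      restored <- guides$spacer[i]
      substr(restored, diffs, diffs) <- "T"
      expect_identical(restored, rc)
    }
  }
})

test_that("a toy window reproduces the hand reverse complement with central C", {
  ref <- tiny_ref()
  # spacer length 11 is not a supported preset; tile a 30 nt guide on a
  # reference wide enough instead, then hand-check a small window directly
  window <- substr(ref$sequence, 9, 19) # CTAGCAGCTAA, target A at offset 6
  expect_identical(substr(ref$sequence, 14, 14), "A")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(window)))
  expect_identical(rc, "TTAGCTGCTAG")
  spacer_manual <- rc
  substr(spacer_manual, 6, 6) <- "C" # opposite the target adenosine
  expect_identical(spacer_manual, "TTAGCCGCTAG")
})

test_that("out-of-bounds mismatch distances are skipped with a warning", {
  ref <- make_reference(length = 120, target_pos = 110, guide_span = 50, seed = 1,
                        mismatch_distance = 45)
  expect_warning(
    guides <- tile_guides(ref, spacer_length = 50, d_min = 18, d_max = 42, step = 6),
    "skipped"
  )
  # windows with win_end = 110 - d + 50 > 120 (d < 40) are dropped
  expect_true(all(guides$window_end <= 120))
  expect_identical(attr(guides, "skipped_d"), c(18L, 24L, 30L, 36L))
})

test_that("scaffold attachment appends the orthologue DR and only the DR", {
  ref <- make_reference(seed = 3)
  guides <- tile_guides(ref, d_min = 24, d_max = 36, step = 6)
  tab <- example_scaffold_table()
  no_dr <- attach_scaffold(guides, tab, include_dr = FALSE)
  expect_identical(no_dr$full_sequence, no_dr$spacer)
  expect_false(any(no_dr$has_direct_repeat))
  with_dr <- attach_scaffold(guides, tab, include_dr = TRUE)
  expect_identical(
    nchar(with_dr$full_sequence),
    nchar(with_dr$spacer) + nchar(tab["PspCas13b"])[[1]]
  )
  expect_true(all(startsWith(with_dr$full_sequence, with_dr$spacer)))
  # two orthologues with different DRs differ only in the DR segment
  g3 <- tile_guides(ref, d_min = 24, d_max = 24, orthologue = "Cas13bt3")
  a <- attach_scaffold(guides[guides$mismatch_distance == 24, ], tab)
  b <- attach_scaffold(g3, tab)
  expect_identical(a$spacer, b$spacer)
  expect_identical(
    substr(a$full_sequence, 51, nchar(a$full_sequence))[[1]],
    tab[["PspCas13b"]]
  )
  expect_identical(
    substr(b$full_sequence, 51, nchar(b$full_sequence))[[1]],
    tab[["Cas13bt3"]]
  )
  expect_error(
    attach_scaffold(guides, tab[c("Cas13bt1", "Cas13bt3")]),
    "unknown orthologue"
  )
})

test_that("non-targeting spacers avoid 15-mer matches to forbidden references", {
  ref <- make_reference(seed = 4)
  nt <- nontargeting_guide(spacer_length = 30, forbidden = list(ref), seed = 7)
  expect_identical(nchar(nt$spacer), 30L)
  # exhaustive substring scan against the reference and its reverse complement
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ref$sequence))
  )
  starts <- 1:(30 - 15 + 1)
  for (s in starts) {
    kmer <- substr(nt$spacer, s, s + 14)
    expect_false(grepl(kmer, ref$sequence, fixed = TRUE))
    expect_false(grepl(kmer, rc, fixed = TRUE))
  }
  nt2 <- nontargeting_guide(spacer_length = 30, forbidden = list(ref), seed = 7)
  expect_identical(nt$spacer, nt2$spacer)
  expect_error(nontargeting_guide(forbidden = list()), "forbidden")
})

test_that("guide FASTA and manifest exports round-trip the spacer set", {
  ref <- make_reference(seed = 3)
  guides <- attach_scaffold(tile_guides(ref))
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_guides(guides, fa, tsv)
  back <- Biostrings::readBStringSet(fa)
  expect_identical(as.character(back), stats::setNames(guides$full_sequence, guides$name))
  man <- utils::read.delim(tsv)
  expect_identical(man$mismatch_distance, guides$mismatch_distance)
  rna <- tempfile(fileext = ".fasta")
  write_guides(guides, rna, tempfile(), rna = TRUE)
  expect_false(any(grepl("T", as.character(Biostrings::readBStringSet(rna)))))
})
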