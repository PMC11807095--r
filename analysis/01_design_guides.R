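#!/usr/bin/env Rscript
# Guide design for the synthetic premature-stop amplicon.
#
# Tiles 50-nt PspCas13b spacers with an A-C mismatch at the target
# adenosine across mismatch distances 18-42 nt (step 6), adds a 30-nt
# series for the compact Cas13bt orthologues, a non-targeting control
# spacer, and scaffold-attached and scaffold-less (direct-repeat removed)
# variants. Writes FASTA + TSV manifests under results/guides/.

suppressPackageStartupMessages(library(adarcall))

out <- "results/guides"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref <- make_reference(length = 200, target_pos = 100, guide_span = 50,
                      seed = 20260920)
write_reference_fasta(ref, file.path(out, "amplicon.fasta"))
message(sprintf(
  "reference: 200 bp synthetic amplicon, target adenosine %s at position %d",
  target_label(ref), ref$target_pos
))

g50 <- tile_guides(ref, spacer_length = 50, d_min = 18, d_max = 42, step = 6)
g30 <- tile_guides(ref, spacer_length = 30, d_min = 18, d_max = 28, step = 2,
                   orthologue = "Cas13bt3")
nt <- nontargeting_guide(spacer_length = 50, forbidden = list(ref), seed = 1)

message(sprintf(
  "tiled %d x 50-nt PspCas13b guides (d = %s) and %d x 30-nt Cas13bt3 guides",
  nrow(g50), paste(g50$mismatch_distance, collapse = ","), nrow(g30)
))

tab <- example_scaffold_table() # synthetic stand-in DR sequences
with_dr <- attach_scaffold(rbind(g50, g30), tab, include_dr = TRUE)
no_dr <- attach_scaffold(rbind(g50, g30), tab, include_dr = FALSE)

write_guides(with_dr, file.path(out, "guides_with_dr.fasta"),
             file.path(out, "guides_with_dr.tsv"))
write_guides(no_dr, file.path(out, "guides_spacer_only.fasta"),
             file.path(out, "guides_spacer_only.tsv"))
write_guides(nt, file.path(out, "nontargeting.fasta"),
             file.path(out, "nontargeting.tsv"))
message("wrote guide FASTA/TSV sets to ", out)
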