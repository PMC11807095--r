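# adarcall

Quantification and site calling for Cas13b-ADAR RNA base editing from
targeted amplicon sequencing.

## The problem

Programmable A-to-I RNA editing recruits the ADAR deaminase to a chosen
adenosine with a Cas13b guide RNA carrying an A–C mismatch at the target
base. Because inosine is read as guanosine, this repairs G>A
premature-stop mutations — such as those truncating usherin in
*USH2A*-associated retinal disease — at the transcript level, without
touching the genome. Evaluating such editors requires a consistent
analysis stack:

* **Guide design** — tile spacers across the target so the A–C mismatch
  sits at a range of distances *d* from the gRNA scaffold, the main
  determinant of editing efficiency.
* **Reporter quantification** — convert dual-luciferase plates (Firefly
  restored by editing, Renilla as expression control) into normalized
  editing efficiencies.
* **Deep-sequencing quantification** — per-adenosine A>G editing rates
  from amplicon FASTQ reads: quality filtering, orientation-aware
  alignment, allele counting.
* **Off-target (bystander) site calling** — ADAR also deaminates nearby
  adenosines in the gRNA-induced duplex; sites are called against pooled
  control replicates with exact tests.
* **Precision** — the per-read view: of the transcripts that received the
  intended correction, how many carry no bystander edit?

`adarcall` implements all five stages plus a generative simulator
(synthetic FASTQ with an explicit editing model, synthetic reporter
plates), so the whole pipeline is testable end to end without sequencing
data.

## The statistics at the core

At reference adenosine *j*, with aligned read bases tallied into counts
`n_A`, `n_G` (other bases and masked/gap columns excluded), the editing
rate is

```
r_j = n_G / (n_A + n_G)
```

Reads are filtered at mean Phred > 30, individual bases masked at
Phred ≤ 20. Off-target sites are called per adenosine from replicate-pooled
counts with a two-sided Fisher exact test against pooled controls,
adjusted across all amplicon adenosines by Benjamini–Hochberg, significant
at adjusted *p* < 0.01. The condition-level off-target summary is the
per-replicate mean of `r_j` over significant off-target sites, averaged
across replicates (mean ± SEM); the on/off ratio divides the on-target
mean by it. Bystander-free precision is `P = n_clean / n_corrected` over
reads with an unmasked G at the target.

The simulator draws each read independently: a transcript is
complex-engaged with probability *e*; engaged transcripts carry the
target edit and, independently, each bystander adenosine *j* with its
conditional probability *q_j*; a uniform substitution error ε then
applies per base. Editing co-occurs on engaged transcripts, which is what
keeps per-read precision below what independent per-site rates would give.

## Worked example

```r
library(adarcall)

ref <- make_reference(length = 200, target_pos = 100, guide_span = 50, seed = 42)
ref
#> amplicon_ref 'synthetic_amplicon': 200 bp, target A at 100 (A29),
#>   guide window [76, 125], 56 adenosines

tile_guides(ref, spacer_length = 50, d_min = 18, d_max = 42, step = 6)[,
  c("name", "mismatch_distance", "window_start", "window_end")]
#>       name mismatch_distance window_start window_end
#> 1 50 nt-18                18           83        132
#> 2 50 nt-24                24           77        126
#> 3 50 nt-30                30           71        120
#> 4 50 nt-36                36           65        114
#> 5 50 nt-42                42           59        108

# a synthetic "injected eye" at 2.04% on-target editing, and a control
cfg  <- cohort_sim_config(ref, on_target_rate = 0.0204,
                          n_reads = 20000, seq_error = 0.001, seed = 1)
eye1 <- quantify_sample(simulate_reads(ref, cfg), ref, sample_id = "eye1")
eye1
#> edit_sample 'eye1': 20000 reads in, 0 failed quality, 0 failed alignment,
#>   20000 analyzed
#>   on-target A29 rate: 2.1016% (depth 20000)

ctrl <- quantify_sample(simulate_reads(ref,
  cohort_sim_config(ref, 0, n_reads = 20000, seq_error = 0.001, seed = 2)),
  ref, sample_id = "pbs1")
calls <- call_sites(list(eye1$sites), list(ctrl$sites))
subset(calls, significant, select = c(label, case_rate, control_rate, p_adj))
#>    label  case_rate control_rate         p_adj
#> 29   A29 0.02101576 0.0005502201 2.527638e-108
```

The on-target estimate (2.10%) recovers the generative truth (2.04%)
within binomial sampling error at 20,000 reads, and the target is the
only site called against the control: the simulated control's rate at A29
(0.055%) is the sequencing-error floor ε/3 ≈ 0.033% plus noise.

The numbered scripts under `analysis/` run the full narrative — guide
design, a simulated luciferase screen, in-vivo-style cohorts through the
orchestrated pipeline (`run_pipeline()`), and the precision analysis —
writing tables under `results/`.

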