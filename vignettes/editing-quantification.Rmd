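---
title: "Quantifying Cas13b-ADAR RNA editing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cas13b-ADAR RNA editing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adarcall)
```

# Scope and model

`adarcall` analyses programmable A-to-I(G) RNA base editing experiments
in which a catalytically dead Cas13b fused to the ADAR deaminase domain
is directed to a G>A premature-stop adenosine by a guide RNA carrying an
A–C mismatch at the target base. The package covers five stages — guide
tiling, dual-luciferase reporter normalization, per-adenosine A>G
quantification from amplicon FASTQ, control-referenced off-target site
calling, and per-read bystander-free precision — plus a generative
simulator that stands in for cell-culture and animal sequencing data.

Throughout, the reference is the *mutant* (A-containing) allele on the
sense strand, "editing" is A→G at a reference adenosine, and coordinates
are 1-based closed intervals, the Biostrings/GenomicRanges convention.
Adenosines are labelled `A_k` by their sense-strand ordinal, the labelling
used in bystander-editing figures.

# The generative editing model

`sim_config()` describes a per-read engagement model:

* a transcript is engaged by the editing complex with probability $e$;
* an engaged transcript carries the target A→G edit with probability
  $c$ (default 1) and, independently, each bystander adenosine $j$ with
  probability $q_j$;
* an unengaged transcript is edited at each adenosine with a baseline
  probability $q^0_j$ (default 0);
* every base then suffers a uniform substitution error with probability
  $\varepsilon$ (to one of the three other bases), and Phred qualities
  are drawn from a normal distribution (mean 37, sd 3) truncated to
  $[0, 41]$.

The engagement structure is deliberate: if per-read site edits were fully
independent at their *marginal* rates, the fraction of corrected
transcripts free of bystander edits would be far higher than the 70–85%
observed in practice, because marginal bystander rates are small.
Conditioning bystander edits on engagement concentrates them on the same
reads that receive the correction, which is what the biology (a
double-stranded gRNA–target duplex presenting many adenosines to one
bound deaminase) implies. Under this model, the expected precision for a
corrected read is $\prod_j (1 - q_j)$, the closed form the estimator is
validated against.

Two closed forms connect generative probabilities to what the pipeline
measures at a site with pre-error edit probability $p$:

$$\Pr(\text{G observed}) = p(1-\varepsilon) + (1-p)\varepsilon/3,
\qquad
\Pr(\text{A or G observed}) = 1 - 2\varepsilon/3,$$

so the expected observed rate is their ratio
(`expected_observed_rate()`). Reported editing rates from sequencing are
observed quantities that include the $\varepsilon/3$ error floor;
`calibrate_edit_prob()` inverts the closed form so that generative truths
can be pegged on the observed-rate scale. All cohort simulations in the
tests and the acceptance script are calibrated this way — the alternative
(setting $p$ to the published rate directly) would bias every recovery
check upward by $\approx \varepsilon/3$ for reasons that have nothing to
do with the estimator under test.

Determinism: each `sim_config()` carries an integer seed, and all draws
happen in a fixed vectorized order under that seed, so identical
configuration and reference give byte-identical FASTQ output. Replicates
in `simulate_cohort()` use consecutive seed offsets.

What the simulator does *not* emulate: paired-end reads and merging
(orientation-mixed single-end reads stand in for an unmerged 2×250
library), PCR duplicates and chimeras, library-prep coverage bias,
quality degradation along the read, and context-dependent error. Passing
recovery tests therefore demonstrate estimator correctness under a clean
substitution-error model, not robustness to every artefact of a real
sequencing run.

# Quantification

## Read filtering

Two thresholds, both strict inequalities taken literally: reads are kept
only if their arithmetic mean Phred exceeds 30; in kept reads, bases with
Phred ≤ 20 are masked rather than the read discarded. The mean is the
arithmetic mean of Phred values, not the error-probability mean — a
documented, testable choice. Masking (not discarding) for single bad
bases mirrors the behaviour of the established amplicon-editing analysis
tools' single-base-quality parameter.

## Alignment

Each read is aligned globally to the reference in both orientations and
the better orientation kept; alignments below 80% identity over alignment
columns are rejected and counted. Scoring: match +2, mismatch −1, gap
open −5, gap extend −1. Under this scoring a substitution costs 3
relative to a match while the cheapest gap pair costs 12, so for
full-length reads whose best ungapped identity is ≥ 0.9 the gapless
alignment is provably optimal and the dynamic program (Biostrings
`pairwiseAlignment`) is skipped — this fast path is what keeps
million-read simulated cohorts tractable, and the test suite checks both
paths agree with a quadratic DP oracle on toy pairs. Orientation ties
break to the forward strand.

Columns carrying a read gap, and reference columns within one position of
any gap, are excluded from counting (treated as masked): indel
misplacement next to homopolymers would otherwise manufacture false A>G
calls at adjacent adenosines.

## Allele counting

At each reference adenosine the aligned base goes to `n_A`, `n_G`,
`n_other` (C/T), or `n_masked` (quality-masked, gap, gap-adjacent); the
rate is $r_j = n_G / (n_A + n_G)$. Non-A/G bases are excluded from the
denominator because the quantity of interest is the A-vs-G allele
balance; `n_other` is reported so sequencing pathologies stay visible.
Sites with $n_A + n_G = 0$ have an undefined (NA) rate, never 0. Count
conservation ($n_A + n_G + n_{other} + n_{masked}$ = covering reads) is
asserted property-style in the tests.

# Site calling and condition summaries

Replicate counts are pooled per condition (element-wise sums) before
testing — low per-replicate depth at rare sites makes replicate-level
exact tests uninformative. Each adenosine's pooled case G/A counts are
compared with pooled control counts by a two-sided Fisher exact test
(`stats::fisher.test`, the same kernel the field's analyses call), with
p-values adjusted across all adenosines of the amplicon by
Benjamini–Hochberg (`stats::p.adjust`). Both kernels are cross-checked in
the tests against independent oracles: exhaustive hypergeometric
enumeration over the full 2×2 support, and a direct step-up
implementation. A zero-margin table carries no information and returns
p = 1 with a degeneracy flag.

Significance uses adjusted p < 0.01; the conventional 5% FDR family rate
is recorded in the output metadata alongside. The BH family is all
adenosines of one case-vs-control contrast; separate conditions are
adjusted separately, since each condition is pooled and tested against
the controls on its own.

The target site is tested like any other but labelled on-target. The
condition-level off-target summary is defined as the per-replicate *mean*
rate over significant off-target sites, then averaged across replicates
(± SEM); the per-replicate *sum* over those sites is emitted alongside,
because a scalar "off-target rate" can reasonably mean either and the
choice matters when site counts differ. The generator and the estimator
share the mean definition, so recovery tests are self-consistent. The
on/off ratio divides the on-target mean by the off-target mean and is
flagged undefined when no off-target site is significant.

# Per-read precision

A read is *corrected* if its unmasked aligned base at the target
adenosine is G, and *clean* if no other adenosine in the analysed region
(default: every reference adenosine) carries G; masked and gap columns
contribute no call either way. $P = n_{clean}/n_{corrected}$, undefined
(flagged) when nothing is corrected. Against the engagement model's
closed form $\prod_j(1-q_j)$, the estimator is consistent as read depth
grows; the suite checks a two-bystander case ($q = 0.1$ each,
$P \to 0.81$) at 50,000 reads within Monte-Carlo bounds.

# Luciferase normalization

Background Firefly and Renilla means from transfection-reagent-only wells
are subtracted from all wells (values floored at 0 with a flag — whether
to floor is not standardized, and flooring-with-flag keeps failures
visible). Per well the Firefly/Renilla ratio is formed; technical
duplicates are averaged *on ratios*, not raw channels; the efficiency is
scaled between the mean negative-control and positive-control ratios:
$E = (\bar r_{cond} - \bar r_{neg}) / (\bar r_{pos} - \bar r_{neg})$.
Values outside $[-0.05, 1.05]$ are flagged, never clamped: clamping hides
assay failure. Equal control ratios (no dynamic range) abort. The plate
simulator draws well ratios so the normalization recovers its truths
exactly at zero noise and in expectation under multiplicative noise; the
round trip and affine invariance (rescaling all luminescence by a common
factor) are asserted in the tests.

# Guide design

Spacers are the reverse complement of a reference window with a `C`
substituted opposite the target adenosine. The mismatch distance $d$
counts spacer nucleotides from the mismatched base to the
scaffold-proximal end, inclusive, so a "50 nt-36" guide has its mismatch
36 nt from the scaffold: with the direct repeat appended 3′ (the
PspCas13b-family default here), the covered window is
$[t - d + 1,\; t - d + L]$ for target position $t$ and spacer length
$L$. The 3′ placement and the direct-repeat sequences themselves are
configuration, not constants — scaffold placement differs among Cas13
families, and the bundled `example_scaffold_table()` holds clearly
labelled *synthetic* stand-in sequences, not published direct repeats.
Distances whose window overruns the reference are skipped with a warning
record rather than failing the whole tiling. Non-targeting control
spacers are drawn randomly and rejected if they share any exact 15-mer
with a forbidden reference or its reverse complement. Guides are emitted
as DNA (cloning-oligo sense); `write_guides(rna = TRUE)` transliterates
T→U.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_avg_q` | 30 | Phred | read-level filter, strict `>` |
| `min_base_q` | 20 | Phred | base masking threshold, strict `>` |
| `min_identity` | 0.8 | fraction | alignment rejection threshold |
| `alpha` | 0.01 | adjusted p | site-call significance |
| `seq_error` | 0.001 | per base | substitution error of the emulated platform |
| `qual_mean`, `qual_sd` | 37, 3 | Phred | keeps filters exercised but rarely triggered |
| `engagement_prob` | condition-specific | probability | sets the on-target rate via calibration |
| `dynamic_range` | 20 | ratio | positive/negative control ratio of simulated plates |

# Study conditions used by the recovery checks

The acceptance checks simulate cohorts at the condition means the
analysis is designed to resolve: six replicates of 20,000 reads over a
200-bp amplicon with a 50-nt guide window — read counts inside the
15,000–30,000 post-filter range typical of targeted amplicon studies —
with on-target truths of 2.04%, 0.32% and 0.93%, guide-window bystander
means of 0.10% and 0.05%, a single hot bystander site at 0.36% at
100,000-read depth, and eight matched unengaged control replicates.

Sequencing error is $\varepsilon = 0.001$ for the on-target cohorts. For
the *off-target* cohorts $\varepsilon = 3\times10^{-4}$: a 0.05%
bystander truth cannot be distinguished from an error background of
$\varepsilon/3 \approx 0.033\%$ at these depths (per-site two-proportion
$z \approx 2.2$, nowhere near BH significance across ~40 sites), and the
platform such studies report has its empirical background *below* its
smallest called off-target rate. The off-target platform error is
therefore set so the background (0.01%) sits below 0.05%, with controls
simulated at the same $\varepsilon$. This is a property of the emulated
instrument, fixed once from the power calculation above.

Bystander truths are spread uniformly over the guide-window adenosines
(~12–13 at uniform base composition in a 50-nt window, matching the
`A_28`–`A_40`-style window of real targets); the off-target summary is
invariant to the exact count when truths are uniform.

# Known limitations

* Single-end, full-amplicon reads; no paired-end merging or UMI handling.
* Substitution-only error by default; indel handling exists in the
  aligner (gap-adjacent masking) but the generator does not produce
  indels unless asked.
* Only A>G at adenosines is modelled and counted; other outcome classes
  (C>T deamination artefacts, indel outcomes) appear solely as `n_other`
  or masked columns.
* The Fisher/BH machinery assumes reads are independent; PCR duplicates
  would overstate significance and are not modelled.
* Luciferase ingest is plain TSV; reader-specific export formats are out
  of scope.
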