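---
title: "Quantifying intron retention with irquant: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention with irquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The quantification model

`irquant` treats every annotated intron as one quantification unit and
estimates the fraction of transcripts retaining it as

$$IRratio = \frac{A_i}{A_i + A_e}$$

where $A_i$ is the intronic abundance and $A_e$ the exonic (spliced)
abundance. The two abundances are deliberately estimated differently by
read technology:

* **Short reads.** $A_i$ is the *median* per-base depth over unmasked
  intron positions. The median is robust to local pile-ups from repeats or
  mispriming, which dominate the false-positive modes of IR detection.
  $A_e$ is $\max(\mathrm{SpliceLeft}, \mathrm{SpliceRight})$: short reads
  rarely span both junctions, so the better-supported boundary represents
  the spliced isoform.
* **Long reads.** $A_i$ is the *minimum* depth over unmasked positions: a
  full-length molecule with a retained intron must cover the intron end to
  end, so any uncovered base is positive evidence against retention. This
  is what lets long-read mode reject alternative-3′-end transcripts that a
  median-based estimator scores as retention (the short estimator sees a
  covered 5′ portion and reports a non-zero ratio; the minimum sees the
  uncovered 3′ span and reports 0). $A_e$ is $\mathrm{ExactSplice}$ — reads
  spliced at *both* boundaries — because a full-length read that matches
  only one boundary is evidence for a different isoform, not for this
  intron's splice.

**Jitter.** Long-read basecalling errors shift alignment endpoints around
splice junctions by a few nucleotides. A read gap therefore matches a
boundary when the observed endpoint is within `jitter` nucleotides of the
annotated one, independently at each endpoint. Defaults: 0 (short mode),
3 (long mode). All three tallies (SpliceLeft, SpliceRight, ExactSplice) use
the same tolerance; each tally is monotone non-decreasing in `jitter`, and
$\mathrm{ExactSplice} \le \min(\mathrm{SpliceLeft}, \mathrm{SpliceRight})$
always.

**Masks.** Intron bases overlapped by exons of other transcripts, or by
user-supplied low-mappability intervals (BED), are excluded from depth
statistics. An intron's own parent exons can never overlap its body, so any
overlapping exon is foreign by construction and masks regardless of strand.
An intron left with no evaluable base keeps its catalog entry and raises
`NoEvaluablePositions`.

## Warnings and their thresholds

| warning | rule | default | why this default |
|---|---|---|---|
| `LowCover` | $A_i + A_e <$ `lowcover_min_depth` | 10 | a junction with informative depth 4 (the classic jitter-disabled failure case) must trigger it, while the depth-25 labeling tier for the CNN must not |
| `MinorIsoform` (long mode) | $\mathrm{ExactSplice} < f \cdot \max(\mathrm{SpliceLeft},\mathrm{SpliceRight})$ | $f = 0.5$ | reproduces the canonical imbalanced case (69 exact against 210 one-sided) while tolerating moderate endpoint losses |

Both are exposed as arguments; the exact numeric cutoffs are this package's
own calibration, since only the qualitative rules are fixed by the method.
Classification (`classify_ir`) calls `IR` when the ratio reaches the chosen
threshold (0.05 or 0.10 are the conventional operating points) *and* no
warning is present; it is monotone in the threshold.

## Coordinates

All internal interval arithmetic uses GRanges/IRanges, i.e. 1-based
inclusive coordinates — the natural convention of the Bioconductor stack
this package is built on. Text outputs are likewise 1-based inclusive;
BED export goes through `rtracklayer`, which performs the 0-based
half-open conversion that format requires.

## The convolutional filter

Candidates (short-read IRratio > 0.05, no warnings) are re-examined the way
an analyst would in a genome browser: as an image. `make_input_array`
renders each locus as a 3 × 160 grid — 30 exonic bases per flank at native
resolution, the intron body linearly resampled to 100 positions — with a
depth channel, a splice-evidence channel (piecewise-constant spans carrying
the three splice counts) and a boundary-marker channel, each max-normalised
to $[0,1]$ (an all-zero channel stays zero, so empty loci stay empty rather
than being amplified).

Ground truth comes from matched long reads: `true-IR` needs no warning,
depth ≥ 25 and IRratio > 0.1; `false-IR` needs depth ≥ 50 and IRratio
exactly 0 — absence of retention is harder to assert than presence, hence
the deeper requirement. Both depth rules are read as minimums. A label
stands only when directional and non-directional long-read runs agree.
Because genuine false positives are scarce, the negative class is augmented
with long-read-negative introns whose short-read IRratio exceeds 0.01, and
any residual imbalance is resolved by downsampling the majority class.

The classifier is a small 1-D convolutional network — two convolution
layers (kernels 7 and 5; 8 and 16 filters), max-pooling, global max-pooling
and a sigmoid unit — written directly on base-R matrix algebra, trained
with Adam (learning rate 0.01, batch 32, at most 40 epochs) and early
stopping on a 10% validation split (patience 6). Geometry and optimizer
settings live in `cnn_config()`. Training uses stratified 10-fold
cross-validation reporting per-fold sensitivity, specificity and balanced
accuracy, then refits on all data. Every stochastic element (fold
assignment, initialisation, batch order, validation split) derives from the
`seed` argument, so results reproduce exactly. At desk scale the filter is
validated on generated data: a separable dataset must reach CV balanced
accuracy ≥ 0.95, label-shuffled data must sit at chance, and a noisy
dataset (even Poisson coverage for true events versus spike-artifact
coverage for false ones) must reach ≥ 0.85. These property checks — not any
particular cell line's accuracy — are what passing tests establish;
performance on real tissue depends on training data the user supplies.

## Differential retention

Two tests over per-sample result tables, after a shared filter (an intron
must reach IRratio ≥ 0.05 in at least one sample and, by default, carry
`LowCover` in none):

* **Count GLM (default).** Per sample, the intronic count (intron depth)
  and exonic count (max of the one-sided splice counts) enter a negative
  binomial GLM with condition, count-type and interaction terms; the
  interaction Wald p-value tests whether the intron:exon balance shifts
  between conditions, and its coefficient is the log2 fold change of the
  retention odds. Fitting is delegated to DESeq2 with size factors fixed
  at 1 (the two counts of a sample already share a depth scale; median-of-
  ratios normalisation would partly absorb the type effect the model
  estimates). Untestable (all-zero) introns get `NA` p-values and are
  excluded from the BH adjustment, which is computed across tested introns
  only. Default call: BH < 0.05 and fold change > 1.5.
* **Empirical delta-ratio.** The effect is the difference in group-mean
  IRratio. The null distribution is built from between-replicate |delta|
  values within conditions, pooled across introns and binned by flanking-
  exon abundance (deciles, merged until each bin holds ≥ 100 null values);
  the p-value is the bin's exceedance fraction with a +1 continuity
  correction. Default call: BH < 0.05 and |delta| ≥ 0.1. Because the test
  measures effects against replicate variability, low-coverage events —
  whose ratios fluctuate strongly between replicates — yield fewer calls
  than the GLM on the same data; that asymmetry is a property, not a bug,
  and is asserted in the test suite.

With more than two conditions, every unordered pair is tested and reported
separately. Group labels are symmetric: swapping groups negates the effect
exactly for the ratio test and within numerical tolerance for the GLM.

## What the simulators emulate — and what they do not

`simulate_model` builds deterministic toy gene models (fixed exon/intron
sizes, alternating strand, optional planted antisense exons).
`simulate_short_reads` plants an exact retained fraction per intron:
retained molecules tile the intron (placement is the only noise source),
spliced molecules produce exact-boundary gapped reads.
`simulate_long_reads` emits full-length molecules with per-endpoint splice
jitter drawn uniformly from ±`endpoint_noise`, and can plant
alternative-3′-end molecules terminating inside an intron.
`simulate_groups` skips alignments entirely and generates replicate-level
result tables: biological noise is logit-normal on the retention level
(default sd 0.2 on the logit scale — a bounded-support choice giving ~±20%
relative variation at moderate ratios) with Poisson counting noise at the
chosen depth, which together produce the overdispersion the NB test
expects.

None of the simulators model sequence content, mappability structure,
positional coverage bias, PCR duplication or realistic nanopore error
profiles; alignment itself is out of scope (coordinates are generated
directly). Passing tests therefore demonstrate the correctness of the
estimators, counting rules, filters and tests under controlled conditions —
not end-to-end performance on real libraries.

## Problem sizes and numerical choices

The shipped checks use the scales at which their statistical properties are
already stable: parameter recovery at depth 100–200 over eight introns
(binomial/placement error at depth 150 is well inside the ±0.05 band);
CNN validation on 200 examples with 10-fold CV; differential power on 500
introns (50 planted at delta 0.3) with 3 replicates per group at depth 100,
and the low-coverage contrast at depth 18, just above the LowCover cutoff.
Ties in the median are resolved by mean-of-middle-two; IRratio printing is
three decimals, round-half-even (4/73 prints 0.055); an intron with
$A_i + A_e = 0$ reports ratio 0 plus `LowCover` rather than NaN; introns
sharing one boundary but not the other are distinct catalog units; and
duplicate introns across transcripts collapse to one unit whose parent ids
aggregate comma-separated.

## Known limitations

Single-end semantics (mate pairs are counted as independent records);
no base-quality or duplicate filtering; annotation input is GTF only;
low-mappability regions must be precomputed (BED); the CNN ships untrained —
labels require matched long-read runs; and the GLM requires ≥ 2 replicates
per condition, degenerating (p = 1 or untestable) on zero-variance input.
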