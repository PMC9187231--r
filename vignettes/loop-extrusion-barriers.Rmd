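---
title: "Modelling and detecting cohesin loop-extrusion barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and detecting cohesin loop-extrusion barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopex)
```

## The model

Cohesin extrudes chromatin loops: a ring complex loads onto the fibre and
reels in DNA from both sides until it unloads or is stopped. In a small,
gene-dense genome such as budding yeast's, the dominant obstacles are
transcribing RNA polymerases. A leg that runs head-on into the polymerase
traffic of a gene -- i.e. enters the gene through its 3' end -- stalls
there, so cohesin accumulates in the intergenic regions between
*convergent* gene pairs, and chromatin loops connect neighbouring
convergent sites. Centromeres are absolute two-sided barriers, and in
hydroxyurea(HU)-arrested S phase the replication forks stalled 5--10 kb on
either side of early-firing origins block extrusion as well.

`loopex` implements this picture as a one-dimensional lattice model plus
the full contact-map analysis stack used to detect its consequences:
binning and coverage-(sqrt) normalization, contact-probability curves,
insulation scores, aggregate peak analysis (APA), HICCUPS-style local
background loop calling, arrowhead-style domain calling, anchored
cis-interaction counts, depth-matched binomial comparisons, and the
fold-enrichment rules that classify cohesin peaks, stress-response genes
and early origins from ChIP-like tracks.

## The simulator

`simulate_extrusion()` is a fixed-timestep kinetic Monte Carlo on bins:

* **Loading.** Each vacant adjacent bin pair loads a new two-legged
  extruder with probability `loading_rate` per step, scaled by the free
  fraction of a finite pool of `cohesin_pool` complexes. The pool
  reflects that nuclear cohesin is limiting; without it, reducing the
  unloading rate ten-fold (Wpl1 depletion) drives the lattice into a
  fully jammed state in which loops are paradoxically *shorter* than
  wild type. Loading never places a leg on an absolute barrier bin.
* **Extrusion.** Each leg attempts `extrusion_step` outward single-bin
  moves per step. A move fails if the target bin is occupied by another
  leg (no bypass, no stacking -- this is what piles cohesin up between
  convergent genes) or if a directional barrier on the target bin
  rejects it with probability `1 - permeability` (entry-blocking
  semantics: a blocked leg parks on the near side and retries every
  step).
* **Unloading.** Each extruder unloads with probability
  `unloading_prob` per step, freeing its bins.

Barriers come from `derive_barriers()`. A gene's 3'-end barrier blocks
only head-on legs; its permeability falls linearly with expression,
`max_permeability * max(0, 1 - expr / permeability_scale)`, reaching an
absolute block at `expr >= permeability_scale` (default 2). At that
saturating expression the gene body is so loaded with polymerase that
co-directional passage stalls too, so absolute gene barriers block both
directions -- this is also how the induced stress-response genes behave,
which insulate on both sides. Condition presets:

| preset | barriers | rates |
|---|---|---|
| `WT_G2M` | all gene 3' ends + centromere | -- |
| `thiolutin` | stress genes (absolute) + centromere | -- |
| `scc2_depleted` | as WT | loading x 0.05 |
| `wpl1_depleted` | as WT | unloading x 0.1 |
| `HU` (`_scc2`, `_wpl1`) | as WT + absolute fork pairs at early origins (+/- 7.5 kb, the midpoint of the 5--10 kb replicated span) | co-depletion multipliers |

The loader/unloader multipliers encode substantial but incomplete
depletion, hence the nonzero residuals.

### Kinetic defaults and what they mean

One step is one attempted bin move per leg; with 2-kb bins a step is
roughly the time cohesin needs to extrude 2 kb per side. Defaults:
`loading_rate = 0.002` per vacant bin pair per step, `unloading_prob =
0.02` (mean residence 50 steps, i.e. ~100 kb of free extrusion per
side), `cohesin_pool = 18` for a 150-bin chromosome. At steady state the
wild type carries ~8 extruders (one per ~35 kb, the yeast-like density);
loader depletion leaves < 10% of that, and unloader depletion roughly
doubles it without jamming the lattice. `max_permeability = 0.05` makes
even a weakly expressed gene hold a leg for ~20 steps, comparable to one
residence time, which is the regime in which wild-type loops pin at
adjacent convergent junctions while the long-lived extruders of
Wpl1-depleted cells traverse to more distant junctions -- reproducing
both the "more loops" and the "longer loops" phenotypes at once.

### From trajectories to data

A sequencing library averages over a population of cells, not a single
nucleus. `simulate_population()` therefore pools `n_cells = 25`
independent trajectories (60 recorded steps each after a 500-step
burn-in). This matters most for slow-turnover conditions: a single
Wpl1-depleted trajectory freezes one arrangement of long-lived loops for
the whole observation window and under-samples the set of loop positions
the population explores.

`render_contact_map()` mixes a polymer background with extruder-mediated
contacts: pixel intensity is `w * B + (1 - w) * L / (0.1 * n_bins)`,
where `B` is the `(1 + s)^-alpha` distance-decay background (defaults
`alpha = 1.5`, `w = 0.7`), `L` the mean per-snapshot count of leg pairs
at that pixel (plus a 0.25-weight within-loop bonus adjacent to the loop
base), and `0.1` extruders per bin the reference density at which loop
contacts carry exactly `1 - w` of the mass. Tying the loop mass to
extruder abundance (rather than renormalising it away) is what lets
loader depletion drain loop signal from the map. `read_depth` counts
(default 4 x 10^5) are then drawn multinomially -- sampling noise
included.

`render_tracks()` emits the matching fold-enrichment tracks. The cohesin
track is time-averaged leg occupancy plus a nonspecific-binding floor
(0.08 occupancy units), mean-normalized to 1: ChIP of a depleted factor
flattens towards baseline instead of inflating noise. RNA pol II paints
expression over gene bodies (under transcription inhibition only stress
genes, amplified 5x); BrdU is a fold-enrichment-2 plateau over the
replicated spans of early origins under HU, flat 1.0 otherwise.

## The analysis stack

All coordinates are 0-based half-open base pairs (BED convention); bin
indices are 1-based. Files with 1-based coordinates must be converted
before use.

* **Normalization.** `vc_sqrt_normalize()` divides each entry by the
  square root of its row and column sums. A single pass -- the reference
  behaviour -- halves the exponent of a multiplicative per-bin bias;
  `iterations > 1` continues to the Sinkhorn fixed point at which a
  planted rank-1 bias is removed entirely. The analyses use one pass.
* **Insulation.** Per 1-bin step, the summed contact signal crossing the
  bin within a 40-kb window (pair separation capped at the window), mean
  normalized. The square window follows the stated definition rather
  than diamond variants. Bins within a window of the chromosome ends are
  masked; the mean normalization is per chromosome.
* **APA.** `(2w+1)`-sized pile-ups (`w = 20` bins); strength = central
  11 x 11 sum over the top-right 11 x 11 corner, the standard convention
  for the unstated background square. Pairs too close to the diagonal
  (`separation <= 2w`) or the edges are skipped and counted, not padded.
  Note the corner sits at larger genomic distance than the centre, so on
  a decaying background absolute strengths exceed 1; comparisons should
  be made against matched random pairs on the same background.
* **Loop calling.** For each testable pixel the expected value is the
  mean of the donut ring (Chebyshev radii 2--5 by default; the mapping
  of the reference parameters "p 6,8 / i 12,16" at 500 bp to 2-kb bins)
  pooled with the lower-left quadrant region, excluding the peak disc;
  the horizontal/vertical stripe filters are a documented
  simplification. One-sided Poisson tails on depth-rescaled counts,
  Benjamini-Hochberg at FDR 0.001, a 1.5x minimum local enrichment
  (guarding against barely-enriched pixels reaching significance at
  high depth), 8-connectivity clustering to the maximally enriched
  pixel, then the strict > 10 kb length filter. Anchor filtering demands
  both anchors (+/- one bin of slack; the reference analysis states no
  tolerance) overlap a cohesin site.
* **Domains.** The arrowhead transform
  `A[i,d] = (M[i,i-d] - M[i,i+d]) / (M[i,i-d] + M[i,i+d])`; a
  candidate's corner score is the fraction of informative cells (one
  side inside, one outside) with the expected sign -- a deliberate
  simplification of the full variance/sparsity heuristic stack --
  threshold 0.6 plus a Bonferroni-corrected exact sign test against the
  coin-flip null (small windows reach 0.6 by chance), zero-denominator
  cells treated as missing, greedy
  non-maximum suppression (ties to the tighter interval), and
  cross-resolution merging that collapses calls agreeing within one
  coarse bin.
* **Quantification.** Cis/trans and anchored counts are reported per
  million total pairs (the natural depth-matched reading of the
  ambiguous "read pair per kilobase"); anchored counts use strict
  `> 10 kb` separation and count a pair once even if both ends hit
  features. Origin-anchored regions are origin +/- 12.5 kb: the
  replicated span plus the bins where fork-blocked extruder legs park.
  Two-sided exact binomial tests at p = 0.5 compare depth-matched
  counts. No short-range religation filter is applied by default.
* **Feature rules.** Cohesin peaks: maximal runs of fold enrichment
  > 2.0, LTR-overlapping peaks dropped; arm sites additionally exclude
  the 25-kb pericentromeric span. Stress-response genes: ORF-mean
  (overlap-weighted; the weighting is unstated in the reference) fold
  enrichment > 4.0 under the inhibitor AND < 2.0 in the control AND an
  up-regulation flag (differential-expression FDR < 1e-5, consumed as
  input). Early origins: overlap with a BrdU peak at fold enrichment
  > 1.5. Between-sample scaling: qPCR-anchored factors from 4--7 common
  sites (`chip_scaling_factors()`), and inverse-spike-proportional
  factors for expression values (`rna_spikein_scale()`; the fuller
  regression-based refinement is out of scope).

### Comparing peak sets across depletions

Fold-enrichment tracks are per-sample mean-normalized, so a fixed
threshold is not comparable between samples whose total bound protein
differs: Wpl1 depletion roughly doubles occupancy and halves every
relative enrichment. `scaled_cohesin_peaks()` reproduces the
qPCR-anchored workflow -- enrichment at the reference sample's strongest
shared sites is measured in absolute (simulated-qPCR) units, a scaling
factor is derived, and peaks are called on the rescaled track. Condition
contrasts of anchored loop counts use this; a single-condition analysis
can use `call_peaks()` directly.

## What the synthetic data does and does not show

The generator reproduces the *structure* the analyses assume: directional
gene barriers whose strength tracks expression, convergent-site cohesin
accumulation, condition presets that alter barriers or rates, a
distance-decay background with multinomial sampling noise, and matching
occupancy tracks with planted ground truth. It does not model 3-D
polymer physics, trans contacts beyond a noise floor, replication fork
progression, cohesive (stably bound) cohesin -- the configuration
carries a hook for a static fraction, deliberately unimplemented, since
the reference data cannot distinguish its contact contribution --
nucleosome-scale detail, restriction-fragment structure, or mappability
artefacts. Passing the recovery tests therefore demonstrates that the
analysis stack detects loop-extrusion barriers *when the generative
assumptions hold*, not that those assumptions describe any particular
real library.

Problem sizes used throughout the tests and the acceptance script -- a
40-gene 300-kb chromosome at 2-kb bins, 25-cell populations,
4 x 10^5 read pairs, 3--10 seed replicates -- are the package's chosen
desk-scale study conditions; genome replicates share one annotation
(seed 1), as biological replicates of one strain would.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline("WT_G2M", seed = 1)
res$manifest$n_loops_anchored     # cohesin-anchored loops on one map

ins <- res$insulation
mins <- insulation_minima(ins, deep_quantile = 0.10)
ab <- absolute_barrier_bins(res$barriers)
mean(vapply(ab, function(b) any(abs(mins - b) <= 1), logical(1)))
```

## Known limitations

* The lattice has hard exclusion and two-sided stepping only; one-sided
  or bypassing extruders are extensions, not options.
* The loop caller omits the horizontal/vertical background filters and
  uses a Poisson (not negative-binomial) pixel model; on strongly
  overdispersed real data its FDR would be optimistic.
* The domain corner score is sign-consistency only; nested domains are
  suppressed rather than resolved.
* `.hic`/`.cool` binary formats are not parsed; dense TSV, pairs TSV,
  BED and bedGraph are the interchange formats.
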