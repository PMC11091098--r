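---
title: "Scoring variant abundance and toxicity maps from sorted and time-course sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring variant abundance and toxicity maps from sorted and time-course sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vampseqr)
library(dplyr)
```

## The experiment this package models

VAMP-seq (variant abundance by massively parallel sequencing) measures the
steady-state cellular abundance of thousands of protein variants at once.
A site-saturated library of single amino-acid variants — for a protein of
length $L$, $19L$ substitutions, $L-1$ premature stops and the wild type,
$20L$ variants in all — is expressed as a GFP fusion from a single-copy
genomic landing pad, with mCherry as an internal expression control. Each
plasmid carries an 18-nt random barcode; long-read sequencing of the
barcode–CDS construct ("subassembly") links each barcode to the variant it
encodes, typically ~21 barcodes per variant. Cells are FACS-sorted into four
equal-occupancy bins by their GFP:mCherry ratio and the barcodes in each bin
are sequenced.

A companion screen measures *toxicity*: the same library is grown without
sorting and sampled on days 0, 5, 7 and 9; variants whose continued
expression impairs growth are progressively depleted from the pool.

A third screen maps degrons (degradation signals) with a tiling library:
24-residue peptides stepping by 12 residues, fused to GFP and sorted the same
way.

## Scores

**Abundance.** For variant $i$ with frequency $f_{i,g}$ in bin $g$, the
protein stability index is the frequency-weighted mean bin index,

$$\mathrm{PSI}_i = \frac{\sum_g g\, f_{i,g}}{\sum_g f_{i,g}},$$

computed per replicate for variants with at least 20 reads in that replicate
(no pseudocounts anywhere). The reported abundance score rescales PSI so the
wild-type amino-acid sequence scores 1 and the nonsense anchor scores 0:

$$\text{abundance score}_i =
  \frac{\mathrm{PSI}_i - \mathrm{PSI}_\mathrm{stop}}
       {\mathrm{PSI}_\mathrm{WT} - \mathrm{PSI}_\mathrm{stop}},$$

where $\mathrm{PSI}_\mathrm{stop}$ is the per-replicate median PSI over the
nonsense variants, averaged over replicates, and $\mathrm{PSI}_\mathrm{WT}$
the wild-type PSI averaged over replicates. Scores are deliberately not
clamped — variants more abundant than wild type exceed 1. The phrase "per
amino acid residue, both averaged over all replicates" admits two orders of
operations for the stop anchor; we take the per-replicate median first and
average the medians (`compute_psi_stop(per_replicate = FALSE)` gives the
pooled alternative; on realistic data the two differ negligibly because stop
PSIs are tightly distributed).

**Toxicity.** Variant frequencies $f_{i,t}$ at day $t$ are first normalized
per variant, $f_{i,t} / \sum_t f_{i,t}$, so each variant carries a
distribution over time points; since each sequenced pool derives from the
same number of cells, no further normalization is applied, and non-toxic
variants drift slightly upward as library complexity falls. The depletion
statistic $\alpha_i$ is the *unweighted* OLS slope of this normalized
trajectory against day. Weighted least squares is deliberately avoided: the
Poisson uncertainty of a frequency is correlated with the frequency itself,
so weighting would systematically discount exactly the late, low-frequency
observations that carry the depletion signal. Days with zero observed counts
enter as zeros. The toxicity score anchors each replicate at two variants,

$$\text{toxicity score}_i =
  \frac{\alpha_i - \alpha_\mathrm{WT}}
       {\alpha_\mathrm{anchor} - \alpha_\mathrm{WT}},$$

so wild type scores exactly 0 and the toxic anchor variant (C152W in the
aspartoacylase system this pipeline is modeled on) exactly 1. Anchoring is
per replicate — the anchors' replicate treatment is not pinned down by the
source description, and per-replicate anchoring makes both fixed points
exact in every replicate, which is the stronger and more testable contract.

**Tiles.** The tile stability index (TSI) is the same weighted-mean-bin
statistic applied to tiles. Because the Odds, Evens and C-terminal (CT)
tiles are sorted as three separate pools, three control degron tiles
(suffixes -RLLL, -RAAA, -DAAA; spiked into every pool) put all pools on one
scale: the unique affine map sending the target pool's RLLL and DAAA TSIs
onto the reference (Odds) pool's is fitted per replicate and applied to all
tiles of that pool, then replicates are averaged. RAAA is carried as a
passenger control, not used in the fit. Fitting per replicate (rather than
after averaging) keeps both control fixed points exact in every replicate.

## Subassembly filters

Long reads are reduced to (barcode, CDS) by exact flank matching; reads with
missing or ambiguous flanks, or a barcode that is not exactly 18 nt, are
rejected with a reason code. Variant calling is a global position-wise
comparison to the reference CDS: any length difference is treated as an
indel and rejected (the placement of an indel is irrelevant when all indel
reads are discarded, so no alignment is attempted), reads with ten or more
nucleotide substitutions are rejected, and reads encoding two or more
amino-acid changes are rejected as multi-variant — the library is
site-saturated single-variant by design. The substitution count is per read;
whether the published filter counted per read or per barcode consensus is
not stated, and per read is the stricter reading. Barcodes whose surviving
reads disagree map to the strict-majority variant (dominant fraction > 0.5)
or are dropped on ties. Counting in the screens is exact-match only: a
barcode one nucleotide away from a map key is never rescued.

Nonsense variants are enumerated at positions $1 \dots L-1$ (312 for
$L = 313$), matching the published arithmetic; whether the real library
used positions 1–312 or 2–313 is not resolvable from the text.

## The synthetic-data generator

All tests run against synthetic data with the statistical structure the
analysis assumes; no sequencing downloads are required. The generator is
first-class, tested code, and its defaults are the study conditions: a
313-residue reference (a fixed synthetic sequence with a cysteine at
position 152, so "C152W" exists as the toxic anchor), ~21 barcodes per
variant (drawn as $1 + \mathrm{Poisson}(20)$ so every variant is covered and
the mean is exact), 18-nt barcodes, four bins of 25% occupancy, $10^6$ reads
per bin, 11 abundance replicates, and a 4-replicate time course on days
0/5/7/9 with $10^6$ reads per day.

*Latent abundance* is a two-component mixture on the normalized reporter
scale: the published distribution is bimodal with a wild-type-like mode and
a stop-like mode, but no generative law is reported, so we chose Beta
components (means 0.85 and 0.15, concentration 25, i.e. within-mode SD
≈ 0.07) — smooth, supported on $[0,1]$, and free of the boundary point
masses a clamped Gaussian would create (point masses would make rank-based
recovery checks ill-defined). Stops are forced into the low mode, wild type
and synonymous entries into the high mode. Half the missense variants are
stable; the published map shows most positions sensitive, so this is on the
tolerant side, which only makes the bimodality and recovery checks harder.

*Sorting* draws each cell's fluorescence as latent value + Gaussian noise
(SD 0.1, a realistic cell-to-cell spread for a log-ratio reporter on a unit
scale), cuts the pooled population at its empirical occupancy quantiles, and
sequences each bin with a multinomial of exactly `reads_per_bin` reads — the
simplest model consistent with normalizing counts to frequencies (no PCR
duplicate structure).

*Toxicity* acts multiplicatively on growth rate, not on sorting — the two
screens are separate experiments. Frequencies at day $t$ are proportional to
$w_i e^{-d_i t}$; the shared base growth rate cancels. Deficits are nonzero
only for low-abundance ($< 0.3$) missense variants, 60% of which are toxic
(Bernoulli); nonsense variants make no full-length protein and are never
toxic, matching the observation that most stops are non-toxic despite low
abundance. A lognormal jitter (SD 0.2) on initial representation emulates
the transfection bottleneck; it cancels exactly in the per-variant
trajectory normalization.

*Predictor tracks* (synthetic stability-change and conservation scores) are
generated through a Gaussian copula on the latent-abundance ranks with the
latent correlation $r = 2\sin(\pi\rho_s/6)$ chosen so the realized Spearman
$\rho_s$ matches its target (defaults $-0.47$ for the 0–5 kcal/mol
destabilization track and $+0.45$ for the conservation track, the magnitudes
reported for the real maps) in expectation.

*Seeding*: one master seed drives every sub-generator through a fixed
splitting scheme (stage offset plus replicate index, all derived seeds below
$2^{31}$), so equal configurations give byte-identical outputs end to end.

What the generator does **not** emulate: sequencing error and error-tolerant
barcode collisions (reads are abstracted to barcode observations), PCR
duplicates, FACS instrument noise beyond the Gaussian ratio spread,
within-bin expression structure (not reported for the real instrument and a
simulator choice here), position-dependent structure in the latent effects
(so "variance explained by position" is near zero on synthetic maps by
construction — the pipeline computes it, the generator does not inject it),
and any coupling of toxicity to sorting depth unless `cell_weights` is
supplied explicitly (used in tests to reproduce the reduced replicate
agreement of toxic, low-abundance variants). Passing recovery tests
therefore demonstrates correctness of the estimators under the assumed
sampling model, not performance on real reads.

## Numerical choices and degenerate inputs

- PSI/TSI are undefined (and the variant unscored in that replicate) when
  all bin frequencies are zero; slopes likewise when a variant has zero
  reads at every day.
- Anchor degeneracies ($\mathrm{PSI}_\mathrm{WT} = \mathrm{PSI}_\mathrm{stop}$,
  equal anchor slopes, coincident control TSIs) are hard errors, never
  silently propagated.
- The ≥20-read filter sums counts across bins (or days) within a replicate;
  the source text says only "per replica", and the summed reading is the
  one that treats bins symmetrically.
- Synonymous barcodes merge into the wild-type amino-acid entry by default
  (counts are merged "for amino acid variants"); keeping them separate
  (`collapse_synonymous = FALSE`) reproduces the wild-type mode of the
  score histogram and feeds the wild-type anchor as extra replicates-worth
  of evidence via `compute_psi_wt(include_synonymous = TRUE)`.
- Ties in majority-rule barcode assignment drop the barcode; a 9:1 split
  maps with dominant fraction 0.9.
- The weighted contact number uses the C$_\alpha$ representative, $1/r^2$
  weights and no cutoff — the canonical definition; the source cites a
  reference without restating the formula, so numerical comparisons to the
  published WCN panels should flag this choice. It is computed over all
  chains supplied, so dimer interfaces gain contacts.
- Stability predictions are rescaled by $1/2.9$ (Rosetta energy units to
  ~kcal/mol) and truncated to $[0, 5]$; alignment filtering drops sequences
  with *strictly more than* 50% gaps.
- Bootstrap CIs are percentile CIs with a caller-supplied seed; no
  multiple-testing correction is applied to correlation CIs (none is applied
  in the analyses this mirrors).
- Position-level medians use missense variants only by default: the stop row
  of a variant-effect heat map is an anchor class, not a substitution
  tolerance readout. Both variance-explained estimators ($r^2$ and
  $1-\mathrm{SSE}/\mathrm{SST}$) are reported because the published "55% of
  variance (equivalent to Pearson 0.77)" is internally inconsistent
  ($0.77^2 = 0.59$) and the exact estimator is not stated.

## Problem sizes used in the checks

The acceptance checks run the generator at the full study scale — the
6260-variant universe, ~21 barcodes per variant, $10^6$ reads per bin and
day, 11 and 4 replicates (about 20 s end to end) — and a 500-variant
time-course benchmark with a continuum of deficits for rank-recovery of
toxicity. Rank recovery is measured against a continuous deficit spectrum
because a point mass of zero-deficit variants makes rank agreement reflect
the tie mass rather than estimator fidelity; the tie-heavy default library
is exercised separately (anchor fixed points, neutral-drift positivity).
Unit tests use 10–96-residue proteins and correspondingly smaller depths.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
lib <- simulate_library(cfg)
facs <- simulate_facs_counts(lib$truth, lib$map, cfg)
ab <- abundance_scores(facs, min_reads = 20)
head(ab$scores)
replicate_stats(ab$replicate_scores)

tc <- simulate_timecourse(lib$truth, lib$map, cfg)
tox <- toxicity_scores(tc, min_reads = 20, toxic_anchor = "C152W")
tox$scores |> filter(variant %in% c("WT", "C152W"))
```

Or run everything at once and inspect the written artifacts:

```{r pipeline, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), "out/")
res$summary
```

## Known limitations

The simulator's read model is barcode-level; it cannot exercise the
flank-extraction and substitution filters with realistic long-read error
profiles (those are tested with constructed reads instead). The tile
simulator ties latent tile stability to mean hydrophobicity — a caricature
of degron biochemistry sufficient to test scoring and renormalization, not a
degron predictor. The control-tile peptide core is a synthetic stand-in
(only the -RLLL/-RAAA/-DAAA suffixes matter to the logic), and the 30-nt
cloning adapters are configurable placeholders, as the real vendor sequences
are not published. Replicate agreement on synthetic data (Pearson ≈ 0.99)
reflects the assumed noise model and should not be read as a claim about any
particular real dataset.
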