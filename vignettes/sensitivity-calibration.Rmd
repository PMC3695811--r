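---
title: "Calibrating SNV detection sensitivity from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating SNV detection sensitivity from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senscall)
library(data.table)
```

## The problem

Targeted capture sequencing (exome-seq and its relatives) covers its target
very unevenly: capture efficiency varies from probe to probe, is linked to
G+C content, and fragments carrying non-reference alleles can be captured or
mapped less efficiently than reference fragments. The consequence is that the
probability of detecting a genuine single-nucleotide variant (SNV) — and of
assigning it the right genotype — varies strongly from base to base. A study
that reports only the variants it found, without quantifying where real
variants were likely *missed*, is easy to over-interpret.

senscall implements an empirical calibration of that missingness. The idea:

1. Start from a deeply sequenced alignment and a panel of known polymorphic
   sites. Calls made on the full alignment that match a panel site in
   position *and* alleles, inside the target regions, form a gold-standard
   **truth set** — accurate without any quality filtering, because the
   cross-reference to known polymorphisms already controls false calls.
2. Randomly remove read pairs with inclusion probabilities 0.1–0.9 to
   emulate shallower sequencing of the same library.
3. Call genotypes on each down-sampled alignment and classify every truth
   record as **TP** (same position, alleles and genotype), **PTP** (partial
   true positive: right position and alleles, wrong genotype) or **FN**
   (no matching call), attaching the read depth at the site in the
   down-sampled alignment.
4. Pool classifications over all inclusion probabilities and estimate, per
   genotype class g and depth d,
   `sensitivity(g, d) = TP / (TP + PTP + FN)`.

The resulting calibration table converts any depth profile into per-base
detection probabilities, which aggregate exactly (they are means over
positions) to exons, genes, pathways or whole exomes, and support questions
such as "what mean on-target depth do I need for 95% total heterozygous
sensitivity?".

## The caller

The original analysis delegated genotype calling to standard tools. senscall
ships its own diploid genotype-likelihood caller so that the whole loop is
self-contained and analytically predictable. For an observation b with
Phred quality q (error probability eps = 10^(-q/10)):

* P(b | hom G) = 1 − eps if b = G, else eps/3,
* P(b | het R/A) = ½ P(b | hom R) + ½ P(b | hom A),

summed in log space over the pileup column (M-covering observations only).
Posteriors combine these with priors (1 − θ_het − θ_hom, θ_het, θ_hom),
defaults θ_het = 1e-3, θ_hom = 5e-4. A variant is emitted when the
Phred-scaled posterior probability that the genotype is not hom-ref reaches
`call_threshold` (default Q30, the conventional 0.1% false-call level), and
the candidate alt allele is the non-reference base with the highest summed
quality — so a site with no alt-bearing read is never emitted. The reported
depth uses the depth-profile definition (M *and* D operations: a read
aligned with a deletion across the position still counts), even though
genotyping uses M-covering bases; this matches how the sensitivity curves
are binned.

## The naive binomial comparison

At a heterozygous site of depth d, the alt-read count under ideal conditions
is k ~ Binomial(d, ½). `binomial_expectation()` pushes every k through the
caller's own decision rule (at a uniform quality, with no sequencing error)
and weights by the binomial mass — the probability that an idealized caller
emits the correct genotype. The empirical curve from an error-free,
unbiased simulation must agree with this enumeration bin by bin; with
reference bias switched on, the empirical heterozygous curve falls below
it — the qualitative headline that motivates empirical calibration in the
first place.

## The synthetic world

No real exomes are redistributable here, so `simulate_*()` generates a
stated world in which every downstream stage is testable:

* **Reference** — one chromosome, G+C drawn per 100-bp window from a
  truncated normal (default mean 0.45, sd 0.1), so G+C-linked bias has
  something to act on.
* **Targets** — `n_targets` intervals (default 50 of 120–400 bp, exon-like),
  separated by gaps of 300–800 bp. The minimum gap is deliberately kept at
  or above the fragment length so that each interval's coverage process is
  independent; closer targets would share fragments and slightly overshoot
  depth.
* **Truth** — each targeted base independently becomes a het SNV
  (rate 1e-3) or hom-alt SNV (rate 1e-3), alt uniform over the three
  non-reference bases. These rates give the ~1 SNV per kb typical of human
  panels; acceptance worlds raise them to 0.01 to reach ~2,000 sites per
  class at desk scale.
* **Reads** — per 100-bp tile, a capture-efficiency multiplier
  e = Lognormal(mean 1, cv = `capture_cv`) × (1 + `gc_bias_slope`·(gc − ½)),
  truncated at 0. Defaults: cv 0.3 (mid-range exome capture uniformity) and
  slope −1 (GC-rich tiles captured worse). Fragment starts form a Poisson
  process whose per-position intensity is chosen so that **every targeted
  position has expected depth `mean_depth` × (local efficiency)** — start
  windows extend one fragment length to the left of each interval, so there
  is no edge falloff in expectation. Reads are 76 bp paired (GAII-era
  geometry), fragments Normal(250, 25) clamped to at least two read lengths
  so mates never overlap the same base — which keeps per-site observations
  independent, an assumption the binomial oracle relies on. Reads are
  emitted pre-aligned at their true coordinates: mapping loss is folded into
  capture efficiency rather than modeled separately, which keeps the
  calibration loop desk-scale (the empirical curve absorbs mapping effects
  on real data anyway).
* **Reference bias** — an alt-carrying fragment survives capture with
  probability `ref_bias` per het alt allele it carries; rejected fragments
  are replaced by fresh draws. Collapsed to its renormalized form, the
  accepted haplotype has odds alt:ref of `ref_bias^m : 1` for a fragment
  covering m het sites, so depth is unchanged and the expected alt fraction
  at an isolated het site is `ref_bias / (1 + ref_bias)` (1/3 at 0.5).
  The default is 1 (unbiased); bias is an opt-in treatment because the
  calibration's job is to *measure* its consequences.
* **Errors and qualities** — substitution errors are uniform at
  `error_rate` (default 1e-3) and base qualities are uniform at the matching
  Phred value, which makes the caller's behavior closed-form testable.
  Error-free reads claim Q40, the usual Illumina quality cap; the binomial
  oracle must be evaluated at the same quality.

What a green test on this world establishes: the estimator, classifier,
down-sampler and scorer are correct relative to their oracles. What it does
not establish: real-data effects the generator omits — alignment artifacts,
indel interference, base-quality miscalibration, duplicate reads (assumed
removed upstream), and capture chemistry differences between platforms.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; conversion
  happens only in the VCF (1-based) reader/writer.
* **Tiling** places remainder tiles at the right edge of each interval:
  deterministic, and consistent with left-anchored tiling.
* **Curve binning** — both estimators are provided. `cumulative_le_d` pools
  all observations with depth ≤ d (the literal estimator definition);
  `exact_d` bins at exactly d and is the default, because per-depth values
  are what the binomial comparison and per-base scoring require. Empty bins
  are `NA` (undefined), never 0; depths above `max_depth` (default 100) are
  clamped into the top row.
* **Down-sampling** draws one uniform per read *name* by hashing
  (seed, name) with an avalanche finalizer, comparing against p. This
  guarantees mates share their fate, determinism under read reordering, and
  nesting of kept-sets across p — so sensitivity is monotone in p on a
  fixed sample.
* **Truth-set genotypes** come from the full-alignment call (the panel may
  or may not carry per-sample genotypes); FN depth is read from the
  down-sampled depth profile at the site.
* **Total sensitivity** is implemented as the depth-histogram-weighted mean
  of the calibrated sensitivity — the mean over targeted positions of
  `table[depth(p)]`. A literal sum of depth × sensitivity over positions is
  unbounded and cannot be a percentage; the histogram-weighted mean is the
  only reading that makes "total detection sensitivity" a [0, 1] quantity.
* **Required depth** fits an isotonic regression to the (mean depth, total
  sensitivity) down-sampling series before interpolating level crossings:
  the series is theoretically monotone but noisy at desk scale.
* **Depth 0 maps to sensitivity 0** regardless of the table: no call is
  possible with no reads.
* **Short tiles** follow the same "at least 90% of bases" rule literally,
  so a 5-base tile needs all 5 bases well-covered.
* **Sparse tables** — small experiments leave depth bins with no
  observations. `fill_recall_table()` closes such gaps by linear
  interpolation (leading gaps fall to 0); the scorer itself refuses
  undefined rows unless asked, and the CLI `score` subcommand interpolates
  with a message.
* **Capture-failure flagging** uses median − k·MAD (scaled MAD, k = 3)
  on well-covered tile counts: robust to the very failures it hunts.

## Known limitations

* Biallelic SNVs only; indels and multiallelic genotypes are out of scope.
* The caller is single-sample; no joint calling, VQSR-style filtering or
  base-quality recalibration.
* The simulator's uniform quality string means quality-dependent caller
  pathologies (e.g. miscalibrated tails) are not exercised.
* Figure-style outputs are left to the user; the package emits tables,
  bedGraph tracks and JSON summaries.
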