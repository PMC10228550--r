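---
title: "MRD detection from cfDNA fragmentation profiles: models and methods"
author: "fragMRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRD detection from cfDNA fragmentation profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the signal

After curative resection of non-small cell lung cancer, minimal residual
disease (MRD) is present in the patients who will relapse, but at the early
post-surgical landmark (~7 days) the circulating tumor DNA fraction in
plasma is often below what mutation-based assays can call. Fragmentomics
reads a different channel: cfDNA is released largely as
nucleosome-protected fragments with a dominant mode near 167 bp and a
dinucleosomal echo near twice that, while tumor-derived fragments are
enriched in the 100–150 bp window, with regional variation along the genome
that reflects tumor chromatin. A genome-wide profile of fragment-size
composition therefore carries tumor signal that aggregates over *all*
tumor-derived fragments rather than the few carrying a trackable mutation.

`fragMRD` implements this analysis as five cooperating modules — fragment
ingestion, fragment size ratio (FSR) feature extraction, penalized Cox
modeling with leave-one-out risk scoring, tumor-informed ctDNA tracking,
and evaluation — plus a synthetic cohort generator that makes every stage
testable.

## Fragment model and size classes

A fragment is one sequenced cfDNA molecule, stored 0-based half-open so
that its length equals `end - start`, which for a properly paired read pair
equals the distance between the 5′ ends of the two reads. BAM ingestion
keeps properly paired, primary, non-duplicate records with mapping quality
at least 30 (a conventional threshold; the upstream study removed
duplicates but stated no MAPQ rule, so the default is exposed as a
parameter). Sex chromosomes are excluded throughout; only the 22 autosomes
are analyzed.

The four size classes are inclusive windows around the two nucleosomal
peaks: ShortPeak1 100–150, LongPeak1 151–220, ShortPeak2 221–300, LongPeak2
311–400 bp. The 301–310 bp gap is preserved as printed in the source
scheme: fragments there count toward per-bin totals but belong to no class.
The scheme is a value object (`sizeClassScheme()`), so a gap-free variant
is one constructor call away.

Heterogeneous sequencing depths are unified by binomial thinning: observed
coverage is total fragment bases over the unmasked autosomal genome size,
and when it exceeds the 5× target each fragment is retained independently
with probability `target/observed`. Thinning is seeded, never upsamples,
and preserves the length distribution in expectation.

## FSR features

The genome is tiled into consecutive full-width 5 Mb bins per chromosome
(trailing partial bins dropped). A bin is excluded when repeat-mask overlap
exceeds half its width — a bin-level rule the source analysis left
unstated. On the human autosomes with the study's mask this yields 541
bins; the construction generalizes to any genome and bin size, and the
feature count is always 4 × (unmasked bins).

The published description ("ratios of the short/long fragments of both
peaks" yet four features per bin) underdetermines the feature composition.
The package's choice: the four per-bin features are the four per-class
*spatial profiles* — for class c and bin b, the fraction of the sample's
genome-wide class-c fragments whose leftmost coordinate falls in b. Each
non-empty class sums to 1 across bins, entries are non-negative, and sparse
bins cannot produce unstable ratios. The short/long contrast is retained as
a diagnostic channel, `SP/(LP + 1)` per peak per bin (pseudocount 1 because
bins can have zero long-fragment counts at 5×-equivalent depth). An
alternative 2-features-per-bin ratio composition can be assembled from the
diagnostic channel if desired.

### GC correction

Coverage depends smoothly on GC content, and the per-bin fractions inherit
that bias. Correction is per sample and per class: a smooth trend of
feature value on bin GC is fitted and removed, and the class mean added
back. The smoother is a natural cubic spline regression (default 6 degrees
of freedom, reduced automatically when few distinct GC values exist; below
8 bins the correction degrades to the identity with a warning). A
projection smoother was chosen deliberately over a kernel/LOESS smoother:
orthogonal projection makes the correction *exactly* mean-preserving and
*exactly* idempotent — correcting an already-corrected profile is a no-op
to machine precision — which are the invariants the pipeline relies on; a
non-projection linear smoother satisfies neither exactly. For the smooth,
low-frequency GC trends at 5 Mb resolution the two families fit equally
well (the tests inject an `exp(2(GC - 0.41))` bias and require the residual
correlation with GC to fall below 0.1).

## Penalized Cox model and LOOCV risk scores

With ~2,000 features and fewer than 100 patients, the survival model must
select features and shrink. The model is elastic-net penalized Cox
regression (Breslow tie handling), maximizing

$$\ell(\beta) - \lambda\left(\alpha\|\beta\|_1 +
\tfrac{1-\alpha}{2}\|\beta\|_2^2\right)$$

with mixing `l1Ratio` α = 0.5 by default (the source names the algorithm
but no hyperparameters). Features are z-scored with parameters fitted on
the training samples only; λ is selected along a 100-value path by 5-fold
cross-validated partial-likelihood deviance *within the training set*, with
seeded fold assignment.

Risk scores are leave-one-out cross-validated: sample i is scored by the
linear predictor of a model that never saw sample i's features or outcome,
standardization included — the leakage guard is tested by perturbing a
sample's outcome and asserting its own score is unchanged. A training fold
without events (or one whose inner CV is degenerate, e.g. a lone event)
falls back to the null model, scores 0, and is flagged.

The MRD cutoff follows the published rule — best sensitivity at a minimum
of 90% specificity — implemented as an exhaustive sweep over midpoints
between consecutive distinct scores (plus sentinels), with ties broken by
higher specificity, then higher threshold. Classification is strict
(`score > threshold`), so specificity 1 is always attainable and the
constraint can always be met. Selecting the cutoff on the pooled
cross-validated scores mirrors the source analysis and is mildly optimistic
relative to a fully nested scheme; the achieved operating point is reported
alongside the threshold.

## Tumor-informed ctDNA tracking

Plasma variants are filtered by three independent predicates — kept only if
(i) present in the paired tumor-tissue profile, (ii) absent from the CHIP
blacklist, and (iii) supported by zero reads in the paired leukocyte
control — so the cascade is order-invariant and each removal reason is
tallied. Survivors face a one-sided exact binomial test of alt reads
against the normal-pool background rate (per-site, with a global fallback);
the test form, α = 0.05, and the absence of a multiplicity correction are
package decisions (the tracked set is small and pre-specified; a Bonferroni
option exists), since the source states only that significance against
background noise was assessed. A sample is ctDNA-positive iff at least one
variant survives; no additional read-count or VAF floor is imposed. The max
VAF over survivors summarizes the sample.

## Evaluation

Sensitivity, specificity, PPV and NPV are computed from integer counts with
exact Clopper–Pearson 95% CIs from beta quantiles; values are carried at
full precision and displayed at one decimal on the percent scale. AUC is
the normalized Mann–Whitney statistic with DeLong CIs (fixed direction, so
null data sit at 0.5); hazard ratios come from Cox fits with Breslow ties,
with log-rank p-values for unadjusted group comparisons; undefined metrics
(empty denominators) are reported as `NA`, never fabricated. Combined
calling is the OR of the fragmentomics and ctDNA calls, optionally pooled
across timepoints (high at either timepoint → high overall); by
construction it can only gain sensitivity and lose specificity relative to
either component. Lead time is recurrence day minus call day; negative
leads are flagged and excluded from the median/range summary.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised; its defaults were fixed once, from the shape of the cohort it
emulates, and are not tuned to test outcomes.

- **Lengths**: healthy mixture 167 ± 10 bp (weight 0.85) + 334 ± 20 bp
  (weight 0.15); tumor component 145 ± 15 bp; mixture weight θ (tumor
  fraction); truncation to [50, 500] bp by rejection.
- **Positions**: healthy fragments land in bins with probability
  proportional to `exp(2(GC − 0.41))` — the injected GC coverage bias the
  correction must remove. Tumor fragments are additionally enriched 3-fold
  in a fixed, seeded 20% subset of bins. This regional enrichment is
  essential, not decorative: with the per-class spatial-profile features, a
  spatially uniform tumor signal would cancel out of the normalized
  profiles entirely, whereas real progressing patients show regionally
  distinct short/long profiles. It is what makes end-to-end recovery
  possible, and honest.
- **Outcomes**: recurrence-destined patients (fraction 23/87 by default)
  get θ near 0.05, the rest near 0; event times are exponential with rate
  `5e-5 × exp(100 θ)` per day, censored uniformly over 1,259 days (the
  cohort's maximum follow-up). These constants give ≈ 0.9 event probability
  in the high group and ≈ 0.03 in the low group — about 23 expected events
  in a cohort of 87. Clinical covariates (age, sex, stage, smoking,
  histology, adjuvant therapy) are drawn with cohort-like frequencies.
- **Variant tables**: true tumor variants draw alt reads as
  Binomial(depth, θ/2) (heterozygous, clonal); CHIP rows are blacklisted
  with VAFs of 1–5%; leukocyte-artifact rows carry ≥ 1 leukocyte read.

What the generator does *not* emulate: sequence content (no FASTQ, no error
model), sex chromosomes, subclonal structure, copy-number or end-motif
signal, batch effects, or inter-patient variation in the healthy length
mixture. Passing tests therefore demonstrate that the pipeline recovers the
*modeled* signal — shorter fragments, regionally redistributed, coupled to
hazard — not that it attains any particular performance on real plasma.

## Problem sizes and numerical choices

The test and acceptance experiments use a 4 × 30 Mb toy genome (24 5-Mb
bins, 96 features), cohorts of 87 patients with 2 × 10^5 fragments per
sample, 10 seeds for signal recovery and null calibration batches of 10–20
seeds — sizes chosen so a full run completes comfortably on a laptop while
keeping Monte-Carlo error well inside the asserted margins. Determinism is
enforced throughout: every generator takes a seed, runs in a private RNG
stream, and restores the caller's RNG state; derived seeds stay within
32-bit range. Degenerate inputs are handled explicitly: empty size classes
yield zero features with a warning, event-free training folds score 0 and
are flagged, zero-depth variants are dropped with a warning, and a
zero-background rate is replaced by the smallest positive double so any alt
support is significant.

## Interfaces

The package's functions are its interface, in the usual R idiom:
`runPipeline(runConfig(...))` orchestrates simulate → extract → fit → ctdna
→ evaluate into a self-describing run directory (config snapshot, seed,
per-stage record counts, TSV/JSON artifacts), and each stage is equally
usable on its own — `loadFragments()` on a BAM/BED, `makeBins()` +
`fsrProfile()` for features, `loocvRiskScores()` + `selectCutoff()` for the
model, `callCtdna()` for variant tracking, and the evaluation functions on
any aligned call sets.

## Known limitations

The 541-bin count is reproducible only with the study's exact repeat mask,
which is not distributed; the bin construction is therefore validated on
its arithmetic and on a synthetic 541-bin genome. Cohort-level quantities
that depend on per-patient dates in the controlled-access data (the
published AUCs, hazard ratios, the 293-day median lead time) are not
recomputable and are represented by the published integer counts and by
property-based recovery on synthetic cohorts. The LOOCV-pooled cutoff is
optimistic relative to nested selection, as noted above.
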