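---
title: "Methods: bait-control filtering and quantification for AP-MS screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bait-control filtering and quantification for AP-MS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapms)
```

## Scope and model

`tapms` analyses a two-arm pulldown: a tagged bait purified from tissue
alongside a mock (empty-tag) control, each arm acquired as 2 process
(gel) replicates × 3 technical (injection) replicates and pooled for
counting. The analysis is deterministic thresholding, not probabilistic
interaction scoring: no SAINT/CompPASS-style model is fitted, because the
workflow being implemented is a reproducible rule cascade whose decisions
must be auditable row by row.

The quantities and rules, in order:

**Tryptic digestion.** Trypsin cleaves C-terminal to K and R. By default
no proline exception is applied; the Keil variant (no cleavage before P)
is available as `proline_rule = TRUE`. Peptides with up to 5 missed
cleavages can be enumerated; every peptide carries 1-based inclusive
coordinates in its parent, and at zero missed cleavages the spans
partition the sequence exactly. Theoretical-peptide counting for the
weighted spectral count uses the canonical digest (zero missed
cleavages), while matching of observed peptides elsewhere tolerates
missed cleavages.

**Observable window.** The number of "theoretically observable" tryptic
peptides counts fully tryptic peptides of 7–35 residues. No bounds are
canonical for this normalisation; 7–35 is the typical detectable tryptic
range and is a declared convention of this package, configurable in every
entry point that uses it.

**Spectral counting.** A spectral count is a PSM count, not a
distinct-peptide count — the standard definition. PSMs qualify at
confidence ≥ 99 (on the search engine's 0–100 scale); decoys never
count. Weighted counts divide by the theoretical-peptide number;
proteins whose digest yields no observable peptide are flagged
(`wsc_defined = FALSE`) rather than dropped.

**Enrichment ratio.** Computed on weighted counts by default (a raw-count
mode is provided, since with a shared denominator the two are identical
per protein and differ only if counts are compared across proteins). The
default pseudocount is 0, giving `+Inf` for bait-exclusive proteins:
the enrichment filter only ever examines control-detected proteins, where
the ratio is finite, so infinity semantics are exact rather than
approximated. A positive pseudocount yields finite ratios when a
continuous score is wanted.

**The cascade.** Filter 1 removes control-detected proteins with ratio
strictly below 30 (a ratio of exactly 30 is retained). Filter 2 removes
proteins on the contaminant list or sharing a gene family with a listed
contaminant. Filter 3 removes proteins strictly above 0.01% of total
tissue protein in the reference proteome, plus their family paralogs;
proteins absent from the reference are retained and flagged ("absence of
evidence retains"). Family relatedness is resolved by an explicit
`families.tsv` resource rather than string heuristics: the groupings
encode expert judgment, and a file makes them auditable and swappable.
Unlisted symbols form their own singleton family. Stages apply strictly
in order; a protein removed at one stage is never re-examined, the bait
bypasses everything, and the per-stage tallies are asserted (in code and
in tests) to partition the input. The kinase fraction excludes the bait
from both numerator and denominator.

**MS1 quantification.** XIC peak areas are trapezoidal integrals of the
intensity trace, per isotope channel (M, M+1, M+2), with linear
interpolation at retention-time window edges so areas are additive over
adjacent windows. The default window is the full trace — no peak picking
or retention-time alignment is attempted. When several charge states of
a peptide are present, the most intense precursor (largest total summed
area) is quantified. Fold change is the ratio of arithmetic mean summed
areas; significance is a two-tailed two-sample t-test on log areas,
Welch by default because replicate variances need not be equal
(pooled-variance Student mode is available). Zero-variance degenerate
inputs are defined by the limits: identical arms give t = 0, p = 1;
constant but different arms give p = 0. Non-positive areas are an error
that points to the configurable pseudo-area floor rather than silently
log-transforming zeros.

**Fragment arithmetic.** Constants are monoisotopic and frozen at six
decimals: proton 1.007276, water 18.010565, phospho +79.96633, H3PO4
neutral loss 97.976896, residue masses from the standard table. Only
singly charged b/y series are generated (the evidence this workflow needs
is b/y at 1+; a/c/x/z and higher fragment charges are out of scope).
Internal math never rounds; comparisons with instrument-precision values
round to the printed precision (2 decimals for precursors, 1 for
fragments).

**Phosphosite localisation.** For each candidate S/T/Y site, the ladder
(including −98 partners of phospho-containing fragments) is matched
against the spectrum at 0.05 Th tolerance (configurable), and the score
is the number of matched *site-determining* ions — ions whose m/z (or
existence) differs from at least one other candidate ladder, so matching
them is informative; ions shared by all candidates score nothing. The
best site maximises this count; ties are reported as ambiguous rather
than resolved silently. This is deliberately a counting argument, not an
Ascore-style probability: the underlying evidence standard is the
qualitative presence of neutral-loss ion pairs.

**Single-peptide validation.** The manual-inspection criteria are
operationalised as: (a) noise floor = median intensity of peaks *not*
matched to the theoretical ladder; majority = strictly more than half of
matched ions with S/N > 3; (b) at least 3 consecutive matched indices
within the b or the y series; (c) every y-ion whose N-terminal residue is
proline must reach the median intensity of matched ions — "intense" has
no published number, so the median is the declared convention; the
criterion is reported not-applicable for proline-free peptides.

**Target-decoy FDR.** A simplified stand-in for search-engine FDR
machinery: sort by descending score, FDR = decoys/targets at or above
each threshold (ties share a threshold), q-value = running minimum from
the least confident end. Decoys are pseudo-reversed tryptic sequences
(C-terminal K/R preserved). No local-FDR density estimation and no
rescoring.

**Peptide uniqueness** is exact substring search against the supplied
FASTA database. Peptides are compared literally with no I/L
equivalencing (a documented limitation: isobaric I/L peptides are
treated as distinct).

## The synthetic-data generator

The generator exists so every stage of the pipeline can be tested
end-to-end without instrument data. Its defaults define the study
conditions used by the test suite and were fixed before any test was
written:

* **Proteome**: 200 random sequences of 100–1500 residues with ~11%
  combined K/R so digests are realistic; 1 bait, 20 true interactors, 50
  contaminants, 129 background binders. Thirteen of the interactors are
  labelled kinases. Contaminants split 40/20/30/10% into
  listed-contaminant, contaminant-family, abundant (> 0.01%), and
  abundant-paralog kinds, so each cascade rule has planted targets.
* **Counts**: per (arm × process × technical) cell, protein counts are
  Poisson (negative binomial with dispersion 0.3 optionally, to stress
  the cascade) with per-replicate mean
  `base_rate × (abundance / 1e-4)^0.5`, times `enrichment_fold = 50` in
  the bait arm for bait and true interactors. `base_rate = 3` PSMs per
  technical replicate at the 0.01% abundance scale; interactor
  abundances are log-uniform on [5e-5, 1e-4] (low-abundance preys),
  background on [1e-5, 1e-4], abundant contaminants on [2e-4, 1e-2].
  With six replicate cells per arm this puts control-arm totals for
  interactors around 13–18 counts, large enough that the Poisson noise
  on a 50-fold true enrichment essentially never drops the observed
  ratio below the 30-fold threshold — the planted signal is designed to
  be recoverable, and recovery failures then indicate pipeline defects
  rather than simulation bad luck. Counts are spread over each protein's
  observable peptides by a uniform multinomial draw; 95% of confidences
  fall in [99, 100]; 2% decoy PSMs are appended.
* **XICs**: Gaussian elution peaks (center 30 s, σ 4 s on a 0–60 s grid)
  with isotope weights 1.0 : 0.55 : 0.2 for M : M+1 : M+2 — a fixed
  peptide-scale approximation; no averagine modelling. Replicate noise
  is multiplicative log-normal at the requested cv, applied
  independently per isotope trace, representing extraction and
  integration variability; summing three channels therefore averages
  part of the noise, as integrating three real isotope traces does.
* **MS/MS**: ladder peaks at theoretical m/z with Gaussian jitter
  (σ 0.005 Th against a 0.05 Th matching tolerance), −98 partners for
  phosphopeptides, uniform noise peaks at ~1/snr relative intensity, and
  a two-fold boost of y-ions C-terminal to proline, mirroring the
  proline effect in collision-induced dissociation (without it the
  proline-intensity criterion would fail on realistic random spectra).
* **Determinism**: every generator is a pure function of its
  configuration; the same config reproduces byte-identical files, and
  the seed is recorded in every output header.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chimeric and co-eluting spectra,
retention-time drift between runs, peptide-specific ionisation
efficiency, search-engine score distributions (confidences are
simulated, not computed from spectra), bait-arm-only "sticky"
contaminants, and interactors whose binding is independent of their
tissue abundance. One visible consequence: because the simulated
background binds both arms at identical rates, the enrichment filter
already removes essentially all nonspecific binders in the end-to-end
run, and the contaminant/abundance filters act as guards that are
exercised by dedicated fixtures rather than by the default simulation.

## Fixtures and problem sizes

The test suite builds all fixtures in code. Property suites use 1,000
random peptides for ladder complementarity, 200 random sequences for
digest-count cross-checks against brute-force enumeration, 100 random
instances for the Welch-test and q-value oracles, and 200 replicate sets
for the MS1 fold-change Monte Carlo; the end-to-end test runs the
default 200-protein simulation once. These sizes keep the full suite
under a minute while leaving the statistical checks comfortably away
from their thresholds.

A deliberate stand-in: the full-scale cascade check runs on
`composition_fixture()`, a synthetic table *constructed* to the
published composition of a Gadd45a muscle pulldown (209 bait-sample
proteins; 20 removed for low enrichment; 19 listed plus 17
family-related contaminants; 78 abundant proteins and paralogs; 75
retained, 13 kinases among the 74 non-bait candidates). It validates the
cascade's bookkeeping at that scale and composition; it is not a
transcription of any deposited dataset. Running the cascade on real
deposited tables only requires writing them as the documented
`quant`/resource TSVs.

## Known limitations

* No retention-time alignment, peak picking from profile data, or
  isotope-pattern scoring; XIC quantification assumes extracted traces.
* Fragment generation stops at singly charged b/y ions.
* The FDR stand-in estimates global q-values only.
* Family maps and contaminant lists are user-supplied resources; the
  package ships no curated lists.
* I/L ambiguity is not resolved in peptide uniqueness or matching.
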