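# tapms

Bait–control filtering and quantification for AP-MS pulldown screens.

## The problem

Tandem affinity purification followed by mass spectrometry (TAP/AP-MS)
identifies the proteins that co-purify with a tagged bait — for example a
FLAG/S-tagged Gadd45a expressed in skeletal muscle — but the raw
identification list is dominated by nonspecific binders: proteins that
stick to beads and tags, and highly abundant tissue proteins that carry
over with any pulldown. `tapms` implements the deterministic analysis
workflow that separates candidate interactors from that background, for
two pooled pulldown samples (control vs bait) acquired as 2 process × 3
technical replicates:

1. **Weighted spectral counting.** The spectral count of protein *i* in
   arm *a* is the number of peptide-spectrum matches (PSMs) at confidence
   ≥ 99, summed over replicates: `sc_i,a`. The weighted count divides by
   the number of theoretically observable tryptic peptides
   (fully tryptic, 7–35 residues): `wsc_i,a = sc_i,a / T_i`, which
   corrects for protein size. The enrichment ratio is
   `r_i = wsc_i,bait / wsc_i,control`, with `r_i = +Inf` for
   bait-exclusive proteins.
2. **Three-filter exclusion cascade.**
   Filter 1 removes control-detected proteins with `r_i < 30`;
   filter 2 removes known affinity-purification contaminants and proteins
   in their gene families; filter 3 removes proteins that individually
   exceed 0.01% of total tissue protein in a deep reference proteome, and
   their paralogs. Both thresholds are strict inequalities; the bait
   bypasses all filters. Every protein receives exactly one verdict, and
   the per-stage tallies always partition the input.
3. **Kinase annotation** of the surviving candidates (the bait is
   excluded from numerator and denominator).
4. **MS1 quantification.** Extracted-ion-chromatogram peak areas for the
   M/M+1/M+2 precursor isotopes are integrated trapezoidally per
   technical replicate; the bait/control fold change is the ratio of mean
   summed areas and significance is a two-tailed Welch t-test on log
   areas (p < 0.05), using the most intense precursor when several charge
   states exist.
5. **Fragment-level phosphosite evidence.** Singly charged b/y ladders,
   phospho (+79.96633 Da) arithmetic and H3PO4 neutral-loss (−97.976896
   Da) partner ions localise phosphosites by counting site-determining
   matched ions; ties are reported as ambiguous.
6. **Spectrum QC.** Proteins need ≥ 2 distinct peptides at confidence
   ≥ 99; single-peptide identifications are validated against their
   spectrum (S/N > 3 for the majority of matched fragments, ≥ 3
   consecutive b- or y-ions, intense proline y-ions), and a simplified
   target-decoy procedure assigns q-values.

A synthetic-data module generates complete pulldown experiments (random
proteome, planted true interactors and contaminants, Poisson spectral
counts coupled to reference abundance, Gaussian XICs, noisy b/y spectra)
so that the whole workflow is testable without instrument data.

## Worked example

The analysis is organised as numbered drivers under `analysis/`, run from
the repository root:

```sh
Rscript analysis/01_simulate.R          # synthetic two-arm pulldown
Rscript analysis/02_run_pipeline.R      # inference -> counts -> cascade
Rscript analysis/03_score_recovery.R    # candidates vs ground truth
Rscript analysis/04_ms1_quantification.R
Rscript analysis/05_phosphosite_evidence.R
```

`01` writes a 200-protein experiment (20 planted interactors, 50 planted
contaminants, ~22,500 PSMs) under `results/experiment/`. `02` then
prints:

```
Quantified 200 proteins after inference
Filter cascade removals:
              retained filter1_low_enrichment    filter2_contaminant
                    21                    179                      0
      filter3_abundant
                     0
Candidates: 21 (13 kinases, 65.0% of non-bait candidates)
```

All 179 nonspecific proteins fall at the enrichment filter because the
simulated background binds both arms symmetrically; the contaminant and
abundance filters guard against bait-arm-only contaminants and are
exercised by their own fixtures. `03` confirms perfect separation on
this simulation:

```
True-interactor recovery: 100.0%
Nonspecific retention:    0.00%
```

`04` quantifies a representative peptide (precursor m/z 785.40 at 2+)
carrying a 31-fold enrichment: noiseless recovery is exact, and across
200 noisy replicate sets (cv 0.1) the median recovered fold change is
30.91 with 99.5% of runs within 15% of truth at p < 0.05. `05` localises
a planted phosphosite from its −98 neutral-loss ion pairs
(site-determining matched ions 15/18/3 for candidate sites S3/T4/T9,
best-supported site T4) and passes the single-peptide validation
criteria.

In code, the core steps are plain function calls:

```r
library(tapms)
cfg   <- simulation_config(seed = 1)
paths <- simulate_experiment(cfg, "results/experiment", overwrite = TRUE)
res   <- run_pipeline(run_config(
  fasta = paths[["fasta"]], psms = paths[["psms"]],
  contaminants = paths[["contaminants"]], families = paths[["families"]],
  kinases = paths[["kinases"]], reference = paths[["reference"]],
  output_dir = "results/pipeline", bait_id = cfg$bait_id))
res$tallies
```

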