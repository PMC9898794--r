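---
title: "Differential SEC-MS analysis with secdiff: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential SEC-MS analysis with secdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secdiff)
```

## The problem

Native size-exclusion chromatography coupled to mass spectrometry
(SEC-MS) separates a cell lysate's protein assemblies by hydrodynamic
size into sequential fractions and quantifies every protein in every
fraction by label-free bottom-up proteomics. Each protein thereby gets
an *elution profile*: an intensity trace across fractions whose peaks
correspond to the apparent molecular weights of the populations it
occupies (monomer, stable complex, higher-order assembly). Comparing two
conditions — for example vehicle-treated cells against cells treated
with a chaperone inhibitor — asks two distinct questions:

1. **Abundance**: which proteins change in total amount (summing over
   all fractions)?
2. **Distribution**: which proteins redistribute between assemblies,
   visible as per-fraction changes or as the loss of a coelution feature
   shared with their complex partners, even when total abundance is
   unchanged?

`secdiff` implements a complete, tested pipeline for both questions on a
two-condition, replicated design (defaults: 2 conditions x 4 biological
replicates x 24 fractions), plus a synthetic-data generator so every
stage can be validated against planted ground truth.

## Input filtering and consolidation

The entry point is a MaxQuant-style proteinGroups table with one LFQ
intensity column per (condition, replicate, fraction) cell. A zero LFQ
intensity is treated as *not observed* throughout — the LFQ convention —
so zeros and empty cells are interchangeable.

The quality cascade removes, in a fixed order: potential contaminants,
reverse (decoy database) matches, entries identified only by a modified
site, and entries supported by fewer than 2 peptides. The order matters
only for the bookkeeping: counts are sequential and disjoint, so every
input record lands in exactly one removal bucket or survives.

Records are then *consolidated*: rows whose leading accessions differ
only by an isoform suffix (`P12345-1`, `P12345-2`) or that share a gene
symbol are merged transitively. Intensities are summed within each
design cell — summation conserves total signal and is the common
practice when collapsing isoform-level quantifications — while peptide
counts take the maximum and accession lists the union.

Finally, the replicate-presence filter keeps proteins observed (any
fraction, either condition) in at least 3 of the 4 replicates. Presence
is deliberately condition-agnostic: a protein robustly present only in
the treated condition is biologically interesting, not a quality
failure.

`scale_per_experiment()` rescales each protein's 48 fraction values per
replicate so the joint maximum is 1. This is for visualization only; all
statistics run on unscaled intensities.

## Molecular-weight calibration

Protein standards of known mass define a log-linear map
`log10(MW kDa) = intercept + slope * fraction`, fitted by ordinary least
squares — the standard gel-filtration calibration. The slope is negative
(large assemblies elute first). `assembled_mass_split()` uses the
calibration to partition each sample's total signal at a threshold of
`factor * monomer MW` (default factor 1.2): signal eluting at an
apparent MW more than 1.2x the protein's monomer mass counts as
"assembled". The two percentages partition 100% exactly, and the
assembled share is non-increasing in the factor. The packaged default
standards lie on the synthetic generator's calibration line and are
meant to be replaced by the standards measured on the user's own column.

## Summed differential analysis

For the abundance question the 24 fractions are summed per (condition,
replicate), giving a proteins x 8 matrix. The workflow is:

1. **Normalization** (`log2_normalize`). The default `vsn_glog` mode is
   a variance-stabilizing transform: per-sample scale factors from
   median calibration, then a generalized log
   `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)` whose width `c` defaults
   to the 1st percentile of the scaled observed values (a
   detection-floor proxy), then two rounds of per-sample median
   recentring. For values far above `c` the transform is plain log2 plus
   a constant; near zero it stays finite and compresses noise. A
   `median_log2` mode (log2 + median centering) is available as a
   simpler alternative, and the run summary records which was used.
2. **Left-censored imputation** (`impute_mnar`, summed workflow only).
   Missing values in LFQ data concentrate at low intensities, so they
   are drawn from a Gaussian shifted into the left tail of each sample's
   observed distribution: mean `mu_s - 1.8 * sigma_s`, standard
   deviation `0.3 * sigma_s`. The 1.8/0.3 parameterization is the
   established default for this scheme; `mu_s` and `sigma_s` are
   computed over observed values only. Imputation is the pipeline's only
   stochastic step and is fully reproducible from the seed.
3. **Moderated test** (`moderated_test`). Per protein, a two-sample
   comparison with empirical-Bayes variance moderation: the pooled
   per-protein variance s^2 with df residual degrees of freedom is
   shrunk toward a global prior (d0, s0^2) estimated across proteins by
   moment matching on log s^2 (digamma/trigamma inversion). The
   moderated t uses the posterior variance
   `(d0*s0^2 + df*s^2) / (d0 + df)` and d0 + df degrees of freedom.
   Setting d0 = 0 recovers the classical pooled t-test exactly; when the
   observed log-variance dispersion does not exceed its sampling noise
   the prior df is infinite, the common variance is estimated by the
   pooled mean of s^2, and the reference distribution is normal. The
   implementation is validated to 1e-8 against an independently coded
   brute-force evaluation of these formulas, and cross-checked against
   limma's empirical-Bayes pipeline (limma is never used as the
   implementation).
4. **Multiple testing and calling**. Benjamini-Hochberg adjustment
   (`stats::p.adjust` behind a validated wrapper), then a protein is a
   differential protein (DP) when `adj_p < 0.05` and `|log2FC| > 1`.

## Per-fraction differential analysis

The distribution question treats each fraction as an independent
control-vs-treated comparison: the protein x 8 matrix of one fraction's
intensities is normalized and tested exactly as above, but **without
imputation** — a fraction where a protein lacks 2 observed values per
group simply excludes that protein from that fraction's test, because
missingness at the fraction level usually means the protein does not
elute there, and inventing left-tail values would manufacture
differences. BH adjustment is applied within each fraction; no
cross-fraction correction is added, because the downstream stringency
rule operates on the union. The *stringent* set contains proteins called
differential in 2 or more fractions (direction not required to agree: a
peak shift produces one up and one down fraction). Singleton-fraction
calls are reported but considered susceptible to stochastic
fractionation noise.

## Complex-centric coelution detection

Against a CORUM-style table of complex hypotheses, the pipeline asks
whether each complex's subunits coelute:

- **Traces** (`build_traces`): per-sample log2 profiles are
  cross-normalized (default: cyclic pairwise lowess of M = difference
  against A = average over cells observed in both samples, three
  cycles; per-sample median scaling as the lighter alternative),
  back-transformed and summed over all 8 samples per fraction. Internal
  missing runs of length <= 2 are filled by natural cubic spline over
  the fraction index, clamped at zero so interpolation only adds signal;
  leading and trailing gaps stay at zero. Longer gaps are left alone to
  avoid inventing peaks.
- **Smoothing**: centered moving average, length 5, edge-truncated.
- **Detection** (`detect_candidates`): at each fraction, the mean
  pairwise Pearson correlation of the subunit traces over a centered
  5-fraction window; maximal runs with mean correlation >= 0.9 are
  candidate regions. Within a region the apex must be an *elution peak*
  — a local maximum of the summed subunit signal. This peak requirement
  is essential: unrelated proteins share monotone rising or falling
  flanks (everything late-eluting rises together out of the detection
  floor), and a correlated flank without a peak is not a coelution
  feature. A subunit counts as coeluting when its windowed correlation
  against the mean of the other subunits at the apex reaches the cutoff
  *and* its unsmoothed trace carries signal in at least 2 of the 3
  fractions around the apex — the support rule that suppresses
  detection-floor traces whose isolated observed cells become spuriously
  correlated pyramids after smoothing (the same motivation as the
  consecutive-fraction identification filters common in co-fractionation
  work). Candidates with apexes within 1 fraction sharing a subunit are
  collapsed (wider bounds, union of subunits).
- **MW consistency**: a feature is kept only if its apex maps to an
  apparent MW of at least 1.2x the largest coeluting subunit's monomer
  MW — otherwise it is an apparent monomer peak, not an assembly.
- **Decoy FDR** (`generate_decoys`, `score_and_fdr`): one size-matched
  decoy per hypothesis, members drawn from the detected proteins such
  that no two decoy members co-occur in any reference complex (the
  co-membership reading of a minimum graph distance of 2). Per complex
  only the best feature is kept — most coeluting subunits, ties broken
  by score, mirroring selection by the largest coeluting subunit count.
  The score is completeness (coeluting/annotated) times the mean
  pairwise apex correlation — the simplest monotone combination, since
  no canonical scoring function is fixed for this step. The q-value of
  a score s is `#decoys >= s / max(1, #targets >= s)`, monotonized to be
  non-increasing in s; features with q <= 0.05 are accepted. If the
  decoy queries yield no features at all, every target q is 0 — distinct
  from running no decoy queries, which is an error.
- **Differential complexes**: for each accepted feature, member
  intensities are summed within the feature bounds per condition and the
  treated/control log2 ratio reported, alongside which members are
  stringent fraction-level DPs. A condition with zero within-feature
  signal is floored at |log2 ratio| = 30 and flagged.

## The synthetic generator

`generate_secms()` draws a proteome whose expected intensity in fraction
f is `A_p * sum_k w_k * exp(-(f - mu_k)^2 / (2 * sd_k^2))`:

- Abundances `A_p` are log2-normal (mean 24, sd 1.5), matching the
  dynamic range of LFQ intensities.
- Monomer masses are log-normal with median 60 kDa and log-sd 0.9,
  matching the spread of annotated human protein masses (5th-95th
  percentile roughly 15-250 kDa). Peak centers come from the same
  log-linear calibration the analysis fits; peak width defaults to 1
  fraction, so peaks span a few fractions of a 24-fraction separation.
- 40% of unperturbed proteins carry an assembled component (weight 0.5)
  at 4-12x their monomer mass; planted complexes place a shared
  assembled peak at the summed member mass times a stoichiometry drawn
  from {1, 2, 4, 8} — real assemblies are frequently higher-order
  oligomers (the octameric mitochondrial isocitrate dehydrogenase 3
  complex at roughly 300 kDa being a case in point), and the
  stoichiometry spread places complex peaks across the separation range.
- Replicate noise is multiplicative log-normal with CV 0.2; each cell is
  then independently censored with logistic probability
  `plogis((m - log2 x) / w)` (midpoint m = 17, width w = 1.5), giving
  left-censored missingness acting on the final noisy values. With these
  defaults roughly a quarter of cells are missing and missing cells are
  systematically dimmer than observed ones, which every generated
  dataset asserts.
- Planted effects: induction multiplies all treated fractions by 4,
  depletion (monomer-only proteins) divides by 4 — |log2FC| = 2, chosen
  to sit clearly above the DP threshold of 1; shifts move weight between
  the monomer and assembled components (0.8/0.2 control vs 0.2/0.8
  treated), changing fractions without changing totals; dissociated
  complexes lose their assembled component in the treated condition.

**What the generator does not emulate**: peptide-level sampling,
chromatographic drift between replicates, correlated missingness within
runs, non-Gaussian peak shapes, and shared-peptide quantification
artifacts. Passing the recovery tests therefore demonstrates that the
statistics and detection logic are correct under the stated model, not
that real DDA SEC-MS data will behave this well — on real data
sensitivity is expected to be much lower, as the sparse, stochastic
sampling of DDA thins elution profiles.

## Benchmark scenarios and problem sizes

The test suite validates each property at the smallest size that gives
stable Monte-Carlo estimates: null calibration on 2000-protein datasets
over 20 seeds; abundance-effect recovery on 1000-protein datasets with
100 planted four-fold effects; coelution FDR and sensitivity on
450-protein datasets with 50 planted complexes and 200 random triples
queried as false hypotheses, over 20 seeds; and one full 5000-protein
pipeline run. The coelution benchmark plants complexes with
stoichiometries 4 and 8 (assemblies of roughly 300 kDa to 2.5 MDa): a
24-fraction gradient genuinely cannot resolve a 1:1 trimer of average
subunits from its own monomer range, because the expected peak
separation (about 4 fractions per mass decade) is smaller than the
effective peak width. That resolution limit — not a detector defect — is
why low-stoichiometry complexes in the generator's default mixture go
undetected, and it mirrors the modest complex yields reported for real
24-fraction DDA datasets.

## Numerical choices and degenerate inputs

- Variance prior: trigamma inversion by Newton iteration (60 steps,
  1e-10 relative tolerance); variances are floored at 1e-300 before
  logs; proteins with zero residual df are excluded from prior
  estimation and from testing.
- A protein with identical group means gets t = 0, p = 1 exactly.
- Windows in which any trace is constant contribute correlation 0
  (conservative); correlation matrices with undefined entries are
  zero-filled.
- All-missing profiles stay all-missing through scaling; an all-zero
  dataset passes the cascade and errors only where statistics become
  undefined (a sample with fewer than 2 observed values names itself in
  the error).
- Every stochastic step takes an explicit integer seed; the pipeline
  driver derives per-stage seeds from one root seed, and rerunning with
  the same configuration reproduces byte-identical output tables.

## Known limitations

- The full-study reproduction (`reproduce_study()`) needs the deposited
  proteinGroups table of the original experiment, which is too large to
  ship with the package; the corresponding acceptance test reports a
  clear failure until the file is dropped into `inst/extdata/`.
- The exact published normalizer is not re-implemented; `vsn_glog` is
  this package's own variance-stabilizing transform and summed DP counts
  can shift slightly between normalization modes.
- Stringency counts significant fractions regardless of direction
  agreement, and per-fraction analyses are BH-corrected within, not
  across, fractions — both deliberate, documented choices.
- No paired or multi-factor designs, no peptide-level quantification,
  and no de-novo (hypothesis-free) complex discovery.
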