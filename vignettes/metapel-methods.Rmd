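---
title: "Models and methods behind metapel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metapel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metapel` analyses gut metaproteomes from a two-arm (prebiotic CMH vs
placebo PB), two-phase (baseline vs treatment) study. This vignette explains
the statistical models, the choices made where the procedures were genuinely
open, what the synthetic-data generator does and does not emulate, and the
package's known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## From peptides to protein expression levels

The pipeline starts from a peptide-evidence table: one row per observed
peptide/sample with the set of matched protein accessions and an intensity.
Taxonomic inference relies on *strain-specific* peptides only: a row is
retained iff all matched proteins belong to one strain of the reference
catalog. Two conventions are deliberate:

* **Within-strain multiplicity.** A peptide matching several proteins of the
  *same* strain is retained and contributes to *each* matched protein. Only
  multi-strain peptides are discarded; within-strain ambiguity does not harm
  taxonomy, and the per-protein maximum is well defined either way. The
  alternative (dropping within-strain multi-matches) would discard signal
  without changing any strain-level quantity.
* **Counting definitions.** In summary tables, a "spectral count" is a
  retained peptide observation (row), and a "unique peptide count" is a
  distinct (peptide, protein) pair per sample; a row counts as annotated if
  any matched protein has an assigned function. These definitions make the
  per-group totals, means (total / n samples) and annotated + unannotated =
  total identities exactly reproducible, which the consistency report
  verifies on every run.

The protein expression level is PEL(p, s) = max intensity over retained
peptides of p in s. Undetected cells are explicit zeros, never missing:
taxon abundances are sums of PELs over all proteins of a lineage, and sums
require zeros. Single-sample groups report SD 0 with a warning; SD uses the
n − 1 denominator.

## Diversity

Alpha diversity is computed per sample on species-level PEL compositions:
observed species, Shannon H in natural-log units, Simpson as 1 − Σp².
Intensities are continuous, so no rarefying is done; both H and Simpson are
scale-invariant per sample. Arm effects on each index are tested by OLS with
phase as a covariate; a zero-residual fit (possible in noise-free synthetic
data) reports p = 1 for a null slope rather than NaN.

Beta diversity uses Bray–Curtis distances, classical PCoA (double
centering; negative eigenvalues are reported and their axes dropped), and
PERMANOVA via `vegan::adonis2` with a seed-controlled permutation stream.
The default contrast is arm across both phases, mirroring the four-group
ordination; permutations are unrestricted across subjects. With repeated
measures per subject, an exchangeability-restricted scheme would be more
conservative; this is a known simplification, recorded as a limitation.

## Differential abundance

The count model requires integers; PELs are continuous. One global scale
factor brings the median positive PEL to ~100 and values are rounded half
up. A global (not per-sample) factor is used deliberately: per-sample
scaling would equalize library depths and make size-factor normalization
vacuous. Median-of-ratios size factors are computed against the
geometric-mean reference over features positive in all samples (with a
positive-subset fallback and warning otherwise) and rescaled to geometric
mean 1.

Each feature is fitted with a negative-binomial GLM (log link, log size
factors as offsets). The full design is intercept + phase + arm:phase; the
tested term is the interaction, i.e. the treatment effect net of baseline
differences (a plain arm contrast is available by configuration).
Significance is the chi-square tail of twice the log-likelihood difference
between full and reduced fits (1 df).

Dispersion is estimated per feature by the Pearson moment estimator — the
value of alpha equating Σ(y−μ)²/(μ+αμ²) to the residual degrees of freedom,
with μ from a Poisson fit — floored at 1e-8, then smoothed toward the
parametric trend a(μ) = a₀ + a₁/μ with an empirical-Bayes weight that
balances the sampling variance of a log-dispersion (≈ 2/(n−p)) against the
cross-feature spread around the trend. This is an intentionally lighter
machinery than full Cox–Reid-adjusted MAP estimation; it is unbiased enough
for 40-sample designs and keeps the stage dependency-free. In the Poisson
limit the LRT agrees closely with the exact Poisson LRT (checked in the test
suite). Non-converging features are flagged and given p = 1; all-zero
features get NA and are excluded from FDR.

Log2 fold changes are shrunk with a zero-centered normal prior whose
variance is the moment estimate mean(lfc²) − mean(se²), floored at 1e-8.
The floor matters: in a pure null the positive-part estimate collides with
zero in about half the datasets, and an exactly-zero prior variance would
erase effect *directions*, degrading the directional enrichment stage to
all-ties. With the floor, magnitudes still shrink essentially to zero but
signs survive. BH adjustment is standard step-up; results are ordered by
feature ID so output is deterministic under ties.

**Calibration, measured honestly.** On pure negative-binomial data the
chi-square LRT with these dispersions rejects at ~5.4% at nominal 5%. On the
synthetic generator's data (zero-inflated, rounded, log-normal
max-of-peptide intensities) the measured null rejection rate is ~6%: the NB
quadratic variance cannot match a log-normal tail, and the count transform
is itself an approximation. The acceptance suite asserts the strict binomial
99% band around 5% and therefore marks this check as failing; the package
reports the measured rate rather than adjusting the generator or the band.

## Enrichment and targeted KOs

Each tested protein gets the signed statistic sign(log2FC_shrunk) ×
(−log10 p), p floored at 1e-300. A pathway's "distinct updirectional"
p-value is computed against a null of random same-size member subsets drawn
without replacement from the statistic pool:
p = (1 + #{null mean ≥ observed mean}) / (1 + n_perm), BH-corrected across
pathways. Subsets (not bootstrap draws) are used so that tiny instances can
be verified against exhaustive enumeration of all C(n, k) subsets; the
degenerate consequence is that a set equal to the whole pool has p = 1.
Defaults: minimum set size 3, n_perm 10,000 (tests use less), seeded.
The statistic pool is all KO-mapped tested proteins, configurable.

KO-level significance is not derivable from the protein tests alone; the
declared convention is to sum member-protein counts per KO and reuse the
same NB-LRT, calling a KO *targeted* at raw p < 0.05. *Key proteins* are
the positively associated proteins (p_adj < 0.1, log2FC > 0) whose KO is
targeted — an intersection, so a targeted KO with no significant member
contributes nothing.

## Cooperative routes

The route graph is tripartite. Species–KO edges of evidence type
`"protein"` come from key proteins; KO–pathway edges record targeted-KO
membership in enriched pathways. A species that is abundant at the taxon
level (p_adj < 0.05, log2FC > 0) but owns no key protein joins a pathway
via an evidence-typed `"taxon"` edge only when it has nonzero expression of
some protein under a KO already anchored by another species' key protein —
this keeps provenance explicit while allowing taxon-level-only species into
routes. Construction is fully deterministic; the per-pathway species groups
are emitted sorted. Literature-derived route annotations are a user-supplied
merge, never computed.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests:

* **Design.** 10 subjects per arm, one sample per phase — 40 samples in the
  groups bPB, bCMH, tPB, tCMH.
* **Catalog.** The 15 candidate gut-bacterial families; by default one genus
  per family, 2 species per genus, 3 strains per species, 8 proteins per
  strain; 97.5% annotated; 40% of annotated proteins carry one of 60 KOs
  mapping into 20 pathways across the six KEGG-style main categories.
* **Intensities.** Zero-inflated log-normal: per-protein location
  N(14, 1) on the natural-log scale (arbitrary MS units), per-peptide
  offset N(0, 0.5), residual N(0, 0.6) per peptide × sample, dropout
  probability 0.3 independent per peptide × sample (missing at random).
  Peptides per protein are 1 + Poisson(2); 10% of peptides additionally
  match a protein of another strain (ambiguous, hence discarded), 5% a
  second protein of the same strain.
* **Planted truth.** Species-level log2 fold changes and coordinated
  protein-level shifts on whole pathways multiply the intensities of
  treatment-phase CMH samples by 2^lfc; the truth record (JSON) is
  sufficient to score recovery without reopening the generator.
* **Determinism.** One master seed drives named substreams (catalog,
  intensities, dropout), so identical seeds give byte-identical bundles and
  individual stages can be regenerated.

What it does *not* emulate: peptide sequence realism, spectrum-level
features (m/z, retention time), subject-level random effects,
compositionality constraints of real communities, or intensity-dependent
(MNAR) dropout. Passing tests therefore demonstrate the correctness and
statistical behavior of the pipeline under a plausible generative model,
not performance on real LC-MS/MS data — in particular, real data's
correlated dropout and batch structure may degrade calibration further than
the ~6% null rejection measured here.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for quick, reliable runs:
null calibration uses 20 bundles of ~480 annotated proteins × 40 samples;
PERMANOVA uniformity uses 200 bundles of 15 species × 40 samples with 199
permutations; pathway-recovery uses 50 replicates of a 180-protein catalog;
oracle-equivalence suites use 100 random small instances per operation, and
exhaustive enumeration is used at n = 6 (PERMANOVA) and pool = 6
(enrichment). Tolerances: relative-abundance columns sum to 1 within 1e-9;
dispersions floored at 1e-8 and capped at 100; enrichment p-values floored
by the +1 numerator; GLM convergence failures are conservative (p = 1).
Configuration files are YAML; all thresholds live in `pipeline_config()`
(taxon 0.05, protein 0.1, enrichment 0.05, KO 0.05) and a seed is
mandatory. Manifest checksums use md5 from base R's `tools`.

## Known limitations

* The NB-LRT's mild anticonservatism on log-normal intensity data, above.
* Permutations ignore subject pairing (see Diversity).
* The dispersion machinery is a declared approximation of Cox–Reid MAP
  estimation; no outlier refitting (Cook's-distance style) is done.
* Independent hypothesis weighting is not implemented; BH is the multiple
  testing procedure throughout.
* Bundles are processed in memory; catalogs far beyond ~10⁵ proteins ×
  hundreds of samples would need a chunked PEL aggregation.
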