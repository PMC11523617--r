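---
title: "Methods: pollution gradients, microbial communities and association networks in larval habitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollution gradients, microbial communities and association networks in larval habitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habnet)
```

# The problem

Container-breeding mosquitoes such as *Aedes albopictus* lay eggs in small
artificial water bodies — rainwater collectors, buckets, watering cans — that
accumulate urban pollutants. `habnet` implements the computational chain of a
field survey of such habitats in urban community gardens: it scores each
garden's exposure to atmospheric, agricultural and industrial pollution,
preprocesses amplicon OTU tables of the water's bacterial, fungal and
microeukaryotic communities, summarizes water physicochemistry, filters
untargeted LC–HRMS chemical features, relates community structure to abiotic
gradients by ordination, and finally ties everything together in a mixed-type
association network. Paired samples from each garden contrast
mosquito-colonized (C) with verified noncolonized (NC) containers.

# Pollution gradient scoring

Each garden's exposure is summarized by three proximity-weighted variables:

* atmospheric: `(qNO2 + qPM2.5 + qPM10) / dH`, where the `q` terms are
  quartile scores (1 = lowest-emission quartile of gardens, 4 = highest) and
  `dH` is the distance to the nearest highway in metres;
* agricultural: `surface^2 / dA`, the squared area of the nearest
  agricultural zone over the distance to it;
* industrial: `1 / dI`, the reciprocal distance to the nearest industrial
  area.

Raw variables are then min–max normalized across the garden set. Quartile
scores use average ranks with an inclusive lower bound, so an all-equal input
yields score 1 for every garden (`quartile_scores()`). The bundled
`lyon_gardens.csv` table carries the published characterization of the 23
surveyed gardens; recomputing the industrial variable from the printed
distances reproduces the printed column at 4 decimal places for 22 of the 23
rows (the BIL row is internally inconsistent in the source: 1/1818 rounds to
0.0006, not the printed 0.0004). The printed atmospheric column is
reproducible only for the rows MID, MOU, ALST, TAS, QUA and ESP; for the
others the printed value cannot be derived from the printed score/distance
pair, so the package reports the recomputed value and leaves the discrepancy
documented rather than forced.

# OTU preprocessing and diversity

OTU tables are plain integer matrices (OTUs x samples) with a sample metadata
frame, as in vegan-style workflows.

* **Contaminant filtering** (`filter_contaminants()`): an OTU detected in a
  negative control is removed unless its relative abundance in some study
  sample is at least 10 times its relative abundance in the controls.
  Relative abundance is per sample; the study-side statistic is the maximum
  over study samples — the most permissive reading compatible with the rule,
  so genuine taxa that merely leak into controls survive. The boundary case
  (exactly 10x) is retained.
* **Rare-OTU filtering** (`filter_rare()`): OTUs with total count below
  0.005% of all reads are dropped; the boundary is kept.
* **Rarefaction** (`rarefy()`): single seeded draw without replacement
  (multivariate hypergeometric) to a common depth — 4103, 6567 and 7204 reads
  for the 16S, ITS and 18S markers respectively. Samples shallower than the
  target are dropped with a warning. Repeated-draw averaging is deliberately
  not performed; a single seeded draw is standard practice and keeps counts
  integer.
* **Diversity**: Shannon index in natural log (zero-count OTUs contribute 0)
  and Bray–Curtis dissimilarity, both via vegan.

# Ordination chain

`gradient_analysis()` runs, per marker x colonization-status stratum:

1. PCA of the abiotic table (standardized variables; the decomposition is of
   the correlation matrix). Axis signs are fixed by making the dominant
   loading positive. The survey describes this step as "principal coordinate
   analysis" of variables; on standardized variables PCA and a
   principal-coordinate analysis of Euclidean distances coincide up to axis
   scaling, so plain PCA is implemented.
2. Sequential PERMANOVA of the community Bray–Curtis matrix on PC1 then PC2
   (999 permutations by default, p-values with the +1 correction). PC1 and
   PC2 enter one joint sequential model by default; marginal per-axis models
   can be run by calling `permanova()` per axis. On seven or fewer samples
   `exhaustive = TRUE` enumerates every relabelling, and the test suite
   checks this against an independent brute-force partition of the Gower
   matrix.
3. dbRDA constrained on the same axes. Bray–Curtis dissimilarities are
   square-root transformed before embedding to reduce negative-eigenvalue
   mass; the remaining negative mass is reported and a warning is raised
   above 5%. For identical model and distances the constrained-inertia
   fraction equals the PERMANOVA R2 (checked to 1e-8).
4. A Spearman rank-correlation screen of every OTU against each axis whose
   PERMANOVA term is significant; constant OTU vectors are reported as `NA`.
   Screen tables exist for both axes even when empty.

`procrustes_test()` measures the concordance of two ordinations as the sum of
the singular values of the cross-product of the centered, unit-sum-of-squares
score matrices (1 for a rigid rotation), with significance from row
permutations. The statistic equals the one computed by `vegan::protest()`,
which the tests use as an independent route.

# Water chemistry and the LC–HRMS feature cascade

`water_summary()` reproduces the published per-status mean ± SE summaries
(SE = sd/sqrt(n)); `toc()` is total minus inorganic carbon. The bundled
`lyon_water_samples.csv` carries the printed per-sample physicochemistry of
the 46 water samples, and the tests verify that the recomputed group means
match every printed mean used in the acceptance checks at printed precision.

`filter_cascade()` applies the untargeted feature filters in order:

1. normalization of every intensity to the injection's internal standard
   (spiked diuron-d6); injections without a usable internal standard are
   excluded loudly;
2. removal of features with QC coefficient of variation above 30%
   (sample sd over mean; "over" is exclusive, so CV = 30% survives);
3. imputation of a missing study replicate by the mean of its two siblings,
   else 0; present values are never altered;
4. detection-rate rule: features must be detected (intensity > 0 after
   imputation and replicate averaging) in 100% of the samples of at least
   one garden pollution group. Whether the published rule meant "in one
   group" or "in every group" is ambiguous; "at least one" is the default
   because the published annotations are garden-specific, and
   `detect_rule = "all_groups"` gives the strict reading;
5. blank rule: mean study intensity must exceed 10 times the mean blank
   intensity (a zero blank with signal counts as a pass);
6. status rule: two-sided Welch t-test between NC and C at alpha = 0.05, no
   multiplicity correction (the published screen reports raw p-values).

Every stage only shrinks the retained set, and the audit records the count
surviving each stage. The synthetic feature generator plants "real" features
that pass every stage and artifact classes that each violate exactly one
stage, so the tests can assert stage-exact behavior and exact recovery.

# The association network

The survey's own methodological contribution is a network over variables of
mixed type — OTU abundances, physicochemical fields, pollution variables,
feature intensities, categorical indicators. `habnet` implements it in four
steps:

1. **Robust standardization** (`modified_zscore()`): `z = (x - med(x)) / MAD`
   with `MAD = median(|x - med(x)|)`, exactly as printed — no 0.6745
   consistency constant. Variables with MAD = 0 cannot be binarized and are
   dropped with an audit entry.
2. **Binarization** (`binarize()`): one-sided, flagging exceptionally *high*
   values (`z > threshold`). The threshold the original analysis used is not
   stated. The default here is `3.5 / 0.6745` (about 5.19): the classical
   robust-outlier convention "flag beyond 3.5" is defined on the
   0.6745-scaled modified z-score, and 5.19 unscaled MAD units is that same
   cutoff expressed on the unscaled score (about 3.5 standard deviations for
   Gaussian variation). Using 3.5 directly on the unscaled score would flag
   roughly 1% of ordinary Gaussian observations as exceptional (it sits at
   only about 2.4 Gaussian standard deviations), and the binomial screen
   below then admits single chance co-occurrences of such spikes as edges,
   degrading planted-truth precision. The threshold is fully configurable.
3. **Scoring** (`zhang_score()`): Zhang's association-rule metric
   `(P(AB) − P(A)P(B)) / max{P(AB)(1 − P(A)), P(A)(P(B) − P(AB))}`, in
   [−1, 1], 0 under independence. The directed formula is asymmetric, so the
   score is computed in both rule directions and the maximum retained.
4. **Testing** (`binomial_edge_test()`): one-sided exact binomial tail
   `P[K ≥ k_obs]` for `K ~ Binomial(n, P(A)P(B))` with supports estimated
   from the data; no multiplicity correction. `build_network()` keeps an
   edge when Zhang's score exceeds 0.25 (the only printed edge threshold)
   *and* p < 0.05, on pairwise-complete samples, recording supports, the
   per-edge n, and the Spearman correlation of the indicators for reference.

Two calibration properties of the screen are worth knowing. First, because
the null `P(A)P(B)` is estimated from the same data — co-occurrences inflate
the estimated null — and the exact tail is discrete, the screen is
*conservative*: in the suite's null simulation (independent indicators with
supports 0.3 and 0.4, n = 100, 1000 replicates) it rejects at about 0.005
when the nominal level is 0.05, an order of magnitude below nominal.
False-edge counts therefore stay well under the alpha-level expectation, but
the screen cannot be said to reject "at" the nominal level, and the
corresponding acceptance check is left failing by design rather than widened. Second, at very small sample sizes (the
13-sample colonized-water scale) the discreteness dominates: one extra
flagged sample can move an edge's p-value across 0.05, so recovery there is
majority-grade, not exact.

# Synthetic data: what it emulates and what it does not

All generators are pure functions of their arguments and a seed.

* `simulate_gardens()`: log-uniform distances between 10 m and 10 km,
  lognormal emissions converted to quartile scores — the realistic span of
  urban point-source distances.
* `simulate_chemistry()`: paired NC/C samples, lognormal concentrations
  (positive, right-skewed, as the published per-sample tables are), with the
  NC:C mean ratios for N2O and CH4 planted at 2 and 6 — the reported status
  effect — by shifting the lognormal meanlog by the log ratio.
* `simulate_otu_table()`: Dirichlet-multinomial counts; 30% of OTUs by
  default carry a log-abundance shift proportional to the garden's
  normalized industrial pollution variable; per-sample totals are drawn in
  [1.2, 2] x depth so rarefaction always succeeds; negative controls carry
  planted contaminants that also leak faintly into study samples.
  Under these defaults a planted gradient at n = 40 samples is detected by
  the PERMANOVA chain in >= 90% of simulations, and a zero planted fraction
  rejects at the nominal rate.
* `simulate_features()`: triplicate study injections, pooled QC injections
  with an *exact* sample CV (a fixed zero-mean unit-sd pattern scaled to the
  target CV, so the CV gate is tested at its boundary deterministically),
  blanks, and an internal-standard row that scales whole injections.
* `plant_associations()`: planted pairs receive exceptional values in
  disjoint sample blocks. Disjointness is deliberate: independently drawn
  exceedance sets collide often enough at n = 100 that the realized data
  contain genuine cross-pair associations, which a recovery score keyed to
  the nominal truth list would miscount as false positives.

What the generators do *not* emulate: taxonomic structure (no phylogeny, no
lineage strings), compositional spike-ins, chromatographic drift within a
batch, correlated physicochemistry (fields are independent given status),
or garden-level random effects beyond the pollution axis. Passing tests
therefore demonstrate that the algorithms implement their definitions and
recover planted structure under controlled conditions — not that the field
study's specific biological findings would replicate.

# Numerical and design choices

* Printed-value comparisons round half-to-even at the printed precision.
* QC CV uses the n−1 sample standard deviation (the convention is not stated
  in the source).
* Detection means intensity > 0 after imputation.
* The blank rule treats a zero blank mean with positive study signal as a
  pass.
* Permutation p-values always use the (1 + hits)/(1 + n_perm) correction;
  all permutation procedures are reproducible given (seed, n_perm).
* Problem sizes in the test-suite simulations (garden counts 6–23, depths
  200–4103, richness 40–300, 100–1000 replicates) were chosen to exercise
  realistic shapes — including the study's own 23-garden, 46-sample scale
  for the chemistry and cascade checks — while keeping each property test
  focused.

# Known limitations

* The agricultural variable's surface unit is not recoverable from the
  published table (the printed magnitudes are inconsistent with any single
  unit choice), so the bundled table carries the printed variable but the
  pipeline recomputes it only when a surface column is supplied.
* The binomial edge screen is conservative (see above); interpreting its
  p-values as exact sizes would be wrong, and no multiplicity correction is
  applied, matching the source analysis.
* `dbrda()` reports and warns about negative-eigenvalue mass but does not
  apply a Lingoes/Cailliez correction; the square-root transform kept the
  mass at zero in every configuration exercised here.
* GraphML export stringifies attribute types as igraph defines them;
  round-tripping preserves values but not R attribute classes.
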