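---
title: "Spatially and temporally resolved salivary metabolomics with salivaMS"
author: "salivaMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially and temporally resolved salivary metabolomics with salivaMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivaMS)
```

## The problem

Saliva is secreted by different glands at different oral locations, and both
its flow and composition are under circadian control. A semi-targeted
LC-MS/MS study of saliva sampled above the tongue (AT), below the tongue
(BT) and at the cheek (CK), three times a day (morning M, afternoon A,
evening E), therefore has to untangle three intertwined structures: spatial
metabolite profiles, diurnal oscillations, and the interaction of the two —
rhythms visible only at one location. `salivaMS` implements the complete
analysis chain for this design, together with a simulator that generates
cohorts with exactly these structures planted, so that every analytical
claim in this vignette is backed by a test that recovers known truth.

## The data model

A `FeatureTable` extends `SummarizedExperiment`: one `intensities` assay
(features × samples, nonnegative, `NA` = missing), feature metadata
(`feature_id`, `polarity`, `mz` in Da, `rt` in minutes, `adduct`, and after
identification `metabolite`, `id_level`, `id_score`) and sample metadata
(`subject_id`, `location`, `time`, `sample_type` ∈ {study, qc_pool, blank},
`run_order`). Two conventions matter throughout:

* a **zero is a measured intensity**, distinct from a missing cell (empty
  string on disk);
* study samples must carry subject, location and time; blanks and QC pools
  must not. Violations are caught by the class validity method at
  construction, so no downstream stage needs to re-check.

## The simulator and what it emulates

Abundances are log10-normal. For study sample $s$ and metabolite $m$:

$$\log_{10} I_{ms} = \log_{10} b_m + \log_{10} L_m(\mathrm{loc}_s) +
\log_{10} T_m(\mathrm{time}_s) + \log_{10} S_m(\mathrm{sex}_s) +
[\mathrm{loc}_s = \mathrm{BT}]\log_{10} d + u_{m,\mathrm{subj}(s)} +
\varepsilon_{ms}$$

with base level $b_m$, location/time/sex multipliers, a global BT dilution
$d \in (0,1]$ (BT is the most dilute, "wateriest" fluid), a subject random
effect $u \sim N(0, \sigma_u^2)$ and noise
$\varepsilon \sim N(0, \sigma^2)$. Multiplicative log-normal noise is the
standard model for LC-MS intensities; the defaults $\sigma = 0.15$,
$\sigma_u = 0.1$ give raw-scale CVs of roughly 40 % and 25 %, realistic for
saliva. Time multipliers can be confined to a subset of locations
(`diurnalLocations`), which is how BT-only rhythms are planted.

**Correlated pairs.** A pair like cortisol–cortisone is coupled through a
Gaussian copula. The target is a *population Spearman* correlation; for a
bivariate normal, $\rho_S = \frac{6}{\pi}\arcsin(\rho_P/2)$. Because the
planted fixed effects (shared diurnal profiles, the BT dilution) already
induce dependence, the generator first converts the Spearman target to a
total Pearson correlation on the log scale, subtracts the fixed-effect
covariance computed over the actual design, and solves for the residual
correlation of the latent noise (clipped to ±0.999 with a warning if the
target is unreachable). The empirical check in the test suite recovers the
0.94 target within ±0.05 at n = 159.

**Design.** Sexes alternate to balance; ages are $N(31.2, 4.7^2)$ rounded
to years and clipped to the recruitment range 18–45; sleep is
$N(7.5, 0.7^2)$ rounded to quarter hours. The full factorial 20 × 3 × 3
design loses `dropoutCount` samples. Two dropout modes exist: uniform at
random, and a `"replicate-study"` preset that reproduces the surviving
margins of the original cohort (AT 56 / BT 59 / CK 44 and M 51 / A 53 /
E 55 out of 180). Only the margins of that dropout are published; the 3 × 3
cell allocation used here (AT: 2/1/1, BT: 1/0/0, CK: 6/6/4 across M/A/E) is
one consistent choice and is fixed in code. Run order interleaves one
leading QC pool, then one QC pool and one blank after every five study
samples. QC pools are computed as the true per-metabolite mean of the
simulated study samples with multiplicative noise at the configured RSD —
pooling after simulation rather than drawing independently, because that is
what a physical QC pool is.

**Rendering.** Each metabolite's intensity is split across configured
adducts/polarities by fractions summing to one (conservation is tested to
machine precision); m/z values follow from the exact mass and standard
adduct shifts; RT gets a bounded uniform jitter. What the simulator does
*not* emulate: chromatographic peak shapes, raw spectra, ionization
suppression, batch drift, or missingness mechanisms beyond sample dropout —
so passing tests demonstrate correctness of the statistical machinery on
idealized intensities, not robustness to instrument pathology.

**Presets.** `paperScaleConfig()` is the study-scale panel used by the
acceptance checks: 100 metabolites — 10 AT markers and 10 CK markers at
location fold change 4, cortisol and cortisone (declining diurnal profile
M > A > E, fold change 4, coupled at ρ = 0.94), N-acetyl-tryptophan with
the opposite nadir-in-morning profile, two BT-only declining rhythms, and
75 nulls — under BT dilution 0.7. The fold change of 4 and n ≈ 50 per
location group give essentially complete power, which is intentional: the
tests assert *recovery of structure*, and the family-wise error side is
exercised by the 75 nulls and by all-null panels. A quarter of the panel
renders as two positive-mode adducts, a quarter as negative mode only, and
a quarter in both polarities, so adduct summation and mode merging do real
work. `correlationPanelConfig()` isolates the correlation network: three
coupled pairs at ρ = 0.94/0.92/0.88 among nulls, with no location or time
effects, so the ρ > 0.8 edge list should contain exactly three edges.

## Spectral library construction

Standards are measured as 3 replicates × 3 concentrations. The annotation
rule requires the precursor in **all** replicates of the configured
concentration levels (default: all nine injections). RT statistics pool all
nine replicates — the alternative, restricting to fully detected levels, is
available through `minConcLevels`. The consensus spectrum uses only
top-concentration replicates: pooled fragments are sorted by m/z and
grouped where consecutive peaks lie within the tolerance (default 0.025 Da,
the common centroided-MS2 setting); a group survives only if every
replicate contributes, the most intense peak per replicate is taken,
consensus m/z and intensity are means, and the base peak is rescaled to
100 %. This gap-based grouping is equivalent to greedy nearest-m/z matching
for well-separated fragments and is provably independent of replicate
order, which the suite tests; it also makes the consensus anti-monotone
(adding a replicate can only remove fragments).

Distinguishing analyte from system peaks via the concentration series is
implemented as a Spearman trend check of total ion intensity against
concentration: a non-increasing (or perfectly flat) trend flags — but does
not reject — the entry as a "possible system peak". Flagging rather than
rejecting was chosen because a saturated detector also produces flat
responses for genuine analytes.

Libraries are serialized as NIST-style MSP (`Name`, `PRECURSORMZ`,
`PRECURSORTYPE`, `IONMODE`, `RETENTIONTIME`, `Num Peaks`, peak lines), with
`RTDEV`, `EXACTMASS`, `ADDUCTS` and optional `INCHIKEY`/`QCNOTES` carried
in a `Comment` key=value field. Numbers are written with 8 significant
digits; the round-trip is tested to 6. Raw mzML import is deliberately out
of scope — the module consumes peak lists and spectra, which is where
vendor-neutral processing hands over.

## Identification

Candidates must match polarity, adduct-corrected neutral mass within
0.01 Da and RT within 0.3 min (the conventional semi-targeted settings; a
stricter 0.1-min post-identification tolerance can be passed as `rtTol`).
With a query MS/MS spectrum, similarity is a cosine on square-root-scaled
intensities over fragments matched greedily by nearest m/z within 0.05 Da,
scaled to [0, 100]; the square-root weighting is the standard compromise
between base-peak dominance and noise fragments. Score ≥ 70 gives MSI
level 1; otherwise mass + RT give level 3. Among level-1 candidates the
best score wins (ties → smaller |mass error|, then |RT error|); among
level-3 candidates the smallest |mass error| wins — a documented package
decision, since no convention exists for level-3 ties.

## Curation order and edge cases

The chain is blank filter → RSD filter → adduct sum (per polarity) → mode
merge, in that order. Decisions worth stating:

* The blank rule removes a feature when **strictly more than** 66 % of
  *study* samples lie **strictly below** the feature's mean blank signal.
  Blanks and QC pools are excluded from the denominator (they trivially sit
  at blank level); a missing study cell counts as below.
* RSD uses the sample standard deviation (n−1) and removes **strictly
  above** 30 %; a feature whose RSD is undefined (fewer than two QC
  injections, or nonpositive QC mean) is removed conservatively under the
  distinct reason code `rsd_undefined`.
* Adduct summation treats missing as zero when at least one adduct has a
  value and keeps an all-missing cell missing; the representative row is
  the most intense adduct, relabelled `[summed]`.
* Mode merging keeps the polarity with the lower QC RSD, ties keep
  positive mode (recorded in the provenance), and requires identical sample
  sets.
* Unannotated features survive the intermediate stages (for reuse) and are
  dropped at the end unless `keepUnannotated = TRUE`.

Every stage satisfies input = removed + kept, stages chain, and the full
chain is idempotent — all three are tested, as is exact conservation of
per-sample totals under adduct summation.

## Statistics

Preprocessing replaces zeros and missing values by half the per-metabolite
minimum positive value, then log10, then a per-metabolite Z score **within
the analysis subset** (subset first, normalize second — the order used for
all subset analyses). Log base 10 is a presentation choice only: the Z
score removes the base, and rank-based statistics are invariant to the
monotone transform (both facts are tested).

The Wilcoxon rank-sum test is delegated to `stats::wilcox.test`, exact when
both groups have ≤ 8 untied observations and a tie-corrected,
continuity-corrected normal approximation otherwise; an independent
enumeration oracle over all $\binom{n_1+n_2}{n_1}$ assignments pins the
exact branch for all group sizes up to 6. Bonferroni adjustment is
$p_{adj} = \min(1, m \cdot p)$ with $m$ = the number of metabolites in the
tested table — a per-comparison family, matching the convention of
correcting by the panel size. Fold changes come from raw-scale group means
(medians behind `useMedians`); significance requires $p_{adj} < 0.05$ and
$|\log_2 FC| > 1$. The per-factor significant set is the union over that
factor's pairs, and time tests are repeated within each location stratum,
reporting per-stratum sets, their counts, and the metabolites significant
in every stratum.

Spearman edges use signed ρ > 0.8 (negative correlations are not edges, per
the positive cutoff convention for metabolite co-regulation networks);
p values use the t approximation on n − 2 degrees of freedom, adequate for
n ≥ 50 and orders of magnitude below any threshold at the planted effect
sizes. Ward clustering is `hclust(..., "ward.D2")` on Euclidean distances;
PCA is `prcomp` on the already-normalized matrix. The "top discriminatory"
ranking — minimum adjusted p across a factor's pairs, ties by larger
|log2FC|, then alphabetically — is a documented stand-in for a display
selection whose original criterion is unpublished.

## PLS-DA

`fitPlsda` is a NIPALS PLS2 against the one-hot class response, X and Y
column-centered (the processed matrix already has unit variance per
metabolite, so no further scaling). The latent iteration starts from the
highest-variance Y column, making the fit deterministic; the fitted
subspace and VIP are invariant to sample order (tested by shuffling). VIP
follows the standard formula with per-component explained Y sum of squares
as weights; $\sum_j VIP_j^2 = p$ holds to 1e−9 on every fit, and VIP > 1.25
is the conventional selection cutoff. Cross-validation is stratified
7-fold, $Q^2 = 1 - \mathrm{PRESS}/\mathrm{SSY}$; the permutation test
refits under label permutation and reports
$p = (1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(n_{perm}+1)$. Defaults of 7
folds and 100 permutations are package choices (the validation quantities
are standard, their counts were not published); the acceptance checks use
49 permutations, which already resolves p to 0.02. An independent
implementation (mixOmics) serves as a cross-check on scores and VIP in the
test suite, not as the implementation.

On null data, $Q^2$ is negative with high probability only once the
cross-validated prediction is stable; the Monte-Carlo checks use 90
samples × 30 variables, where the null $Q^2 > 0$ rate is below 3 %. With
smaller fixtures (e.g. 30 × 15, 5 folds) the rate rises above 10 % — a
property of cross-validated PLS, not of this implementation, and the reason
the null-behavior tests are sized as they are.

## Pipeline, problem sizes and determinism

`runPipeline()` chains simulate → build-library → identify → curate →
stats → plsda → score from one nested config (YAML via
`readPipelineConfig()`), writes TSV/MSP artifacts and a manifest of md5
checksums, and is bit-reproducible given config + seed. The study-scale run
(159 + 65 QC/blank samples, 100 metabolites, 150 rendered features)
completes in well under a minute; the full test suite simulates dozens of
such cohorts. `scoreRecovery()` scores each planted effect against the
analysis designed to detect it: location markers against the location
factor, systemic rhythms against the unstratified time factor, and
location-confined rhythms against the stratified tests of exactly their
locations.

## Known limitations

* The simulator's idealizations listed above; in particular, missing values
  arise only by design, never from detection limits.
* The MS/MS similarity replaces a proprietary composite identification
  score; cutoffs transfer in spirit, not numerically.
* Batch structure is single-batch: blanks are pooled, and no drift or batch
  correction is provided.
* Mode merging assumes adduct summation has already collapsed each
  metabolite to one row per polarity.
* The Spearman p approximation and the copula calibration both lean on
  large-n normality; below ~20 samples, use exact methods instead.
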