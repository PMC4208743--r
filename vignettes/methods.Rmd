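---
title: "Methods: group ICA, Icasso stability and lagged functional network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group ICA, Icasso stability and lagged functional network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `rsfnc` implements, the
parameters that matter and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the package's test
suite and acceptance script do not themselves compute.

## The generative model behind the pipeline

The pipeline assumes the masked 4D data of subject $s$ follow a noisy linear
mixing model

$$ Y_s(v, t) \;=\; \sum_{k=1}^{K} a_k\, M_{sk}(v)\, c_{sk}(t) \;+\;
   \varepsilon_s(v, t), $$

where $M_{sk}$ are spatially sparse network maps, $c_{sk}$ are band-limited
(0.01–0.1 Hz) time courses, $a_k$ is a signal amplitude, and $\varepsilon$
is unstructured noise. Spatial ICA estimates the maps as maximally
independent spatial sources; sparseness makes the maps super-Gaussian, the
regime in which Infomax with a logistic nonlinearity is consistent.

## Group ICA

**Two-stage reduction.** Each subject's voxel-demeaned data are reduced to
their top $k_1$ temporal principal components (default $k_1 =
\mathrm{round}(1.5\,C)$, the convention of the standard group-ICA toolchain;
nothing in the analysis is sensitive to $k_1$ as long as it exceeds the true
source count). The reduced sets are concatenated along the reduced-time
dimension and reduced again to the model order $C$, with whitening, so the
group data have identity row covariance. A warning is raised when the
retained variance fraction falls below 0.6, a symptom of underfitting the
order.

**Model order.** $C$ is a configuration parameter (default 8 for the
synthetic design: 6 planted sources plus headroom). There is no principled
universal estimator of the number of components; the package deliberately
leaves $C$ to the analyst, and higher orders (e.g. 40 or 75 in whole-brain
analyses) are supported unchanged.

**Infomax.** Natural-gradient ascent on the entropy of
$g(WX)$ with $g(u) = 1/(1+e^{-u})$:
$\Delta W \propto (I + (1-2g(U))U^{\mathsf T})\,W$. Updates are applied on
random voxel blocks of size $\lceil\min(5\ln V,\,0.3V)\rceil$ — many weight
updates per pass, which is what makes the conventional learning-rate scale
$0.015/\ln C$ effective. The learning rate anneals by 0.9 whenever the
epoch-level weight change rises; convergence is declared when the relative
weight change drops below $10^{-6}$ (cap 512 epochs). Divergence triggers a
restart from a fresh random orthogonal $W$ at half the rate. Output sources
are unit-variance with the sign fixed so each map's largest-magnitude voxel
is positive; this makes repeated runs comparable and the pipeline
deterministic given a seed.

**Icasso.** Infomax is repeated `n_runs = 20` times from fresh random
initial conditions. All $20\,C$ estimates are pooled; similarity is the
absolute Pearson correlation between source maps (absolute, because ICA
recovers sources only up to sign). Average-linkage agglomerative clustering
on $1-\sigma$ cuts the pool into $C$ clusters. Cluster quality is

$$ I_q(C_m) \;=\; \frac{1}{|C_m|^2}\sum_{i,j\in C_m}\sigma_{ij}
   \;-\; \frac{1}{|C_m||C_{-m}|}\sum_{i\in C_m, j\notin C_m}\sigma_{ij}, $$

which is 1 exactly when a cluster's members are identical and orthogonal to
everything else, and degrades toward 0 as runs disagree. The cluster
representative is the **centrotype**, the member with maximal summed
intra-cluster similarity. A stable decomposition is one where every retained
cluster has $I_q > 0.8$; the acceptance script recomputes the minimum
matched $I_q$ on a fresh synthetic cohort.

**Back-reconstruction.** Dual (spatial-temporal) regression: regressing each
subject's volumes on the group maps gives subject time courses; regressing
each voxel's series on those time courses gives subject maps, which are then
z-scaled (mean 0, SD 1 over in-mask voxels) so intensities are comparable
across subjects. In the noiseless limit this recovers the generating maps
and time courses exactly, which the tests verify. The z-scaling divides by
the map SD (not a residual-noise SD); this is a declared choice where
toolbox conventions are ambiguous.

## Network identification

Three screens, each an explicit rule (the field's practice of visual
inspection is replaced by thresholds so the pipeline is automatic, with the
scatter data still emitted for plotting):

1. **Tissue overlap** — keep components correlating more with the
   gray-matter map than with white matter and CSF.
2. **Template sorting** — greedy one-to-one assignment of templates to
   components by descending $|r|$; ranking on magnitude makes the assignment
   invariant to the sign ambiguity of ICA maps, and the signed $r$ is
   recorded. An exhaustive-optimal assignment is available by flag; on
   well-separated problems the two agree (tested). A warning fires when an
   assigned correlation falls below 0.2 — template overlaps around 0.3–0.55
   are typical for genuine matches.
3. **Spectral screen** — from a Welch spectrum (Hann window of length
   $\min(T,128)$, 50% overlap, per-segment linear detrend, unit total
   power): the *dynamic range* (peak power minus the minimum power above the
   peak) and the *low/high-frequency power ratio* (power below 0.10 Hz over
   power in 0.15–0.25 Hz). Components with ratio > 2 (default) pass. At
   TR = 2.7 s the Nyquist frequency (0.185 Hz) truncates the upper band; the
   package warns and integrates to Nyquist. Welch parameters are fixed in
   configuration; they are a declared choice, not a published constant.

## Within-network statistics

Per network: voxelwise one-sample t maps per group (two-sided, df $n-1$),
Bonferroni-corrected over in-mask voxels at $\alpha = 0.05$; a conjunction
mask (both groups suprathreshold, intersected with gray matter); then a
two-sample GLM on conjunction voxels with demeaned age, gender (0/1; the
group t is invariant to the coding, tested) and maximum motion as nuisance
covariates. Group significance requires Bonferroni-corrected $p < \alpha$
and additionally $p < \alpha/n_{\text{networks}}$ (0.05/6 = 0.008).
Bonferroni was chosen over random-field-theory FWE deliberately: RFT needs a
smoothness estimate that is not part of the model here, while Bonferroni is
conservative and exactly testable by Monte-Carlo (the suite verifies the
familywise error rate on null maps). With no covariates the GLM t equals the
classic pooled two-sample t to $10^{-10}$ (tested against a hand-coded
oracle).

## Between-network connectivity

Subject time courses of the selected networks are band-pass filtered
(zero-phase order-5 Butterworth, 0.01–0.1 Hz). Zero-phase filtering uses
odd-reflection padding *and* steady-state initial conditions (matched
start-up); without the latter, low cutoff frequencies leave a long trailing
transient. For each of the $C(C-1)/2$ pairs the **maximal lagged
correlation** is computed: candidate lags on a TR/10 grid within ±3 s, the
second series shifted by cubic-spline interpolation (at whole-sample lags
the spline passes through the data, so the scan agrees exactly with a
discrete-lag oracle), Pearson correlation over the overlap, and the signed
$r$ of maximal $|r|$ reported with its lag. Sub-TR interpolation is
necessary because ±3 s spans barely ±1 sample at TR 2.7 s. Ties break
toward the lag nearest zero, then negative. A positive lag means the second
network lags the first.

Correlations are Fisher-z transformed. Within-group: one-sample t per pair,
BH-FDR over pairs within group. Between-group: OLS of z on [intercept,
group, demeaned covariates], t on the group coefficient, BH-FDR over pairs
(q = 0.05); BH rather than BY because the pairs' dependence is mild and BH
is the field's default. Lags are compared between groups with a pooled t.
Note one property of the maximal-lag statistic worth knowing: maximizing
$|r|$ over a lag grid biases each subject's estimate away from zero; the
bias largely cancels in group means because adjacent candidate lags are
strongly correlated for 0.01–0.1 Hz signals, and the parameter-recovery
tests confirm group means land within ±0.05 z of the planted values at the
full design size.

## Clinical-course analyses

The medication-load composite sums per-drug codes: antidepressants and mood
stabilizers contribute 1 (dose levels 1–2) or 2 (levels 3–4); antipsychotics
contribute their chlorpromazine-equivalent code 0–2; no medication
contributes 0. The numeric low→1 / high→2 mapping is an interpretation of
the categorical scheme, declared here and in the documentation. Aberrant
connectivity is correlated (Pearson, uncorrected by design) with the number
of depressive and manic episodes, onset age, years in remission and
medication load within the patient group, and contrasted between patients
with and without a psychotic history (pooled t).

## The synthetic cohort: what it emulates and what it does not

`synthetic_spec()` defaults encode the study design the pipeline targets: 35
controls and 30 patients, 120 volumes at TR 2.7 s with the first 4
discarded, six sparse networks, band 0.01–0.1 Hz, and a planted group
difference of −0.078 (HC) vs +0.122 (BD) on the meso/paralimbic–right-
frontoparietal pair with all other pairs null — a realistic effect size for
the headline contrast. Ages are drawn near N(41, 9); patients receive
illness-course variables and medication records drawn from the drug classes
seen in such cohorts; a configurable number of subjects get a > 3 mm motion
step so the QC stage has true positives.

Design choices worth stating:

- **Exact correlation shaping.** After band-passing, time courses are
  empirically whitened (inverse Cholesky of their sample correlation) and
  colored by the Cholesky factor of the target matrix, so each subject's
  *sample* correlation over the retained volumes equals the planted matrix
  exactly. Shaping targets the post-discard segment, because that is what
  every downstream stage sees. Lags, when planted, are applied afterwards by
  sub-sample spline shifts of designated rows and perturb the correlations
  second-order; exact joint control of a full lag matrix and a correlation
  matrix is overdetermined, so lags take precedence on designated pairs
  only.
- **CNR.** No acquisition-faithful contrast-to-noise value exists for this
  design; the defaults (blob peak amplitude 1, noise SD 0.5) were chosen
  once so that ICA recovery succeeds at the reduced 12-subject test size,
  and are configuration-exposed rather than claimed realistic. At this CNR
  the planted signal holds roughly a tenth of total variance — so
  subject-level PCA "explained variance" is dominated by noise, which is
  expected and harmless: recovery quality is measured on maps and time
  courses, not on variance fractions.
- **Problem sizes.** The validation cohort is 12 subjects on a 20×24×20 grid
  (~4300 in-mask voxels) at model order 8 with 20 Icasso runs; the
  FNC-recovery and error-control simulations use the full 65-subject design
  over 20 and 50 seeds respectively. These sizes were chosen as the smallest
  at which the contracts are sharp (stability > 0.8, recovery within
  ±0.05 z, FDR/FWE at nominal level).
- **Not emulated:** hemodynamic response convolution, physiological noise,
  scanner drift, field distortions, anatomy, and spatial normalization.
  Passing tests therefore demonstrate the *statistical pipeline* is correct
  and stable under its assumed generative model — not that any particular
  acquisition meets those assumptions.

## Numerical and degenerate-input conventions

- Voxel indexing is R-native: 1-based, column-major over (x, y, z); world
  coordinates via the NIfTI affine. All internal numerics are double; NIfTI
  is written float32.
- Motion files use the SPM dialect (rotations in radians on disk, converted
  to degrees exactly once on load). The motion exclusion clauses combine as
  OR: at the stated thresholds the derivative clause would otherwise be
  unreachable without the range clause.
- Zero-variance voxels in t maps get t = 0 with a warning counter;
  zero-variance inputs to correlations raise errors (maps) or NA with a
  warning (clinical variables).
- Collinear designs (GLM condition number > 1e12) raise errors naming the
  condition number rather than producing silent garbage.
- The motion group-test df is pooled ($n_1+n_2-2$); Welch is available by
  flag.
- All randomness flows from explicit seeds; repeated runs are bitwise
  reproducible (tested for the cohort writer, the ICA stage and the
  pipeline's FNC table).

## Known limitations

- Bonferroni FWE is conservative relative to random-field or
  permutation-based voxelwise control; with strong spatial smoothness it
  costs power within networks.
- The maximal-lag search reports a lag even when the correlation is
  negligible; lag estimates are only meaningful for pairs with substantial
  coupling.
- Greedy template assignment can differ from the optimal assignment when
  components mix templates; the optimal matcher exists behind a flag for
  such cases.
- The pipeline assumes one mask shared by all subjects and templates;
  between-subject registration is out of scope.
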