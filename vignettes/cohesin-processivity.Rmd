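---
title: "Distance-biased regulation at clustered loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-biased regulation at clustered loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Clustered protocadherin (cPcdh) genes — three tandem clusters (alpha, beta,
gamma; 58 isoform genes in mouse) spanning about one megabase — are
activated by shared downstream super-enhancers through CTCF/cohesin-mediated
chromatin loops. Cohesin extrudes loops along the chromatin fiber; the mean
linear genomic length it extrudes before release is its *processivity*.
When processivity drops (for example when the CTCF N-terminal YDF motif that
contacts cohesin is mutated, or when the release factor WAPL is abundant),
enhancer contact — and hence expression — of *distal* promoters collapses
first, while proximal promoters are comparatively spared. Because the beta
cluster lies farthest from its enhancers, a processivity defect shows up as
a *genomic-distance-biased* downregulation that hits the beta cluster
hardest.

`cohesinproc` packages this reasoning as a testable pipeline:

1. a synthetic locus generator with a *known* processivity ground truth,
2. per-modality quantification (RNA counts, ChIP peak enrichment, 4C
   contact profiles) with fold changes, t-tests and BH adjustment,
3. a genome-binned Poisson enrichment scan (the "Manhattan" statistic) that
   asks whether downregulated genes pile up in one genomic bin,
4. a distance-trend stage that regresses per-gene log2 fold change on
   promoter-enhancer distance and inverts the slope into a processivity
   estimate, and
5. contact-matrix topology: cis-depth normalization, Knight-Ruiz balancing,
   directionality index, HMM domain calling, differential contact maps.

## The generator model

Enhancer-promoter contact intensity at linear distance $d$ is modelled as

$$ c(d) = A\,e^{-d/\lambda} \;+\; b\,\left(\frac{\max(d, s)}{s}\right)^{-\gamma} $$

with amplitude $A$, processivity $\lambda$ (bp), and a power-law background
(coefficient $b$, exponent $\gamma$, distance floor $s$) standing in for the
generic contact decay of chromatin. The exponential term is the
loop-extrusion component: if extrusion ends after an exponentially
distributed extruded length with mean $\lambda$, the chance that a loop
spans a gap $d$ decays as $e^{-d/\lambda}$. With the background disabled
($b = 0$) the mutant/wild-type contact ratio has the closed form

$$ \frac{c_{\mathrm{mut}}(d)}{c_{\mathrm{wt}}(d)}
   = \exp\!\left[-d\left(\tfrac{1}{\lambda_{\mathrm{mut}}}
   - \tfrac{1}{\lambda_{\mathrm{wt}}}\right)\right], $$

so per-gene $\log_2$ fold change is *linear in distance* with slope
$-\eta\,\Delta(1/\lambda)/\ln 2$, where $\eta$ is the expression-coupling
exponent ($\mu_{\mathrm{mut}} = \mu_{\mathrm{wt}} \cdot
\mathrm{ratio}(d)^\eta$). No quantitative contact-to-expression law is
established for this locus; $\eta$ is a generator convention (default 1),
not an empirical claim, and the recovery stage divides it back out.

Defaults: $\lambda_{\mathrm{wt}} = 400$ kb, $\lambda_{\mathrm{mut}} = 150$
kb, $A = 1$, $b = 0.1$, $\gamma = 1$, $s = 10$ kb, $\eta = 1$. The lambdas
are the planted truth every recovery experiment is judged against.

### Locus geometry

One synthetic 100-Mb chromosome; the locus starts at 60 Mb with 14 alpha,
22 beta and 22 gamma genes at 15-kb spacing (40-kb inter-cluster gaps) and
an enhancer block (HS7, HS5-1, HS7L, HS5-1bL, HS18-20, HS21, HS22)
downstream of all genes. Cluster-to-enhancer assignment is alpha to HS5-1,
beta to HS18-22, gamma to HS5-1bL; with the enhancer block downstream of
everything, every beta gene is farther from its elements than every gamma
gene — the geometric fact behind the beta-versus-gamma contrast. Distances
run from each gene's 5'-UTR anchor to the *midpoint of the spanning
interval* of its assigned element set; the enhancer-side reference point is
not standardized anywhere, so midpoint is this package's documented choice
(a nearest-edge rule is available). Strand is recorded but ignored by
distance computations. All coordinates are 0-based half-open (BED
convention), in bp; kb/Mb appear only in presentation.

Placing the whole enhancer block downstream of the gamma cluster follows
the generator's ordering invariant (anchors increase alpha, beta, gamma,
then enhancers). In the real locus HS5-1 sits between the alpha and beta
clusters; the synthetic alpha cluster is therefore *farther* from its
enhancer than its real counterpart. Only the beta-versus-gamma contrast is
asserted by any test, and it is unaffected.

### What the generator emulates — and what it does not

Emulated: negative-binomial replicate counts (dispersion 0.05, three
replicates per condition, 20 M nominal reads — a typical bulk RNA-seq
design), log-normal background expression with a configurable fraction
(default 10%) of planted background fold changes for the scan null,
Poisson-sampled symmetric contact matrices with power-law decay, planted
domain blocks and extrusion-driven enhancer rows, per-cluster 4C tracks
with viewpoints at the assigned element-set reference points, and ChIP
peaks whose mutant intensity scales with the same contact ratio (elements
without CTCF sites — the HS7/HS7L analogs — stay condition-independent).

Not emulated: read-level artifacts (mappability, GC), batch effects,
isoform structure, stochastic single-cell promoter choice, polymer
dynamics, trans contacts. Passing tests show the *analysis machinery* is
correct and well-calibrated against a known truth; they do not certify
biological fidelity of the synthetic data.

### Depth choices

ChIP peaks default to 2000 expected reads per promoter peak per replicate
(enhancer peaks 3x) and 4C tracks to 5e6 reads, the realistic scale for
strong cohesin peaks and for viewpoint-concentrated 4C libraries. These
scales matter for one subtle reason: the fold-change estimator
$\log_2[(\bar{x}_{\mathrm{mut}}+p)/(\bar{x}_{\mathrm{wt}}+p)]$ has
$O(1/\mu)$ curvature, so at very low mutant counts (distal genes under
strong depletion) the fitted distance slope acquires a small systematic
steepening. At the default depths this bias is negligible relative to
Monte-Carlo error.

Each 4C track carries signal only within a symmetric 1.25-Mb window around
its viewpoint and is normalized (RPM) within that window. A shared
asymmetric window would give each cluster's track a different captured
share of the exponential tail, shifting per-cluster fold changes by
different constants and distorting the pooled distance slope.

## Quantification choices

- FPKM uses the recorded nominal library size as denominator, not the
  realized column sum: the mutant loses a few percent of total locus
  signal, and realized-total normalization would leak that composition
  shift into every gene's fold change (intercept, not slope — but cleaner
  to avoid).
- Pseudo-count 0.01 (FPKM/RPM units) stabilizes log ratios at near-zero
  levels.
- The two-sample t-test defaults to Welch's unequal-variance form; a
  pooled-variance flag (`var_equal = TRUE`) is available. BH adjustment is
  applied within each modality across all features.
- DEG calling uses strict inequalities (|log2FC| > 0.5, adjusted p < 0.05),
  so boundary values are excluded. With only three replicates a per-gene
  t-test has essentially no genome-wide power after BH adjustment — that is
  precisely what shrinkage-based callers (deliberately out of scope here)
  provide. `call_degs(p_column = "p")` is the documented low-replicate
  alternative, and the pipeline's scan stage uses it so the Manhattan
  statistic sees a realistically sized hit set.

## The Poisson enrichment scan

The genome is tiled into non-overlapping 1-Mb bins (a sliding mode with a
`step` below the width exists; the two conventions circulate side by side
and the package surfaces both rather than hiding the difference).
Downregulated-gene anchors are counted per bin; the genome-wide rate is the
maximum-likelihood estimate $\hat\lambda = \sum_i k_i / n_{\mathrm{bins}}$,
and each bin is scored by the upper tail $P(X \ge k)$ of
$\mathrm{Poisson}(\hat\lambda)$, computed in log space so values far below
1e-300 keep a finite $-\log_{10} p$. Fold enrichment is $k/\hat\lambda$.
The per-bin p-values are reported raw (that is how such scans are usually
quoted); a BH column is emitted for convenience but never used for
ranking. The rate denominator defaults to all bins; a
`denominator_bins` argument restricts it (for example to gene-bearing
bins) — with 302 hits a 231-fold top bin corresponds to roughly 2490
effective bins, fewer than a full mammalian assembly tiles, so both
denominators are legitimate and neither is asserted as canonical.

## Distance trend and processivity recovery

`fit_distance_trend()` is ordinary least squares of log2 fold change on
distance (the generator's exponential model is linear on this scale; a
lowess smoother is drawn on plots but excluded from inference). It returns
a classed model object with `print`/`summary`/`coef`/`predict`/`confint`/
`plot` methods. `recover_processivity_delta()` inverts the slope:
$\Delta(1/\lambda) = -\mathrm{slope}\cdot\ln 2/\eta$ and
$\lambda_{\mathrm{mut}} = (1/\lambda_{\mathrm{wt}} +
\Delta(1/\lambda))^{-1}$; a non-positive implied rate is flagged
inconsistent rather than silently returned. The recovery experiments run
with the power-law background disabled — the regime in which the closed
form is exact; with the background enabled the trend flattens at large
distances and the recovered $\lambda_{\mathrm{mut}}$ is biased upward by
design of the model, not by an estimator defect.

## Contact-matrix topology

- **Depth normalization** scales the matrix so the total cis count (each
  unordered pair once) hits the target (default 1e8). Scaling precedes
  balancing; the order only affects the absolute scale, not the balanced
  structure.
- **Knight-Ruiz balancing** finds weights $w$ with
  $w_i M_{ij} w_j$ having unit row sums, via damped Newton iterations on
  $x \circ (Mx) = 1$ (direct solve of the Jacobian system, positivity
  preserved by step halving) with a symmetric Sinkhorn-style fixed-point
  fallback; both reach the same fixed point. Zero rows are masked and
  reported, and non-convergence within the iteration budget is an error
  with the residual, never a silent pass-through.
- **Directionality index**: for each bin, $A$ = upstream and $B$ =
  downstream contact sums within a window (default 2 Mb worth of bins),
  $E = (A+B)/2$, $\mathrm{DI} = \mathrm{sign}(B-A)\,[(A-E)^2/E +
  (B-E)^2/E]$. Edge bins with truncated windows are flagged; zero-coverage
  bins get missing DI (not zero).
- **HMM decoding**: three states (downstream-biased, unbiased,
  upstream-biased) with single-Gaussian emissions, fitted by Baum-Welch
  with scaled forward-backward. Initialization is deterministic
  (quantile-spread means, spread/3 SDs, sticky transitions), and the
  unbiased state's mean is anchored at zero — the defining property of
  "unbiased" — which also prevents two states from splitting a single
  biased mode on degenerate inputs. Missing DI bins are treated as
  unobserved. The cited methodology used Gaussian mixtures per state;
  single components are a documented simplification (`n_states` is
  configurable). MAP ties break toward the unbiased state.
- **Domain calling**: consecutive identical MAP states merge into regions;
  regions under 3 bins or with median state posterior below 0.99 are
  excluded (both thresholds exactly as conventionally quoted, both
  surfaced as arguments); a domain runs from a retained downstream-biased
  region to the end of the next retained upstream-biased region.
- **Differential maps** are elementwise mutant-minus-WT differences of
  identically binned, identically depth-normalized matrices. Note that
  under the exponential model the *absolute* contact difference peaks at
  intermediate distance ($d^* = \ln(\lambda_{\mathrm{wt}}/
  \lambda_{\mathrm{mut}})\,/\,\Delta(1/\lambda)$, about 235 kb at the
  defaults — gamma territory), while the *ratio* keeps falling with
  distance; "beta is hit hardest" is a statement about ratios, and the
  tests phrase it that way.

### Benchmark sizes

The boundary-recovery benchmark uses 500-bin matrices at 40-kb bins (a
20-Mb region, 8 planted boundaries, ~2.2-Mb domains, 2e6 cis contacts,
3-fold within-domain elevation) so the 2-Mb DI window spans 50 bins — the
classic scale at which DI domain calling was established. The locus
close-up matrix uses 10-kb bins. Recovery counts a planted boundary as
found when a called domain edge lies within one bin of it.

## Reproducibility

Every stochastic routine takes a seed and restores the caller's RNG state.
The pipeline spawns per-stage seeds deterministically from one root seed
and logs them; rerunning a config reproduces the run report bit for bit
(the report carries an md5 hash of both config and content). Experiment
sizes throughout (50-seed recovery, 100-seed ordering and planted-bin
rates, 10-matrix boundary benchmark) were chosen as the smallest designs
whose Monte-Carlo error is comfortably below the effects being measured.

## Known limitations

- The t-test stage is honest but underpowered at n = 3; genome-wide DEG
  lists at adjusted significance require a shrinkage-based caller, which
  this package intentionally does not reimplement.
- The processivity inversion assumes the generator's exponential
  contact-ratio law and a known $\eta$; on real data it estimates a
  model-defined surrogate, not a direct biophysical measurement.
- KR balancing uses a dense solve per Newton step — fine into the low
  thousands of bins, not engineered for whole-genome matrices.
- The HMM is fitted per matrix with a single EM run from a deterministic
  start; pathological DI profiles could in principle favor a different
  local optimum.
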