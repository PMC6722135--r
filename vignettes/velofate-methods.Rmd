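---
title: "Methods: steady-state velocity, transition-probability fate calls, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state velocity, transition-probability fate calls, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `velofate`, the parameters that
matter, the design decisions taken where the design was genuinely open, and
what the synthetic cohort does and does not establish about real data. It
states no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## 1. The kinetic model and the steady-state velocity estimator

Each gene follows the two-stage transcription model

$$\frac{du}{dt} = \alpha - \beta u, \qquad \frac{ds}{dt} = \beta u - \gamma s,$$

with unspliced abundance $u$, spliced abundance $s$, transcription rate
$\alpha$ (molecules per unit time), splicing rate $\beta$ and degradation
rate $\gamma$. Time is measured in splicing units ($\beta = 1$), the
standard convention that makes $\gamma$ a degradation-to-splicing ratio. At
equilibrium $u^\ast = \alpha/\beta$ and $s^\ast = \alpha/\gamma$, so
equilibrium cells lie on the phase-plane line $u = \gamma s$ and the
velocity $v = u - \gamma s$ measures kinetic disequilibrium: $v > 0$ during
induction, $v < 0$ during repression. `trajectory_moments()` carries the
analytic transient solution, including the $\beta = \gamma$ limit
$(e^{-\beta t}-e^{-\gamma t})/(\gamma-\beta) \to t\,e^{-\beta t}$, which is
cross-checked against a numerical integrator in the tests.

The estimator (`fit_gamma()`) follows the steady-state recipe exactly as
parameterized in the reference workflow:

* both layers are **size-normalized by the same per-cell factor** (the
  spliced total over its median). Using one factor for both layers is a
  deliberate choice: it removes library-size variation without touching the
  per-cell $u\!:\!s$ ratio that the slope fit estimates. Whether the
  original run normalized before pooling is not stated anywhere; this is the
  package's documented default.
* values are pooled over each cell's 20 nearest neighbors in PC space
  (self included), smoothing count noise before the slope fit;
* per gene, the cells in the bottom and top 2% of pooled $s$ (each tail
  separately, union) anchor a least-squares fit of $u = \gamma s$ through
  the origin, $\hat\gamma = \sum s u / \sum s^2$, floored at $10^{-4}$.
  The extreme tails are used because they are the cells most likely to sit
  at their transcriptional steady state.

**When is this estimator consistent?** The quantile selection is on *pooled,
observed* $s$. If cells within a tail share one true mean, the tail is
selected on count noise and the slope is attenuated (errors-in-variables):
the selected $s$ exceeds its expectation while $u$ does not follow. The fit
is accurate when the tails are anchored by *real* expression differences
that move $u$ and $s$ together along the line — between-population
differences and co-regulated within-population programs that neighboring
cells share. This is exactly the structure real data has, and the synthetic
cohort therefore includes it (section 5); without it, recovery of planted
$\gamma$ degrades by 10–15% in a way no estimator tweak can fix.

## 2. Transition probabilities, arrows, and the kernel noise floor

For cell $i$ and each of its $k = 20$ graph neighbors $j$,
$r_{ij}$ is the Pearson correlation, over velocity genes, between $i$'s
velocity vector ($s'_i - s_i$, the extrapolated minus current state) and the
displacement $s_j - s_i$. Weights $\exp(r_{ij}/\sigma)$ with
$\sigma = 0.05$ (the parameterized method's default; the bandwidth is not
stated in the reference) are row-normalized with self excluded. Degenerate
vectors (zero velocity or zero displacement) give $r = 0$ by convention, and
velocities that are zero up to floating-point residue are treated as exact
zeros so equilibrium data yields uniform rows rather than noise.

Embedding arrows subtract a uniform baseline,
$a_i = \sum_j T_{ij}\hat e_{ij} - \tfrac1k \sum_j \hat e_{ij}$, so an
uninformative row cancels to a near-zero arrow; the per-cell **relative 2D
velocity** is $\lVert a_i \rVert$, the distance from the cell position to
its projected position.

Two numerical properties are worth knowing:

* **Noise floor.** With $n_g$ velocity genes, noise correlations scale like
  $1/\sqrt{n_g} \approx 0.03$ at $n_g = 1000$, and the kernel amplifies
  them by $e^{r/\sigma}$. Per-cell arrow lengths on equilibrium data with
  count noise therefore sit at a substantial fraction of the signal arrow
  length — they are a *relative*, not an absolute, measure. The package's
  null test uses the exact equilibrium cohort (zero-noise diagnostic mode),
  where $v \equiv 0$ and arrows vanish identically; on the noisy
  equilibrium cohort the meaningful null statement, which the tests assert,
  is that every population's fate call is self-dominant.
* **Direction checks belong in a linear embedding.** t-SNE bends
  trajectories, so "the latent-time gradient" is not a single direction in
  a t-SNE layout. The direction-recovery test evaluates arrows in the PCA
  embedding, where the gradient is well-defined.

## 3. The fate statistic TPn

For a starting subset of $j$ cells, the total single-step transition
probability onto target cell $n$ is $\mathrm{TP}n = \sum_{i=1}^j
\mathrm{TP}in / j$. When every subset row is stochastic,
$\sum_n \mathrm{TP}n = 1$ exactly (tested to $10^{-10}$ against brute-force
summation), and TPn of a union of disjoint subsets is the size-weighted
average of the parts. Subset cells can receive mass from mutual neighbors;
the reference does not state whether such self-transitions were included
before plotting, so they are **reported but excluded from the fate call's
ranking** — `fate_call()` returns the top non-self cluster mass. Subsets
are drawn on embeddings with Gaussian confidence ellipses (sample mean and
$n-1$ covariance scaled by $\chi^2_2$ quantiles; 95% in fate maps, 80% in
trajectory views; collinear subsets get a floored minor axis and a warning).

## 4. Clustering, trajectory, and screening choices

* **Community detection** is Louvain on shared-nearest-neighbor Jaccard
  weights with a resolution parameter and a fixed seed; resolutions 0.1–0.3
  for subset-level structure and 2.5 for trajectory sub-clustering, as in
  the reference workflow. kNN is exact Euclidean with ties broken by cell
  index.
* **Marker detection** defaults to the two-component zero-inflated
  ("bimod") likelihood-ratio test (point mass at zero plus a Normal for
  positives, $\chi^2$ with 3 df), with a rank-sum fallback. The adjustment
  method behind "adjusted p" is not stated in the reference; Bonferroni is
  the default (the conservative classic of the toolkit family), BH is
  selectable. Retention uses adjusted $p < 10^{-2}$.
* **"Detectable levels of Csf1r"** has no printed threshold; it is
  implemented as an expressing-cell fraction per cluster with default 0.25,
  configurable.
* **Lineages** are root-to-leaf paths of the Euclidean MST over cluster
  centroids. Full simultaneous principal curves with shrinkage are replaced
  by a **single-lineage iterative principal curve** (projection →
  arc-length ordering → local-linear smoothing at span 0.5, 10 iterations,
  convergence at a relative arc shift of $10^{-3}$): the trajectory of
  interest is a single path (patrolling monocyte → CD64+CD16.2+ →
  CD206− IM), so the multi-lineage machinery would be dead code.
  Pseudotime is the final arc-length position scaled to $[0,1]$; it is
  invariant to rigid rotations of PC space (tested).
* **Temporal genes**: the reference regresses genes on pseudotime with a
  generalized additive model but does not state the basis or flexibility;
  the package uses a natural cubic spline basis with df = 4 and an F-test
  against the intercept-only model, ranking by ascending p-value with ties
  broken by gene identifier. Constant genes get $p = 1$.
* **GSEA** ranks genes by Signal2Noise $(\mu_A-\mu_B)/(\sigma_A+\sigma_B)$
  with each $\sigma$ floored at $\max(0.2\lvert\mu\rvert, 0.2)$ (the
  canonical implementation's floor), uses the weighted running-sum ES
  ($p = 1$), and obtains NES, nominal p and FDR from 100 phenotype-label
  permutations. With fewer distinct permutations than requested a warning
  reports the exact count.
* **GO over-representation** reports reference/expected/specific counts and
  fold enrichment = specific/expected. The reference's table footnote names
  a Mann–Whitney U test, which does not apply to a 2×2 over-representation
  layout; Fisher's exact (one-sided) is the default and the package makes
  no claim to reproduce those printed p-values — only the fold-enrichment
  arithmetic, which it reproduces exactly.
* **Small estimators**: analyte z-scores use the sample (n−1) standard
  deviation (the denominator is unstated in the reference); label-decay
  half-life is log-linear least squares through the origin after
  normalization to the reference timepoint, $t_{1/2} = \ln 2/\lambda$, with
  an explicit $\infty$ for non-decreasing series and a bootstrap CI over
  replicates — the reference never describes its estimation method, so the
  printed month figures are treated as qualitative only.

## 5. What the synthetic cohort emulates

`simulate_cohort()` plants five populations of 200 cells over 1000 genes:
two stable monocyte pools, a CD64+CD16.2+ population in active transit,
and two stable IM pools. Defaults (all configurable in `sim_config()`):

| parameter | default | rationale |
|---|---|---|
| $\gamma$ | lognormal(log 0.7, 0.4), clamped to [0.2, 2.5] | degradation/splicing ratios around the phase-plane slopes typical of velocity analyses |
| base rate | lognormal(log 6, 0.5) | median spliced counts of a well-sequenced 10x cell (~6k–9k UMI over 1000 genes) |
| marker fold | 4 (transit population 4) | strong but not exclusive subset markers |
| trajectory fold | 8, over 100 genes | a differentiation program large enough to dominate the temporal screen |
| transit window | latent times 0.2–0.8 of a 4-splicing-unit transit | mid-induction cells clearly above the $u = \gamma s$ line |
| size factors | mean-one lognormal, sdlog 0.3 | library-size variation |
| per-population modulation | sdlog 0.35 on constitutive genes | cell types express shared programs at different levels |
| cell heterogeneity | sdlog 0.35 per gene and cell (0.15 for trajectory genes) | gene-autonomous rate noise; the planted program drives its genes tightly |
| gene modules | 4 programs, activity sdlog 0.5 | co-regulated programs shared by neighboring cells |
| mito block | 20 genes, 2% of each cell's counts (capped 4%); violators 8–15% | gives the 5% QC filter work to do with exact separability |
| QC violators | 10 low-depth (0.5% depth) + 10 high-mito cells | planted filter targets |

Three structural features are load-bearing, not cosmetic:

1. **The transit population is a bridge, not an island.** Transit cells
   carry the full differentiation program: trajectory genes and the
   terminal population's markers are being induced along their analytic
   transients, the starting population's markers repressed, and
   constitutive levels drift log-linearly between the endpoint populations.
   Without this convergence, kNN neighborhoods never cross population
   boundaries and the TPn statistic degenerates to pure self-mass.
2. **Within-population co-regulation.** The module factors give
   transcriptionally similar cells correlated expression, which survives
   k-NN pooling and anchors the extreme-quantile $\gamma$ fit (section 1).
   I.i.d. per-cell noise alone does not: pooling averages it away and the
   tails select on Poisson noise.
3. **Heterogeneity moves cells along the steady-state line.** All rate
   factors multiply $u$ and $s$ together, so they spread cells along
   $u = \gamma s$ rather than off it — mimicking expression heterogeneity,
   not kinetic disequilibrium.

A `steady_state = TRUE` mode places transit cells at the quasi-static
equilibrium of rates interpolated along the same path — a null cohort with
identical geometry but no disequilibrium. `noise = "none"` returns the
real-valued kinetic means (integrality is deliberately relaxed in this
diagnostic mode).

**What passing tests do and do not show.** On this cohort the pipeline
recovers the planted populations (ARI), degradation rates (90%+ of
well-expressed genes within 10%), the transit population's elevated
relative 2D velocity, its fate (CD206− IM, never the monocyte pools), the
latent-time ordering (Spearman ≥ 0.9), and the planted temporal program in
the top-100 screen — across seeds, as the acceptance script recomputes.
The generator does **not** emulate transcriptional bursting beyond
lognormal rate noise, batch effects, doublets, ambient RNA, multi-branch
differentiation, read-level artifacts, or the unspliced layer's lower
capture efficiency (a `unspliced_capture` knob exists, default 1, because a
global capture factor simply rescales every $\hat\gamma$ by a constant).
Passing here shows the estimators do what they claim under the stated
generative assumptions; it does not certify performance on tissues with
weaker structure than the planted one.

## 6. Problem sizes and degenerate inputs

The default cohort is 5×200 cells × 1000 genes, which keeps a full
pipeline pass at a few seconds and the whole test suite plus the
20-replicate fate study within a few minutes on one CPU; these sizes are
the package's chosen study conditions, and the acceptance script reports
the `n` actually used next to every quantity.

Degenerate inputs are handled explicitly rather than by accident: empty QC
results, all-zero cells (named in the error), all-zero genes (dropped from
the velocity field with a message), constant covariates (plain z-scoring
with a warning), under-filled dispersion bins (merged with a neighbor),
flat screes (configured default with a warning), coincident embedded points
(skipped and renormalized in arrow projection), collinear ellipse inputs
(floored minor axis), isolated cells (zero transition rows, excluded from
$j$ with a warning), non-decreasing decay series (explicit infinite
half-life), and k = 0 pooling (identity with a warning).

## 7. Orchestration

`run_pipeline(default_config(seed), outdir)` executes
simulate/ingest → QC → normalization → PCA/clustering/embedding →
velocity → fate → trajectory with one seed-bearing config (YAML
round-trip), writes per-stage TSVs as each stage completes (partial output
is retained on failure, and the failing stage is named), and a
line-oriented `key: value` manifest with seeds, parameter provenance and
per-stage row counts. The package deliberately ships no shell entry point:
its users drive analyses from R, as with the packages this one sits
alongside.
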