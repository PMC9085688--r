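---
title: "Linking agricultural landscape structure to plant population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking agricultural landscape structure to plant population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrolandgen)
```

## The problem

Forest herbs in agricultural landscapes persist as small populations in
scattered forest fragments. Their gene flow depends on animal vectors —
pollinators, wild boar, deer, birds — that must cross the agricultural
matrix between fragments. The composition (which land uses) and
configuration (how they are arranged, and how linear elements such as
hedgerows and roads are oriented) of that matrix should therefore leave a
signature in the populations' genetic structure: diversity within
populations and differentiation among them.

`agrolandgen` implements the full analysis chain for testing this idea:

1. **Population genetics** from microsatellite genotypes: rarefied allelic
   richness $A_r$, expected and observed heterozygosity $H_e$, $H_o$, the
   inbreeding coefficient $F = 1 - H_o/H_e$, and the pairwise
   differentiation measures $G''_{ST}$ (Hedrick-standardized, suited to
   highly polymorphic markers) and $D_{PS}$ (one minus the proportion of
   shared alleles).
2. **Landscape metrics** in circular buffers around populations
   (node level) and rectangular strips between population pairs
   (link level), including the decomposition of linear elements into
   parallel and orthogonal length components relative to the
   gene-dispersal direction.
3. **Mixed-model inference**: linear mixed models with a landscape-window
   random intercept and, for pairwise responses, a maximum-likelihood
   population-effects (MLPE) correlation; scale selection, significance
   screening, collinearity reduction, all-subsets AICc selection and full
   model averaging with importance values and a landscape $R^2$.
4. **Synthetic data** with known ground truth, so every stage can be
   validated closed-loop.

## Genetic statistics

Allele frequencies are counted in gene copies. Diploid records with both
alleles scored have known dosage. Tetraploid partial heterozygotes (fewer
recorded alleles than the ploidy) have unknown dosage; each distinct
allele then receives an equal share of the ploidy's gene copies. This
equal-weight rule is unbiased under ignorance of the true dosage and keeps
frequencies summing to one.

Allelic richness uses hypergeometric rarefaction,
$A_r = \sum_i [1 - \binom{N-N_i}{g} / \binom{N}{g}]$, to a common gene
count $g$, by default the smallest per-locus gene count across the
populations being compared — a deterministic choice that makes every locus
rarefiable everywhere. $H_e$ uses Nei's $n/(n-1)$ sample-size correction by
default (configurable). Observed heterozygosity counts an individual-locus
record as heterozygous when it carries at least two distinct alleles; this
definition is dosage-free and hence works identically for both ploidies.

For a population pair, $D_{PS}$ is computed on the population allele
frequency vectors (per locus $\sum_a \min(p_A, p_B)$, averaged over loci)
rather than on averaged individual pairs — simpler, and the natural
population-level reading of "proportion of shared alleles".
$G''_{ST} = k(H_T - H_S) / [(kH_T - H_S)(1 - H_S)]$ with $k = 2$; $H_S$ and
$H_T$ are averaged across loci before the formula is applied once, and
negative estimates are reported rather than clamped. Pairs sharing fewer
than three scored loci are flagged missing.

Spatial context enters through edge-to-edge patch distance (minimum
boundary distance, zero for touching patches) and Hanski's
incidence-function connectivity $S_i = \sum_{j \ne i} e^{-\alpha d_{ij}}
A_j^b$ over same-window neighbours, with population size $A_j$ measured in
flowering shoots. The defaults $\alpha = 1/1000\,$m$^{-1}$ and $b = 0.5$
are deliberate placeholders: the parameterization is study-specific and
both are plain configuration values. The modelling layer consumes
$-S_i$ as "isolation" so that larger values mean more isolated.

## Landscape metrics and their geometry

All geometry is planar, in metres; geographic coordinates are not
supported, which is appropriate for windows a few kilometres across.
Buffers (default distances 125, 250, 500, 1000, 2000 m) are discs
approximated by 256-vertex polygons (area error below 0.01%) clipped to the
window; strips (default width-to-length ratios 1:7 to 2:3) are rectangles
whose long axis joins the two population centres, also clipped. All
denominators use the clipped area.

Percent covers are clipped class areas over the zone area. Crop covers
(RAPE, MAIZE, CEREAL) weight each arable parcel's area by the fraction of
recorded years (2008–2017) the parcel grew that crop — a frequency reading
of "crop dominance" that preserves additivity: crop covers can never sum
beyond the ARABLE cover. A winner-take-all assignment would lose that
property.

The orientation decomposition clips each polyline feature to the zone
(each connected clipped piece counts as one feature) and projects each
straight segment of length $\ell$ onto a reference direction:
$\ell\,|\cos\theta|$ parallel, $\ell\,|\sin\theta|$ orthogonal, so per
segment $p^2 + o^2 = \ell^2$. In strips the reference is the strip axis; in
buffers it is the direction from the clipped feature's arc-length midpoint
to the population centre. Clipping before locating the midpoint keeps the
reference local to the part of the element the animal would actually
encounter; features whose midpoint coincides with the centre have no
defined direction and are counted as fully orthogonal and flagged. The
conditioning variable is the orthogonal-to-parallel ratio
$(o + c)/(p + c)$ with a $c = 1$ m stabilizer, which keeps the ratio
finite and order-preserving when a zone holds no element of a class.

Shannon diversity uses natural logs over the eight area-based classes
(crops not split). Edge density counts only shared boundaries between
parcels of *different* class inside the zone; the zone outline and window
border are excluded, so a uniform landscape scores zero at every scale.

Because no vector-GIS stack is among the package's dependencies — and
because the buffer/strip clipping rules are part of the method itself —
the geometry layer (convex clipping, polyline clipping, polygon distance,
Voronoi partition by half-plane intersection) is implemented in the
package and validated against independent oracles: dense boundary
sampling for distances, per-segment projection for orientation, and exact
area conservation for the Voronoi tiling.

## Mixed models

Node-level responses ($A_r$, $H_e$, $H_o$, $F$) are modelled with a random
intercept per landscape window. Link-level responses ($G''_{ST}$,
$D_{PS}$) add the MLPE structure: a random effect per population entering
every pair that contains it, which accounts for the non-independence of
pairwise observations. The marginal covariance is

$$\Sigma = \sigma^2_w Z_w Z_w^\top + \sigma^2_p A A^\top + \sigma^2_e I,$$

with $Z_w$ the window indicator and $A$ the pair-incidence matrix (two
unit entries per row). The implementation profiles out $\beta$ (by GLS)
and $\sigma^2_e$, and maximizes over the log variance ratios
$\log(\sigma^2_w/\sigma^2_e)$, $\log(\sigma^2_p/\sigma^2_e)$ from three
fixed starting points (so fits are deterministic given data), using the
Woodbury identity on the low-rank structure so each evaluation costs
$O(n(q+p)^2)$ rather than $O(n^3)$. Ratios indistinguishable from the
zero boundary collapse to exactly zero. The test suite checks the ML
log-likelihood against a dense multivariate-normal evaluation and against
`lme4` for the window-only case, and REML variance components against
closed-form balanced-ANOVA estimators.

Before modelling, every variable (responses included) is Box-Cox
transformed to symmetrize its distribution and then centred and scaled, so
coefficients are standardized. Non-positive variables are shifted by
$|\min| + 1\%$ of the range first; $\lambda$ maximizes the profile
likelihood over $[-3, 3]$.

Model comparison uses $AIC_c = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$
counting fixed coefficients *plus all variance parameters* (window, MLPE
population, residual) — one consistent convention across node and link
levels, since none is standard for MLPE. Likelihood-ratio tests and all
$AIC_c$ comparisons of different fixed structures use ML; REML is reserved
for final refits. The marginal $R^2$ follows the Nakagawa–Schielzeth
variance decomposition with the MLPE random variance entering as
$2\sigma^2_p$ (each row carries two population effects); again a
documented convention, as no standard exists for MLPE models.

## Three-step selection and averaging

**Step 1 — scale.** For each metric family, single-metric models (basic
determinants + the metric) are fitted at every scale; a quadratic term is
kept when it lowers $AIC_c$, conditioning-variable interactions (O:P for
linear elements, PROPGREEN for settlement) are always included where
defined, and link-level models may add a distance interaction when it
lowers $AIC_c$. The scale with the lowest $AIC_c$ wins; ties break toward
the smaller scale and then the simpler model, making reruns
deterministic. A likelihood-ratio screen at $\alpha = 0.15$ (all
metric-related terms dropped jointly) decides which families continue.

**Step 2 — collinearity.** Pairwise Pearson $|r| \ge 0.7$ is not
tolerated. Clusters of intrinsically related metrics are replaced by the
standardized first principal-component score, sign-oriented to correlate
positively with the cluster's first-named member. What counts as
"intrinsic" is not algorithmically decidable; the `intrinsic` argument
accepts an explicit grouping, and by default all collinear clusters are
composited. For pairs declared non-intrinsic the member with the lower
single-metric $AIC_c$ is kept: choosing by importance in the final model —
the conceptual ideal — is circular to automate, and the single-metric
$AIC_c$ is the closest non-circular proxy.

**Step 3 — averaging.** All term subsets obeying marginality (quadratics
require their linear term, interactions both mains) and the landscape-term
cap (4 node / 9 link) are fitted by ML. When an unusually permissive
screen leaves so many terms that the subset count would exceed the
configured candidate budget (`max_models`, default 10,000), the
weakest-screened families (largest LRT p) are dropped from the global
model until enumeration is feasible — the same sample-size logic that
motivates the term caps in the first place. Models within $\Delta AIC_c < 2$
of the best are refit with REML and fully averaged: Akaike weights from
the ML $AIC_c$, coefficients from the REML refits, absent terms
contributing zeros. A term's importance is the summed weight of component
models containing it; terms with importance $\ge 0.5$ are reported. The
$R^2$ of "the average model" is computed on the single best model
containing all important terms — averaging coefficients across models with
different random-structure estimates has no defined $R^2$, and the best
full model is also the natural one for visualization. The landscape $R^2$
is the difference from the basic model's marginal $R^2$ (population size +
isolation at node level, distance only at link level); negative values are
reported unclamped.

The crop question — do specific crops explain more than arable cover in
general? — is answered by running both variants through all three steps
and reporting the one with the higher final marginal $R^2$; exact ties
favour the crop split as the more informative variant.

Effect shapes are summarized with the field's symbols: `/` and `\` for
monotone effects, `∩`/`∪` for unimodal effects whose vertex lies in the
central half of the predictor range, asymmetric `/∩`, `\∩`, `/∪`, `\∪`
when the vertex sits outside it (the prefix follows the overall trend over
the range), and `X` for effects involving an important interaction. The
central-half vertex rule quantifies what is otherwise a visual judgement.

## The synthetic-data generator

The generator emulates the study conditions rather than any particular
map: square windows (default 5 × 5 km), a Voronoi mosaic of parcels with
classes assigned greedily toward target area fractions (defaults echo an
arable-dominated mosaic: 45% arable, 12% forest, 18% grassland, 7%
settlement, ...), linear elements as random-walk chains whose segment
angles follow a von Mises distribution (concentration `kappa` controls the
orientation bias the O:P metrics should detect), per-year crop rotations
drawn from configurable probabilities, and up to six populations per
window placed in forest parcels with at least 200 m separation and
flowering-shoot counts drawn log-uniformly over 15 to 1.2 × 10⁷.

Genotypes follow a hierarchical Dirichlet divergence model: per locus an
ancestral frequency vector (symmetric Dirichlet), then population vectors
from `Dirichlet(ancestral × (1−θ)/θ)` with
`θ = plogis(theta_a + theta_b × driver)`; `theta_b` links a chosen
node-level landscape metric to genetic divergence, giving the pipeline a
known signal to recover. This is deliberately *not* a coalescent or
spatially explicit gene-flow simulation: it produces the right statistical
shape (exchangeable individuals, landscape-correlated divergence) at a
tiny cost, but it cannot emulate linkage, mutation models, isolation by
distance within windows, or temporal dynamics — so passing recovery tests
says the *inference machinery* works, not that the generator is a
biological model. Responses for the model-recovery studies are drawn
exactly from the mixed-model generative process, with the truth recorded.

Every stage draws from its own named seed substream, so changing one
stage's draws cannot silently shift another's, and all generators are pure
functions of (config, seed).

## Numerical choices and problem sizes

Tolerances: frequency sums to 1 within 1e-12; geometric oracle agreement
to 1e-9; likelihood optimization to ~1e-8 on the log-likelihood (Brent /
Nelder–Mead on profiled ratios); disc discretization error below 0.1%.
Degenerate inputs: constant columns are dropped from modelling with a
record in the result; metrics with undefined values propagate as missing;
monomorphic pairs yield flagged-missing $G''_{ST}$.

The validation studies run at sizes chosen to give stable Monte-Carlo
estimates while keeping the whole suite quick on a single core: 200
replicates for interval calibration (n = 120 pairs, 16 populations per
window, 4 windows), 100 replicates for selection power (n = 100 links, 8
candidate families), 1000 random polylines for the geometry oracle, and a
pinned two-window golden scenario for byte-identical regression of the
full pipeline.

## Limitations

- The collinearity step cannot know which metrics are "ecologically
  related"; the default composites everything collinear, which can merge
  metrics a scientist would keep apart (supply `intrinsic` to control it).
- The marginal-$R^2$ and parameter-counting conventions for MLPE models
  are documented choices, not community standards; comparisons with other
  software should compare likelihoods, not $R^2$.
- GENEPOP import is read-only and diploid.
- Geometry assumes simple polygons in a projected CRS; there is no raster
  support, reprojection, or resistance-surface modelling.
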