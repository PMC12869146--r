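---
title: "Small-area mapping of telehealth use with the BYM Poisson model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area mapping of telehealth use with the BYM Poisson model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telespat)
```

## The problem

Claims databases record, for every health-care visit, who was seen, where
they live, when, by what modality (telehealth or in person), and with what
diagnosis. Aggregated to small areas — ZIP-code tabulation areas (ZCTAs) in
US practice — those records yield an annual *telehealth use rate*: the
proportion of an area's residents who had at least one telehealth visit
that year. Rates over small areas are noisy (many areas are sparsely
populated) and spatially dependent (neighbouring areas share
infrastructure, providers, and demographics), so raw rates are a poor basis
for identifying under-served places. The established remedy in disease
mapping is a hierarchical Poisson model with spatially structured random
effects, and that is the model at the core of this package.

`telespat` implements the whole workflow: generating synthetic claims with
known ground truth, building the neighbourhood graph, filtering records into
an analysis cohort, computing descriptive trends, screening covariates,
fitting the spatial model by MCMC, and turning posterior draws into the
reported products — relative risks, model-comparison tables, and
exceedance-probability maps.

## The model

Let $Y_i$ be the telehealth outcome count in area $i$ (by default the
number of *unique* patients with a telehealth visit; a visits-based
numerator is also supported), and $E_i$ the resident population. The
Besag–York–Mollié (BYM) convolution model is

$$Y_i \sim \mathrm{Poisson}(E_i\, e^{\eta_i}), \qquad
  \eta_i = \beta_0 + x_i^\top \beta + u_i + v_i ,$$

with $\log E_i$ acting as an offset, $x_i$ the standardized area-level
covariates (so each $\beta_j$ is a log relative risk per one standard
deviation), $v_i \stackrel{iid}{\sim} N(0, 1/\tau_v)$ unstructured
heterogeneity, and $u$ an intrinsic conditional autoregressive (ICAR)
field over the queen-contiguity graph:

$$p(u \mid \tau_u) \propto \tau_u^{(n-c)/2}
  \exp\Big\{ -\frac{\tau_u}{2} \sum_{i \sim j} (u_i - u_j)^2 \Big\},$$

where $i \sim j$ ranges over neighbour pairs (areas sharing any boundary
point, edge or corner), $n$ is the number of areas and $c$ the number of
connected components of the graph. The ICAR density is improper — flat
along constant shifts within each component — so identifiability requires a
sum-to-zero constraint per component. We use the classic additive $u + v$
parameterization rather than the rescaled BYM2 variant, matching the
Besag-style covariance the analysis is built around.

Exponentiated coefficients are reported as relative risks (RR): the
multiplicative change in the area rate per 1 SD of a covariate. The RR
point estimate is $\exp(\bar\beta_j)$ and the 95% credible interval is the
exponential of the 2.5%/97.5% posterior quantiles of $\beta_j$ — because
$\exp$ is monotone, these are identically the quantiles of the RR draws.

## Priors and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `beta_prec` | `1e-4` | Normal prior precision on $\beta_0$ and $\beta$; effectively vague on standardized covariates. |
| `tau_shape`, `tau_rate` | `1`, `5e-4` | Gamma hyperprior on both precisions $\tau_u$, $\tau_v$; a common weakly-informative disease-mapping default. |
| `fixed_tau_u`, `fixed_tau_v` | `NULL` | Optionally hold a precision fixed (used for oracle comparisons). |
| `tolerance` (queen contiguity) | `1e-9` | Distance within which boundary points are considered shared; absorbs coordinate perturbation from GeoJSON round trips. |
| `threshold_fraction` (exceedance) | per year | Fraction of the reference rate defining "low use" — e.g. 0.5 flags areas at least 50% below the state mean; early low-uptake years warrant a smaller fraction (0.1). |

The source analysis this design follows did not state its hyperpriors;
those defaults are package choices, exposed in `bym_priors()` so a user can
reproduce any other choice.

## Inference: Metropolis-within-Gibbs, not INLA

Models of this family are often fitted with integrated nested Laplace
approximation. This package deliberately uses its own
Metropolis-within-Gibbs sampler instead: the scientific content is the
model, not the approximation algorithm, and a from-scratch MCMC engine can
be validated exactly against a brute-force oracle (below), which an
approximation cannot. One sweep of `fit_bym_poisson()`:

1. **Coefficients.** Scalar normal random-walk updates of $\beta_0$ and each
   $\beta_j$, each with its own proposal scale. (Per-coordinate updates are
   used instead of a joint block because the intercept's conditional
   posterior is far tighter than the coefficients'; a shared block scale
   mixes poorly.)
2. **Structured effects.** Single-site random-walk updates of every $u_i$,
   vectorized over the colour classes of a greedy proper colouring of the
   adjacency graph: sites within a colour class share no edge, so they are
   conditionally independent and their accept/reject decisions can be made
   simultaneously. This gives single-site correctness at vectorized cost.
3. **Recentring.** $u$ is recentred to per-component sum-to-zero, with
   $\beta_0$ absorbing the global shift. For a connected graph this leaves
   $\eta$ unchanged (exact); for multi-component graphs the residual
   per-component shifts are removed in the standard GeoBUGS manner, with
   the vague intercept absorbing them over iterations. Structured effects
   of isolated areas are pinned at 0; such areas are carried entirely by
   $v$ (a flag to drop islands instead is available at the adjacency
   level).
4. **Unstructured effects.** All $v_i$ updated simultaneously (iid prior,
   area-local likelihood).
5. **Precisions.** Conjugate Gamma draws:
   $\tau_u \mid u \sim \Gamma(a + (n-c)/2,\; b + \tfrac12\sum_{i\sim j}(u_i-u_j)^2)$ and
   $\tau_v \mid v \sim \Gamma(a + n/2,\; b + \tfrac12\sum v_i^2)$.

Proposal scales adapt every 50 sweeps during burn-in toward an acceptance
rate of 0.44 (the scalar-update optimum), then freeze, so the retained
chain is a fixed-kernel Markov chain. All randomness flows through R's
RNG from the single `seed` in `mcmc_config()`: identical seeds give
bit-identical chains. Split-chain $\widehat R$ and a lag-1 effective sample
size are available from `convergence_diagnostics()`; they are reported,
not enforced.

## Validation surfaces

Three independent checks stand behind the sampler, all run routinely in the
test suite:

* **Grid-integration oracle.** `grid_posterior_oracle()` integrates the
  unnormalized posterior of toy problems (≤ 3 areas, ≤ 4 free parameters
  after the sum-to-zero constraint, fixed precisions) on a tensor grid with
  trapezoid normalization, warning if boundary density exceeds $10^{-6}$ of
  the peak. Sampler posterior means agree with the oracle within 0.05 on
  the standard 3-area path toy, and the oracle itself agrees with 1-D
  quadrature to $10^{-4}$ and is stable under grid refinement to $10^{-3}$.
* **Parameter recovery.** `parameter_recovery_study()` simulates studies on
  20×20 lattices with truth $\beta = (0.3, -0.2)$, $\tau_u = \tau_v = 4$,
  area populations 500–5000 and a baseline rate of 5 per 100 residents —
  count levels representative of mid-sized areas in a pandemic-era year —
  and refits with 20,000 sweeps. Across 20 replicates the posterior means
  are unbiased to within ±0.05 and the 95% intervals cover truth in at
  least 17 of 20.
* **Reduction to known fits.** With both random effects disabled and vague
  priors, posterior means match `glm(family = poisson)` within 0.01; the
  precision full conditionals are unit-tested against hand computation.

## Model comparison and exceedance maps

`compute_dic()` reports the deviance information criterion
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\hat\theta)$, using
the *conditional* focus (deviance evaluated given the random effects at
their posterior means) — the usual choice for convolution models, whose
marginal likelihood is not available in closed form. The identity
$\mathrm{DIC} = \bar D + p_D$ holds exactly by construction and a negative
$p_D$ warns rather than fails. `compare_models()` fits a list of
specifications (canonically: crude = one covariate + iid effect; crude
spatial = one covariate + both effects; fully adjusted = all retained
covariates + both effects) with spec-indexed seeds and ranks them. Under
simulated spatial clustering ($\tau_u = 0.5$, negligible iid noise) the
spatial model wins in ≥ 18/20 replicates; with real covariate effects and
modest iid noise ($\tau_v = 100$) the adjusted model wins in ≥ 18/20. Both
experiments use 12×12 lattices and 6000 sweeps — sizes at which the DIC
margin dominates its Monte-Carlo error; with large free iid heterogeneity
the omitted-covariate signal is partly absorbed by $v$ and the ordering is
genuinely uncertain, which is a property of DIC, not of the implementation.

`exceedance_probabilities()` reports, per area, the fraction of posterior
draws in which the fitted rate $e^{\eta_i}$ falls below
`threshold_fraction` × a reference rate. The reference is the
population-weighted mean fitted rate *within the same draw*, keeping the
comparison internally coherent; a fixed external reference value is also
supported, as is applying the threshold to raw or smoothed rates via the
returned draws. Probabilities are exact Monte-Carlo counts (they match a
brute-force recount of the draws identically) and are monotone in the
threshold by construction.

## The synthetic-data generator

Real all-payer claims are not redistributable, so every stage is exercised
against `generate_grid_lattice()` + `simulate_area_panel()` +
`simulate_visit_records()`, which emulate the *statistical structure* the
analysis assumes:

* a planar partition of unit cells whose queen graph is known in closed
  form (centre cell of a 3×3 grid has exactly 8 neighbours);
* rurality assigned by deterministic row banding (top third `city`, middle
  `suburban_town`, bottom `rural`), so all three classes occur on any grid
  with ≥ 3 rows and tests are reproducible;
* covariates drawn with optional equicorrelation and then standardized;
* $u$ drawn *exactly* from the ICAR prior by sampling the non-null
  eigendirections of the graph Laplacian (no propriety fudge factor), so
  per-component sums are zero to $10^{-10}$;
* counts drawn from the Poisson offset model, with the full truth
  ($\beta_0, \beta, u, v, \tau$) attached for recovery tests;
* visit records expanded from the counts with deterministic patient ids,
  year-dependent diagnosis-code mixes, an in-person visit volume implied by
  the configured telehealth share (default 0.3), and a configurable
  fraction of records corrupted with missing or out-of-frame area ids to
  exercise the cohort filters.

What the generator does **not** emulate: payer mix, the construction of
deprivation indices from census inputs, survey sampling error in
covariates, irregular polygon geometry, or within-year seasonality. Tests
passing on synthetic data therefore establish the correctness of the
*computations*, not the real-world validity of any particular covariate
specification.

## Descriptive layer choices

* **Cohort filters** run in a fixed order — missing fields, study-year
  range, area validity — and log a ledger in which
  `records_in - records_dropped = records_out` holds at every stage, so
  attrition diagrams are exactly reconstructable.
* **Use rates** count each patient once per area-year however many visits
  they made. A patient appearing in two areas in one year counts in both
  areas' numerators: the estimand is the area-level rate and no
  cross-area deduplication is attempted.
* **Rurality shares** divide each class's telehealth visits by *all*
  telehealth visits of the year — including visits in areas of unknown
  class — and round half-up to one decimal, the convention of published
  summary tables (whose printed totals can slightly exceed the sum over
  tabulated classes). Years with zero telehealth visits are flagged, never
  reported as 0%.
* **Trend testing** uses the Cochran–Armitage score test
  (`stats::prop.trend.test`) on annual proportions with equally spaced
  year scores — the standard test for a monotone trend in proportions,
  chosen because the analysis this follows reported only "a significant
  upward trend" without naming a test. A label-permutation fallback is
  provided for tiny counts and doubles as the oracle in tests. Under a
  simulated null the p-values are uniform (KS check over 200 replicates).
* **Diagnosis rankings** order codes per year by descending telehealth
  visit count with a lexicographic tie-break, producing the long-format
  table behind a top-k heat map.

## Covariate screening

`vif_screen()` computes $\mathrm{VIF}_j = 1/(1 - R_j^2)$ and iteratively
removes the worst offender above the threshold (default 5.0), recomputing
after each removal — single-pass removal can discard more than necessary.
Ties (including several infinite VIFs from exact collinearity) drop the
*later* column in the user's ordering: retention priority is a substantive
judgment (construct validity, data completeness) that the caller encodes by
listing preferred variables first, not something the code invents. VIF is
scale-free, and the implementation is cross-checked against an independent
reference implementation in the test suite; the canonical two-column design
with correlation 0.9 gives VIF $= 1/(1-0.81) \approx 5.263$ and triggers a
drop at threshold 5.

## Numerical and design notes

* Queen contiguity is decided by whether any polygon vertex lies within
  `tolerance` of another polygon's boundary — this covers shared edges,
  corners, and T-junctions of a planar partition; proper crossings would
  mean overlapping areas and are rejected upstream by the
  self-intersection check.
* Component labels, not just connectivity, are tracked because the ICAR
  rank deficiency is one per component; single-area components (islands)
  contribute no free dimension.
* Multi-year studies are produced by repeated single-year simulations with
  year-indexed seeds, and models are fitted per year — mirroring analyses
  that fit pandemic-era years separately because covariate effects shift
  between years.
* The pipeline derives every stage seed from one global seed by a fixed
  affine scheme, so each artifact is independently re-derivable; manifests
  record MD5 hashes of all outputs and identical configurations reproduce
  identical manifests bit for bit.
* Problem sizes used by the standing test suite (20×20 recovery lattices,
  12×12 DIC experiments, 6000–20,000 sweeps) were chosen as the smallest
  sizes at which the checked signal clearly dominates Monte-Carlo noise.

## Known limitations

* Single-chain sampling with additive $u + v$: when the data carry little
  information, the split of variance between $\tau_u$ and $\tau_v$ is
  weakly identified and mixes slowly — a well-known property of the BYM
  parameterization. Identified functionals ($\beta$, $u + v$, fitted
  rates) are what the reported products use.
* No spatiotemporal model: years are fitted independently; no
  zero-inflation or negative-binomial likelihood.
* The oracle covers toy problems only; at full scale, correctness rests on
  the recovery and reduction checks.
* Exceedance maps are data products (GeoJSON properties); cartographic
  rendering is out of scope.

## A worked example

```{r example, eval = FALSE}
lat <- generate_grid_lattice(10, 10, seed = 1)
adj <- queen_adjacency(lat)
cfg <- sim_config(10, 10, beta0 = log(0.05), beta = c(0.3, -0.2),
                  tau_u = 4, tau_v = 4, seed = 2)
panel <- simulate_area_panel(lat, cfg, c("density", "poverty"),
                             adjacency = adj)
fit <- fit_bym_poisson(panel, adj, model_spec(c("density", "poverty")),
                       bym_priors(), mcmc_config(8000, 2000, thin = 2,
                                                 seed = 3))
summarize_rr(fit)
compute_dic(fit, panel)
exceedance_probabilities(fit, panel, threshold_fraction = 0.5)
```

An end-to-end run (simulation → filters → rates → shares → trend → VIF →
three-model comparison → RR table → exceedance GeoJSON → manifest) is one
call: `run_pipeline(demo_pipeline_config("out"))`.
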