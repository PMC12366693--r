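---
title: "Simulating the continental Neolithic expansion and inferring admixture by ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the continental Neolithic expansion and inferring admixture by ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demicabc)
```

## The model

`demicabc` implements a spatially explicit simulation and inference
machine for the interaction between indigenous hunter-gatherers (HG) and
expanding Neolithic farmers (FA) along the continental route from
Anatolia into central Europe. Two population layers live on a lattice of
100 x 100 km cells in Plate Carree (equirectangular) georeferencing;
each cell holds one HG and one FA deme. Time advances in generations of
25 years; the default full-scale frame is 1600 generations from 40,000
yr B.P.

Each generation applies three steps per deme, in a fixed order chosen
for determinism (growth needs last generation's sizes, admixture needs
post-growth densities, migration moves the final residents):

1. **Logistic growth with Lotka-Volterra competition.** With gene copies
   `N` in a layer of carrying capacity `K` and growth rate `r`, and `N'`
   in the competing layer,
   `N <- max(0, round(N + r N (1 - (N + alpha N') / K)))`. The
   competition coefficient `alpha` is symmetric between layers within a
   zone: `alpha = 1` south of latitude 43.2 degrees and a variable
   `alpha_N` north of it, so the northern zone can sustain longer HG-FA
   cohabitation.
2. **Assimilation admixture.** Where both layers occupy a cell, an
   expected `gamma_t * N_HG * N_FA / (N_HG + N_FA)` gene copies move
   from the HG to the FA deme (stochastically rounded, capped at
   `N_HG`). The contact form — the admixture rate times a term
   proportional to both densities — is the published assimilation-model
   interaction; it is isolated in `admixture_transfers()` so it can be
   swapped. Gene flow is strictly unidirectional HG to FA.
3. **Migration.** Each copy emigrates with probability `m`; emigrants go
   to one of the four orthogonal neighbours (stepping stone), except
   that a fraction `P_LDD` of FA emigration events are long-distance,
   with distance drawn from a gamma kernel (shape 1.209, rate 0.15046
   per deme width; mean ~8 deme widths, about 800 km) and uniform
   direction. Migrants drawn toward water or off the grid stay home
   (stepping stone) or redraw up to 10 times (LDD).

Population sizes are integer gene copies ("effective haploid" sizes);
K_HG derives from Paleolithic density estimates (0.04-0.0675
individuals/km^2, one third sexually mature, two gene copies each — see
`K_from_density()`), K_FA from earlier demogenetic work.

### Scenarios

Six admixture scenarios vary `gamma` in space and time. AM1 is constant;
AM2/AM5 impose a 10-band spatial gradient (each band shifts the rate by
10% of the maximum) increasing/decreasing away from the FA origin;
AM3/AM4 ramp `gamma` linearly from 0 at colonization to the maximum at
the end of the local cohabitation period; AM6 has two spatial zones
(split at 43.2 degrees) and a ramp of variable length `t_inc`. Because
the appropriate ramp speed depends on how long the layers actually
cohabit, a preliminary constant-rate campaign is run and the mean
cohabitation time is regressed on `K_HG`, `K_FA` and `alpha_N` with a
GAM (`calibrate_cohabitation()`); ramp scenarios then set
`gamma_inc = 1/t_inc` with `t_inc` the predicted cohabitation time
(AM3/AM4) or a uniform integer between 1 and it (AM6). The band geometry
for AM2/AM5 (equal-width lattice-distance bands from the FA origin) is a
package convention: only the 10 zones and their 10% steps are part of
the scenario definitions, not an exact geometry, so the profile
function is kept swappable. Likewise the gradient floor is `0.1 * gamma_max` (ten equal
steps ending at the maximum), the natural reading of bands that differ
by 10% of the maximum rate.

### Genetics

The forward pass records, per generation and deme: post-regulation
sizes, post-admixture sizes, resident counts, immigrant counts by source
direction, LDD events, and admixture transfers. The backward coalescent
is conditioned on these *exact counts*, so forward and backward are
consistent by construction: one gene copy per sampled individual
(pseudo-haploid representation) activates at its sample's generation
(serial sampling), picks its origin each generation in proportion to the
recorded inflows (admixture transfers move FA lineages into the HG
layer), and co-located lineages coalesce by uniform parent assignment —
pairwise probability `1/N`. Lineages reaching generation 0 coalesce in a
panmictic ancestral pool; FA lineages older than the farmer seeding
coalesce in a panmictic source pool of size `K_FA` standing in for the
unmodelled Anatolian source.

Sequences are 50 independent loci of 1000 bp (configurable) under a
finite-sites model: Poisson mutations per branch at
`mu = 2.15e-8`/site/generation, each substituting a uniformly chosen
different base; sequencing error then flips each site independently with
probability `eps` — so an error-only pair mismatches at rate
`2 eps (1 - eps) + (2/3) eps^2`. A finite-sites representation (rather
than infinite sites) is used because repeat mutation and sequencing
error must interact on concrete bases.

### Summary statistics and ABC

Pairwise pseudo-haploid diversity is the mismatch fraction between two
single-base-call genomes pooled over loci. Genomes are grouped into
population samples by deme, layer and age: sorted ages are chained while
adjacent gaps are at most 300 years, and chains are recursively split at
their largest internal gap until every group's age span is below 300
years and below the gap to its nearest neighbour (this realizes the rule
that the maximum intragroup difference stays below the minimum
intergroup difference; the recursive largest-gap split is the package's
deterministic tie-break). The statistic vector is the within-sample mean
for every sample with at least two genomes followed by all between-sample
means, label-sorted; the study's 23-sample scheme gives 14 + 253 = 267
values from 2211 pairs of 67 genomes.

Inference is two-step ABC. The **demographic filter** rejects histories
that cannot produce every sample at its deme, generation and layer, or
in which HGs survive to the end of the simulation anywhere on the map
(the global reading of extinction is deliberate). **Model choice** runs
a 2000-tree classification forest on the raw statistic vectors
(scenarios subsampled to equal counts), with the selected scenario's
posterior probability from a regression forest on the out-of-bag
misclassification indicator and the confusion matrix from out-of-bag
predictions. **Estimation** reduces the statistics by a per-statistic
Box-Cox power transform followed by PLS regression of parameters on
statistics, keeping the first components (10 by default; the component
count rule accepts the smallest number beyond which every parameter's
RMSE improves by less than 2%), retains the `round(delta * N)` closest
simulations by Euclidean distance, and applies a GLM regression
adjustment: a linear-Gaussian model of statistics given parameters is
fitted on the retained set, the retained parameter cloud is smoothed
into a Gaussian mixture (diagonal Silverman bandwidth), and the
posterior — likelihood at the observed statistics times that smoothed
truncated prior — is an analytic Gaussian mixture. Marginals are
evaluated on 1000-point grids over the prior support (resolution chosen
so HDI mass error stays well below 0.1%) and summarized by mode, mean
and the shortest 95% HDI (ties resolved toward the most central
window). The marginal-density goodness-of-fit p-value is the fraction of
retained simulations whose model marginal density falls below the
observed vector's. Two-dimensional posteriors are the corresponding 2-D
mixture marginals, sampled by a seeded random-walk Metropolis chain with
acceptance-rate tuning and a split-chain Gelman-Rubin guard; probability
queries such as `P(gamma_S > gamma_N)` are draw fractions.

## The scaled-down study conditions

The full campaigns behind the source study (hundreds of thousands of
simulations on a 75 x 47 map of western Eurasia against a real
267-statistic observed vector) are not reproducible at package-check
scale, and the real coastline raster is not shipped (the packaged
default world is an all-land synthetic mask). The package's own
experiments therefore run on a 10 x 6 toy lattice under an explicit
**coalescent rescaling**: time is compressed from 1600 to 200
generations (factor 8), carrying-capacity priors are divided by 8
(K_HG 33.75-56.25, K_FA 150-300 gene copies) and the mutation rate is
multiplied by 8 (`1.72e-7`). This preserves the model's dimensionless
structure — `K_FA/K_HG`, the competition balance `alpha K_FA / K_HG`,
within-deme coalescence fractions per simulated epoch, and
`theta = 2 K mu`, hence pseudo-haploid mismatch fractions in the
study's observed 1e-4 to 1e-3 range with the sequencing-error
contribution (1e-4 to 2.4e-4) a comparable share, as in the empirical
data. Per-generation rates (growth, migration, admixture, competition)
are dimensionless and unchanged. The ancestral pool behind generation 0
defaults to 2000 gene copies in these campaigns: it stands in for the
deep HG-versus-Anatolian-farmer divergence that accumulates before the
simulated window on the real timeline and is what makes admixture
legible in the statistics; `trace_genealogies()` itself defaults to
`K_anc = K_HG` for single-layer closed-form work.

The farmer onset on the toy is generation 60 of 200, placed after the
HG layer has filled the small lattice — mirroring the study's timeline,
where hunter-gatherers occupy the map long before the farmer seeding —
rather than scaling the onset fraction directly. The toy sampling
scheme (3 HG samples of 2-3 genomes at generations 70-110, 4 FA samples
of 4-5 genomes at 90-170, in both zones) mirrors the study scheme's
structure; the LDD-ablation experiment uses a deliberately tight
schedule (far demes sampled 16-24 generations after onset) that
stepping-stone spread alone cannot meet. Toy campaigns use 10-20 loci:
when only averaged diversities are compared, a locus count far below
the ~5000 empirical capture loci is sufficient.

What these toys do **not** emulate: coastline/geography effects, any
environment-dependent K or m (uniform by design), ascertainment of the
empirical capture panel, or postmortem damage (the empirical pipeline
trims it; `eps` absorbs the residual). Passing tests therefore validate
the machinery and its statistical calibration, not the study's
real-data posterior values.

## Numerical and design notes

- **Half-open cells, strict north rule, half-up generation rounding** —
  all boundary conventions are fixed for determinism; a cell centered
  exactly on 43.2 degrees is southern.
- **Rejection ties** break by row index; rejection is otherwise
  row-order invariant.
- **Degenerate inputs**: constant statistics are dropped (with a
  warning) before the power transform; a singular statistic covariance
  is ridge-regularized; parameters with zero true value are excluded
  from relative-bias averages with a warning; an empty scheme is valid;
  `delta * N < 2` is an error.
- **The LDD parameter 0.15046** is interpreted as a *rate* (the kernel
  mean `shape/rate = 8.04` deme widths then matches the stated ~800 km
  average; a scale reading would not).
- **m_FA prior** is 0.1-0.5, the tabulated prior range.
- **Goodness-of-fit calibration** is checked without rejection
  (`delta = 1`), where the p-value is a pure rank statistic of the
  observed vector among exchangeable simulations and hence exactly
  uniform under the null. Conditioning the retained set on the observed
  vector (smaller `delta`) centers the fitted model on the observation
  and shifts the null p-values upward (we measure means around
  0.55 at `delta = 0.5`): the conditioned p-value is conservative,
  which is the safe direction for a screen that discards ill-fitting
  scenarios.
- **Problem sizes** in the packaged experiments (10,000 coalescent pair
  replicates; 200 calibration/coverage replicates; 80 simulations per
  arm for the AM6-degeneracy check; 1000 per arm for the LDD ablation;
  2000 per scenario for model choice; a 5000-simulation AM6 campaign
  with 20 pseudo-observed replicates for ratio recovery) were chosen so
  the whole suite runs on a laptop core in tens of minutes while keeping
  Monte-Carlo error well inside each check's tolerance.

## Known limitations

- The GLM marginals truncate each parameter to its own prior interval;
  joint truncation effects across parameters are ignored except in the
  2-D sampler.
- The backward tracer requires the demography to have been recorded by
  this package's forward pass (or a hand-built equivalent such as
  `constant_deme_db()`); it cannot consume external simulator output.
- Multifurcating merges (several lineages picking one parent) are kept
  as multifurcations; for small demes this is the honest discrete-time
  genealogy, but it differs from a strictly binary Kingman limit.
- The no-admixture equivalence AM6(t_inc = 1, gamma_S = gamma_N) ~ AM1
  is exact except at the seeding deme in the seeding generation, where
  the ramp contributes a zero rate for one generation.
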