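---
title: "Updating categorical maps by Markov chain random field cosimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updating categorical maps by Markov chain random field cosimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrfupdate)
```

## The problem

Categorical soil maps (and categorical landscape maps generally) age:
class boundaries shift, classes are re-taxonomized, and mapping errors
surface. A full re-survey is rarely affordable, but when a good legacy
map exists, most of it is still correct — what is needed is a way to
combine a *sparse* set of new survey points with the *exhaustive* legacy
map into an updated map, together with an honest statement of where the
update is uncertain.

`mcrfupdate` implements this combination as sequential cosimulation
under a Markov chain random field (MCRF) model. The package covers the
whole workflow: transiogram estimation from point samples, cross-field
transition probability estimation against the legacy map, random-path
sequential simulation with and without the legacy map (Co-MCSS and
MCSS), occurrence-probability post-processing, and a synthetic scenario
generator for controlled evaluation.

## The model

An MCRF treats the categorical field as a single spatial Markov chain
that decides its class at an uninformed location $\mathbf{u}_0$ by
Bayesian updating on its nearest informed neighbors in different
directions. Writing $p_{ij}(h)$ for the transiogram — the probability
of class $j$ at lag distance $h$ from a location of class $i$ — the
simplified local solution under conditional independence of the
neighbors is

$$
p\left[i_0 \mid i_1,\dots,i_m\right] =
\frac{p_{i_1 i_0}(h_{10}) \prod_{g=2}^{m} p_{i_0 i_g}(h_{0g})}
     {\sum_{f=1}^{n}\left[p_{i_1 f}(h_{10}) \prod_{g=2}^{m} p_{f i_g}(h_{0g})\right]},
$$

where $i_1$ is the *designated first* neighbor — the location the chain
is taken to arrive from, whose term runs in the transposed direction —
and $i_2,\dots,i_m$ are the remaining neighbors. With one neighbor the
posterior is simply the transiogram row from that neighbor; with none,
the chain is assumed to arrive from outside the search range and the
marginal class proportions are used.

A colocated auxiliary field (the legacy map, with classes $r$) enters
multiplicatively through cross-field transition probabilities
$b_{i_0 r_0}$, collected in the row-stochastic cross-field transition
probability matrix (CTPM) estimated by frequency counting,
$b_{ik} = f_{ik} / \sum_j f_{ij}$, from samples colocated with legacy
cells:

$$
p\left[i_0 \mid i_1,\dots,i_m; r_0\right] \propto
b_{i_0 r_0}\, p_{i_1 i_0}(h_{10}) \prod_{g=2}^{m} p_{i_0 i_g}(h_{0g}).
$$

Two limiting behaviors follow directly and are exercised in the test
suite. If a legacy class is observed together with exactly one updated
class (a unit CTPM column), every simulated realization reproduces that
class deterministically — unchanged and merged-only classes are simply
inherited from the legacy map. If a CTPM column is constant across
primary classes, the auxiliary carries no information there and the
term cancels, leaving the sample-only (MCSS) distribution;
`is_uninformative()` flags such columns.

## Transiogram estimation and interpolation

Experimental transiograms are estimated omnidirectionally: every
ordered sample pair within `max_lag` contributes its class transition
to the bin `floor(d / bin_width)`, in both orderings — the symmetric
use of sparse data that is standard for omnidirectional statistics.
Directional (anisotropic) estimation is deliberately out of scope.

Two numerical choices matter:

* **Lag anchors are mean pair distances.** Each bin's matrix is
  anchored at the mean distance of the pairs it contains, not at the
  nominal bin center. With gridded or near-gridded data the observed
  distances cluster well below or above the nominal center, and
  anchoring at the nominal center would systematically shift the
  interpolated curves — visibly so against the matrix-power benchmark
  of a known one-dimensional Markov chain, which the test suite checks
  to ±0.01. Mean-distance anchors are common practice in experimental
  variography for the same reason. Bins with no pairs at all are
  dropped from the anchor grid; the interpolation simply spans the gap.

* **Identity at zero, marginal sill beyond the last anchor.** The model
  is anchored at $h = 0$ with the identity matrix ($p_{ij}(0) =
  \delta_{ij}$) and interpolates linearly between anchors. Strictly
  beyond the last anchor every row returns the marginal proportions —
  the theoretical sill of a stationary transiogram — rather than
  holding the last estimated value. This can introduce a small step at
  the last anchor when the experimental value has not yet decayed to
  the sill; we prefer the principled limit over extrapolating noise.
  Evaluated rows are renormalized so they sum to one exactly.

Rows of a bin with no pairs for some head class are filled with the
marginals (with a warning): the class was effectively absent from the
conditioning data at that lag, and the sill is the least-informative
stochastic completion.

## Neighborhood search and the sequential algorithm

Conditional independence of neighbors is only tenable if they lie in
different directions, so the engine uses a quadrant search: around the
cell being simulated, the four 90° sectors centered on the cardinal
directions (boundaries at 45°, 135°, 225°, 315°) each contribute at
most their single nearest informed cell within the search radius.
Determinism requires explicit tie rules: a cell exactly on a sector
boundary belongs to the counter-clockwise sector, and equal distances
break to the smallest `(row, col)`. The designated first neighbor is
the globally nearest entry.

`sequential_simulate()` fixes the sample cells, visits the remaining
cells in a uniformly random permutation, draws each cell's class from
its local conditional distribution, and immediately adds the drawn
cell to the informed set — previously simulated cells condition later
ones exactly like original samples, which is what makes single-sweep
sequential simulation valid. Reproducibility is bit-exact under a
seed: one RNG stream per realization, consuming the path permutation
first and then one uniform per cell (inverse-CDF draw over codebook
order). `simulate_realizations()` derives the seed of realization $r$
as `seed + r`.

If every candidate class has zero numerator at some cell (possible
with sparse data and hard zeros in the transiograms or the CTPM), the
distribution falls back in order to (1) the CTPM likelihood times the
marginals, (2) the marginals, (3) uniform; fallback counts are
reported in the realization metadata rather than silently absorbed.

The search radius defaults to 30 cells, a value appropriate for sample
densities around 3% of cells; it should generally be chosen so that
an empty search neighborhood is rare.

## The synthetic scenario generator

Real legacy/reference map pairs with known ground truth are scarce, so
the package ships a generator (`generate_scenario()`) that emulates
the structure of a realistic map-update problem end to end:

* a **legacy map** of 7 classes on a 175 × 128 grid (22,400 cells),
  built by seeded region growth from randomly placed patch seeds —
  contiguous patches, class proportions controlled to about ±0.05.
  The generator is deliberately independent of the MCRF engine so that
  end-to-end tests are not circular. Default proportions
  (.08, .18, .21, .14, .05, .16, .18) include two minor classes that
  participate in merges;
* an **update scenario**: two taxonomy merges (7 → 5 classes) plus two
  localized swaps in opposite corners of the map, each relabeling a
  fraction (default 0.6) of the eligible cells of one legacy class as
  contiguous sub-patches. "Changed" cells are those where the
  reference differs from the *merge-relabeled* legacy map, so pure
  taxonomy merges do not count as change;
* a **sample set** of 646 points at distinct cell centers: a share
  (default 0.15) placed uniformly in changed cells, standing for the
  update survey, and the rest placed uniformly in unchanged cells as
  pseudo-samples — conditioning points read off the legacy map where
  it is trusted. The survey share is a free parameter because real
  surveys vary widely in how concentrated they are on suspected
  change.

What the generator does *not* emulate: real soilscape geometry
(drainage-controlled elongated polygons, scale-dependent boundary
complexity), anisotropic spatial correlation, spatially biased or
clustered survey designs, and legacy maps with internal error. Passing
tests on these scenarios therefore demonstrate the correctness and
internal consistency of the method, not its field accuracy on any
particular real survey.

## What the evaluation computes

The test suite verifies, among other properties: exact agreement (to
1e−12) of the engine's local distributions with brute-force evaluation
of the product formula over all candidate states; recovery of matrix
powers $P^h$ (±0.01) from a 100,000-step simulated two-state Markov
chain; agreement of sequential draws with the analytic local
distribution on a 1 × 3 grid with fixed ends (2,000 realizations,
three standard errors); exact reproduction of unchanged and
merged-only classes through unit CTPM columns; and, on the default
synthetic scenario with 100 realizations per method and radius 30,
that the cosimulation's optimal-prediction accuracy (percentage of
correctly classified cells, sample cells excluded) strictly exceeds
the sample-only simulation's. These problem sizes run in seconds
thanks to the compiled engine core and were chosen to match the
canonical study configuration exactly rather than a scaled-down proxy.

A compact illustration:

```{r example}
sc <- generate_scenario(n_rows = 60, n_cols = 50, n_samples = 200, seed = 7)
ex <- estimate_transiograms(sc$samples, bin_width = 1, max_lag = 25,
                            n_classes = 5)
marg <- tabulate(sc$samples$class_code + 1L, 5)
model <- build_model(ex, marg / sum(marg))
ct <- estimate_ctpm(colocate(sc$samples, sc$legacy), 5, 7)
round(ct$b, 3)

tmpl <- categorical_raster(matrix(0L, 60, 50),
                           codebook = sc$reference$codebook)
reals <- simulate_realizations(20, tmpl, sc$samples, model,
                               aux = list(raster = sc$legacy, ctpm = ct),
                               radius = 15, seed = 1)
opt <- optimal_prediction(occurrence(reals))
pcc(opt$prediction, sc$reference, exclude = sc$samples)
```

## Known limitations

* The conditional-independence simplification ignores data clustering;
  no power-parameter or other clustering correction is applied.
* Transiogram models are interpolated, not fitted parametrically;
  very sparse samples give ragged experimental curves and the model
  inherits that noise between anchors.
* Only colocated auxiliary conditioning is supported (no
  cross-transiograms to auxiliary fields at nonzero lags), and
  multiple auxiliaries are treated as mutually independent.
* Anisotropy is not modeled; all transiograms are omnidirectional.
* Uncertainty maps reflect only variability verified by the sample
  data: errors present in the legacy map but untouched by any sample
  propagate silently into the update, with occurrence probability 1.
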