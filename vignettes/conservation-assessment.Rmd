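---
title: "Reserve selection and gap analysis for simulated national floras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reserve selection and gap analysis for simulated national floras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

National protected-area (PA) systems are rarely representative samples of
national biodiversity: reserves accumulate where land is cheap and scenic —
usually mountains — while lowland species go under-protected. Quantifying
that bias and proposing complementary reserves takes four coupled steps:

1. model many species' ranges jointly from sparse point occurrences,
2. binarize the modelled occurrence probabilities into range maps,
3. select candidate reserve networks with a spatially explicit optimizer, and
4. report how well each network represents each species group.

`reserveplanr` implements this pipeline end to end, together with a
synthetic-data module that generates landscapes, virtual species, biased
surveys, and elevation-biased existing-PA masks with the statistical
structure the analysis assumes. Every stage is therefore testable without
any external data download.

```{r pipeline}
library(reserveplanr)
st <- run_synthetic_study(seed = 1)
st$representation$existing   # mean % of range protected, by species group
autoplot(st$env)             # the simulated landscape
```

## The synthetic world

`make_landscape()` builds elevation from deterministic ridge segments plus
seeded, spatially smoothed Gaussian noise. All climate layers are
*deterministic functions of elevation and position*:

* annual mean temperature `T = T_sea − λ·z/1000 + γ·(u − 1/2)` with lapse
  rate `λ = 6.5` °C/km, sea-level temperature 14 °C and a 4 °C
  north–south gradient (`u` is the north→south position in [0,1]);
* warmest/coldest-quarter temperatures add/subtract a latitude-dependent
  seasonal amplitude (11 °C north, 8 °C south), and seasonality is that
  amplitude;
* precipitation is a smooth function of elevation (orographic term,
  550 mm/km) and position.

Deriving climate from terrain is deliberate: the species models then face
the same predictor collinearity (temperature ≈ −elevation) that dominates
real mountainous study regions, so predictor selection behaves realistically
rather than ideally. Slope and aspect come from central finite differences;
aspect on flat cells is set to 0 by convention (northness = sin(aspect) = 0),
which keeps the degenerate case testable.

Virtual species (`simulate_species()`) carry Gaussian niches on annual mean
temperature and annual precipitation. Niche widths are drawn log-uniformly
with one stratum per species, so each world spans several orders of
magnitude in true range area (the default 60-species world spans more than
three) and contains both lowland and montane specialists. True range =
rescaled suitability ≥ 0.5; range areas are exact cell counts times the cell
area (0.1 km² by default on a 120×120 grid — a 1,440 km² desk-scale
"country").

Surveys (`sample_occurrences()`) emulate mountain-transect inventories: 15
transects whose start cells are drawn with probability ∝ rank(elevation)
(`elevation_bias = 1`; 0 gives a provably unbiased sampler — bias enters
*only* through start-cell choice, transects are centred on the start with
uniform orientation), and a species is recorded at a site with probability
`detection_prob × suitability`. Species with fewer than two records are
dropped with a warning, matching the minimum a species needs downstream
(the SD threshold requires a sample standard deviation).

The existing-PA mask (`make_existing_pas()`) grows contiguous patches from
high-elevation seeds until it covers 5.7% of cells. With the default bias
the mask's mean elevation far exceeds the landscape mean and at least one
lowland species has 0% of its true range protected — the "lowland gap" the
whole analysis is about. With `elevation_bias = 0` growth is elevation-blind
and the mask is unbiased in expectation (a Monte-Carlo test in the suite).

## Multi-response MARS

All species of a batch are fitted jointly by multivariate adaptive
regression splines on the site-by-species matrix: rows are distinct survey
sites, responses are 0/1 with absences supplied by *inventory
pseudo-absences* (sites where other species were recorded). The model is a
shared expansion in hinge functions

\[ \hat y_s(x) = \beta_{0s} + \sum_m \beta_{ms} B_m(x), \qquad
   B_m(x) = \prod_j \max(0,\, \sigma_{mj}(x_{v_{mj}} - k_{mj})) \]

with one least-squares coefficient vector per species and predictions
clamped to [0,1]. The forward pass adds mirrored hinge pairs greedily,
minimizing the residual sum of squares summed across species; candidate
knots are observed values, subsampled to ≤ 50 quantiles per variable. The
backward pass deletes terms one at a time under the multi-response GCV

\[ \mathrm{GCV}(M) = \frac{\mathrm{RSS}/(nS)}{(1 - C(M)/n)^2}, \qquad
   C(M) = M + d\,(M-1)/2 , \]

with penalty `d = 3`, maximum 21 terms and maximum interaction degree 2
(classical defaults; the alternatives matter little here because the
synthetic signal is low-dimensional). Responses are fitted by least squares
on the 0/1 matrix rather than a logistic link — the classical multi-response
formulation — with clamping supplying the probability contract. Species are
batched into random groups whenever more than 300 would be fitted jointly;
the remainder of an uneven split goes to the final group. Model skill is
scored by fit-data AUC (Mann–Whitney form, midranks for ties) of each
species' presences against all pseudo-absences in its group matrix; there is
no hold-out by default because rare species cannot spare records.

## Thresholding

`sd_threshold()` converts probabilities to ranges with the data-driven rule
θ = max(ε, mean(p_occ) − sd(p_occ)) over the species' own occurrence-point
probabilities (sample SD). The operative phrase "one standard deviation of
the occurrence probabilities" is ambiguous; mean − 1·SD is the default and
`centre_offset = NULL` gives the other reading (the SD itself as the cut).
The floor ε = 0.001 prevents clamped-zero probability rasters from becoming
all-landscape ranges. Presence is `p ≥ θ`, which guarantees every occurrence
point scoring at or above the threshold stays inside the range.
`max_sss_threshold()` (maximize sensitivity + specificity, lowest maximizer
on ties) is provided as the standard alternative.

## Reserve selection

Ranges are aggregated onto square planning units (PUs) of 6×6 fine cells
(3.6 km² — the desk-scale analogue of a 4 km² planning grid; 0.1 km² cells
cannot tile an exact 4 km² square, and the grid must tile evenly). Amounts
conserve range areas exactly. The optimizer minimizes the Marxan-form score

\[ \sum_{u \in R} c_u \;+\; \mathrm{BLM} \cdot \partial(R) \;+\;
   \sum_s \mathrm{SPF}_s \cdot
   \max\!\big(0,\, (t_s - h_s)/t_s\big) \]

where ∂(R) is the boundary length between selected and unselected PUs plus
outer-landscape exposure, `h_s` the amount held and `t_s = prop_s ×
range area`. The proportional shortfall makes SPF unit-free; this objective
form is an interpretation (reserve-selection papers rarely print their
objective) and is pinned down by tests against exhaustive enumeration.
Costs default to PU area — no land-price layer exists in scope.

Simulated annealing starts from the locked-in PUs plus a random fifth of the
available ones, flips one random available PU per iteration (Metropolis
acceptance), cools geometrically (×0.95 every `n_PU` iterations) from an
adaptive initial temperature probed from the score-change spread, and
finishes with greedy improvement sweeps. The default run length is
`min(10⁴·n_PU, 10⁶)` iterations — the classical default with a cap that
keeps 100-run suites on the 400-PU default world fast. Incremental score
bookkeeping is audited against full recomputation (≤ 1e−9 relative) and
best-of-100 runs attains the enumerated optimum on every random ≤ 12-PU
instance in the suite. Per-run seeds are integer hashes of
(master seed, run index), so results replay exactly.

Scenario presets mirror the study designs: `scenario_equal_area()`
(re-select the existing extent from scratch, nothing locked in),
`scenario_additional(lock_in = TRUE/FALSE)` (grow to double the existing
extent or 17% of the landscape, with or without the existing PAs locked in
at majority coverage of a PU — the 0.5 cutoff is configurable, and exactly
50% locks in). Because the optimizer targets range proportions, not extent,
final networks are capped by taking PUs in descending summed-solution
(irreplaceability) order — locked-in PUs first, ties by ascending PU id —
stopping at the prefix nearest the extent target without preferring to
exceed it (equidistant prefixes resolve to the smaller).

## Gap reporting

`representation()` reports per-species percent of range inside a network
and arithmetic group means for all/endangered/endemic/biological-resource
species. `stratified_comparison()` classes species into 10 equal-width bins
of range size or mean range elevation (boundary values drop to the lower
class; equal-width rather than quantile classes because fixed breaks are the
usual reading of such figures) and tests each class with a Wilcoxon rank-sum:
exact permutation enumeration for n ≤ 12 (valid under ties, where the
standard implementation refuses to be exact), otherwise the tie-corrected
normal approximation with continuity correction. Significance is reported
at 0.05 and 0.01. `perimeter_area_ratio()`, `network_overlap()` and
`elevation_summary()` complete the report.

## What passing tests do and do not show

The synthetic worlds reproduce the *structure* of the study — elevation-
biased PAs over-represent montane, small-range species; free selection
spreads representation evenly and sits at lower elevation — and the suite
asserts exactly those directions on the seeded default world. They do not
reproduce any published percentage: those depend on a specific national
survey, real climate surfaces and real PA polygons. Two known divergences:

* Virtual species have noise-free niches, so sparsely recorded species are
  *easier* to separate on fit data (their few records sit at their niche
  optimum); real surveys show the opposite because rare-species records
  carry identification and habitat noise the generator does not model.
* Fit-data AUC flatters all models relative to independent validation,
  synthetic or real.

Other numerical conventions, chosen once: PU-id ascending tie-breaks in
capping; rook adjacency (corner contact contributes no boundary);
outer-edge exposure counts toward boundary length by default (togglable);
group flags are drawn independently per species with default rates 10%
endangered / 15% endemic / 25% biological resource, giving a designated
minority like real national lists; degenerate inputs (flat terrain, empty
ranges, all-equal stratification values) take documented conventions rather
than errors wherever a convention is testable.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes,
at run time, the published study-geometry identities (PA percentage, extent
targets, mean records per species, survey coverage, modelling-group sizes)
and the full synthetic assessment at the default problem sizes (120×120
cells, 60 species, 400 PUs, 100 annealing runs per scenario), writing every
quantity as JSON. The testthat suite runs the same checks plus the
per-module oracles.
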