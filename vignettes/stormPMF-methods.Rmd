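---
title: "Source apportionment and acute-exposure assessment for high-frequency pesticide monitoring"
author: "stormPMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source apportionment and acute-exposure assessment for high-frequency pesticide monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and data model

stormPMF analyses continuous multi-compound concentration records from small
streams sampled on a regular high-frequency grid (20 minutes by default),
together with 10-minute rainfall and 15-minute water level. Three
conventions run through the whole package:

* **Half-open intervals.** Every timestamped value refers to
  `[t, t + spacing)`, and composite windows are half-open too, so windows
  tile the record without overlap or double counting.
* **Explicit gaps.** Maintenance and QC interruptions are kept as flagged
  gap rows rather than dropped, so gap accounting in the composite
  emulation (windows are invalidated above a 10% gap fraction by default)
  stays checkable.
* **Raw values below the LOQ are kept.** Censoring is a *flag*, not a
  substitution. The LOQ/2 rule applies only when building the factorization
  input; the set-to-LOQ rule only inside composite emulation. Keeping the
  raw value lets the uncertainty branches and the signal-to-noise metric
  operate on what was measured.

Rainfall is aligned across grids by mass-conserving rebinning (each source
interval's depth is integrated over the target bins, so totals agree to
rounding error for *any* pair of spacings); water level is linearly
interpolated.

## Event classification

Events are maximal wet spells separated by at least `event_gap` (default
2 h) without rain. The only classification input is rain intensity: an event
is **large** when its maximum intensity exceeds `intensity_threshold`
(default 1 mm/10 min), otherwise **small**. Water level deliberately plays
no role in event classification — using it as a second criterion would make
the classes circular with the hydrological interpretation they are meant to
support; the observation that only large events push the stream above a
given stage is then a diagnostic, not a definition. Analysis windows of 3 h
(small) and 14 h (large) are attached to each event start as metadata; they
do not affect the event boundaries. Events truncated by the record edges
are kept and flagged `partial`.

**Dry days** have zero daily rain and a within-day water-level standard
deviation at or below `dry_level_sd_threshold`. No universally valid value
for that threshold exists (it depends on gauge noise and baseflow
stability), so it is an explicit parameter; the default of 0.5 cm
distinguishes quiescent days from recession tails in the synthetic
catchment and is meant to be tuned to the gauge at hand.

## Screening and the uncertainty model

Per compound `j` with LOQ `L_j` and relative measurement error `a_j` (a
dimensionless fraction in [0, 1], supplied as metadata):

* uncertainty: `u_ij = sqrt((a_j x_ij)^2 + L_j^2)` for `x_ij > L_j`, and
  `u_ij = (5/6) L_j` for `x_ij <= L_j` (the boundary uses the censored
  branch);
* distance metric: `d_ij = 0` when censored, `(x_ij - u_ij)/u_ij` above the
  LOQ — negative values, where the measurement is smaller than its own
  uncertainty, count as computed;
* signal-to-noise `S/N_j` is the mean of `d_ij` over non-gap samples, and
  species are classed **bad** (`S/N <= 0.2`), **weak** (`0.2 < S/N <= 1`) or
  **good** (`S/N > 1`). Bad species are excluded from the factorization;
  weak species keep their data but have `u` tripled.

`S/N` is scale-equivariant (rescaling `x` and `L` jointly leaves it
unchanged) and non-increasing in the LOQ; both properties are enforced as
tests.

## The factorization

The model is `X = G F + E` with nonnegative contributions `G` (n x p, scale
fixed so every column has mean 1) and profiles `F` (p x m, ng/l per unit
contribution), minimizing the uncertainty-weighted least squares objective
`Q = sum((X - GF)^2 / U^2)`.

**Solver.** Weighted nonnegative *hierarchical* alternating least squares:
for one factor at a time, the contribution column and then the profile row
are replaced by their exact nonnegative blockwise minimizers (with per-cell
weights the problem is separable across samples for a fixed factor, so the
minimizer is a ratio of two weighted inner products clipped at zero). The
objective therefore descends monotonically for fixed weights — a property
the test suite asserts on the recorded iteration history. We chose HALS
over projected alternating least squares because the exact blockwise
minimizer preserves the descent guarantee that projection destroys, and
over classical multiplicative updates because its convergence on
exact-low-rank inputs is orders of magnitude faster; all three minimize the
same objective. Convergence is declared after 10 consecutive sweeps with a
relative objective change below 1e-8 (cap 5000 sweeps), or immediately when
`Q` falls below 1e-12 of the zero-model objective (exact factorizations).

**Robust mode.** After a burn-in, every tenth sweep rescales the effective
uncertainty of outlying cells: where `|e_ij|/u_ij > 4`, `u` is inflated to
`|e_ij|/4`, capping any cell's influence at the cutoff. The reported
`Q_robust` excludes those cells entirely while `Q_true` keeps them; the
exclusion set is computed against the *base* uncertainties. Whether the
reference implementation of this method class applies the exclusion during
optimization or only in reporting is not documented publicly; doing both —
capped influence while fitting, exclusion in reporting — reconciles the two
readings and is our own choice.

**Multi-start and factor count.** Local minima are real (the test suite
constructs instances where single starts plateau), so fits are repeated
from `n_runs = 20` seeded starts and the lowest-`Q_robust` model kept; the
relative spread of run objectives is the stability diagnostic. The factor
count is the analyst's choice, guided by the scan of `Q_robust/Q_exp`
with `Q_exp = n m_good - p (n + m_good)` (`m_good` counts good-class
species only). `detectElbow()` encodes the reading "decreased substantially,
then only slightly": it returns the largest p whose ratio still drops by
more than 5% relative — beyond the true complexity the ratio flattens to
within a percent or two, well clear of that margin. When uncertainties are
correctly specified and p matches the truth, `Q_robust/Q_exp` sits near 1
(about 1.03 on the default synthetic scenario).

**Identifiability caveats.** Scale and order ambiguities are fixed
deterministically (column means of `G`, factors ordered by fitted mass),
but rotational ambiguity is intrinsic: in particular, *constant* baseline
mass can be shuffled freely between factors whose contributions all contain
a constant component. Recovery tests are therefore only meaningful when the
planted factors are identifiable (see the generator below). Degenerate
solutions (a factor with near-zero fitted mass) trigger one re-seeded
refit and are reported, never silently accepted.

**Bootstrap.** Moving-block resampling of samples (default 50 rows per
block, about 17 h, longer than the autocorrelation of single storm
responses), refit per replicate, factors mapped to the base solution by
best profile cosine (threshold 0.6); the per-factor mapping rate and
profile quantiles are reported, and unmapped factors are counted.

## Composite emulation and exposure

`compositeAverage()` averages non-gap samples over half-open windows of
3.5 days (growing season) or 14 days, after setting censored samples to the
LOQ (the convention of the composite monitoring programme being emulated;
LOQ/2 and zero rules are available). The **underestimation factor** is the
window's maximum 20-minute concentration over its composite mean; when the
composite is censored the LOQ enters the denominator and the factor is
flagged as a lower bound, and a composite of exactly zero (possible under
the zero rule) is undefined, never divided through. Because the clock
alignment of a composite sampler is rarely known, `startOffsetSweep()`
recomputes the factors over a grid of window offsets and reports the
worst case — for a single spike of height `h` on baseline `b` this
approaches `h W / (h + b (W - 1))` for a window of `W` samples, a closed
form the tests check exactly.

Exceedances are assessed at both resolutions. What counts as "one
exceedance" is ambiguous in monitoring practice (per sample? per episode?
per compound?), so the report carries all three: sample counts, episode counts (maximal runs of
consecutive exceeding samples; a gap interrupts a run), and distinct
compounds. Only compounds with the relevant standard are tallied; the rest
are listed. Chronic assessment is the same machinery with a 14-day window
and a chronic standards table.

## The synthetic catchment

The generator exists so that every stage has a ground truth. Its defaults
describe a 41-day growing-season campaign in a small, flashy agricultural
catchment, matching the dimensions the analysis is designed for:

* **Rainfall** (10-min): storms arrive at ~0.6/day with a 2 h minimum
  separation; about a third are "large", drawing lognormal total depths
  (median 12 mm) spread over 1-8 h with gamma weights, the rest are small
  (median 0.5 mm, capped below 1 mm/10 min). Across seeds this yields on
  average ~8 large and ~14 small events, ~120 mm total rain and campaign
  maximum intensities around 7-15 mm/10 min.
* **Water level** (cm): a discrete linear reservoir (half-life
  `k ln 2`, default k = 6 h, gain 1.5 cm/mm over 10 cm baseflow), so large
  events — and only they — push the stream well above ~20 cm.
* **Concentrations**: 6 factors x 17 species. Factor 1 is a legacy source
  whose contribution scales inversely with water level (pure dilution: its
  concentration minimum coincides with the level maximum). Factors 2-6 are
  event-driven: rainfall, gated per event by Bernoulli-lognormal activation
  (different storms mobilize different sources), convolved with a delayed
  gamma kernel (lags 0.5-6 h, supporting the delayed peaks seen in flashy
  catchments). Profile loads are expressed in multiples of each species'
  LOQ (primary 40x, secondary 15x, tertiary 6x, small cross-loads), so
  signal strength is comparable across the 2-100 ng/l LOQ range; the
  default screen then keeps all 17 species with 14 classed good — the
  class structure the method expects to operate on.
* **Baselines**: between events, each event factor's quiescent level drifts
  slowly (sinusoids with 14-30 day periods and distinct phases, emulating
  application-season dynamics). This is a deliberate identifiability
  device: perfectly constant baselines are rotationally non-identifiable
  (constant mass moves freely between factors), and no quantitative
  description of between-event behaviour is available to emulate, so the
  baseline model is a free design choice of the generator.
* **Noise and censoring**: observations are the clean mixture plus
  zero-truncated Gaussian noise with
  `sd = sqrt((a_j x)^2 + kappa L_j^2)` (`kappa = 1` by default, making the
  screening uncertainty model exactly correct, which is what the
  `Q_robust/Q_exp ~ 1` diagnostic presumes); values below the LOQ are
  flagged, not overwritten. Ten percent of samples sit in contiguous
  maintenance gaps.

What passing recovery tests on this generator shows — and what it does not:
they show that the estimator chain (screening, weighting, robust multi-start
HALS, elbow scan) recovers *identifiable* planted structure through
realistic censoring, gaps and noise at the study's dimensions (matched
profile cosines and contribution correlations above 0.9, elbow at p = 6 in
at least 80% of seeded replicates). They do not certify behaviour on real
records, whose factors need not be identifiable, whose uncertainties are
never exactly correct, and whose baseline structure may be far less
benign.

## Numerical choices and problem sizes

Tolerances and cut-points that are part of the method (1 mm/10 min, 2 h,
0.2/1 S/N cut-points, LOQ/2, 5/6 LOQ, the robust cutoff 4, the 25%
fingerprint filter, 20 runs) are defaults mirroring standard practice for
this analysis and are all configurable. Recovery and elbow experiments in
the tests and the acceptance script run the full 41-day scenario
(n ≈ 2950 x 17); the factor-number scan is evaluated over p = 4-8 with
single-start fits capped at 400 sweeps, and the multi-start-versus-brute-force
comparison uses 30 x 5 instances — sizes at which the experiments complete
comfortably on a single core while exercising the full-dimension problem
where it matters. Test fixtures elsewhere use smaller grids.

## Known limitations

* No rotational (Fpeak-style) exploration, no constrained profiles, no
  displacement error estimation — base runs plus bootstrap only.
* `a_j` is an input, constant per compound; no error-estimation recipe is
  included.
* The generator is statistical, not hydrological: no infiltration or
  drainage-network physics, and its dry-weather behaviour is a stylized
  free choice.
* Exceedance tallies implement one defensible operationalization
  (samples/episodes/compounds); other definitions in circulation may count
  differently.
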