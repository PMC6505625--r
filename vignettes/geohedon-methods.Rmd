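---
title: "Mobility and expressed happiness: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobility and expressed happiness: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geohedon)
```

`geohedon` analyzes streams of GPS-geolocated short messages: it
summarizes each individual's movement (expected location, radius of
gyration, visit locales), normalizes trajectory shapes into a common
home–work frame, and measures expressed happiness of pooled message text
with a lexicon-based hedonometer, including exact word-shift
attributions of happiness differences. This vignette explains the models
behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-population generator does and does not
emulate, and the numerical decisions a maintainer would want written
down.

## Geometry

All planar computation uses a per-user azimuthal-equidistant projection
on a sphere of radius 6,371,000 m, centered on the coordinate-wise
midrange of the user's positions (or their expected location, where that
is the natural origin). The projection's defining property — planar
distance from the origin equals great-circle distance — makes the two
radial quantities the pipeline cares about (distance from expected
location, and hence gyradius) exact; chord distortions between
off-center point pairs are second-order at commute scale. Ellipsoidal
geodesy would change distances by ~0.3%, far below the ~10 m GPS noise
floor of the data model, so a spherical Earth is used throughout.
Points antipodal to the projection origin are outside the projection's
extent and are a hard error.

## Mobility summaries

The **expected location** is the planar mean of a user's positions
mapped back to latitude/longitude; the **gyradius** is the RMS
great-circle distance of the positions from it. Gyradius is 0 iff all
positions coincide, is invariant to rigid motions of the trajectory, and
scales linearly with uniform spatial scaling — all asserted as tests.

**Spatial autocorrelation.** Moran's I and Geary's C are computed with
the classical double-sum formulas over row-standardized k-nearest-
neighbour weights (k = 8 by default; k is a parameter). The weight
scheme is a package choice — nothing in the data model fixes one — and
k-NN keeps the statistics defined for irregular point sets such as
per-user mode locations. Null expectations (−1/(n−1) and 1) are verified
by permutation in the test suite, and the implementation is
cross-checked against an independent one (`ape::Moran.I`).

## Trajectory normalization

Treating each position as a unit mass, the inertia tensor of the
mean-centered planar trajectory is diagonalized. The normalization then

1. translates the trajectory to its center of mass;
2. rotates it so the principal axis (leading eigenvector) is east–west;
3. resolves the 180° ambiguity — a principal *axis* fixes a line, not a
   direction — by placing the user's mode location (rank-1 locale
   center; fallback: the median along-axis coordinate when the user has
   no locale) on the east side, `x ≥ 0`. This reproduces deterministically
   the home-east / work-west layout in which pooled densities show the
   home locale about one standard deviation east of the origin;
4. divides each axis by its post-rotation standard deviation, computed
   with the n-denominator (population convention, matching the
   equal-mass tensor).

Numerical decisions: when the two eigenvalues tie to within a relative
1e−8, every direction is principal, so the east–west axis itself is kept
(this also makes normalizing an already-normalized trajectory the
identity, which is asserted as an invariant). Collinear trajectories are
detected as `sigma_y <= 1e-9 * sigma_x` — rotation round-off leaves the
minor spread at ~1e−14 rather than exactly zero — and excluded with a
logged reason, since their frame is undefined.

Pooled outputs: the **density map** (default grid x ∈ [−6, 6],
y ∈ [−4, 4] in normalized units, 0.1-unit cells; out-of-extent points
dropped and counted; cell masses sum to exactly 1 over the retained
points), the **corridor profile** (histogram of `x/σx` restricted to
`|y/σy| ≤ 1`; the half-width is a parameter whose default of one
standard deviation is a package choice — no canonical value exists), and
the **isotropy ratio** `sqrt(λ_minor/λ_major)`, equal to the
minor-to-major spread ratio, averaged within equal-count gyradius
groups. The ratio's algebraic definition is also a recorded package
choice; it is 1 for circular movement and 0 for collinear movement,
which pins it up to monotone transformation.

## Locales

A locale is defined by three properties: ≥ 10 member messages, every
member within 100 m of the center, the center the mean member position,
and no two locales of one user intersecting. The definition does not fix
a construction, so the package uses a deterministic three-phase
procedure chosen for determinism and O(n·k) cost:

1. **leader pass** in chronological order — each message joins the
   nearest candidate whose running-mean center is within 100 m, else
   opens a candidate;
2. **refinement** — reassign all messages to their nearest candidate
   center (if within 100 m) and recompute centers as member means, until
   stable (at most 20 iterations);
3. **greedy acceptance** in descending count (ties: earliest first
   message) — a candidate sets its radius to its maximum member distance
   and is accepted iff it has ≥ 10 members and intersects no accepted
   circle. Members of rejected candidates are locale-less. Keeping the
   higher-count locale on overlap preserves the head of the rank
   distribution that the rank analyses use.

If refinement hits the iteration cap mid-oscillation, a member can sit
marginally beyond 100 m of the recomputed mean; the farthest members are
then trimmed (recomputing the center) until the membership rule holds,
so the definitional invariants — radius ≤ 100 m, count ≥ 10, disjoint
circles, center = member mean — hold unconditionally and are asserted
post-hoc on every extraction.

Visitation probabilities are `count_i / N` with `N` the user's *total*
message count, so they need not sum to 1. Rank ties break by earliest
first visit (determinism without randomness). The pooled Zipf fit is
ordinary least squares of `log10 p` on `log10 rank` over all pooled
points with no rank truncation. Note one structural property of this
estimand: when users differ in locale count, per-user normalization
gives users with more locales lower intercepts and longer rank ranges,
so the pooled OLS slope sits slightly steeper than the per-user
generating exponent (about −1.34 pooled for a per-user exponent of
−1.3 under the default population). The recovery tolerance (±0.1)
covers this; the unit test that checks pure noise recovery holds the
locale count fixed so its noise-free slope is exactly the exponent.

**Diurnal profiles** distribute messages over the 168 local week-hours
(Monday 00:00 → Sunday 23:00; local time = UTC + stored offset) for
mode-locale messages and all other messages separately, each curve
summing to 1. Records lacking an offset are excluded from diurnal
analysis only.

## Filtering

Robotic accounts are users for whom at least half (inclusive ≥ 0.5) of
messages contain one of `pressure, humid, humidity, earthquake, traffic,
coupon` as a lowercased *token* — substring matching would make
`humidity` redundant with `humid`, contradicting the two being separate
list entries. Foursquare check-ins are detected by the stable share-URL
marker `4sq.com` (case-insensitive) rather than the variable "I'm at…"
phrasing. Check-ins stay in the mobility corpus and are excluded only
from sentiment analyses; the activity threshold (≥ 30 messages; ≥ 800
for heavy-user analyses; strictly > 50 for the pooled density map) is
inclusive except where "more than" dictates otherwise. Filtering is
idempotent, and the sentiment corpus is a subset of the mobility corpus
by construction.

## Hedonometer and word shifts

Scores are frequency-weighted means of per-word happiness over lexicon
words outside the *open* neutral band `(5 − Δh, 5 + Δh)`; Δh = 1 by
default, so scores of exactly 4.0 or 6.0 are retained. A bag with no
scorable word yields an explicit no-score (`NA`), never a silent 0.
Tokenization (a package convention; no canonical tokenizer exists for
this kind of text) lowercases, extracts lexicon tokens containing
punctuation (emoticons like `:(`) by longest match first, then splits on
whitespace and strips edge punctuation while keeping internal
apostrophes. Binned trends pool words per bin — averaging per-tweet
scores is deliberately not offered, since individual tweets are too
short for stable scores — and bins are equal-count splits (sizes
differing by at most one, ties kept stable). The bin representative for
log-linear trend fits is the median binned value, robust to the heavy
right tail; whether a mean, median, or midpoint is "the" bin coordinate
is unknowable from the data model, and the choice is recorded here.

Word shifts normalize frequencies over *scorable* words only. That
convention is forced: it is the one under which the per-word
contributions `(h(w) − h_ref)(p_comp − p_ref)` sum *exactly* (to 1e−12
in tests, over arbitrary random count pairs) to `h_comp − h_ref`
computed with the same neutral-band filter, so printed percentages sum
to 100. Classification: `+` means strictly happier than the reference
text's mean (a word exactly at the mean contributes zero and is grouped
with `-`); arrows by whether the comparison text uses the word more.
Ranking is by absolute percent contribution with alphabetical
tie-breaks.

## The synthetic population

The generator emits corpora with the statistical structure the analysis
assumes, with ground truth exposed, so pipeline stages are tested by
parameter recovery. Per individual: 3–15 locale centers (home, work at a
lognormal separation of median 3 km, minor locales scattered at the
separation scale, all ≥ 250 m apart), visited with exactly Zipf
probabilities of exponent 1.3 — per-individual exactness is a
simplification; only population-level approximate Zipf is the claim
being emulated. 80% of ordinary messages come from locales, the rest
scatter uniformly within 3 commute-scale gyradii. GPS noise is isotropic
σ = 5 m, reading the "10 m circle" accuracy of phone GPS as a ~2σ
containment radius. Message counts are lognormal (median 60; the
heavy-user regime uses median 900 across 300 individuals). Local time
offsets come from the four continental-US zones; mode-locale messages
draw local hours weighted toward 8–10 am and 10 pm–midnight with the
morning peak higher and the afternoon valley lower than the overnight
one, other messages from a flatter midday-weighted curve. Bots (2% of
users, stationary, every message carrying a trigger keyword) and
check-ins (5% of messages, tagged with the `4sq.com` marker) provide
filter-recovery targets.

**Excursions.** Each message starts a long-range excursion episode with
probability 0.01; an episode spans a geometric number of consecutive
messages (mean 20 — a vacation of a week or two at typical posting
rates) posted near a destination drawn lognormally with median 500 km
(log-sd 2.0, capped below the antipode). Episodes, rather than
independent single-message trips, are what real travel looks like, and
they give the message-distance distribution the heavy upper tail that
real corpora show: under the defaults the farthest of ten equal-count
distance deciles has a geometric-mean distance near 2,500 km, the
distance scale at which far-from-home happiness is quoted.

**Happiness model.** Expected filtered word happiness at distance `d`
from the user's (realized) expected location is

    mu(d) = h_dip + beta  * log10(d / d_dip)          for d > d_dip
    mu(d) = h_dip + alpha * log10(d_dip / max(d, 30)) for d <= d_dip

a shallow local maximum near home, a minimum at commute scale
(`d_dip` = 10 km, itself a recorded choice — only "a short daily
commute" scale is pinned), and a logarithmic rise beyond. The defaults
are calibrated once, by measurement on the default population, to the
two printed anchor values: `beta = 0.1` and
`h_dip = 6.13 − 0.1·log10(2.5e6/1e4) ≈ 5.890` pin `mu(2500 km) = 6.13`
exactly, and `alpha = 0.0495` makes the nearest-decile distance
(geometric mean ≈ 385 m under the defaults) score 5.96. Message texts
are then sampled, conditional on each message's realized distance, as a
mixture of a positive-enriched and a negative-enriched word pool (drawn
from the packaged example lexicon, plus ~30% neutral filler words that
the band filter removes) with the mixture weight solving the pooled
expectation `mu(d)`. Conditioning on the *realized* distance from the
*realized* centroid — computed after the geometry is generated — is what
lets the analysis pipeline, which can only ever see realized positions,
recover `mu` without attenuation.

**What the generator does not emulate:** road networks and gravity-model
mobility, demographic structure, text with real linguistic structure
(word frequencies are conditionally independent given distance), bursty
posting dynamics, location-dependent GPS error, or spatially clustered
populations of users. Passing recovery tests therefore demonstrates the
*estimators* are correct and calibrated, not that real corpora satisfy
the generator's assumptions.

All randomness flows through a single mandatory seed (the caller's RNG
state is restored afterwards); identical (config, seed) pairs give
byte-identical corpora.

## Problem sizes and runtime

The shipped tests and the acceptance script use populations sized so the
statistics they check are well-resolved while a full run stays
comfortably on a laptop: the standard population is 3,000 individuals
(~200k messages, giving ≥ 10⁵ scorable words in each of ten distance
bins, so bin scores carry sampling errors well below the ±0.02
tolerances checked), the heavy-user population is 300 individuals at
~900 messages, and normalization contracts are checked on 500
individuals. The full test suite runs in about two and a half minutes;
the acceptance script in under half a minute.

## Known limitations

- The locale construction is one deterministic realization of an
  underdetermined definition; other constructions satisfying the same
  invariants can produce different (equally valid) locale sets,
  particularly for diffuse clusters near the 100 m scale.
- Pooled Zipf slopes are estimands of the pooled point cloud, not of any
  single user's exponent (see above).
- The hedonometer is a bag-of-words instrument: negation, sarcasm and
  context are invisible by design, which is why scores are only ever
  attached to large pooled texts.
- Moran's I / Geary's C significance is not computed analytically;
  permutation is the intended route and only the statistics themselves
  are provided.
- The corpus container is an in-memory tibble; corpora far beyond ~10⁷
  messages would need chunked IO that the package does not provide.
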