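# geohedon

Mobility and expressed happiness in geolocated message streams.

`geohedon` characterizes the "pattern of life" of individuals from
GPS-geolocated short messages (one record per message: opaque user id,
timestamp with local offset, latitude/longitude, text) and couples that
mobility structure to lexicon-based sentiment measurement. It is aimed at
computational social scientists and digital epidemiologists who want the
full chain — quality-control filtering, per-user mobility summaries,
trajectory-shape normalization, visit-locale extraction, hedonometric
scoring, word-shift decomposition — as tested, composable R functions,
together with a seeded synthetic-population generator so every stage can
be validated by parameter recovery without access to any proprietary
corpus.

## The instruments

**Radius of gyration.** For an individual `a` with message positions
`r_i` (i = 1..N) and expected location `r̄` (the trajectory's center of
mass), the gyradius is the RMS displacement

    r_g = sqrt( (1/N) Σ_i |r_i − r̄|² )

— the RMSE of predicting the individual's position by their average
location. All planar math happens in meters via a per-user
azimuthal-equidistant projection (sphere of radius 6371 km), which keeps
distances from the projection center exactly great-circle.

**Trajectory normalization.** Treating each position as a unit mass, the
trajectory's 2×2 inertia tensor is diagonalized; the leading eigenvector
is the principal axis (typically the home–work corridor). Each
trajectory is translated to its center of mass, rotated so the principal
axis is east–west with the mode location (rank-1 locale) on the east
side, and each axis divided by its standard deviation. In this common
frame trajectory shapes pool across users into density maps, corridor
profiles and isotropy ratios (`sqrt(λ_minor/λ_major)`).

**Locales.** A locale is a circle of radius ≤ 100 m containing ≥ 10 of
one user's messages, centered on the mean member position, with no two
locales of a user overlapping. Locale visitation probabilities
`p_i = count_i / N` fall off with rank approximately as a Zipf law,
`p(rank) ∝ rank^(−s)` with `s ≈ 1.3`; the rank-1 locale is the user's
*mode location*.

**Hedonometer.** A text `T` scores

    h_avg(T) = Σ_i h(w_i) f_i / Σ_i f_i

over words with a lexicon happiness score `h` on the 1–9 scale, skipping
the neutral band `4 < h < 6` (tunable half-width Δh, default 1). Words
are pooled per bin — never per tweet. A word-shift decomposes the
difference between two texts exactly into per-word contributions
`(h(w) − h_ref)(p_comp(w) − p_ref(w))`, classified by whether the word is
relatively happy/sad and used more/less.

Spatial autocorrelation of per-user summaries is available through
classical Moran's I and Geary's C with row-standardized k-nearest-
neighbour weights.

## Worked example

```r
library(geohedon)

cfg <- population_config(n_individuals = 200)
gen <- generate_population(cfg, seed = 2011)
flt <- filter_corpus(tag_checkins(gen$corpus), min_messages = 30)
flt
#> <gh_filter_report> 4 bots removed, 17 users below threshold,
#>   700 check-ins tagged, 13634 messages surviving

mt  <- mobility_table(flt$corpus)
lex <- read_lexicon(example_lexicon_path())
m   <- flt$corpus[sentiment_eligible(flt$corpus, flt$bot_user_ids), ]
d   <- mt$messages$distance_m[match(m$message_id, mt$messages$message_id)]
happiness_by_distance(m$text, d, lex, k = 5)[, c("bin", "d_median", "n_words", "h_avg")]
#>   bin d_median n_words h_avg
#> 1   1     1048   14444 5.948
#> 2   2     4108   14726 5.887
#> 3   3    17189   14371 5.930
#> 4   4   130162   14443 6.004
#> 5   5   949968   14564 6.130
```

Messages are binned by distance from their author's expected location
into five equal-count groups; each bin's words are pooled and scored
once. The dip at commute scale (~4 km here) followed by the logarithmic
rise toward the farthest bin is the structural signature the package
measures. A word shift between the nearest and farthest bins attributes
the difference:

```r
bins <- equal_count_bins(d, 5)
ws <- word_shift(word_counts(m$text[bins == 1], lex),
                 word_counts(m$text[bins == 5], lex), lex)
ws
#> <gh_wordshift> h_ref = 5.9475, h_comp = 6.1302, delta_h = +0.1827, 12 words
rank_contributions(ws, top_n = 4)
#>   rank word  type percent cumulative_percent
#> 1    1 jail -down    15.1               15.1
#> 2    2  war -down    14.2               29.2
#> 3    3 down -down    11.9               41.1
#> 4    4   :( -down    10.8               51.9
```

The largest contributions to the far-from-home happiness excess come
from negative words used *less* far away (`-down`), mirroring the
behavior of real populations.

The staged pipeline (`run_stage()` / `run_report()`) writes each stage's
tables plus a JSON manifest to a directory for inspectable, diffable
runs; see `vignettes/geohedon-methods.Rmd` for the science and the
design decisions.

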