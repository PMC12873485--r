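---
title: "Nutrient profiling of marketed foods: model, pipeline and synthetic corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient profiling of marketed foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npiscore)
```

## The scoring model

`npiscore` implements the UK 2004/05 Nutrient Profile Model (NPM), the
instrument used to regulate food advertising to children in the UK and
widely reused in food-marketing content analyses. Per 100 g of food, four
penalty components — energy (kJ), saturated fat (g), total sugar (g) and
sodium (mg) — each earn 0–10 "A" points from a threshold table, and three
credit components — fruit/vegetable/nut fraction (%), fibre (g) and
protein (g) — each earn 0–5 "C" points. Every table is read with a
*strict* inequality: an amount exactly on a threshold does not earn the
point. This convention is load-bearing at label-round values (energy of
exactly 335 kJ scores 0, not 1), which is why the tables are stored as
literal constants rather than computed multiples — `0.7 * 3` is
2.0999… in binary floating point and would silently flip the 2.1 g
fibre boundary.

The total is

NPM = A − c~fvn~ − c~fibre~ − c~protein~,

with one interaction, the **protein cap**: when A ≥ 11 and the food does
not earn the maximum 5 fruit/veg/nut points, protein points are withheld.
The cap prevents protein-fortified but otherwise poor foods from scoring
well. Totals span [−15, 40]. The Nutrient Profile Index is the linear
rescaling NPI = −2·NPM + 70, reported on a nominal 1–100 scale with
higher = healthier; a food is classified *healthy* iff NPI ≥ 64,
algebraically identical to NPM ≤ 3.

The fruit/veg/nut table awards only 1, 2 or 5 points (>40 %, >60 %,
>80 %); 3 and 4 are unattainable by design, and the tests assert this.

### Numerical and interface choices

* **Clamping.** The index is reported clamped to [1, 100] to honour the
  nominal scale, but the unclamped value `npi_raw` is retained and is
  what the healthy test and the unhealthy-proportion denominator use.
  Whether values below 1 should be clamped at all is not decidable from
  the scale's description alone; keeping both values makes either
  reading available.
* **Fibre basis.** The NPM's fibre thresholds were defined for NSP
  (Englyst) fibre; US nutrition labels report AOAC-style dietary fibre,
  for which adjusted thresholds (0.9, 1.9, 2.8, 3.7, 4.7 g) are the
  accepted equivalent. AOAC is the default, switchable per profile or
  per file via `fibre_basis`.
* **Units.** Energy is accepted in kJ or kcal (4.184 kJ/kcal); sodium
  directly in mg or via salt at 400 mg sodium per g salt. Per-serving
  rows are rescaled by `100 / serving_weight_g`; a per-serving row with
  no serving weight is unscorable, never silently guessed.
* **Missing components.** Missing A-nutrients make a food unscorable
  (it exits the pipeline with an explicit omission reason); missing
  C-components score 0 with a warning, since credits can only lower the
  total — a conservative default that biases toward *unhealthy*, never
  toward a spurious pass.
* **The ingredient rule.** When the fruit/veg/nut fraction is unknown,
  a fruit, vegetable or nut among the first five ingredients sets it to
  exactly 50 % — the stated lower bound of the underlying assumption,
  worth 1 C-point. Firing to 50 rather than anything larger is the
  conservative choice; an explicitly supplied fraction is never
  overwritten. The lexicon ships as editable YAML.

## The product pipeline

Featured products carry a type (food / beverage / supplement), a brand
flag, and a category from a configurable taxonomy. Categorisation is a
total, deterministic function: restaurant-flagged foods always map to
the restaurant category before any keyword rule; ordered keyword rules
(shipped as YAML) handle the rest; unmatched items land in the
type-appropriate "other" bucket with a warning, never a failure.
Beverages are never scored — the NPM is not considered reliable for
them — and supplements are likewise reported by category only.

Each food's nutrition data is resolved along a fixed hierarchy that
mirrors how such studies assemble their data: restaurant foods first
against a table of pre-extracted index values (as published fast-food
report data), falling back to averaging the brand's top five menu items;
branded/packaged foods against a branded-label table; remaining foods
against a generic reference table (typical recipes); anything found
nowhere is omitted from the index analysis with the reason recorded.
The top-five average is taken on the NPI scale, matching how
pre-extracted index values and freshly scored items can be combined at
all; note that averaging on the NPM scale first and converting would
give the same mean (the map is linear), but the healthy verdict from a
mean can differ from the majority verdict of per-item classifications —
the aggregate's verdict is taken from the mean, and the choice is
configurable only in the sense that callers may score items themselves.
The five items are taken as given rows rather than re-derived from
popularity data, which is an upstream data-collection concern.

Every food exits the pipeline either scored or with an explicit
`omission_reason`, and the summary layer asserts
`scored + omitted = foods`. One product per video is enforced at
validation; a duplicated `video_id` is an error, not a deduplication.

## Descriptive summaries

`summarize_study()` reproduces the descriptive layer typical of these
analyses: prevalence of product-featuring videos, the type split, the
branded share, per-category frequency tables overall and by brand
status, brand-stratified NPI means and sample (n−1) standard deviations,
and the unhealthy proportion over scored foods only. Percentages are
rounded half-up to 1 decimal (so 1360/8871 prints as 15.3), means and
SDs to 2. Every percentage is computed from the module's own
denominator — published tables in this literature occasionally carry
percentages inconsistent with their stated denominators, and recomputing
is the only reproducible convention. Category rows sort by descending
count with alphabetical tie-breaks, so output is invariant to input
order.

## The synthetic corpus generator

No public corpus of influencer videos exists, so the generator emulates
the statistical structure such a corpus: per video a product-featuring
indicator (default probability 1360/8871 ≈ 0.153), per product a type
(food/beverage/supplement at 755/580/25 of 1360), a brand flag (0.476),
and a category drawn from per-stratum mixes. The category mixes were
backed out of published stratum percentages where available (e.g.
branded beverages: 38.9 % energy drinks, 21.3 % alcoholic) and filled
with realistic shares where only top categories are published; stratum
sizes behind those percentages (≈244 branded and ≈526 unbranded foods,
380/200 beverages) were recovered by dividing printed counts by printed
percentages.

Food healthfulness is drawn **on the NPM scale** — a discretized normal
truncated to [−15, 40] per brand stratum — and inverted to a full
nutrient profile by `npm_to_profile()`, a constructive inverse of
`compute_npm()`: non-negative targets are met through A-points alone,
negative targets through credits with all penalties zero (so the protein
cap can never bite), and amounts are placed strictly inside the required
bins, midpoints by default or jittered within the bin for generated
corpora. Drawing on the NPM scale makes the stratum NPI moments directly
controllable: with targets (49.58, 17.80) branded and (57.61, 20.52)
unbranded, the defaults are mean = (70 − NPI)/2 and sd = NPI-sd/2 on
the NPM scale. Discretization adds variance 1/12 on the NPM scale
(≈0.03 index points of SD) and truncation is ~3 SD out on either side,
so realized stratum means land within one index point of target at ten
thousand scored foods, which the acceptance suite verifies on a
50 000-video corpus.

Omission ("no nutrition information") probabilities are stratified by
brand: with an expected 755 foods of which 47.6 % are branded, rates of
81/(755·0.524) ≈ 0.205 (unbranded) and 5/(755·0.476) ≈ 0.014 (branded)
give an expected overall omission share of 11.4 % with the 81:5 split.

What the generator deliberately does **not** model: video engagement,
influencer identity, posting time, ingredient lists (fruit/veg/nut
fractions are emitted directly), per-serving label bases (all rows are
emitted per 100 g; the normalisation path has its own unit tests), or
any correlation between category and healthfulness within a stratum.
Passing the end-to-end tests therefore shows that the pipeline
faithfully recovers the moments and proportions it is fed — not that
real label data are free of the entry errors, unit mixups and recipe
assumptions that dominate error in real studies.

## Problem sizes and determinism

The test suite runs the boundary-grid oracle comparison at 10 000
profiles, parameter recovery end-to-end at 50 000 videos (≈7 600
products), and byte-level determinism at 2 000 videos — sizes chosen so
the statistical checks have power (3-standard-error bands; a 1-point
band on stratum NPI means at ≈2 000 branded scored foods) while the full
suite stays fast. A single seed in `generator_config()` governs every
draw; repeated runs are byte-identical through simulate → score →
summarise, and all tables sort deterministically.

## Known limitations

* The keyword categoriser is a deterministic stand-in for human coding;
  real studies double-code with reliability statistics, which is out of
  scope here.
* The NPM tables are the 2004/05 model; later consultation drafts with
  different thresholds are not implemented (the YAML config accepts
  alternative tables of the same shape).
* Restaurant top-five aggregation classifies from the mean index; with
  a nonlinear cut-off, per-item verdicts can disagree with the
  aggregate's verdict in either direction.
* Synthetic profiles are NPM-consistent but not nutritionally realistic
  (a food may carry all its penalty points in sugar alone); they
  exercise the scoring paths, not nutrition science.
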