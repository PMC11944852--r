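---
title: "Matching FFQ items to dietary-guideline food groups: the adgat method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching FFQ items to dietary-guideline food groups: the adgat method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgat)
library(tibble)
```

## The problem

Food frequency questionnaires (FFQs) report habitual intake as grams per day
of a fixed list of food items — the Dietary Questionnaire for Epidemiological
Studies (DQES), widely used in Australian cohorts, outputs 101 such items.
Dietary guidelines, however, are phrased in *servings per day* of five food
groups (grains; vegetables and legumes; fruit; dairy and alternatives; lean
meats and alternatives) plus a limit on *discretionary* foods (energy-dense,
nutrient-poor foods high in saturated fat, added salt, added sugar or
alcohol). The national ADG food composition database bridges the two scales:
it assigns each of its 5742 surveyed foods a number of food-group servings
per 100 g, a discretionary flag and an energy density (kJ/100 g) — but its
records are keyed by food ID, and an FFQ item has no food ID.

`adgat` closes that gap with a rule-based record-linkage pipeline: each FFQ
item is matched to one or more database records by string search over the
hierarchical food descriptions, the matches are collapsed into a single
servings-per-100 g row per item, and reported intakes (g/day) are then
converted to servings/day by simple linear scaling:

$$\text{servings/day} \;=\; \frac{\text{g/day} \times \text{servings/100 g}}{100}.$$

## The matching pipeline

Matching one item runs four deterministic stages (`match_item()` composes
them; each stage is also exported for inspection):

1. **Candidate search** (`string_search()`). A record is a candidate when
   its normalized description contains any of the item's search terms as a
   substring. Normalization lowercases, collapses punctuation other than
   commas to spaces, and preserves the comma structure because descriptions
   are hierarchical with the most generic descriptor first. Recall is
   deliberately broad (any term, substring match); precision is restored by
   the later stages, mirroring a broad-then-narrow search protocol. The
   search also notes, per candidate, whether a term sits in the *primary
   position* (the first comma-delimited descriptor begins with it) and
   whether the record is a *"not further defined"* (NFD) summary — the
   database's representative average over all variants of a food.

2. **Exclusions** (`apply_exclusions()`), each recorded in an audit trail:

   * *(a) all-zero records*: every group serving is zero **and** the record
     is not discretionary-flagged. Records that are zero in all five groups
     but flagged (beer, spirits) are retained — they carry discretionary
     servings.
   * *(b) raw-form records* for items consumed cooked or processed, when
     the item names an animal protein or starchy vegetable/pulse (raw
     records of these foods pre-date nutrient retention adjustments; the
     cooked records already embed them). The keyword lists are
     configuration, not code (`match_config()`), since any fixed list is a
     vocabulary choice. Keyword hits are word-bounded: "strawberries"
     contains the substring "raw" but not the word.
   * *(c) mixed-dish records* ("stuffed", "casserole", "with", "dish",
     "pie", "soup") when the item implies a single food, i.e. its expected
     form is not `mixed`. Dish keywords appearing in the item's own search
     terms are ignored for that item: an item that itself names a pie is
     not implying a single food, and must be allowed to match pie records.
   * *(d) NFD/general records* when the item names a specific variety
     (e.g. wholemeal bread): a summary over all breads would dilute the
     specific answer.

3. **Selection** (`apply_selection()`). For a *generic* item with a
   primary-position NFD summary among the survivors, that summary is
   selected: it is the database's own average over the variants, which is
   exactly what a generic FFQ item means. When several NFD candidates
   qualify, the lexicographically lowest food ID is taken — in the real
   database an NFD summary is unique per food, so this tie-break only
   matters for adversarial synthetic inputs, and a single-record resolution
   keeps the method labels unambiguous. Otherwise primary-position
   candidates are preferred when any exist; otherwise the survivors stand.

4. **Method classification** (`classify_method()`): `"not further defined"`
   when the NFD route resolved the item, `"single"` for exactly one
   ordinary record, `"average"` for two or more. Zero survivors raise an
   error carrying the full audit trail. Per-item overrides
   (`match_config(overrides = ...)`) pin food IDs directly for items where
   automated matching is insufficient — the package exposes overrides
   rather than guessing how two human coders would adjudicate an ambiguous
   item.

Every stage is deterministic: identical inputs and configuration give
identical results, and all tie-breaks are lexicographic by food ID.

## Aggregation and the discretionary rules

`build_adgat_row()` collapses an item's matched records:

* Food-group servings are the **unweighted arithmetic mean** per component.
  Consumption-weighted averaging would be preferable in principle but
  requires reliable population consumption data per database food, which an
  FFQ protocol does not carry.
* The item is classified **discretionary** when strictly more than 20% of
  the matched records carry the discretionary flag
  (`classify_discretionary()`; at exactly 20% the rule does not trigger).
* Discretionary servings per 100 g are mean energy density divided by
  600 kJ — the guideline-defined energy content of one discretionary
  serving — and 0 for non-discretionary items, even when individual matched
  records are flagged (`discretionary_servings()`).

Both constants are parameters of `discretionary_params()`. The mean energy
is taken over **all** matched records by default, consistent with the
group-serving mean; `energy_over = "flagged"` restricts it to the flagged
records for sensitivity analyses, since published protocols do not pin this
choice down. All arithmetic runs at full floating precision; rounding
(half-up, one decimal) happens only at serialization
(`write_adgat_table()`), with optional full-precision sidecar columns.

## The packaged reference table

The package ships the complete 101-item reference summary table for the
DQES (`load_reference_table()`): per item, its expected form, the method by
which it was resolved, and servings per 100 g for the five groups and
discretionary foods. The file is pinned by an md5 checksum so transcription
drift fails loudly. The worked conversion is then one multiplication:

```{r butter}
tab <- load_reference_table()
tab[tab$item_name == "Butter", ]
aggregate_daily_servings(
  tibble(item_name = "Butter", grams_per_day = 20), tab)
```

20 g/day of butter at 5.0 discretionary servings/100 g is 1.0 discretionary
serving per day. `adherence_report()` compares servings/day against a
recommendation profile: food groups are adequacy targets (met when consumed
≥ recommended), discretionary servings a limit (met when ≤). Recommended
counts are configuration data per age-sex stratum, never hard-coded. Mixed
dishes (hamburger, pizza) legitimately contribute to both food groups and
discretionary servings; the report keeps the two independent and leaves the
joint interpretation to the analyst.

## The synthetic generator

Rebuilding the reference table from scratch needs the external database
download, so all tests run on synthetic look-alikes.
`generate_synthetic_adg_db()` emulates the structural features the matcher
must survive: generic-first comma descriptions, one NFD summary plus named
variants per planted food word, raw-form decoys, mixed-dish decoys,
all-zero decoy records and unrelated filler foods, with configurable
fractions of NFD, discretionary and all-zero records and uniform energy
densities. The all-zero fraction is honored exactly
(`round(fraction * n_foods)` records); the NFD and discretionary fractions
are topped up to their targets where the planted families do not already
exceed them. The generator is a pure function of its spec (seed included)
and emits a manifest naming every planted record, so matcher tests have
ground truth by construction. Synthetic intakes
(`generate_intake_profile()`) draw grams/day from a log-normal distribution
(default meanlog = log 30, sdlog = 0.8, 20% non-consumption zeros) — the
conventional right-skewed shape of dietary intake data.

What the synthetic data does **not** emulate: real description vocabulary
and misspellings, correlated intakes across items, portion-size structure,
or nutrient panels beyond energy. Passing tests therefore demonstrate that
the rules are implemented as stated and behave deterministically — not that
the curated search terms are optimal for the real 5742-food database, which
is why the audit trail and per-item overrides exist.

## Numerical and design choices

* Problem sizes in the test suite: exhaustive oracle comparisons run on
  hundreds of randomized databases of ≤10 records (every selection and
  exclusion branch), property checks on 1000 randomized aggregation cases
  and 50 randomized intake vectors; synthetic databases of 50–400 records
  exercise the end-to-end path. These sizes give full branch coverage while
  keeping the suite fast to iterate.
* Equality tolerances in tests are 1e-12 (pure floating-point identities);
  matching itself involves no tolerances.
* Degenerate inputs: empty candidate sets are legal mid-pipeline and only
  an error at classification; empty intake lists score to zero servings;
  empty tables serialize to a header-only file.
* The per-item search terms for the DQES are not published; the packaged
  `dqes_items.yaml` derives them from the item names (base terms, comma
  alternates, singular fallbacks, em-dash variety qualifiers, with em-dash
  items marked specific) and is meant to be edited by users as a versioned
  config.

## Limitations

Food-group resolution stops at the five broad groups: no wholegrain/refined
split, no dairy-fat tiers, no dietary-variety scoring. Averages are
unweighted (see above). The 600 kJ serving and the >20% threshold are
national-guideline constants; both are parameters for adaptation to other
guideline systems, and the whole pipeline — string search, exclusions,
NFD selection, mean aggregation — transfers to any FFQ/composition-database
pair with hierarchical descriptions.
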