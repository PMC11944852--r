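# adgat

Dietary guidelines prescribe *servings per day* of five food groups —
grains; vegetables and legumes; fruit; dairy and alternatives; lean meats
and alternatives — plus a limit on *discretionary* foods (energy-dense,
nutrient-poor foods high in saturated fat, added salt, added sugar or
alcohol). Food frequency questionnaires (FFQs), the workhorse of
epidemiological cohorts, report intake as *grams per day* of fixed food
items instead. `adgat` converts between the two so that guideline adherence
can be evaluated from FFQ data.

It does this in two steps:

1. **Food matching.** Each FFQ item is linked to one or more records of an
   ADG-style food composition database (foods with hierarchical
   comma-separated descriptions, food-group servings per 100 g, a
   discretionary flag and energy in kJ/100 g) by a deterministic rule
   pipeline: substring search over normalized descriptions, exclusion rules
   (all-zero records, raw forms of foods consumed cooked, mixed dishes when
   a single food is meant, generic summaries when a specific variety is
   named), preference for primary-position and "not further defined" (NFD)
   summary records, and a method label per item (`single`, `average`,
   `not further defined`). Multiple matches are collapsed by unweighted
   means. An item is discretionary when strictly more than 20% of its
   matched records are flagged, and its discretionary servings per 100 g
   are mean energy density / 600 kJ (one discretionary serving ≡ 600 kJ).

2. **Adherence scoring.** With a per-item servings/100 g table in hand,
   reported intakes convert linearly:
   `servings/day = g/day × servings/100 g ÷ 100`, summed per person and
   compared against a recommendation profile (food groups are adequacy
   targets, discretionary servings a limit).

The package ships the complete 101-item reference table for the Dietary
Questionnaire for Epidemiological Studies (DQES), checksum-pinned, so step 2
works out of the box; step 1 is fully implemented (with audit trails,
keyword configuration and per-item overrides) for users who bring their own
database export or questionnaire. A seeded synthetic database generator
emulates the structural hazards of real composition data — NFD summaries,
raw/cooked variants, mixed-dish and all-zero decoys — so every stage is
testable without downloads.

## Worked example

```r
library(adgat)
library(tibble)

tab <- load_reference_table()          # 101 items, servings per 100 g
tab[tab$item_name == "Butter", ]
#> # A tibble: 1 × 9
#>   item_name form      method  grains vegetables_legumes fruit dairy_alternatives
#>   <chr>     <chr>     <chr>    <dbl>              <dbl> <dbl>              <dbl>
#> 1 Butter    processed not fu…      0                  0     0                  0
#> # ℹ 2 more variables: meat_alternatives <dbl>, discretionary <dbl>

s <- aggregate_daily_servings(
  tibble(person_id = "P1",
         item_name = c("Butter", "Apples", "Pizza"),
         grams_per_day = c(20, 150, 100)),
  tab)
tidy(s)
#> # A tibble: 6 × 3
#>   person_id component          servings_per_day
#>   <chr>     <chr>                         <dbl>
#> 1 P1        grains                         1.4
#> 2 P1        vegetables_legumes             0.3
#> 3 P1        fruit                          1.05
#> 4 P1        dairy_alternatives             0.5
#> 5 P1        meat_alternatives              0.2
#> 6 P1        discretionary                  2.8
```

Reading the output: 150 g/day of apples at 0.7 fruit servings/100 g is 1.05
fruit servings/day; the 100 g of pizza contributes across four food groups
(1.4 grains, 0.3 vegetables, 0.5 dairy, 0.2 meat) *and* 1.8 discretionary
servings, which together with butter's 1.0 (20 g × 5.0/100) gives 2.8
discretionary servings/day. `adherence_report()` then compares each
component with a recommendation profile.

Matching a questionnaire against a database export:

```r
db    <- read_adg_database("adg_db.csv")          # or with a column dialect
items <- read_ffq_items(dqes_items_path())        # the packaged 101 items
m     <- match_item(items[19, ], db)              # one item, with audit trail
tidy(m)                                           # kept/excluded per record
tab   <- build_adgat_table(match_items(items, db))
```

A thin command-line wrapper over the same functions lives at
`inst/cli/adgat.R` (`adgat build | score | simulate | validate`).

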