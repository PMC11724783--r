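# nppm

Rule-based assessment of commercially produced foods for infants and young
children (FIYC, under 36 months) against the WHO Regional Office for
Europe's **Nutrient and Promotion Profile Model (NPPM)** — the framework
public-health researchers use to audit supermarket baby-food assortments —
plus the aggregation such audits report: compliance tables by category and
age band, nutrient means with 95 % CIs per 100 g and per 100 kcal, and
one-way ANOVA across categories.

Intended users: nutritional-epidemiology and food-policy researchers
auditing labelled product data, and anyone who needs a reproducible,
configurable implementation of the NPPM criteria.

## What it implements

**Nutrient composition** (any applicable failure ⇒ non-compliant; all
printed thresholds inclusive; editable rule table):

* energy: dry cereals ≥ 80 kcal/100 g (as prepared), dairy/fruit & veg/
  meals ≥ 60 kcal/100 g, snacks ≤ 50 kcal per serving;
* protein: dry cereals with milk ≤ 5.5 g/100 kcal; savoury meals
  ≥ 3 g/100 kcal (elevated minimum with meat/poultry/fish);
* fat ≤ 4.5 g/100 kcal (≤ 6 for meat meals);
* total sugar ≤ 15 % of energy for meals and non-fruit snacks
  (%E = g sugar × 4 kcal/g ÷ kcal × 100);
* added and free sugars (syrups, honey, juices, concentrates) prohibited,
  detected from the ingredient list via an extensible sugar-class lexicon;
* salt ≤ 0.125 g/100 kcal (≤ 0.25 with cheese);
* confectionery and drinks must not be marketed as FIYC at all.

**Promotional requirements**: no nutrition/health/marketing claims; no
marketing from under 6 months; adequate breastfeeding-support statement;
spout warning on spouted packs; name reflecting the main ingredients;
declared ingredient proportions; preparation instructions; front-of-pack
high-sugar flag when sugar exceeds 30 %E (fruit & veg, cereals) or 40 %E
(dairy) — strict cut-offs.

A synthetic-data generator (`generate_products()`) emulates a realistic
assortment with planted, exactly-known ground truth, so the whole pipeline
is testable offline; see the methods vignette
(`vignettes/nppm-methods.Rmd`) for the model, defaults and design
decisions.

## Worked example

```r
library(nppm)

# a 469-product synthetic assortment at the calibrated defaults
sim <- generate_products(synthetic_config(n = 469), seed = 1)
a   <- assess_products(sim$products)

compliance_table(a, by = "criterion", which = "nutrient")
#>   stratum     criterion n_applicable n_fail pct_fail pct_pass
#> 1     all   added_sugar          455     94       21       79
#> 2     all        energy          454    125       28       72
#> 3     all           fat          455     14        3       97
#> 4     all marketability          469     14        3       97
#> 5     all       overall          469    248       53       47
#> 6     all       protein          191      9        5       95
#> 7     all          salt          455     69       15       85
#> 8     all     sugar_pct          223    110       49       51
```

Each row is one criterion: `n_applicable` counts products the criterion
applies to and could be assessed on (grey-row categories and non-marketable
confectionery/drinks are excluded from denominators), `pct_fail` is the
failure rate rounded half-up. The `overall` row uses the any-fail verdict
over all 469 products — here 47 % of the assortment is nutrient-compliant.
`sugar_pct` only applies to meals and non-fruit snacks (223 products), and
about half of them exceed 15 % of energy from sugar; the added-sugar
prohibition catches 21 % of marketable products.

```r
s <- nutrient_summary(sim$products, "per_100g")
dplyr::filter(s$summary, nutrient == "energy")
#>   category nutrient   n      mean     lower     upper
#> 1  Cereals   energy  52 393.31538 386.96346 399.66731
#> 2    Dairy   energy   9  71.73333  59.58291  83.88376
#> 3 FruitVeg   energy 143  69.32727  66.48228  72.17227
#> 4    Meals   energy 181  67.52707  65.46449  69.58966
#> 5   Snacks   energy  69 416.69420 401.89404 431.49436

s$anova[s$anova$nutrient == "energy", c("f", "df_between", "df_within", "p_value")]
#>          f df_between df_within p_value
#> 1 3133.490          4       449       0
```

Snacks are by far the densest category (417 kcal/100 g, 95 % CI 402–431)
and the purée-dominated fruit & vegetable and meals categories the least
dense; the one-way ANOVA confirms the categories differ (p < 0.001).

Real product tables are read with
`read_products("products.csv")` (canonical CSV schema, or the NPPM
template dialect via a column mapping); invalid rows land in an error
ledger rather than being silently dropped. A thin command-line wrapper for
simulate/ingest/assess/summarize lives at `inst/cli/nppm.R`.

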