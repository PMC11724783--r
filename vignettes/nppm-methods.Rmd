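---
title: "Assessing foods for infants and young children against the WHO NPPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing foods for infants and young children against the WHO NPPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nppm)
```

## The model

Commercially produced foods for infants and young children (FIYC, under 36
months) are audited in two halves under the WHO Regional Office for
Europe's Nutrient and Promotion Profile Model (NPPM):

* **Nutrient composition.** Category-specific thresholds on energy density,
  protein, fat, total sugar and salt, plus an outright prohibition of added
  and free sugars. Nutrient criteria are expressed per 100 kcal
  (g/100 kcal = g/100 g × 100 / kcal/100 g), per 100 g, as a percent of
  energy, or per serving, depending on the criterion.
* **Promotional requirements.** No nutrition, health or marketing claims;
  no marketing from under 6 months; a statement supporting continued
  breastfeeding; "do not suck from the spout" guidance on spouted packs; a
  product name that reflects the main ingredients; declared ingredient
  proportions; preparation instructions where needed; and a front-of-pack
  (FOP) high-sugar flag when energy from sugar exceeds 30 % (fruit/
  vegetable and cereal products) or 40 % (dairy).

Both halves use the *any-fail* convention: failing a single applicable
criterion makes the product non-compliant overall. Confectionery and
drinks must not be marketed as FIYC at all; they fail marketability
outright and their nutrient panel is skipped rather than failed.

## The rule table

All nutrient criteria live in an editable table
(`default_rule_table()`, serializable to YAML) keyed by criterion,
category and a subcategory condition, with threshold, direction and
assessment basis. The shipped defaults are the model's published
main-table values:

| criterion | scope | threshold |
|---|---|---|
| energy | dry cereals (as prepared) | ≥ 80 kcal/100 g |
| energy | dairy, fruit & veg, meals | ≥ 60 kcal/100 g |
| energy | snacks | ≤ 50 kcal/serving |
| protein | dry cereals with milk | ≤ 5.5 g/100 kcal |
| protein | savoury meals | ≥ 3 g/100 kcal (≥ 4 with meat/poultry/fish) |
| fat | general | ≤ 4.5 g/100 kcal (≤ 6 for meat meals) |
| total sugar | meals, non-fruit snacks | ≤ 15 % of energy |
| added/free sugar | all marketable | prohibited |
| salt | general | ≤ 0.125 g/100 kcal (≤ 0.25 with cheese) |

Design choices where the published material leaves the point open:

* **Boundary convention.** Printed thresholds are inclusive: a meal at
  exactly 60 kcal/100 g or salt at exactly 0.125 g/100 kcal passes,
  because the criteria are printed as ≤/≥. The FOP cut-offs are the
  opposite: "exceeding 30 %" is read strictly, so exactly 30 % does not
  require the flag. Comparisons carry a 10⁻⁹ relative tolerance so that
  values equal to a threshold up to floating-point noise behave like the
  printed value, while differences at label precision (0.001 g) always
  resolve.
* **Energy conversion.** Percent of energy from sugar uses the standard
  4 kcal/g carbohydrate factor; the model does not restate it.
* **Elevated protein minimum.** The requirement that meals containing
  meat, poultry or fish meet "higher" protein levels is not quantified in
  the main criteria table; the default is 4 g/100 kcal, stored in the rule
  table with `source = "supplementary_default"` and overridable like any
  other entry.
* **Disabled placeholders.** Fruit-content, added-water and
  percent-of-weight protein criteria exist in the model's supplementary
  criterion matrix without main-table cut-offs. They ship as
  `applicable = FALSE` rows so users who hold those cut-offs can enable
  them; the defaults never assess them.
* **Ingredients category.** With no category-specific wording, the
  category-generic criteria (fat, salt, added sugar) apply to it and the
  category-specific ones (energy, protein, sugar %E) do not.
* **Dry cereals without a prepared-energy declaration** are assessed on
  the dry label energy with a warning note rather than being dropped,
  mirroring how published composition tables fall back to the dry value.
* **Incomplete nutrient panels.** A missing declaration makes that
  criterion *not assessable* (never imputed, never silently passed). By
  default the product is judged on its remaining criteria and flagged
  `incomplete`; a `strict` policy that fails incomplete products is
  selectable, since the model's own handling is unstated.

## Sugar and claim lexicons

Ingredient lists are scanned against a ~90-term lexicon mapping patterns
to sugar classes (added, free, liberated, milk-intrinsic,
plant-intrinsic). Matching is case-insensitive substring containment on
whitespace-normalized text, longest-pattern-first, so "apple juice
concentrate" resolves to a free sugar rather than the bare fruit "apple".
Added and free sugars trigger the prohibition; liberated sugars (fruit
purées used as ingredients) are reported only, with a strict mode
(`liberated = "prohibit"`) available — whether purée in a savoury meal
should trigger the prohibition rather than only the %-energy limits is
genuinely unresolved, so the default records without failing. The claims
rule works the same way over a nutrition/health/marketing claim lexicon;
since any recognized claim is disallowed on FIYC, detection suffices. A
manual adjudication column (`name_reflects_main_ingredients`) always
overrides the name-clarity heuristic, which otherwise requires every
non-descriptor token of the product name to match a token of the top-3
ingredients.

## Statistics

Category summaries report mean and 95 % CI per nutrient on the per-100 g
and per-100 kcal bases. Intervals use the *t* distribution
(mean ± t₀.₉₇₅,ₙ₋₁·sd/√n); at the category sizes involved the difference
from a normal interval is negligible and *t* is exact under normality.
Categories are compared with classical one-way equal-variance ANOVA
(`stats::oneway.test`); groups with fewer than two observations are
excluded (a single-product category contributes no within-group
variance), and the all-degenerate case (zero variance everywhere, unequal
means) is reported as p = 0 with a `degenerate` flag. Report percentages
are rounded half-up to whole percent, matching how printed compliance
tables round.

## The synthetic generator

`generate_products()` emulates the kind of assortment a UK supermarket
audit collects, with planted ground truth so every pipeline stage can be
verified without any data download:

* The default category mix (meals 38 %, fruit & vegetables 30 %, snacks
  16 %, cereals 11 %, confectionery 3 %, dairy 1 %, ingredients and
  drinks <1 %) and age distribution (14 % marketed from under 6 months,
  55 % from 6–9 months) follow the published breakdown of such an
  assortment; per-category nutrient distributions are truncated normals
  with means from the published composition table (e.g. snacks
  416 kcal/100 g, meals 69 kcal/100 g) and sds recovered from the printed
  95 % CIs (sd = half-width × √n / 1.96). Truncation bounds sit at
  physical limits, so no record is invalid.
* **Verdict-first sampling.** The overall nutrient verdict is drawn first
  (per-category fail rates: snacks 67 %, meals 64 %, fruit & veg 46 % as
  published; cereals 23 %, dairy 17 %, ingredients 0 % chosen once so
  that overall compliance lands near the published 45 %). For a planted
  failure, the failing subset of applicable criteria is drawn at
  conditional rates (redrawn until non-empty) calibrated so the marginal
  added-sugar prevalence is near 19 % and criterion pass rates near their
  published values; nutrient values are then sampled from the pass or
  fail side of each product's threshold. Planted truth is therefore exact
  by construction, not asymptotic, and the ledger can demand 100 %
  agreement.
* The generator restates applicability and thresholds in its own compact
  logic instead of calling the rule engine, so ledger agreement is a
  genuine two-implementation cross-check.
* Label fields (claims on every pack, adequate breastfeeding statements
  on 5 %, spouts on 55 % of fruit & vegetable packs with warnings on
  27 %, name clarity 71 %, preparation instructions 63 %) are Bernoulli
  draws at the planted prevalences; ingredient lists come from
  lexicon-clean pools with a prohibited term inserted exactly when an
  added-sugar failure is planted; names are constructed to pass or fail
  the clarity heuristic as planted.

What the generator does **not** emulate: real brand text, correlated
nutrient panels within a brand, multi-criterion failure correlation
beyond the planted structure, OCR noise, or real ingredient phrasing
diversity. Passing the planted-truth tests therefore demonstrates that
the engine implements the criteria faithfully — not that the lexicons
would capture every formulation seen on real packs.

Because nutrient values are sampled conditional on planted verdicts,
sample means shift slightly from the configured means where a threshold
truncates a tail (a fully-compliant fruit & vegetable assortment, floor
60 kcal/100 g, averages above the configured 64); the calibration tests
compare against the truncated-normal mean.

## Problem sizes and numerical checks

The test suite validates, at sizes chosen to keep a full run in a few
minutes on one CPU: the boundary suite (every enabled threshold at/below/
above, all categories); engine-vs-brute-force oracle agreement on a
±10 % grid in 1 % steps around every threshold (≥ 2,000 products); exact
planted-rate recovery on a 10,000-product assortment; CI coverage
95 % ± 1 % and ANOVA type-I error within 3 binomial SEs of 5 % over
10,000 replicates; and the two-group identity F = t² to 10⁻¹⁰.

## Known limitations

* The canonical CSV schema is this package's construction; the model's
  own Excel template is mapped on via an editable column mapping.
* Claim and sugar lexicons are seeded with common UK label phrasings and
  are deliberately user-extensible; recall on real packs depends on the
  lexicon, not the engine.
* Micronutrient criteria (iron, vitamins) are outside the model's current
  scope and this package's.
* The name-clarity heuristic is an operationalization of a judgement the
  model leaves to human reviewers; the manual override column is the
  intended escape hatch.
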