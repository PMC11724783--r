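#' Convert a per-100 g nutrient value to the per-100 kcal basis
#'
#' The model's primary assessment basis normalizes nutrient mass to energy:
#' g per 100 kcal = g per 100 g x 100 / kcal per 100 g.
#'
#' @param value_g_100g Nutrient mass, g per 100 g.
#' @param energy_kcal_100g Energy density, kcal per 100 g.
#' @return g per 100 kcal; `NA` when energy is missing or non-positive.
#' @export
#' @examples
#' per_100kcal(3.1, 69) # about 4.49 g protein per 100 kcal
per_100kcal <- function(value_g_100g, energy_kcal_100g) {
  ifelse(is.na(energy_kcal_100g) | energy_kcal_100g <= 0, NA_real_,
         value_g_100g * 100 / energy_kcal_100g)
}

## Source column on the per-100 g scale for each per-100 kcal criterion.
criterion_nutrient_column <- c(
  protein = "protein_g_100g",
  fat = "fat_g_100g",
  salt = "salt_g_100g"
)

## Compute the observed value of one criterion for every product, on the
## basis its matched rule specifies. Returns list(observed, note).
observed_on_basis <- function(products, criterion, basis) {
  n <- nrow(products)
  observed <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  for (b in unique(basis[!is.na(basis)])) {
    i <- which(!is.na(basis) & basis == b)
    if (b == "kcal_per_100g") {
      observed[i] <- products$energy_kcal_100g[i]
    } else if (b == "kcal_per_100g_prepared") {
      prep <- products$prepared_energy_kcal_100g[i]
      dry <- products$energy_kcal_100g[i]
      observed[i] <- ifelse(is.na(prep), dry, prep)
      note[i][is.na(prep) & !is.na(dry)] <-
        "prepared energy not declared; assessed on dry-product label energy"
    } else if (b == "kcal_per_serving") {
      observed[i] <- products$energy_kcal_100g[i] * products$serving_g[i] / 100
      note[i][is.na(products$serving_g[i])] <- "serving size not declared"
    } else if (b == "g_per_100kcal") {
      col <- criterion_nutrient_column[[criterion]]
      observed[i] <- per_100kcal(products[[col]][i], products$energy_kcal_100g[i])
    } else if (b == "pct_energy") {
      observed[i] <- pct_energy_from_sugar(products$total_sugar_g_100g[i],
                                           products$energy_kcal_100g[i])
    } else if (b == "marketable") {
      observed[i] <- as.numeric(!products$category[i] %in% non_marketable_categories())
    } else if (b == "prohibited_ingredient_count") {
      ## filled by the caller from the sugar profile
      observed[i] <- NA_real_
    }
  }
  list(observed = observed, note = note)
}

## Evaluate one criterion for all products against the rule table.
evaluate_criterion <- function(products, rules, criterion, observed_override = NULL) {
  products <- check_products(products)
  m <- match_rules(products, rules, criterion)
  ob <- observed_on_basis(products, criterion, m$basis)
  if (!is.null(observed_override)) ob$observed <- observed_override
  skip <- products$category %in% non_marketable_categories() & criterion != "marketability"
  applicable <- m$applicable & !skip
  passed <- rep(NA, nrow(products))
  idx <- which(applicable & !is.na(ob$observed))
  passed[idx] <- cmp_threshold(ob$observed[idx], m$threshold[idx], m$direction[idx])
  note <- ob$note
  note[applicable & is.na(ob$observed) & is.na(note)] <- "observed value missing"
  note[skip & m$applicable] <- "category must not be marketed; nutrient criteria skipped"
  tibble::tibble(
    product_id = products$product_id,
    criterion = criterion,
    applicable = applicable,
    passed = passed,
    observed = ob$observed,
    threshold = m$threshold,
    direction = m$direction,
    basis = m$basis,
    note = note
  )
}

#' Individual nutrient criteria
#'
#' Each of these evaluates one nutrient-composition criterion for every row
#' of a product table against a rule table and returns one rule result per
#' product: whether the criterion applies to that product, whether it
#' passed (`NA` = not assessable, e.g. a missing declaration), the observed
#' value on the criterion's basis, and the matched threshold.
#'
#' `energy_rule` assesses dry cereals on prepared energy (falling back to
#' the dry-product label energy with a note when no prepared value is
#' declared), dairy/fruit-veg/meals on kcal per 100 g, and snacks on kcal
#' per serving (energy x serving size / 100). `sugar_pct_rule` needs the
#' percent of energy from sugar, computed internally via
#' [pct_energy_from_sugar()]. `added_sugar_rule` fails any product whose
#' ingredient list contains an added- or free-sugar term (see
#' [sugar_profile()]). `marketability_rule` fails confectionery and drinks
#' outright. All printed thresholds are inclusive.
#'
#' @param products A product tibble ([read_products()], [generate_products()]
#'   or a hand-built data frame with the canonical columns).
#' @param rules A rule table; defaults to [default_rule_table()].
#' @return A tibble of rule results with columns `product_id`, `criterion`,
#'   `applicable`, `passed`, `observed`, `threshold`, `direction`, `basis`,
#'   `note`.
#' @seealso [assess_nutrients()] for the full panel and overall verdict.
#' @name nutrient_rules
NULL

#' @rdname nutrient_rules
#' @export
energy_rule <- function(products, rules = default_rule_table()) {
  evaluate_criterion(products, rules, "energy")
}

#' @rdname nutrient_rules
#' @export
protein_rule <- function(products, rules = default_rule_table()) {
  evaluate_criterion(products, rules, "protein")
}

#' @rdname nutrient_rules
#' @export
fat_rule <- function(products, rules = default_rule_table()) {
  evaluate_criterion(products, rules, "fat")
}

#' @rdname nutrient_rules
#' @export
sugar_pct_rule <- function(products, rules = default_rule_table()) {
  evaluate_criterion(products, rules, "sugar_pct")
}

#' @rdname nutrient_rules
#' @export
salt_rule <- function(products, rules = default_rule_table()) {
  evaluate_criterion(products, rules, "salt")
}

#' @rdname nutrient_rules
#' @export
marketability_rule <- function(products, rules = default_rule_table()) {
  evaluate_criterion(products, rules, "marketability")
}

#' @rdname nutrient_rules
#' @param lexicon Sugar lexicon for ingredient classification.
#' @param liberated Whether liberated sugars are prohibited; see
#'   [sugar_profile()].
#' @export
added_sugar_rule <- function(products, rules = default_rule_table(),
                             lexicon = default_sugar_lexicon(),
                             liberated = c("report", "prohibit")) {
  prof <- sugar_profile(products, lexicon, liberated)
  evaluate_criterion(products, rules, "added_sugar",
                     observed_override = prof$n_prohibited_ingredients)
}

#' Assess the full nutrient-composition panel
#'
#' Runs every enabled criterion in the rule table (marketability, energy,
#' protein, fat, percent of energy from sugar, added-sugar prohibition,
#' salt, plus any user-enabled supplementary criteria) over a product table
#' and derives each product's overall nutrient verdict under the any-fail
#' convention: a product is nutrient-compliant only if it may be marketed at
#' all and every applicable, assessable criterion passes.
#'
#' @param products A product tibble.
#' @param rules Rule table; defaults to [default_rule_table()].
#' @param lexicon Sugar lexicon for the added-sugar prohibition.
#' @param liberated Whether liberated sugars are prohibited
#'   (see [sugar_profile()]).
#' @param incomplete_policy How products with not-assessable criteria enter
#'   the overall verdict. `"available"` (default) judges them on the
#'   criteria that could be assessed and flags them incomplete; `"strict"`
#'   deems any product with a not-assessable applicable criterion
#'   non-compliant.
#' @return A list with `results` (long tibble of rule results, one row per
#'   product x criterion) and `verdicts` (per-product tibble with
#'   `marketable`, `nutrient_compliant`, `incomplete`).
#' @export
assess_nutrients <- function(products, rules = default_rule_table(),
                             lexicon = default_sugar_lexicon(),
                             liberated = c("report", "prohibit"),
                             incomplete_policy = c("available", "strict")) {
  incomplete_policy <- match.arg(incomplete_policy)
  products <- check_products(products)
  criteria <- setdiff(unique(rules$criterion[rules$applicable]), "added_sugar")
  ## marketability first, then the printed order
  pref <- c("marketability", "energy", "protein", "fat", "sugar_pct", "added_sugar", "salt")
  criteria <- union("added_sugar", criteria)
  criteria <- c(intersect(pref, criteria), setdiff(criteria, pref))
  results <- purrr::map_dfr(criteria, function(cr) {
    if (cr == "added_sugar") {
      added_sugar_rule(products, rules, lexicon, liberated)
    } else {
      evaluate_criterion(products, rules, cr)
    }
  })
  verdicts <- results |>
    dplyr::group_by(.data$product_id) |>
    dplyr::summarise(
      n_failed = sum(.data$applicable & !is.na(.data$passed) & !.data$passed),
      incomplete = any(.data$applicable & is.na(.data$passed)),
      .groups = "drop"
    )
  verdicts <- products |>
    dplyr::select("product_id", "category") |>
    dplyr::left_join(verdicts, by = "product_id") |>
    dplyr::mutate(
      marketable = !.data$category %in% non_marketable_categories(),
      nutrient_compliant = .data$marketable & .data$n_failed == 0 &
        !(incomplete_policy == "strict" & .data$incomplete)
    ) |>
    dplyr::select("product_id", "category", "marketable",
                  "nutrient_compliant", "incomplete")
  list(results = results, verdicts = verdicts)
}
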