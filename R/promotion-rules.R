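#' Default claim lexicon
#'
#' Patterns for nutrition, health and marketing claims scanned on-pack.
#' Under the model, the presence of any such claim on a food for infants
#' and young children makes the product non-compliant with the claims
#' requirement, so the lexicon only needs to recognize claims, not judge
#' them. Matching is case-insensitive substring containment on normalized
#' whitespace, as for the sugar lexicon.
#'
#' @return A tibble with columns `pattern` and `type`
#'   (`nutrition`/`health`/`marketing`).
#' @export
default_claim_lexicon <- function() {
  lex <- function(type, patterns) tibble::tibble(pattern = patterns, type = type)
  dplyr::bind_rows(
    lex("nutrition", c(
      "no added sugar", "no added sugars", "low in sugar", "low sugar",
      "sugar free", "no added salt", "low in salt", "source of vitamin",
      "source of vitamins", "source of minerals", "source of iron",
      "source of calcium", "source of fibre", "source of protein",
      "high in", "rich in", "1 of your 5 a day", "one of your 5 a day",
      "no preservatives", "no artificial"
    )),
    lex("health", c(
      "supports healthy growth", "healthy growth", "supports development",
      "good for", "aids digestion", "immune", "strong bones",
      "brain development", "supports your baby"
    )),
    lex("marketing", c(
      "organic", "tasty", "yummy", "delicious", "scrummy", "scrumptious",
      "perfect for little hands", "little ones love", "kids love",
      "natural goodness", "made with love", "wholesome", "perfectly balanced"
    ))
  )
}

#' @rdname default_claim_lexicon
#' @param path CSV path with columns `pattern`, `type`.
#' @export
read_claim_lexicon <- function(path) {
  lex <- readr::read_csv(path, col_types = "cc", progress = FALSE, show_col_types = FALSE)
  names(lex)[names(lex) == "class"] <- "type"
  if (!all(c("pattern", "type") %in% names(lex))) {
    stop("claim lexicon needs 'pattern' and 'type' columns", call. = FALSE)
  }
  if (anyDuplicated(normalize_text(lex$pattern))) {
    stop("claim lexicon patterns must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(lex$type), c("nutrition", "health", "marketing"))
  if (length(bad) > 0) stop("unknown claim types: ", paste(bad, collapse = ", "), call. = FALSE)
  lex
}

promo_result <- function(products, criterion, applicable, passed,
                         observed = NA_real_, note = NA_character_) {
  n <- nrow(products)
  applicable <- rep_len(applicable, n)
  passed <- rep_len(as.logical(passed), n)
  passed[!applicable] <- NA
  tibble::tibble(
    product_id = products$product_id,
    criterion = criterion,
    applicable = applicable,
    passed = passed,
    observed = rep_len(as.numeric(observed), n),
    threshold = NA_real_,
    direction = NA_character_,
    basis = "promotion",
    note = rep_len(as.character(note), n)
  )
}

#' Promotional requirement rules
#'
#' Each rule evaluates one promotional requirement per product and returns
#' rule results in the same shape as the nutrient rules (`applicable`,
#' `passed` with `NA` = not assessable, `note`).
#'
#' \describe{
#'   \item{`claims_rule`}{fails a product if any on-pack claim text matches
#'     the claim lexicon — nutrition, health or marketing claims are all
#'     disallowed on foods for this age group.}
#'   \item{`age_label_rule`}{fails products marketed from under 6 months,
#'     or carrying no parseable age recommendation at all.}
#'   \item{`breastfeeding_statement_rule`}{passes only products carrying an
#'     adequate statement supporting continued breastfeeding.}
#'   \item{`spout_warning_rule`}{applies to spouted packs only; passes when
#'     the pack advises that children should not suck from the spout.}
#'   \item{`name_clarity_rule`}{passes when the product name reflects the
#'     main ingredients: every food token in the name must match a token of
#'     the top-`k` ingredients (descriptor words like "porridge" or "pouch"
#'     are ignored). A manual adjudication in
#'     `name_reflects_main_ingredients` always takes precedence.}
#'   \item{`ingredient_list_rule`}{passes when the ingredient list declares
#'     the required proportions (largest ingredient, water/stock, fruit
#'     content), recorded in `ingredient_proportions_declared`.}
#'   \item{`preparation_instructions_rule`}{applies to categories whose
#'     products need preparation (by default cereals and meals); passes when
#'     instructions are present.}
#'   \item{`fop_label_rule`}{applies to products whose sugar energy share
#'     requires a front-of-pack high-sugar flag; passes when the flag is on
#'     the pack.}
#' }
#'
#' @param products A product tibble.
#' @return A tibble of rule results (see [nutrient_rules]).
#' @seealso [assess_promotion()]
#' @name promotion_rules
NULL

#' @rdname promotion_rules
#' @param lexicon Claim lexicon; defaults to [default_claim_lexicon()].
#' @export
claims_rule <- function(products, lexicon = default_claim_lexicon()) {
  products <- check_products(products)
  pats <- normalize_text(lexicon$pattern)
  claims <- split_claims(products$claim_texts)
  n_matched <- vapply(claims, function(cl) {
    if (length(cl) == 0) return(0)
    cl <- normalize_text(cl)
    sum(vapply(cl, function(s) any(vapply(pats, grepl, logical(1), x = s, fixed = TRUE)), logical(1)))
  }, numeric(1))
  promo_result(products, "claims", applicable = TRUE, passed = n_matched == 0,
               observed = n_matched)
}

#' @rdname promotion_rules
#' @export
age_label_rule <- function(products) {
  products <- check_products(products)
  age <- products$lower_age_months
  passed <- !is.na(age) & age >= 6
  note <- ifelse(is.na(age), "no age recommendation found", NA_character_)
  promo_result(products, "age_label", applicable = TRUE, passed = passed,
               observed = as.numeric(age), note = note)
}

#' @rdname promotion_rules
#' @export
breastfeeding_statement_rule <- function(products) {
  products <- check_products(products)
  has <- products$has_breastfeeding_statement %in% TRUE
  adequate <- products$breastfeeding_statement_adequate %in% TRUE
  note <- ifelse(has & !adequate, "statement present but inadequate", NA_character_)
  promo_result(products, "breastfeeding_statement", applicable = TRUE,
               passed = has & adequate, note = note)
}

#' @rdname promotion_rules
#' @export
spout_warning_rule <- function(products) {
  products <- check_products(products)
  has_spout <- products$has_spout %in% TRUE
  promo_result(products, "spout_warning", applicable = has_spout,
               passed = products$has_spout_warning %in% TRUE)
}

## Descriptor tokens that name a format, not an ingredient.
name_descriptor_tokens <- function() {
  c("porridge", "puree", "pouch", "pot", "jar", "snack", "snacks", "bites",
    "bar", "bars", "melts", "puffs", "wafers", "biscotti", "meal", "mix",
    "multigrain", "wholegrain", "cereal", "baby", "toddler", "little",
    "first", "stage", "creamy", "smooth", "chunky", "mini", "organic",
    "rice", "cakes", "fingers", "sticks", "crisps", "breadsticks", "mash",
    "bake", "pie", "stew", "casserole", "curry", "risotto", "pasta",
    "smoothie", "yoghurt", "yogurt", "dessert")
}

#' @rdname promotion_rules
#' @param k Number of leading ingredients whose tokens may justify the name
#'   (default 3).
#' @export
name_clarity_rule <- function(products, k = 3) {
  products <- check_products(products)
  ing <- parse_ingredients(products$ingredients)
  name_toks <- tokenize_words(ifelse(is.na(products$name), "", products$name))
  desc <- name_descriptor_tokens()
  passed <- rep(NA, nrow(products))
  note <- rep(NA_character_, nrow(products))
  for (i in seq_len(nrow(products))) {
    override <- products$name_reflects_main_ingredients[i]
    if (!is.na(override)) {
      passed[i] <- override
      note[i] <- "manual adjudication"
      next
    }
    if (nrow(ing[[i]]) == 0) {
      note[i] <- "empty ingredient list; name clarity not assessable"
      next
    }
    top <- head(ing[[i]]$ingredient, k)
    ing_toks <- unique(unlist(tokenize_words(top)))
    food <- setdiff(name_toks[[i]], desc)
    passed[i] <- length(food) == 0 || all(food %in% ing_toks)
  }
  promo_result(products, "name_clarity", applicable = TRUE, passed = passed,
               note = note)
}

#' @rdname promotion_rules
#' @export
ingredient_list_rule <- function(products) {
  products <- check_products(products)
  promo_result(products, "ingredient_list", applicable = TRUE,
               passed = products$ingredient_proportions_declared %in% TRUE)
}

#' @rdname promotion_rules
#' @param applicable_categories Categories whose products require
#'   preparation instructions.
#' @export
preparation_instructions_rule <- function(products,
                                          applicable_categories = c("Cereals", "Meals")) {
  products <- check_products(products)
  appl <- products$category %in% applicable_categories
  promo_result(products, "preparation_instructions", applicable = appl,
               passed = products$has_preparation_instructions %in% TRUE)
}

#' @rdname promotion_rules
#' @param required Logical vector: is the front-of-pack flag required for
#'   each product? Defaults to computing it from the sugar profile.
#' @param fop_thresholds Passed to [fop_flag_required()].
#' @export
fop_label_rule <- function(products, required = NULL,
                           fop_thresholds = c(FruitVeg = 30, Cereals = 30, Dairy = 40)) {
  products <- check_products(products)
  if (is.null(required)) {
    pctE <- pct_energy_from_sugar(products$total_sugar_g_100g, products$energy_kcal_100g)
    required <- suppressWarnings(fop_flag_required(products$category, pctE, fop_thresholds))
  }
  promo_result(products, "fop_label", applicable = required,
               passed = products$has_fop_sugar_flag %in% TRUE)
}

#' Assess all promotional requirements
#'
#' Runs every promotion rule over a product table and derives the overall
#' promotion verdict under the any-fail convention: compliant only if every
#' applicable, assessable promotional requirement passes. Not-applicable
#' rules (e.g. the spout warning on a jar) never affect the verdict.
#'
#' @inheritParams claims_rule
#' @inheritParams preparation_instructions_rule
#' @inheritParams fop_label_rule
#' @param k Passed to [name_clarity_rule()].
#' @param incomplete_policy As in [assess_nutrients()].
#' @return A list with `results` (long rule-result tibble) and `verdicts`
#'   (per-product `promotion_compliant`, `fop_flag_required`, `incomplete`).
#' @export
assess_promotion <- function(products, lexicon = default_claim_lexicon(),
                             applicable_categories = c("Cereals", "Meals"),
                             fop_thresholds = c(FruitVeg = 30, Cereals = 30, Dairy = 40),
                             k = 3,
                             incomplete_policy = c("available", "strict")) {
  incomplete_policy <- match.arg(incomplete_policy)
  products <- check_products(products)
  pctE <- pct_energy_from_sugar(products$total_sugar_g_100g, products$energy_kcal_100g)
  required <- suppressWarnings(fop_flag_required(products$category, pctE, fop_thresholds))
  results <- dplyr::bind_rows(
    claims_rule(products, lexicon),
    age_label_rule(products),
    breastfeeding_statement_rule(products),
    spout_warning_rule(products),
    name_clarity_rule(products, k = k),
    ingredient_list_rule(products),
    preparation_instructions_rule(products, applicable_categories),
    fop_label_rule(products, required = required, fop_thresholds = fop_thresholds)
  )
  verdicts <- results |>
    dplyr::group_by(.data$product_id) |>
    dplyr::summarise(
      n_failed = sum(.data$applicable & !is.na(.data$passed) & !.data$passed),
      incomplete = any(.data$applicable & is.na(.data$passed)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      promotion_compliant = .data$n_failed == 0 &
        !(incomplete_policy == "strict" & .data$incomplete)
    ) |>
    dplyr::select("product_id", "promotion_compliant", "incomplete")
  verdicts <- dplyr::left_join(
    tibble::tibble(product_id = products$product_id, fop_flag_required = required),
    verdicts, by = "product_id")
  list(results = results, verdicts = verdicts)
}

#' Assess products against the full model
#'
#' One-call pipeline: nutrient-composition panel ([assess_nutrients()]) plus
#' promotional requirements ([assess_promotion()]), returning the combined
#' per-product verdicts.
#'
#' @inheritParams assess_nutrients
#' @inheritParams assess_promotion
#' @param claim_lexicon Claim lexicon for [claims_rule()].
#' @return A list with `nutrient_results`, `promotion_results` (long
#'   rule-result tibbles) and `verdicts`: one row per product with
#'   `category`, `age_bucket`, `marketable`, `nutrient_compliant`,
#'   `promotion_compliant`, `fop_flag_required` and the two `incomplete`
#'   flags.
#' @export
#' @examples
#' sim <- generate_products(synthetic_config(n = 50), seed = 1)
#' a <- assess_products(sim$products)
#' table(a$verdicts$nutrient_compliant)
assess_products <- function(products, rules = default_rule_table(),
                            lexicon = default_sugar_lexicon(),
                            claim_lexicon = default_claim_lexicon(),
                            liberated = c("report", "prohibit"),
                            applicable_categories = c("Cereals", "Meals"),
                            fop_thresholds = c(FruitVeg = 30, Cereals = 30, Dairy = 40),
                            incomplete_policy = c("available", "strict")) {
  products <- check_products(products)
  nut <- assess_nutrients(products, rules, lexicon, liberated, incomplete_policy)
  promo <- assess_promotion(products, claim_lexicon, applicable_categories,
                            fop_thresholds, incomplete_policy = incomplete_policy)
  verdicts <- nut$verdicts |>
    dplyr::rename(nutrient_incomplete = "incomplete") |>
    dplyr::left_join(
      promo$verdicts |> dplyr::rename(promotion_incomplete = "incomplete"),
      by = "product_id") |>
    dplyr::left_join(
      products |> dplyr::select("product_id", "age_bucket"),
      by = "product_id")
  list(nutrient_results = nut$results,
       promotion_results = promo$results,
       verdicts = verdicts)
}
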