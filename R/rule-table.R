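#' Default NPPM nutrient-criterion rule table
#'
#' Builds the configurable criterion matrix used by the nutrient rules: one
#' row per (criterion, category, subcategory condition) with its threshold,
#' comparison direction, assessment basis and applicability.
#'
#' The shipped defaults reproduce the model's published nutrient requirements:
#' \itemize{
#'   \item energy: dry cereals/starches at least 80 kcal/100 g as prepared;
#'     dairy, fruit & vegetable and meal products at least 60 kcal/100 g;
#'     snacks at most 50 kcal per serving;
#'   \item protein: dry cereals containing milk at most 5.5 g/100 kcal;
#'     savoury meals at least 3 g/100 kcal, raised to 4 g/100 kcal when the
#'     meal contains meat, poultry or fish (the elevated minimum is a
#'     supplementary-sourced default and can be edited);
#'   \item fat: at most 4.5 g/100 kcal, relaxed to 6 g/100 kcal for meals
#'     with meat, poultry or fish;
#'   \item total sugar: at most 15 percent of energy for meals and
#'     non-fruit-based snacks;
#'   \item added sugar: any added or free sugar ingredient is prohibited in
#'     every marketable category;
#'   \item salt: at most 0.125 g/100 kcal, or 0.25 g/100 kcal for products
#'     containing cheese;
#'   \item marketability: confectionery and drinks must not be marketed as
#'     foods for infants and young children at all.
#' }
#' Thresholds are inclusive at the boundary (a product exactly at a printed
#' limit passes). Rows with \code{applicable = FALSE} are never assessed and
#' never enter compliance denominators; the fruit-content, added-water and
#' percent-of-weight protein criteria ship as disabled placeholder rows
#' (\code{source = "supplementary_placeholder"}) because the model defines
#' them in its supplementary criterion matrix without main-table cut-offs —
#' users with those cut-offs can enable and fill them in.
#'
#' @return A tibble with columns \code{criterion}, \code{category},
#'   \code{condition} (an R expression over the subcategory flag columns, or
#'   \code{NA} for the category default), \code{priority} (higher wins when
#'   several conditions match), \code{applicable}, \code{threshold},
#'   \code{direction} (\code{"le"} or \code{"ge"}), \code{basis} and
#'   \code{source}.
#' @seealso [read_rule_table()], [write_rule_table()], [assess_nutrients()]
#' @export
#' @examples
#' default_rule_table()
default_rule_table <- function() {
  row <- function(criterion, category, condition, priority, applicable,
                  threshold, direction, basis, source) {
    tibble::tibble(
      criterion = criterion, category = category, condition = condition,
      priority = priority, applicable = applicable, threshold = threshold,
      direction = direction, basis = basis, source = source
    )
  }
  main <- "main_criteria"
  supp <- "supplementary_default"
  ph <- "supplementary_placeholder"
  dplyr::bind_rows(
    ## energy density
    row("energy", "Cereals", NA, 1, TRUE, 80, "ge", "kcal_per_100g_prepared", main),
    row("energy", "Dairy", NA, 1, TRUE, 60, "ge", "kcal_per_100g", main),
    row("energy", "FruitVeg", NA, 1, TRUE, 60, "ge", "kcal_per_100g", main),
    row("energy", "Meals", NA, 1, TRUE, 60, "ge", "kcal_per_100g", main),
    row("energy", "Snacks", NA, 1, TRUE, 50, "le", "kcal_per_serving", main),
    row("energy", "Ingredients", NA, 1, FALSE, NA, NA, "kcal_per_100g", main),
    ## protein
    row("protein", "Cereals", "contains_milk", 2, TRUE, 5.5, "le", "g_per_100kcal", main),
    row("protein", "Cereals", NA, 1, FALSE, NA, NA, "g_per_100kcal", main),
    row("protein", "Meals", "is_savoury_meal & contains_meat_poultry_fish",
        3, TRUE, 4, "ge", "g_per_100kcal", supp),
    row("protein", "Meals", "is_savoury_meal", 2, TRUE, 3, "ge", "g_per_100kcal", main),
    row("protein", "Meals", NA, 1, FALSE, NA, NA, "g_per_100kcal", main),
    row("protein", c("Dairy", "FruitVeg", "Snacks", "Ingredients"),
        NA, 1, FALSE, NA, NA, "g_per_100kcal", main),
    ## fat
    row("fat", "Meals", "contains_meat_poultry_fish", 2, TRUE, 6, "le", "g_per_100kcal", main),
    row("fat", c("Cereals", "Dairy", "FruitVeg", "Meals", "Snacks", "Ingredients"),
        NA, 1, TRUE, 4.5, "le", "g_per_100kcal", main),
    ## total sugar as % of energy
    row("sugar_pct", "Meals", NA, 1, TRUE, 15, "le", "pct_energy", main),
    row("sugar_pct", "Snacks", "!is_fruit_based_snack", 2, TRUE, 15, "le", "pct_energy", main),
    row("sugar_pct", "Snacks", NA, 1, FALSE, NA, NA, "pct_energy", main),
    row("sugar_pct", c("Cereals", "Dairy", "FruitVeg", "Ingredients"),
        NA, 1, FALSE, NA, NA, "pct_energy", main),
    ## added / free sugar prohibition (count of prohibited ingredients must be 0)
    row("added_sugar", c("Cereals", "Dairy", "FruitVeg", "Meals", "Snacks", "Ingredients"),
        NA, 1, TRUE, 0, "le", "prohibited_ingredient_count", main),
    ## salt
    row("salt", c("Cereals", "Dairy", "FruitVeg", "Meals", "Snacks", "Ingredients"),
        "contains_cheese", 2, TRUE, 0.25, "le", "g_per_100kcal", main),
    row("salt", c("Cereals", "Dairy", "FruitVeg", "Meals", "Snacks", "Ingredients"),
        NA, 1, TRUE, 0.125, "le", "g_per_100kcal", main),
    ## marketability: 1 = may be marketed, 0 = may not
    row("marketability", setdiff(nppm_categories(), non_marketable_categories()),
        NA, 1, TRUE, 1, "ge", "marketable", main),
    row("marketability", non_marketable_categories(),
        NA, 1, TRUE, 1, "ge", "marketable", main),
    ## placeholders without main-table cut-offs; disabled until configured
    row("fruit_content", c("FruitVeg", "Snacks", "Meals"), NA, 1, FALSE, NA, "le", "pct_fruit", ph),
    row("added_water", "FruitVeg", NA, 1, FALSE, NA, "le", "pct_added_water", ph),
    row("protein_pct_weight", "Meals", NA, 1, FALSE, NA, "ge", "pct_weight", ph)
  )
}

#' Read a rule table from a YAML file
#'
#' @param path Path to a YAML file as written by [write_rule_table()].
#' @return A rule-table tibble (see [default_rule_table()]).
#' @export
read_rule_table <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- purrr::map_dfr(raw$rules, function(r) {
    tibble::tibble(
      criterion = r$criterion,
      category = r$category,
      condition = r$condition %||% NA_character_,
      priority = as.numeric(r$priority %||% 1),
      applicable = isTRUE(r$applicable),
      threshold = if (is.null(r$threshold)) NA_real_ else as.numeric(r$threshold),
      direction = r$direction %||% NA_character_,
      basis = r$basis,
      source = r$source %||% "user"
    )
  })
  validate_rule_table(rules)
  rules
}

#' Write a rule table to a YAML file
#'
#' The file round-trips: [read_rule_table()] on the output reproduces the
#' input table.
#'
#' @param rules A rule-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rules, path) {
  validate_rule_table(rules)
  entries <- purrr::pmap(rules, function(criterion, category, condition, priority,
                                         applicable, threshold, direction, basis, source) {
    e <- list(criterion = criterion, category = category, priority = priority,
              applicable = applicable, basis = basis, source = source)
    if (!is.na(condition)) e$condition <- condition
    if (!is.na(threshold)) e$threshold <- threshold
    if (!is.na(direction)) e$direction <- direction
    e
  })
  yaml::write_yaml(list(rules = entries), path)
  invisible(path)
}

validate_rule_table <- function(rules) {
  needed <- c("criterion", "category", "condition", "priority", "applicable",
              "threshold", "direction", "basis", "source")
  missing <- setdiff(needed, names(rules))
  if (length(missing) > 0) {
    stop("rule table is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(rules$threshold < 0, na.rm = TRUE)) {
    stop("rule-table thresholds must be non-negative", call. = FALSE)
  }
  bad_cat <- setdiff(unique(rules$category), nppm_categories())
  if (length(bad_cat) > 0) {
    stop("unknown categories in rule table: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  dup <- rules |>
    dplyr::count(.data$criterion, .data$category, .data$condition, .data$priority) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate rule-table entries for ",
         paste(dup$criterion, dup$category, sep = "/", collapse = "; "), call. = FALSE)
  }
  invisible(rules)
}

## Resolve the single matching rule-table entry for one criterion across a
## product table. Conditions are R expressions over the subcategory flag
## columns, evaluated vectorized in the product data; among matching entries
## the highest priority wins, and the priority-1 default must have no
## condition so that exactly one entry matches every product.
match_rules <- function(products, rules, criterion) {
  cand <- rules[rules$criterion == criterion, , drop = FALSE]
  n <- nrow(products)
  out <- tibble::tibble(
    applicable = rep(FALSE, n), threshold = rep(NA_real_, n),
    direction = rep(NA_character_, n), basis = rep(NA_character_, n),
    matched = rep(FALSE, n), priority = rep(-Inf, n)
  )
  if (nrow(cand) == 0) return(out)
  for (i in seq_len(nrow(cand))) {
    in_cat <- products$category == cand$category[i]
    cond <- cand$condition[i]
    if (!is.na(cond)) {
      ok <- eval(parse(text = cond)[[1]], envir = products)
      ok <- !is.na(ok) & ok
    } else {
      ok <- rep(TRUE, n)
    }
    take <- in_cat & ok & cand$priority[i] > out$priority
    out$applicable[take] <- cand$applicable[i]
    out$threshold[take] <- cand$threshold[i]
    out$direction[take] <- cand$direction[i]
    out$basis[take] <- cand$basis[i]
    out$priority[take] <- cand$priority[i]
    out$matched[take] <- TRUE
  }
  out
}
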