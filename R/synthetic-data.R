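#' Configuration for the synthetic product generator
#'
#' Returns the generator's study-condition defaults, all overridable via
#' arguments. The defaults emulate a realistic UK supermarket assortment of
#' foods for infants and young children: the eight-category mix and age
#' distribution of such an assortment (meals 38 %, fruit & vegetables 30 %,
#' snacks 16 %; 14 % marketed from under 6 months), category-conditional
#' nutrient distributions (truncated normals with means such as 416 kcal/
#' 100 g for snacks and 69 kcal/100 g for meals), planted overall
#' nutrient-fail rates per category (snacks 67 %, meals 64 %, fruit & veg
#' 46 %), conditional per-criterion fail shares calibrated so the marginal
#' added-sugar prevalence lands near 19 %, and label-field prevalences
#' (claims on every pack, adequate breastfeeding statement on 5 %).
#'
#' @param n Number of products.
#' @param category_mix Named proportions over the eight categories
#'   (must sum to 1).
#' @param age_dist Named proportions over the four age bands.
#' @param overall_fail_rate Named per-category probability that a marketable
#'   product fails the overall nutrient assessment.
#' @param conditional_fail Named per-criterion probability that a criterion
#'   fails, given the product was planted as an overall nutrient fail and
#'   the criterion applies (the failing subset is redrawn until non-empty).
#' @param flag_prevalence Named prevalences for subcategory flags
#'   (`contains_milk` among cereals, `is_savoury_meal` among meals,
#'   `meat_given_savoury`, `contains_cheese` among meals,
#'   `is_fruit_based_snack` among snacks).
#' @param promo_rates Named planted pass rates / prevalences for the
#'   promotional fields: `claims_pass`, `breastfeeding_pass`,
#'   `spout_prevalence_fruitveg`, `spout_prevalence_meals`,
#'   `spout_warning_pass`, `name_clarity_pass`, `ingredient_list_pass`,
#'   `ingredient_list_pass_cereals`, `preparation_instructions_pass`,
#'   `fop_flag_pass` (probability the flag is on pack when required).
#' @param nutrient_params Per-category tibble of truncated-normal means and
#'   sds for energy, protein, fat, sugar and salt per 100 g; defaults
#'   derived from a published category composition table (sd recovered from
#'   the 95 % CI half-width as hw x sqrt(n) / 1.96).
#' @return A list of class `nppm_synthetic_config`.
#' @seealso [generate_products()]
#' @export
synthetic_config <- function(n = 469,
                             category_mix = NULL,
                             age_dist = NULL,
                             overall_fail_rate = NULL,
                             conditional_fail = NULL,
                             flag_prevalence = NULL,
                             promo_rates = NULL,
                             nutrient_params = NULL) {
  category_mix <- category_mix %||%
    (c(Cereals = 53, Dairy = 6, FruitVeg = 139, Meals = 178, Snacks = 76,
       Ingredients = 1, Confectionery = 15, Drinks = 1) / 469)
  age_dist <- age_dist %||%
    (c(under6 = 66, m6to9 = 256, m10to11 = 58, m12plus = 89) / 469)
  overall_fail_rate <- overall_fail_rate %||%
    c(Cereals = 0.23, Dairy = 0.17, FruitVeg = 0.46, Meals = 0.64,
      Snacks = 0.67, Ingredients = 0, Confectionery = 1, Drinks = 1)
  conditional_fail <- conditional_fail %||%
    c(energy = 0.45, protein = 0.11, fat = 0.04, sugar_pct = 0.75,
      added_sugar = 0.35, salt = 0.25)
  flag_prevalence <- flag_prevalence %||%
    c(contains_milk = 0.7, is_savoury_meal = 0.85, meat_given_savoury = 0.5,
      contains_cheese = 0.12, is_fruit_based_snack = 0.4)
  promo_rates <- promo_rates %||%
    c(claims_pass = 0, breastfeeding_pass = 0.05,
      spout_prevalence_fruitveg = 0.55, spout_prevalence_meals = 0.15,
      spout_warning_pass = 0.27, name_clarity_pass = 0.71,
      ingredient_list_pass = 0.80, ingredient_list_pass_cereals = 0.58,
      preparation_instructions_pass = 0.63, fop_flag_pass = 0.10)
  hw_sd <- function(hw, n) hw * sqrt(n) / 1.96
  nutrient_params <- nutrient_params %||% tibble::tribble(
    ~category, ~energy_mean, ~energy_sd, ~protein_mean, ~protein_sd,
    ~fat_mean, ~fat_sd, ~sugar_mean, ~sugar_sd, ~salt_mean, ~salt_sd,
    "Cereals", 391, hw_sd(6.5, 53), 12.1, hw_sd(0.9, 53),
    5.5, hw_sd(1.15, 53), 16.2, hw_sd(3.4, 53), 0.21, hw_sd(0.055, 53),
    "Dairy", 74, hw_sd(8, 6), 2.6, hw_sd(0.3, 6),
    2.3, hw_sd(0.6, 6), 4.4, hw_sd(1.8, 6), 0.07, hw_sd(0.015, 6),
    "FruitVeg", 64, hw_sd(3, 139), 1.3, hw_sd(0.15, 139),
    1.1, hw_sd(0.2, 139), 8.6, hw_sd(0.6, 139), 0.03, hw_sd(0.005, 139),
    "Meals", 69, hw_sd(2, 178), 3.1, hw_sd(0.2, 178),
    2.2, hw_sd(0.15, 178), 2.5, hw_sd(0.2, 178), 0.08, hw_sd(0.01, 178),
    "Snacks", 416, hw_sd(14, 76), 7.5, hw_sd(0.4, 76),
    11.9, hw_sd(1.25, 76), 12.5, hw_sd(3.15, 76), 0.18, hw_sd(0.05, 76),
    "Ingredients", 350, 50, 1.0, 1.0, 1.0, 1.0, 1.5, 1.0, 0.02, 0.02,
    "Confectionery", 380, 60, 3.0, 2.0, 8.0, 5.0, 40, 15, 0.10, 0.10,
    "Drinks", 45, 15, 0.5, 0.5, 0.2, 0.3, 9.0, 4.0, 0.02, 0.02
  )
  cfg <- list(n = n, category_mix = category_mix, age_dist = age_dist,
              overall_fail_rate = overall_fail_rate,
              conditional_fail = conditional_fail,
              flag_prevalence = flag_prevalence,
              promo_rates = promo_rates,
              nutrient_params = nutrient_params)
  class(cfg) <- "nppm_synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n < 1) stop("n must be positive", call. = FALSE)
  if (abs(sum(cfg$category_mix) - 1) > 1e-8) {
    stop("category_mix proportions must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$category_mix), nppm_categories())) {
    stop("category_mix must name all eight categories", call. = FALSE)
  }
  if (abs(sum(cfg$age_dist) - 1) > 1e-8) {
    stop("age_dist proportions must sum to 1", call. = FALSE)
  }
  rates <- c(cfg$overall_fail_rate, cfg$conditional_fail,
             cfg$flag_prevalence, cfg$promo_rates)
  if (any(rates < 0 | rates > 1)) {
    stop("planted rates must lie in [0, 1]", call. = FALSE)
  }
  p <- cfg$nutrient_params
  if (any(p$energy_sd <= 0 | p$protein_sd <= 0 | p$fat_sd <= 0 |
          p$sugar_sd <= 0 | p$salt_sd <= 0)) {
    stop("nutrient sds must be positive", call. = FALSE)
  }
  if (any(p$energy_mean <= 0)) stop("energy means must be positive", call. = FALSE)
  ## planted fails must be reachable: a category with a fail rate needs at
  ## least one criterion with a non-zero conditional fail probability
  if (any(cfg$overall_fail_rate[setdiff(nppm_categories(), non_marketable_categories())] > 0) &&
      all(cfg$conditional_fail == 0)) {
    stop("infeasible config: overall fails planted but every conditional ",
         "criterion fail probability is 0", call. = FALSE)
  }
  invisible(cfg)
}

## Clean per-category ingredient pools (no added/free sugar lexicon hits)
## and the prohibited pool used to plant added-sugar failures.
ingredient_pools <- function() {
  list(
    base = list(
      Cereals = c("oat flour", "wholegrain wheat flour", "rice flour",
                  "barley flakes", "millet flour", "water"),
      Dairy = c("whole milk", "yogurt", "cream", "rice starch", "water"),
      FruitVeg = c("apple", "banana", "carrot", "sweet potato",
                   "butternut squash", "pear", "mango", "parsnip", "water"),
      Meals = c("carrot", "potato", "tomato", "onion", "courgette",
                "red lentils", "basmati rice", "olive oil", "water"),
      Snacks = c("oat flour", "apple", "raisin", "wholegrain wheat flour",
                 "sunflower oil", "maize"),
      Ingredients = c("cornflour", "water"),
      Confectionery = c("cocoa mass", "oat flour", "water"),
      Drinks = c("water", "spring water")
    ),
    meat = c("chicken breast", "beef mince", "cod fillet", "turkey breast"),
    cheese = "mild cheddar cheese",
    milk = "whole milk powder",
    prohibited = c("sugar", "glucose syrup", "honey", "apple juice concentrate",
                   "grape juice concentrate", "maltodextrin", "invert sugar",
                   "fruit juice concentrate")
  )
}

fail_name_pool <- function() {
  c("Sunshine Treat", "Rainbow Surprise", "Happy Tummy", "Magic Munch",
    "Gigglers Delight", "Tiny Explorer")
}

category_descriptor <- function() {
  c(Cereals = "Porridge", Dairy = "Yoghurt", FruitVeg = "Puree",
    Meals = "Stew", Snacks = "Bites", Ingredients = "Mix",
    Confectionery = "Bar", Drinks = "Smoothie")
}

## relative offset used to keep planted failures clearly beyond a threshold
.plant_eps <- 1e-3

#' Generate a synthetic product table with planted ground truth
#'
#' Draws `config$n` products. For each product the overall nutrient verdict
#' is planted first (Bernoulli at the category's overall fail rate;
#' confectionery and drinks always fail because they must not be marketed);
#' for planted failures a non-empty subset of the applicable criteria is
#' drawn to fail at the conditional rates; nutrient values are then sampled
#' from truncated normals restricted to the pass or fail side of each
#' product's threshold, so the ledger truth is exact by construction rather
#' than asymptotic. Label fields are drawn Bernoulli at the planted
#' prevalences, ingredient lists from clean or prohibited-term pools, and
#' product names are constructed to pass or fail the name-clarity heuristic
#' as planted.
#'
#' The generator derives applicability and thresholds from its own compact
#' restatement of the published criteria — an independent code path from the
#' rule engine — so agreement between pipeline verdicts and the ledger is a
#' genuine cross-check.
#'
#' @param config A [synthetic_config()] list.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `products` (a product tibble accepted by
#'   [assess_products()]) and `truth` (the planted ledger: one row per
#'   product with every criterion outcome, `nutrient_compliant`,
#'   `promotion_compliant` and `fop_required`).
#' @export
#' @examples
#' sim <- generate_products(synthetic_config(n = 20), seed = 42)
#' sim$truth[, c("product_id", "nutrient_compliant", "promotion_compliant")]
generate_products <- function(config = synthetic_config(), seed = NULL) {
  validate_synthetic_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  cats <- nppm_categories()
  category <- sample(names(config$category_mix), n, replace = TRUE,
                     prob = config$category_mix)
  fp <- config$flag_prevalence

  is_dry_cereal <- category == "Cereals"
  contains_milk <- is_dry_cereal & rbinom(n, 1, fp[["contains_milk"]]) == 1
  is_savoury_meal <- category == "Meals" & rbinom(n, 1, fp[["is_savoury_meal"]]) == 1
  contains_meat_poultry_fish <- is_savoury_meal &
    rbinom(n, 1, fp[["meat_given_savoury"]]) == 1
  contains_cheese <- category == "Meals" & rbinom(n, 1, fp[["contains_cheese"]]) == 1
  is_fruit_based_snack <- category == "Snacks" &
    rbinom(n, 1, fp[["is_fruit_based_snack"]]) == 1

  bucket <- sample(names(config$age_dist), n, replace = TRUE, prob = config$age_dist)
  months <- integer(n)
  months[bucket == "under6"] <- 4L
  months[bucket == "m6to9"] <- sample(6:9, sum(bucket == "m6to9"), replace = TRUE)
  months[bucket == "m10to11"] <- sample(10:11, sum(bucket == "m10to11"), replace = TRUE)
  months[bucket == "m12plus"] <- sample(12:24, sum(bucket == "m12plus"), replace = TRUE)
  age_label <- sprintf("from %d months", months)

  marketable <- !category %in% non_marketable_categories()
  fail_overall <- !marketable |
    rbinom(n, 1, config$overall_fail_rate[category]) == 1

  ## applicability, restated from the printed criteria
  app <- tibble::tibble(
    energy = marketable & category %in% c("Cereals", "Dairy", "FruitVeg", "Meals", "Snacks"),
    protein = marketable & ((category == "Cereals" & contains_milk) |
                              (category == "Meals" & is_savoury_meal)),
    fat = marketable,
    sugar_pct = marketable & (category == "Meals" |
                                (category == "Snacks" & !is_fruit_based_snack)),
    added_sugar = marketable,
    salt = marketable
  )
  crit <- names(app)

  ## criterion outcomes: TRUE pass, FALSE fail, NA not applicable
  pass <- matrix(NA, nrow = n, ncol = length(crit), dimnames = list(NULL, crit))
  for (cr in crit) pass[app[[cr]], cr] <- TRUE
  todo <- which(fail_overall & marketable)
  while (length(todo) > 0) {
    any_fail <- rep(FALSE, length(todo))
    for (cr in crit) {
      appl <- app[[cr]][todo]
      f <- appl & rbinom(length(todo), 1, config$conditional_fail[[cr]]) == 1
      pass[todo[f], cr] <- FALSE
      pass[todo[appl & !f], cr] <- TRUE
      any_fail <- any_fail | f
    }
    todo <- todo[!any_fail]
  }

  params <- config$nutrient_params[match(category, config$nutrient_params$category), ]

  ## energy per 100 g (dry label value for cereals)
  e_lo <- rep(5, n); e_hi <- rep(800, n)
  plain60 <- category %in% c("Dairy", "FruitVeg", "Meals")
  p60 <- plain60 & pass[, "energy"] %in% TRUE
  f60 <- plain60 & pass[, "energy"] %in% FALSE
  e_lo[p60] <- 60
  e_hi[f60] <- 60 * (1 - .plant_eps)
  e_lo[category == "Cereals"] <- 150
  e_lo[category == "Snacks"] <- 100; e_hi[category == "Snacks"] <- 600
  energy <- rtruncnorm(n, params$energy_mean, params$energy_sd, e_lo, e_hi)

  ## prepared energy for cereals, on the planted side of 80 kcal/100 g
  prepared <- rep(NA_real_, n)
  ic <- which(category == "Cereals")
  if (length(ic) > 0) {
    pe_lo <- ifelse(pass[ic, "energy"] %in% TRUE, 80, 30)
    pe_hi <- ifelse(pass[ic, "energy"] %in% TRUE, 200, 80 * (1 - .plant_eps))
    prepared[ic] <- rtruncnorm(length(ic), 100, 15, pe_lo, pe_hi)
  }

  ## snack serving size: energy x serving / 100 vs 50 kcal
  serving <- rep(NA_real_, n)
  isn <- which(category == "Snacks")
  if (length(isn) > 0) {
    cap <- 5000 / energy[isn]
    s_lo <- ifelse(pass[isn, "energy"] %in% FALSE, cap * (1 + .plant_eps), 1)
    s_hi <- ifelse(pass[isn, "energy"] %in% FALSE, 100, pmin(cap, 60))
    serving[isn] <- rtruncnorm(length(isn), 15, 5, s_lo, s_hi)
  }
  serving[category %in% c("Confectionery", "Ingredients")] <- 20

  ## per-100 kcal criteria translate to g/100 g bounds given energy
  side_bounds <- function(passed, thr_g, lo0, hi0, direction) {
    lo <- lo0; hi <- hi0
    if (direction == "le") {
      lo[passed %in% FALSE] <- (thr_g * (1 + .plant_eps))[passed %in% FALSE]
      hi[passed %in% TRUE] <- pmin(hi0, thr_g)[passed %in% TRUE]
    } else {
      hi[passed %in% FALSE] <- (thr_g * (1 - .plant_eps))[passed %in% FALSE]
      lo[passed %in% TRUE] <- pmax(lo0, thr_g)[passed %in% TRUE]
    }
    list(lo = lo, hi = hi)
  }

  prot_thr <- ifelse(category == "Cereals", 5.5,
                     ifelse(contains_meat_poultry_fish, 4, 3))
  prot_dir <- ifelse(category == "Cereals", "le", "ge")
  prot_g <- prot_thr * energy / 100
  bl <- side_bounds(ifelse(app$protein, pass[, "protein"], NA), prot_g,
                    rep(0, n), rep(60, n), "le")
  bg <- side_bounds(ifelse(app$protein, pass[, "protein"], NA), prot_g,
                    rep(0, n), rep(60, n), "ge")
  prot_lo <- ifelse(app$protein & prot_dir == "le", bl$lo,
                    ifelse(app$protein, bg$lo, 0))
  prot_hi <- ifelse(app$protein & prot_dir == "le", bl$hi,
                    ifelse(app$protein, bg$hi, 60))
  protein <- rtruncnorm(n, params$protein_mean, params$protein_sd, prot_lo, prot_hi)

  fat_thr_g <- ifelse(category == "Meals" & contains_meat_poultry_fish, 6, 4.5) * energy / 100
  bf <- side_bounds(ifelse(app$fat, pass[, "fat"], NA), fat_thr_g,
                    rep(0, n), rep(100, n), "le")
  fat <- rtruncnorm(n, params$fat_mean, params$fat_sd, bf$lo, pmin(bf$hi, 100))

  ## total sugar: %E limit where applicable; sugar energy never exceeds total
  sugar_cap <- pmin(95, energy / 4)
  sug_thr_g <- 15 * energy / 400
  bs <- side_bounds(ifelse(app$sugar_pct, pass[, "sugar_pct"], NA), sug_thr_g,
                    rep(0, n), sugar_cap, "le")
  sugar <- rtruncnorm(n, params$sugar_mean, params$sugar_sd, bs$lo, pmin(bs$hi, sugar_cap))

  salt_thr_g <- ifelse(contains_cheese, 0.25, 0.125) * energy / 100
  bsa <- side_bounds(ifelse(app$salt, pass[, "salt"], NA), salt_thr_g,
                     rep(0, n), rep(5, n), "le")
  salt <- rtruncnorm(n, params$salt_mean, params$salt_sd, bsa$lo, bsa$hi)

  ## ingredient lists
  pools <- ingredient_pools()
  pr <- config$promo_rates
  prop_pass_rate <- ifelse(category == "Cereals",
                           pr[["ingredient_list_pass_cereals"]],
                           pr[["ingredient_list_pass"]])
  proportions_declared <- rbinom(n, 1, prop_pass_rate) == 1
  added_fail <- app$added_sugar & pass[, "added_sugar"] %in% FALSE
  name_pass <- rbinom(n, 1, pr[["name_clarity_pass"]]) == 1
  ingredients <- character(n)
  name <- character(n)
  desc <- category_descriptor()
  for (i in seq_len(n)) {
    base <- pools$base[[category[i]]]
    k <- min(length(base), sample(3:5, 1))
    ing <- sample(base, k)
    if (contains_meat_poultry_fish[i]) ing <- c(sample(pools$meat, 1), ing)
    if (contains_cheese[i]) ing <- c(ing, pools$cheese)
    if (contains_milk[i]) ing <- c(ing, pools$milk)
    if (added_fail[i]) ing <- c(ing, sample(pools$prohibited, 1))
    if (name_pass[i]) {
      lead <- ing[seq_len(min(2, length(ing)))]
      name[i] <- stringr::str_to_title(paste(paste(lead, collapse = " & "),
                                             desc[[category[i]]]))
    } else {
      name[i] <- sample(fail_name_pool(), 1)
    }
    if (proportions_declared[i]) {
      ing[1] <- paste0(ing[1], ":", sample(30:70, 1))
    }
    ingredients[i] <- paste(ing, collapse = "|")
  }

  ## promotional fields, drawn at planted prevalences
  claims_pass <- rbinom(n, 1, pr[["claims_pass"]]) == 1
  claim_pool <- c("no added sugar", "organic", "supports healthy growth",
                  "1 of your 5 a day", "tasty", "source of vitamins")
  claim_texts <- ifelse(claims_pass, "", sample(claim_pool, n, replace = TRUE))
  bf_pass <- rbinom(n, 1, pr[["breastfeeding_pass"]]) == 1
  bf_inadequate <- !bf_pass & runif(n) < 0.5
  spout_prev <- ifelse(category == "FruitVeg", pr[["spout_prevalence_fruitveg"]],
                       ifelse(category == "Meals", pr[["spout_prevalence_meals"]], 0.02))
  has_spout <- rbinom(n, 1, spout_prev) == 1
  spout_pass <- has_spout & rbinom(n, 1, pr[["spout_warning_pass"]]) == 1
  prep_appl <- category %in% c("Cereals", "Meals")
  prep_pass <- rbinom(n, 1, pr[["preparation_instructions_pass"]]) == 1
  has_prep <- ifelse(prep_appl, prep_pass, rbinom(n, 1, 0.5) == 1)
  pctE <- sugar * 400 / energy
  fop_required <- (category %in% c("FruitVeg", "Cereals") & pctE > 30) |
    (category == "Dairy" & pctE > 40)
  fop_pass <- fop_required & rbinom(n, 1, pr[["fop_flag_pass"]]) == 1

  products <- tibble::tibble(
    product_id = sprintf("syn%05d", seq_len(n)),
    brand = sample(paste("Brand", LETTERS[1:12]), n, replace = TRUE),
    name = name,
    category = category,
    age_label = age_label,
    lower_age_months = months,
    age_bucket = bucket_age(months),
    is_dry_cereal = is_dry_cereal,
    contains_milk = contains_milk,
    is_savoury_meal = is_savoury_meal,
    contains_meat_poultry_fish = contains_meat_poultry_fish,
    contains_cheese = contains_cheese,
    is_fruit_based_snack = is_fruit_based_snack,
    is_puree_with_spout = has_spout & category == "FruitVeg",
    energy_kcal_100g = round(energy, 1),
    prepared_energy_kcal_100g = round(prepared, 1),
    protein_g_100g = round(protein, 2),
    fat_g_100g = round(fat, 2),
    total_sugar_g_100g = round(sugar, 2),
    salt_g_100g = round(salt, 4),
    serving_g = round(serving, 1),
    ingredients = ingredients,
    claim_texts = claim_texts,
    has_breastfeeding_statement = bf_pass | bf_inadequate,
    breastfeeding_statement_adequate = bf_pass,
    has_preparation_instructions = has_prep,
    has_spout = has_spout,
    has_spout_warning = spout_pass,
    has_fop_sugar_flag = fop_pass,
    name_reflects_main_ingredients = NA,
    ingredient_proportions_declared = proportions_declared
  )

  ## rounding the stored labels must not cross a planted threshold; recompute
  ## the planted side from the rounded values and fix rare crossers by
  ## nudging the value to the safe side of the bound
  products <- fix_rounding(products, pass, app,
                           list(prot_thr = prot_thr, prot_dir = prot_dir))

  ## recompute fop from rounded values for the ledger
  pctE_r <- products$total_sugar_g_100g * 400 / products$energy_kcal_100g
  fop_required <- (category %in% c("FruitVeg", "Cereals") & pctE_r > 30) |
    (category == "Dairy" & pctE_r > 40)
  products$has_fop_sugar_flag <- products$has_fop_sugar_flag & fop_required

  age_pass <- months >= 6
  promo_pass_mat <- cbind(
    claims = claims_pass,
    age_label = age_pass,
    breastfeeding_statement = bf_pass,
    spout_warning = ifelse(has_spout, spout_pass, NA),
    name_clarity = name_pass,
    ingredient_list = proportions_declared,
    preparation_instructions = ifelse(prep_appl, prep_pass, NA),
    fop_label = ifelse(fop_required, fop_pass, NA)
  )
  truth <- tibble::tibble(
    product_id = products$product_id,
    category = category,
    marketable = marketable,
    energy_pass = pass[, "energy"],
    protein_pass = pass[, "protein"],
    fat_pass = pass[, "fat"],
    sugar_pct_pass = pass[, "sugar_pct"],
    added_sugar_pass = pass[, "added_sugar"],
    salt_pass = pass[, "salt"],
    nutrient_compliant = marketable &
      apply(pass, 1, function(r) all(r, na.rm = TRUE)),
    claims_pass = promo_pass_mat[, "claims"] == 1,
    age_label_pass = promo_pass_mat[, "age_label"] == 1,
    breastfeeding_pass = promo_pass_mat[, "breastfeeding_statement"] == 1,
    spout_warning_pass = promo_pass_mat[, "spout_warning"] == 1,
    name_clarity_pass = promo_pass_mat[, "name_clarity"] == 1,
    ingredient_list_pass = promo_pass_mat[, "ingredient_list"] == 1,
    preparation_instructions_pass = promo_pass_mat[, "preparation_instructions"] == 1,
    fop_label_pass = promo_pass_mat[, "fop_label"] == 1,
    promotion_compliant = apply(promo_pass_mat, 1, function(r) all(r == 1, na.rm = TRUE)),
    fop_required = fop_required
  )
  list(products = products, truth = truth)
}

## After rounding stored label values, push any value that crossed its
## planted threshold back to the correct side (rounded to label precision).
fix_rounding <- function(products, pass, app, extra) {
  e <- products$energy_kcal_100g
  ## energy per 100 g
  plain <- products$category %in% c("Dairy", "FruitVeg", "Meals")
  p <- plain & pass[, "energy"] %in% TRUE & e < 60
  products$energy_kcal_100g[p] <- 60
  f <- plain & pass[, "energy"] %in% FALSE & e >= 60
  products$energy_kcal_100g[f] <- 59.9
  ## prepared energy
  ic <- products$category == "Cereals"
  pe <- products$prepared_energy_kcal_100g
  p <- ic & pass[, "energy"] %in% TRUE & !is.na(pe) & pe < 80
  products$prepared_energy_kcal_100g[p] <- 80
  f <- ic & pass[, "energy"] %in% FALSE & !is.na(pe) & pe >= 80
  products$prepared_energy_kcal_100g[f] <- 79.9
  e <- products$energy_kcal_100g
  ## snack serving
  isn <- products$category == "Snacks"
  per_serv <- e * products$serving_g / 100
  p <- isn & pass[, "energy"] %in% TRUE & !is.na(per_serv) & per_serv > 50
  products$serving_g[p] <- floor(5000 / e[p] * 10) / 10
  f <- isn & pass[, "energy"] %in% FALSE & !is.na(per_serv) & per_serv <= 50
  products$serving_g[f] <- ceiling((5000 / e[f]) * 10 + 1) / 10
  ## per-100kcal nutrients
  clamp <- function(value, thr_g, passed, dir, digits) {
    obs_pass <- if (dir == "le") value <= thr_g else value >= thr_g
    bad_p <- passed %in% TRUE & !obs_pass
    bad_f <- passed %in% FALSE & obs_pass
    step <- 10^-digits
    if (dir == "le") {
      value[bad_p] <- floor(thr_g[bad_p] / step) * step
      value[bad_f] <- ceiling(thr_g[bad_f] / step) * step + step
    } else {
      value[bad_p] <- ceiling(thr_g[bad_p] / step) * step
      value[bad_f] <- floor(thr_g[bad_f] / step) * step - step
    }
    pmax(value, 0)
  }
  prot_thr_g <- extra$prot_thr * e / 100
  pp <- ifelse(app$protein, pass[, "protein"], NA)
  le <- extra$prot_dir == "le"
  products$protein_g_100g[le] <- clamp(products$protein_g_100g, prot_thr_g, pp, "le", 2)[le]
  products$protein_g_100g[!le] <- clamp(products$protein_g_100g, prot_thr_g, pp, "ge", 2)[!le]
  fat_thr_g <- ifelse(products$category == "Meals" & products$contains_meat_poultry_fish,
                      6, 4.5) * e / 100
  products$fat_g_100g <- clamp(products$fat_g_100g, fat_thr_g,
                               ifelse(app$fat, pass[, "fat"], NA), "le", 2)
  sug_thr_g <- 15 * e / 400
  products$total_sugar_g_100g <- clamp(products$total_sugar_g_100g, sug_thr_g,
                                       ifelse(app$sugar_pct, pass[, "sugar_pct"], NA), "le", 2)
  salt_thr_g <- ifelse(products$contains_cheese, 0.25, 0.125) * e / 100
  products$salt_g_100g <- clamp(products$salt_g_100g, salt_thr_g,
                                ifelse(app$salt, pass[, "salt"], NA), "le", 4)
  products
}

#' Deterministic boundary fixtures for every enabled threshold
#'
#' Places one product exactly at, just below and just above every enabled
#' numeric threshold in the rule table, for every applicable category and
#' subcategory condition, plus fixtures around the strict front-of-pack
#' high-sugar cut-offs and the marketability rule. Per-100 kcal and
#' percent-of-energy fixtures use an energy density of 100 kcal/100 g so
#' the observed value equals the constructed per-100 g value exactly.
#'
#' @param rules Rule table; defaults to [default_rule_table()].
#' @param fop_thresholds Strict front-of-pack cut-offs per category.
#' @return A list with `products` (fixture product tibble) and `expected`
#'   (one row per fixture with `product_id`, `criterion` and the expected
#'   outcome: `expected_passed` for rule criteria, `expected_fop` for the
#'   flag fixtures).
#' @export
make_boundary_fixtures <- function(rules = default_rule_table(),
                                   fop_thresholds = c(FruitVeg = 30, Cereals = 30, Dairy = 40)) {
  enabled <- rules[rules$applicable & !is.na(rules$threshold) &
                     rules$basis != "marketable", , drop = FALSE]
  rows <- list()
  exp <- list()
  add <- function(id, category, criterion, expected, flags = character(0),
                  energy = 100, prepared = NA, protein = 0, fat = 0,
                  sugar = 0, salt = 0, serving = NA) {
    r <- tibble::tibble(
      product_id = id, name = id, category = category,
      energy_kcal_100g = energy, prepared_energy_kcal_100g = prepared,
      protein_g_100g = protein, fat_g_100g = fat,
      total_sugar_g_100g = sugar, salt_g_100g = salt, serving_g = serving
    )
    for (f in .subcategory_flags) r[[f]] <- f %in% flags
    rows[[length(rows) + 1]] <<- r
    exp[[length(exp) + 1]] <<- tibble::tibble(
      product_id = id, criterion = criterion, expected = expected)
  }
  flags_for_condition <- function(cond) {
    if (is.na(cond)) return(character(0))
    pos <- regmatches(cond, gregexpr("[a-z_]+", cond))[[1]]
    neg <- regmatches(cond, gregexpr("!\\s*[a-z_]+", cond))[[1]]
    neg <- sub("^!\\s*", "", neg, perl = TRUE)
    setdiff(intersect(pos, .subcategory_flags), neg)
  }
  for (i in seq_len(nrow(enabled))) {
    e <- enabled[i, ]
    if (e$criterion == "added_sugar") next # count-based, no numeric boundary
    thr <- e$threshold
    delta <- max(thr * 1e-3, 1e-4)
    pts <- c(at = thr, below = thr - delta, above = thr + delta)
    for (p in names(pts)) {
      v <- pts[[p]]
      expected <- if (e$direction == "le") v <= thr else v >= thr
      id <- paste(e$criterion, e$category, i, p, sep = "_")
      flags <- flags_for_condition(e$condition)
      switch(e$basis,
        kcal_per_100g = add(id, e$category, e$criterion, expected,
                            flags, energy = v),
        kcal_per_100g_prepared = add(id, e$category, e$criterion, expected,
                                     flags, energy = 391, prepared = v),
        kcal_per_serving = add(id, e$category, e$criterion, expected, flags,
                               energy = 400, serving = v / 4),
        g_per_100kcal = {
          if (e$criterion == "protein") {
            add(id, e$category, e$criterion, expected, flags, protein = v)
          } else if (e$criterion == "fat") {
            add(id, e$category, e$criterion, expected, flags, fat = v)
          } else {
            add(id, e$category, e$criterion, expected, flags, salt = v)
          }
        },
        pct_energy = add(id, e$category, e$criterion, expected, flags,
                         sugar = v / 4)
      )
    }
  }
  ## marketability
  add("marketability_Confectionery", "Confectionery", "marketability", FALSE)
  add("marketability_Drinks", "Drinks", "marketability", FALSE)
  add("marketability_Meals", "Meals", "marketability", TRUE)
  ## front-of-pack flag: strict inequality, so the boundary itself is "no flag"
  for (cat in names(fop_thresholds)) {
    thr <- fop_thresholds[[cat]]
    for (p in c("at", "below", "above")) {
      v <- switch(p, at = thr, below = thr - 0.01, above = thr + 0.01)
      id <- paste("fop", cat, p, sep = "_")
      add(id, cat, "fop_required", v > thr, energy = 100, sugar = v / 4)
    }
  }
  products <- dplyr::bind_rows(rows)
  products$ingredients <- "water"
  products$claim_texts <- ""
  products <- check_products(products)
  expected <- dplyr::bind_rows(exp)
  list(products = products, expected = expected)
}
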