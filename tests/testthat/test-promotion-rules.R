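promo_product <- function(id = "p", category = "Meals", claims = "",
                          months = 6L, bf = FALSE, bf_ok = FALSE,
                          spout = FALSE, warning = FALSE, name = "Carrot Stew",
                          ingredients = "carrot:60|potato|water",
                          props = TRUE, prep = TRUE, override = NA) {
  tibble::tibble(
    product_id = id, category = category, name = name,
    lower_age_months = months, claim_texts = claims,
    has_breastfeeding_statement = bf, breastfeeding_statement_adequate = bf_ok,
    has_spout = spout, has_spout_warning = warning,
    has_preparation_instructions = prep, ingredient_proportions_declared = props,
    name_reflects_main_ingredients = override, ingredients = ingredients,
    energy_kcal_100g = 69, total_sugar_g_100g = 2.5,
    has_fop_sugar_flag = FALSE
  )
}

test_that("any nutrition, health or marketing claim fails the claims rule", {
  expect_false(claims_rule(promo_product(claims = "no added sugar"))$passed)
  expect_false(claims_rule(promo_product(claims = "supports healthy growth"))$passed)
  expect_false(claims_rule(promo_product(claims = "100% organic"))$passed)
  expect_true(claims_rule(promo_product(claims = ""))$passed)
  expect_true(claims_rule(promo_product(claims = "store in a cool dry place"))$passed)
  # adding a claim never converts a fail into a pass
  p1 <- promo_product(claims = "tasty")
  p2 <- promo_product(claims = "tasty|no added sugar")
  expect_false(claims_rule(p1)$passed)
  expect_false(claims_rule(p2)$passed)
  expect_gte(claims_rule(p2)$observed, claims_rule(p1)$observed)
})

test_that("age labelling fails under-6-month marketing and missing ages", {
  expect_false(age_label_rule(promo_product(months = 4L))$passed)
  expect_true(age_label_rule(promo_product(months = 6L))$passed)
  expect_false(age_label_rule(promo_product(months = NA_integer_))$passed)
})

test_that("breastfeeding statements must be present and adequate", {
  expect_true(breastfeeding_statement_rule(promo_product(bf = TRUE, bf_ok = TRUE))$passed)
  expect_false(breastfeeding_statement_rule(promo_product(bf = FALSE))$passed)
  expect_false(breastfeeding_statement_rule(promo_product(bf = TRUE, bf_ok = FALSE))$passed)
})

test_that("spout guidance applies to spouted packs only", {
  r <- spout_warning_rule(promo_product(spout = TRUE, warning = FALSE))
  expect_true(r$applicable)
  expect_false(r$passed)
  expect_true(spout_warning_rule(promo_product(spout = TRUE, warning = TRUE))$passed)
  jar <- spout_warning_rule(promo_product(spout = FALSE))
  expect_false(jar$applicable)
  expect_true(is.na(jar$passed))
})

test_that("name clarity matches name tokens against the top ingredients", {
  ok <- promo_product(name = "Apple & Banana Porridge",
                      ingredients = "oat flour|apple|banana")
  expect_true(name_clarity_rule(ok)$passed)
  bad <- promo_product(name = "Strawberry Treat",
                       ingredients = "apple puree|sugar")
  expect_false(name_clarity_rule(bad)$passed)
  # an ingredient beyond the top k does not justify the name
  deep <- promo_product(name = "Strawberry Porridge",
                        ingredients = "oat flour|water|apple|strawberry")
  expect_false(name_clarity_rule(deep)$passed)
  expect_true(name_clarity_rule(deep, k = 4)$passed)
  # a manual adjudication always wins
  forced <- promo_product(name = "Strawberry Treat",
                          ingredients = "apple puree|sugar", override = TRUE)
  expect_true(name_clarity_rule(forced)$passed)
  empty <- promo_product(ingredients = "")
  expect_true(is.na(name_clarity_rule(empty)$passed))
})

test_that("ingredient-list and preparation-instruction requirements", {
  expect_true(ingredient_list_rule(promo_product(props = TRUE))$passed)
  expect_false(ingredient_list_rule(promo_product(props = FALSE))$passed)
  r <- preparation_instructions_rule(promo_product(category = "Cereals", prep = FALSE))
  expect_true(r$applicable)
  expect_false(r$passed)
  snack <- preparation_instructions_rule(promo_product(category = "Snacks"))
  expect_false(snack$applicable)
})

test_that("the FOP label rule applies only where the flag is required", {
  sweet <- promo_product(category = "FruitVeg", ingredients = "apple")
  sweet$total_sugar_g_100g <- 10 # 62 %E at 64 kcal
  sweet$energy_kcal_100g <- 64
  r <- fop_label_rule(sweet)
  expect_true(r$applicable)
  expect_false(r$passed)
  sweet$has_fop_sugar_flag <- TRUE
  expect_true(fop_label_rule(sweet)$passed)
  plain <- promo_product(category = "Meals")
  expect_false(fop_label_rule(plain)$applicable)
})

test_that("promotion verdict is the conjunction of applicable rules, order-free", {
  good <- promo_product(id = "good", bf = TRUE, bf_ok = TRUE)
  bad <- promo_product(id = "bad", bf = TRUE, bf_ok = TRUE,
                       claims = "no added sugar")
  a <- assess_promotion(dplyr::bind_rows(good, bad))
  expect_equal(a$verdicts$promotion_compliant[a$verdicts$product_id == "good"], TRUE)
  expect_equal(a$verdicts$promotion_compliant[a$verdicts$product_id == "bad"], FALSE)
  # reversing input order leaves per-product verdicts unchanged
  b <- assess_promotion(dplyr::bind_rows(bad, good))
  m <- match(a$verdicts$product_id, b$verdicts$product_id)
  expect_equal(b$verdicts$promotion_compliant[m], a$verdicts$promotion_compliant)
  # a not-applicable rule never affects the verdict
  jar <- promo_product(id = "jar", bf = TRUE, bf_ok = TRUE, spout = FALSE, warning = FALSE)
  pouch_ok <- promo_product(id = "pouch", bf = TRUE, bf_ok = TRUE,
                            spout = TRUE, warning = TRUE)
  v <- assess_promotion(dplyr::bind_rows(jar, pouch_ok))$verdicts
  expect_true(all(v$promotion_compliant))
})
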