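test_that("identical seeds reproduce identical output, different seeds differ", {
  a <- generate_products(synthetic_config(n = 120), seed = 31)
  b <- generate_products(synthetic_config(n = 120), seed = 31)
  expect_identical(a, b)
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_products(a$products, path1)
  write_products(b$products, path2)
  expect_identical(readLines(path1), readLines(path2))
  c <- generate_products(synthetic_config(n = 120), seed = 32)
  expect_false(identical(a$products, c$products))
})

test_that("an all-compliant config yields 100 % compliance end to end", {
  cfg <- synthetic_config(
    n = 150,
    overall_fail_rate = c(Cereals = 0, Dairy = 0, FruitVeg = 0, Meals = 0,
                          Snacks = 0, Ingredients = 0, Confectionery = 1, Drinks = 1),
    category_mix = c(Cereals = 0.2, Dairy = 0.1, FruitVeg = 0.3, Meals = 0.25,
                     Snacks = 0.1, Ingredients = 0.05, Confectionery = 0, Drinks = 0),
    promo_rates = c(claims_pass = 1, breastfeeding_pass = 1,
                    spout_prevalence_fruitveg = 0.5, spout_prevalence_meals = 0.1,
                    spout_warning_pass = 1, name_clarity_pass = 1,
                    ingredient_list_pass = 1, ingredient_list_pass_cereals = 1,
                    preparation_instructions_pass = 1, fop_flag_pass = 1),
    age_dist = c(under6 = 0, m6to9 = 0.6, m10to11 = 0.2, m12plus = 0.2)
  )
  sim <- generate_products(cfg, seed = 4)
  a <- assess_products(sim$products)
  expect_true(all(a$verdicts$nutrient_compliant))
  expect_true(all(a$verdicts$promotion_compliant))
})

test_that("pipeline verdicts equal the planted ledger product by product", {
  sim <- generate_products(synthetic_config(n = 600), seed = 101)
  a <- assess_products(sim$products)
  v <- a$verdicts[match(sim$truth$product_id, a$verdicts$product_id), ]
  expect_equal(v$nutrient_compliant, sim$truth$nutrient_compliant)
  expect_equal(v$promotion_compliant, sim$truth$promotion_compliant)
  expect_equal(v$fop_flag_required, sim$truth$fop_required)
  # per-criterion outcomes, not just the verdicts
  crit_cols <- c(energy = "energy_pass", protein = "protein_pass",
                 fat = "fat_pass", sugar_pct = "sugar_pct_pass",
                 added_sugar = "added_sugar_pass", salt = "salt_pass")
  for (cr in names(crit_cols)) {
    got <- a$nutrient_results[a$nutrient_results$criterion == cr, ]
    got <- got[match(sim$truth$product_id, got$product_id), ]
    planted <- sim$truth[[crit_cols[[cr]]]]
    expect_equal(ifelse(got$applicable, got$passed, NA), planted,
                 info = cr)
  }
})

test_that("sample means are calibrated to the configured distributions", {
  cfg <- synthetic_config(
    n = 4000,
    category_mix = c(Cereals = 0, Dairy = 0, FruitVeg = 0.5, Meals = 0.5,
                     Snacks = 0, Ingredients = 0, Confectionery = 0, Drinks = 0),
    overall_fail_rate = c(Cereals = 0, Dairy = 0, FruitVeg = 0, Meals = 0,
                          Snacks = 0, Ingredients = 0, Confectionery = 1, Drinks = 1)
  )
  sim <- generate_products(cfg, seed = 55)
  p <- sim$products
  params <- cfg$nutrient_params
  for (cat in c("FruitVeg", "Meals")) {
    x <- p$energy_kcal_100g[p$category == cat]
    mu <- params$energy_mean[params$category == cat]
    # fully-compliant sampling truncates at the 60 kcal floor, which shifts
    # the mean upward a little; 3 SE around the truncated-normal mean
    sdv <- params$energy_sd[params$category == cat]
    trunc_mean <- mu + sdv * dnorm((60 - mu) / sdv) /
      (1 - pnorm((60 - mu) / sdv))
    expect_lt(abs(mean(x) - trunc_mean), 3 * sd(x) / sqrt(length(x)) + 0.5)
  }
})

test_that("category mix and planted rates land near their targets at scale", {
  sim <- generate_products(synthetic_config(n = 4000), seed = 77)
  p <- sim$products
  mix <- table(p$category)[c("Meals", "FruitVeg", "Snacks")] / nrow(p)
  expect_lt(max(abs(as.vector(mix) - c(178, 139, 76) / 469)), 0.03)
  tr <- sim$truth
  snack_fail <- mean(!tr$nutrient_compliant[tr$category == "Snacks"])
  expect_lt(abs(snack_fail - 0.67), 0.06)
  expect_lt(abs(mean(tr$breastfeeding_pass) - 0.05), 0.015)
  expect_lt(abs(mean(tr$added_sugar_pass %in% FALSE) - 0.19), 0.04)
})

test_that("infeasible configurations error before sampling", {
  expect_error(synthetic_config(n = 0), "positive")
  expect_error(
    synthetic_config(category_mix = c(Cereals = 1, Dairy = 0, FruitVeg = 0,
                                      Meals = 0, Snacks = 0, Ingredients = 0,
                                      Confectionery = 0, Drinks = 0.5)),
    "sum to 1")
  expect_error(
    synthetic_config(overall_fail_rate = c(Cereals = 1.2, Dairy = 0, FruitVeg = 0,
                                           Meals = 0, Snacks = 0, Ingredients = 0,
                                           Confectionery = 1, Drinks = 1)),
    "\\[0, 1\\]")
  expect_error(
    synthetic_config(conditional_fail = c(energy = 0, protein = 0, fat = 0,
                                          sugar_pct = 0, added_sugar = 0, salt = 0)),
    "infeasible")
})

test_that("boundary fixtures receive their expected verdicts", {
  fx <- make_boundary_fixtures()
  a <- assess_nutrients(fx$products)
  rule_exp <- fx$expected[fx$expected$criterion %in% unique(a$results$criterion), ]
  got <- dplyr::inner_join(rule_exp, a$results,
                           by = c("product_id", "criterion"))
  expect_equal(nrow(got), nrow(rule_exp))
  expect_true(all(got$applicable))
  expect_equal(got$passed, got$expected)
  # front-of-pack fixtures: strict at the cut-off
  fop_exp <- fx$expected[fx$expected$criterion == "fop_required", ]
  prods <- fx$products[match(fop_exp$product_id, fx$products$product_id), ]
  flag <- fop_flag_required(prods$category,
                            pct_energy_from_sugar(prods$total_sugar_g_100g,
                                                  prods$energy_kcal_100g))
  expect_equal(flag, fop_exp$expected)
})
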