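meal <- function(energy = 69, protein = 3.1, fat = 2.2, sugar = 2.5,
                 salt = 0.08, savoury = TRUE, meat = FALSE, cheese = FALSE,
                 id = "m") {
  tibble::tibble(
    product_id = id, category = "Meals", energy_kcal_100g = energy,
    protein_g_100g = protein, fat_g_100g = fat, total_sugar_g_100g = sugar,
    salt_g_100g = salt, is_savoury_meal = savoury,
    contains_meat_poultry_fish = meat, contains_cheese = cheese
  )
}

test_that("per-100 kcal conversion is a ratio, identity at 100 kcal", {
  expect_equal(per_100kcal(3.1, 69), 3.1 * 100 / 69, tolerance = 1e-12)
  expect_equal(round(per_100kcal(3.1, 69), 2), 4.49)
  expect_equal(per_100kcal(7.3, 100), 7.3)
  # scale invariance under joint scaling
  expect_equal(per_100kcal(3 * 2.7, 50 * 2.7), per_100kcal(3, 50))
  expect_true(is.na(per_100kcal(3, 0)))
})

test_that("energy rule assesses each category on its printed basis", {
  # meals: >= 60 kcal/100 g inclusive
  expect_true(energy_rule(meal(energy = 60))$passed)
  expect_false(energy_rule(meal(energy = 59.9))$passed)
  # snacks: <= 50 kcal per serving
  snack <- tibble::tibble(product_id = "s", category = "Snacks",
                          energy_kcal_100g = 400, serving_g = 10,
                          total_sugar_g_100g = 5)
  r <- energy_rule(snack)
  expect_equal(r$observed, 40)
  expect_true(r$passed)
  snack$serving_g <- 13
  expect_false(energy_rule(snack)$passed)
  snack$serving_g <- NA_real_
  r <- energy_rule(snack)
  expect_true(r$applicable)
  expect_true(is.na(r$passed)) # not assessable without a serving size
  # dry cereals: prepared energy >= 80, dry label fallback with a note
  cereal <- tibble::tibble(product_id = "c", category = "Cereals",
                           energy_kcal_100g = 391,
                           prepared_energy_kcal_100g = 80)
  expect_true(energy_rule(cereal)$passed)
  cereal$prepared_energy_kcal_100g <- 79
  expect_false(energy_rule(cereal)$passed)
  cereal$prepared_energy_kcal_100g <- NA_real_
  r <- energy_rule(cereal)
  expect_true(r$passed) # 391 on the dry label
  expect_match(r$note, "dry-product")
})

test_that("protein, fat and salt rules follow their per-100 kcal thresholds", {
  # dry cereal with milk <= 5.5 g/100 kcal, boundary inclusive
  cereal <- tibble::tibble(product_id = "c", category = "Cereals",
                           energy_kcal_100g = 100, contains_milk = TRUE,
                           protein_g_100g = 5.5)
  expect_true(protein_rule(cereal)$passed)
  cereal$protein_g_100g <- 5.6
  expect_false(protein_rule(cereal)$passed)
  cereal$contains_milk <- FALSE
  expect_false(protein_rule(cereal)$applicable)
  # savoury meals >= 3; elevated minimum with meat/poultry/fish
  expect_true(protein_rule(meal(energy = 100, protein = 3))$passed)
  expect_false(protein_rule(meal(energy = 100, protein = 2.9))$passed)
  expect_false(protein_rule(meal(energy = 100, protein = 3.5, meat = TRUE))$passed)
  expect_true(protein_rule(meal(energy = 100, protein = 4, meat = TRUE))$passed)
  expect_false(protein_rule(meal(savoury = FALSE))$applicable)
  # fat <= 4.5, meat meals up to 6
  expect_true(fat_rule(meal(energy = 100, fat = 4.5))$passed)
  expect_false(fat_rule(meal(energy = 100, fat = 4.6))$passed)
  expect_true(fat_rule(meal(energy = 100, fat = 6, meat = TRUE))$passed)
  expect_false(fat_rule(meal(energy = 100, fat = 6.1, meat = TRUE))$passed)
  # salt <= 0.125, cheese up to 0.25
  expect_true(salt_rule(meal(energy = 100, salt = 0.125))$passed)
  expect_false(salt_rule(meal(energy = 100, salt = 0.126))$passed)
  expect_true(salt_rule(meal(energy = 100, salt = 0.25, cheese = TRUE))$passed)
  # missing declaration -> not assessable, never a silent pass
  expect_true(is.na(salt_rule(meal(salt = NA))$passed))
})

test_that("sugar %E rule covers meals and non-fruit snacks only", {
  expect_true(sugar_pct_rule(meal(energy = 100, sugar = 15 / 4))$passed)
  r <- sugar_pct_rule(meal()) # 2.5 g, 69 kcal -> 14.5 %E
  expect_equal(r$observed, 2.5 * 4 / 69 * 100, tolerance = 1e-12)
  expect_true(r$passed)
  expect_false(sugar_pct_rule(meal(energy = 100, sugar = 3.76))$passed)
  snack <- tibble::tibble(product_id = "s", category = "Snacks",
                          energy_kcal_100g = 100, total_sugar_g_100g = 10,
                          is_fruit_based_snack = TRUE)
  expect_false(sugar_pct_rule(snack)$applicable)
  snack$is_fruit_based_snack <- FALSE
  expect_true(sugar_pct_rule(snack)$applicable)
  expect_false(sugar_pct_rule(snack)$passed) # 40 %E
})

test_that("confectionery and drinks are non-marketable and never nutrient-compliant", {
  conf <- tibble::tibble(product_id = c("x", "y", "z"),
                         category = c("Confectionery", "Drinks", "Meals"),
                         energy_kcal_100g = 100, protein_g_100g = 3,
                         fat_g_100g = 2, total_sugar_g_100g = 2,
                         salt_g_100g = 0.05, is_savoury_meal = TRUE)
  r <- marketability_rule(conf)
  expect_equal(r$passed, c(FALSE, FALSE, TRUE))
  a <- assess_nutrients(conf)
  v <- a$verdicts
  expect_equal(v$marketable, c(FALSE, FALSE, TRUE))
  expect_equal(v$nutrient_compliant, c(FALSE, FALSE, TRUE))
  # nutrient criteria are skipped, not failed, for non-marketable products
  skipped <- a$results[a$results$product_id == "x" & a$results$criterion != "marketability", ]
  expect_true(all(!skipped$applicable))
})

test_that("overall nutrient verdict fails on any single criterion", {
  ok <- meal(id = "ok")
  bad_salt <- meal(id = "bad", salt = 0.2) # 0.29 g/100 kcal at 69 kcal
  a <- assess_nutrients(dplyr::bind_rows(ok, bad_salt))
  expect_equal(a$verdicts$nutrient_compliant, c(TRUE, FALSE))
  failed <- a$results[a$results$product_id == "bad" & !is.na(a$results$passed) &
                        a$results$applicable & !a$results$passed, ]
  expect_equal(failed$criterion, "salt")
})

test_that("incomplete panels follow the selected policy", {
  p <- meal(salt = NA)
  avail <- assess_nutrients(p, incomplete_policy = "available")
  strict <- assess_nutrients(p, incomplete_policy = "strict")
  expect_true(avail$verdicts$nutrient_compliant)
  expect_true(avail$verdicts$incomplete)
  expect_false(strict$verdicts$nutrient_compliant)
})

test_that("rules are one-sided monotone in their threshold direction", {
  set.seed(11)
  for (i in 1:25) {
    e <- runif(1, 60, 500)
    base <- meal(energy = e, protein = runif(1, 0, 8), fat = runif(1, 0, 8),
                 sugar = runif(1, 0, e / 4), salt = runif(1, 0, 0.6),
                 meat = runif(1) < 0.5)
    worse <- base
    worse$total_sugar_g_100g <- min(base$total_sugar_g_100g * 1.5, e / 4)
    worse$salt_g_100g <- base$salt_g_100g * 1.5
    worse$fat_g_100g <- base$fat_g_100g * 1.5
    better <- base
    better$salt_g_100g <- base$salt_g_100g * 0.5
    # more sugar/salt/fat never turns a fail into a pass
    expect_false(isTRUE(sugar_pct_rule(worse)$passed) && isFALSE(sugar_pct_rule(base)$passed))
    expect_false(isTRUE(salt_rule(worse)$passed) && isFALSE(salt_rule(base)$passed))
    expect_false(isTRUE(fat_rule(worse)$passed) && isFALSE(fat_rule(base)$passed))
    # less salt never turns a pass into a fail
    expect_false(isFALSE(salt_rule(better)$passed) && isTRUE(salt_rule(base)$passed))
  }
})

test_that("toggling a not-applicable criterion's observed value changes nothing", {
  snack <- tibble::tibble(product_id = "s", category = "Snacks",
                          energy_kcal_100g = 400, serving_g = 10,
                          protein_g_100g = 2, fat_g_100g = 3,
                          total_sugar_g_100g = 30, salt_g_100g = 0.1,
                          is_fruit_based_snack = TRUE)
  v1 <- assess_nutrients(snack)$verdicts$nutrient_compliant
  snack$total_sugar_g_100g <- 90 # sugar %E rule not applicable to fruit snacks
  snack$protein_g_100g <- 50 # protein rule not applicable to snacks
  v2 <- assess_nutrients(snack)$verdicts$nutrient_compliant
  expect_identical(v1, v2)
})

test_that("the rule table round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rule_table(default_rule_table(), path)
  back <- read_rule_table(path)
  expect_equal(as.data.frame(back), as.data.frame(default_rule_table()))
})

test_that("an edited threshold takes effect through the config", {
  rules <- default_rule_table()
  rules$threshold[rules$criterion == "salt" & is.na(rules$condition) &
                    rules$category == "Meals"] <- 0.05
  expect_false(salt_rule(meal(energy = 100, salt = 0.1), rules)$passed)
  expect_true(salt_rule(meal(energy = 100, salt = 0.05), rules)$passed)
})
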