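test_that("lower marketed age is extracted from label strings", {
  # hand-assigned truths over the label variants seen on UK packs
  labels <- c(
    "from 4 months", "4 months+", "6 months+", "6-9 months", "6–9 months",
    "10-11 months", "12-24 months", "12–36 months", "from 7 months",
    "suitable from 6 months", "1 year+", "2 years+", "1-3 years",
    "from 10 mths", "8m+", "stage 1 (from 4 months)", "toddler", "",
    NA, "36 months"
  )
  truth <- c(4, 4, 6, 6, 6, 10, 12, 12, 7, 6, 12, 24, 12, 10, 8, 4, NA, NA, NA, 36)
  expect_equal(parse_lower_age(labels), as.integer(truth))
})

test_that("age buckets are total and monotone in months", {
  expect_equal(as.character(bucket_age(c(0, 4, 5, 6, 9, 10, 11, 12, 24, 48))),
               c("under6", "under6", "under6", "m6to9", "m6to9",
                 "m10to11", "m10to11", "m12plus", "m12plus", "m12plus"))
  expect_true(is.na(bucket_age(NA)))
  b <- as.integer(bucket_age(0:48))
  expect_true(all(diff(b) >= 0))
})

test_that("a header-only file yields an empty table and empty ledger", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("product_id", "brand", "name", "category"), collapse = ","), path)
  res <- read_products(path)
  expect_equal(nrow(res$products), 0)
  expect_equal(nrow(res$errors), 0)
})

test_that("valid rows become product records with their per-100g values", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    product_id = "m1", brand = "B", name = "Veg Stew", category = "Meals",
    subcategory_flags = "is_savoury_meal;contains_meat_poultry_fish",
    age_label = "from 6 months",
    energy_kcal_100g = 69, protein_g_100g = 3.1, fat_g_100g = 2.2,
    total_sugar_g_100g = 2.5, salt_g_100g = 0.08
  ), path)
  res <- read_products(path)
  expect_equal(nrow(res$products), 1)
  p <- res$products
  expect_equal(p$category, "Meals")
  expect_equal(p$energy_kcal_100g, 69)
  expect_equal(p$protein_g_100g, 3.1)
  expect_equal(p$fat_g_100g, 2.2)
  expect_equal(p$total_sugar_g_100g, 2.5)
  expect_equal(p$salt_g_100g, 0.08)
  expect_true(p$is_savoury_meal)
  expect_true(p$contains_meat_poultry_fish)
  expect_false(p$contains_cheese)
  expect_equal(p$lower_age_months, 6L)
})

test_that("invalid rows go to the error ledger; nothing is dropped silently", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    product_id = c("a", "b", "c", "d"),
    name = c("ok", "bad cat", "neg", "odd age"),
    category = c("Meals", "Sweets", "Meals", "Meals"),
    age_label = c("from 6 months", "from 6 months", "from 6 months", "sometime"),
    energy_kcal_100g = c(70, 70, -5, 70),
    protein_g_100g = 3, fat_g_100g = 2, total_sugar_g_100g = 2,
    salt_g_100g = 0.05
  ), path)
  res <- read_products(path)
  # rejected: unknown category + negative nutrient; kept with warning: bad age
  expect_equal(sort(res$products$product_id), c("a", "d"))
  rejected <- res$errors[res$errors$severity == "error", ]
  expect_setequal(rejected$product_id, c("b", "c"))
  expect_true(any(grepl("unknown category", rejected$reason)))
  expect_true(any(grepl("negative", rejected$reason)))
  warned <- res$errors[res$errors$severity == "warning", ]
  expect_equal(warned$product_id, "d")
  expect_true(is.na(res$products$lower_age_months[res$products$product_id == "d"]))
  # rows are conserved between table and ledger
  expect_equal(nrow(res$products) + length(unique(rejected$row)), 4)
})

test_that("decimal commas and sodium are normalized on input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    'product_id,name,category,age_label,energy_kcal_100g,protein_g_100g,fat_g_100g,total_sugar_g_100g,sodium_mg_100g',
    'x,Puree,Fruit & Vegetable,from 6 months,"64,5","1,3","1,1","8,6",32'
  ), path)
  res <- read_products(path)
  expect_equal(res$products$energy_kcal_100g, 64.5)
  expect_equal(res$products$category, "FruitVeg")
  expect_equal(res$products$salt_g_100g, 32 * 2.5 / 1000)
})

test_that("the template dialect maps column names onto the canonical schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    `Product ID` = "t1", `Product name` = "Oat Porridge", Category = "Cereals",
    `Age recommendation` = "4 months+", `Energy (kcal/100g)` = 390,
    `Energy prepared (kcal/100g)` = 85, `Protein (g/100g)` = 12,
    `Fat (g/100g)` = 5, `Total sugar (g/100g)` = 15, `Salt (g/100g)` = 0.2
  ), path)
  res <- read_products(path, dialect = "template")
  expect_equal(res$products$prepared_energy_kcal_100g, 85)
  expect_equal(res$products$lower_age_months, 4L)
})

test_that("writing and re-reading a product table is lossless", {
  sim <- generate_products(synthetic_config(n = 60), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_products(sim$products, path)
  back <- read_products(path)
  expect_equal(nrow(back$errors), 0)
  cols <- intersect(names(sim$products), names(back$products))
  expect_equal(as.data.frame(back$products[cols]),
               as.data.frame(sim$products[cols]))
})
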