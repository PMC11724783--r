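## Canonical column order for the product CSV schema.
canonical_columns <- function() {
  c("product_id", "brand", "name", "category", "subcategory_flags", "age_label",
    "energy_kcal_100g", "prepared_energy_kcal_100g", "protein_g_100g",
    "fat_g_100g", "total_sugar_g_100g", "salt_g_100g", "serving_g",
    "ingredients", "claim_texts", "has_breastfeeding_statement",
    "breastfeeding_statement_adequate", "has_preparation_instructions",
    "has_spout", "has_spout_warning", "has_fop_sugar_flag",
    "name_reflects_main_ingredients", "ingredient_proportions_declared")
}

numeric_columns <- function() {
  c("energy_kcal_100g", "prepared_energy_kcal_100g", "protein_g_100g",
    "fat_g_100g", "total_sugar_g_100g", "salt_g_100g", "serving_g")
}

boolean_columns <- function() {
  c("has_breastfeeding_statement", "breastfeeding_statement_adequate",
    "has_preparation_instructions", "has_spout", "has_spout_warning",
    "has_fop_sugar_flag", "name_reflects_main_ingredients",
    "ingredient_proportions_declared")
}

## Category synonyms accepted on input (website wording, spelling variants).
category_synonyms <- function() {
  c("cereals" = "Cereals",
    "dairy" = "Dairy",
    "fruitveg" = "FruitVeg",
    "fruit & vegetable" = "FruitVeg",
    "fruit and vegetables" = "FruitVeg",
    "fruit & vegetables" = "FruitVeg",
    "fruit and vegetable" = "FruitVeg",
    "meals" = "Meals",
    "meals and meal components" = "Meals",
    "snacks" = "Snacks",
    "snacks and finger foods" = "Snacks",
    "ingredients" = "Ingredients",
    "ingredient" = "Ingredients",
    "confectionery" = "Confectionery",
    "confectionary" = "Confectionery",
    "drinks" = "Drinks",
    "drink" = "Drinks")
}

normalize_category <- function(x) {
  unname(category_synonyms()[normalize_text(x)])
}

#' Parse the lower marketed age from a label string
#'
#' Extracts the minimum recommended age, in months, from free-text age
#' labels such as `"from 4 months"`, `"6 months+"`, `"12-24 months"` or
#' `"1 year+"`. Ranges return their lower bound; years are converted to
#' months; when several age tokens appear the smallest wins.
#'
#' @param label_text Character vector of label strings.
#' @return Integer vector of months, `NA` where no age token is found.
#' @export
#' @examples
#' parse_lower_age(c("from 4 months", "6 months+", "12-24 months", "no age"))
parse_lower_age <- function(label_text) {
  vapply(label_text, function(txt) {
    if (is.na(txt) || !nzchar(trimws(txt))) return(NA_integer_)
    s <- normalize_text(txt)
    s <- gsub("–|—", "-", s) # en/em dash
    months <- integer(0)
    m <- regmatches(s, gregexpr("(\\d+)\\s*(?:-|to)\\s*\\d+\\s*\\+?\\s*(months?|mths?|mos?|m\\b)", s, perl = TRUE))[[1]]
    months <- c(months, as.integer(sub("^(\\d+).*", "\\1", m)))
    m <- regmatches(s, gregexpr("(\\d+)\\s*\\+?\\s*(months?|mths?|mos?|m\\b)", s, perl = TRUE))[[1]]
    months <- c(months, as.integer(sub("^(\\d+).*", "\\1", m)))
    m <- regmatches(s, gregexpr("(\\d+)\\s*(?:-|to)\\s*\\d+\\s*\\+?\\s*(years?|yrs?|y\\b)", s, perl = TRUE))[[1]]
    months <- c(months, 12L * as.integer(sub("^(\\d+).*", "\\1", m)))
    m <- regmatches(s, gregexpr("(\\d+)\\s*\\+?\\s*(years?|yrs?|y\\b)", s, perl = TRUE))[[1]]
    months <- c(months, 12L * as.integer(sub("^(\\d+).*", "\\1", m)))
    if (length(months) == 0) return(NA_integer_)
    min(months)
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign an age band to a lower recommended age
#'
#' Buckets months into the four reporting bands used for age-stratified
#' compliance tables: under 6 months, 6–9, 10–11, and 12 months or older.
#'
#' @param months Integer vector of lower recommended ages in months.
#' @return Factor with levels `under6`, `m6to9`, `m10to11`, `m12plus`;
#'   `NA` for missing months.
#' @export
#' @examples
#' bucket_age(c(4, 6, 9, 10, 11, 12, 24))
bucket_age <- function(months) {
  lab <- dplyr::case_when(
    is.na(months) ~ NA_character_,
    months < 6 ~ "under6",
    months <= 9 ~ "m6to9",
    months <= 11 ~ "m10to11",
    TRUE ~ "m12plus"
  )
  factor(lab, levels = c("under6", "m6to9", "m10to11", "m12plus"))
}

## Accept decimal commas and stray unit text in numeric label fields.
parse_label_number <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "NA", "na", "n/a", "-")] <- NA_character_
  x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

parse_label_boolean <- function(x) {
  s <- normalize_text(ifelse(is.na(x), "", x))
  out <- rep(NA, length(x))
  out[s %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[s %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Read a product table
#'
#' Reads a labelled product table in the package's canonical CSV schema (or
#' a template dialect mapped onto it), normalizes categories and ages,
#' expands subcategory flags, and validates each row. Rows that cannot be
#' assessed at all (unknown category, negative nutrient, nutrient mass above
#' 100 g/100 g, implausible age) are rejected into an error ledger with the
#' row number and reason; recoverable problems (an unparseable age label)
#' are kept with a warning entry. Nothing is dropped silently: every input
#' row appears either in the product table or in the error ledger.
#'
#' A `sodium_mg_100g` column, if present, fills a missing salt value using
#' the standard conversion salt (g) = sodium (mg) x 2.5 / 1000. Decimal
#' commas in numeric fields are accepted.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect `"canonical"` for the package schema; `"template"` to remap
#'   column names first via `mapping`.
#' @param mapping For the template dialect: a data frame (or path to a
#'   two-column CSV) with columns `template_column`, `canonical_column`.
#' @return A list with `products` (validated product tibble) and `errors`
#'   (ledger tibble with `row`, `product_id`, `field`, `reason`, `severity`;
#'   severity `"error"` rows were rejected, `"warning"` rows were kept).
#' @seealso [write_products()], [assess_products()]
#' @export
read_products <- function(path, dialect = c("canonical", "template"), mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (dialect == "template") {
    if (is.character(mapping)) {
      mapping <- readr::read_csv(mapping, show_col_types = FALSE, progress = FALSE)
    }
    if (is.null(mapping)) {
      mapping <- readr::read_csv(
        system.file("extdata", "template_column_mapping.csv", package = "nppm"),
        show_col_types = FALSE, progress = FALSE)
    }
    idx <- match(names(raw), mapping$template_column)
    names(raw)[!is.na(idx)] <- mapping$canonical_column[idx[!is.na(idx)]]
  }
  validate_products(raw)
}

## Validate a raw character table into a product tibble + error ledger.
validate_products <- function(raw) {
  err <- tibble::tibble(row = integer(), product_id = character(),
                        field = character(), reason = character(),
                        severity = character())
  for (col in setdiff(canonical_columns(), names(raw))) raw[[col]] <- NA_character_
  n <- nrow(raw)
  if (n == 0) {
    return(list(products = empty_products(), errors = err))
  }
  id <- ifelse(is.na(raw$product_id) | !nzchar(raw$product_id),
               sprintf("row%04d", seq_len(n)), raw$product_id)

  add_err <- function(err, rows, field, reason, severity) {
    if (length(rows) == 0) return(err)
    dplyr::bind_rows(err, tibble::tibble(
      row = rows, product_id = id[rows], field = field,
      reason = reason, severity = severity))
  }

  category <- normalize_category(raw$category)
  bad <- which(is.na(category))
  err <- add_err(err, bad, "category", "unknown category", "error")

  nums <- lapply(numeric_columns(), function(col) parse_label_number(raw[[col]]))
  names(nums) <- numeric_columns()
  for (col in numeric_columns()) {
    bad_neg <- which(!is.na(nums[[col]]) & nums[[col]] < 0)
    err <- add_err(err, bad_neg, col, "negative value", "error")
  }
  ## sodium fallback for salt
  if ("sodium_mg_100g" %in% names(raw)) {
    sodium <- parse_label_number(raw$sodium_mg_100g)
    use <- is.na(nums$salt_g_100g) & !is.na(sodium) & sodium >= 0
    nums$salt_g_100g[use] <- sodium[use] * 2.5 / 1000
  }
  for (col in c("protein_g_100g", "fat_g_100g", "total_sugar_g_100g")) {
    bad_big <- which(!is.na(nums[[col]]) & nums[[col]] > 100)
    err <- add_err(err, bad_big, col, "mass exceeds 100 g per 100 g", "error")
  }

  months <- parse_lower_age(raw$age_label)
  unparsed <- which(is.na(months) & !is.na(raw$age_label) & nzchar(trimws(raw$age_label)))
  err <- add_err(err, unparsed, "age_label", "unparseable age label; age set missing", "warning")
  bad_age <- which(!is.na(months) & (months < 0 | months > 48))
  err <- add_err(err, bad_age, "age_label", "age outside 0-48 months", "error")

  flags <- parse_flag_tokens(raw$subcategory_flags)
  bools <- lapply(boolean_columns(), function(col) parse_label_boolean(raw[[col]]))
  names(bools) <- boolean_columns()

  products <- tibble::tibble(
    product_id = id,
    brand = raw$brand %||% NA_character_,
    name = raw$name,
    category = category,
    age_label = raw$age_label,
    lower_age_months = months,
    age_bucket = bucket_age(months)
  )
  products <- dplyr::bind_cols(products, flags, tibble::as_tibble(nums))
  products$ingredients <- ifelse(is.na(raw$ingredients), "", raw$ingredients)
  products$claim_texts <- ifelse(is.na(raw$claim_texts), "", raw$claim_texts)
  products <- dplyr::bind_cols(products, tibble::as_tibble(bools))

  rejected <- sort(unique(err$row[err$severity == "error"]))
  list(products = products[setdiff(seq_len(n), rejected), , drop = FALSE],
       errors = err[order(err$row), , drop = FALSE])
}

parse_flag_tokens <- function(x) {
  toks <- strsplit(ifelse(is.na(x), "", normalize_text(x)), ";", fixed = TRUE)
  toks <- lapply(toks, trimws)
  out <- lapply(.subcategory_flags, function(f) {
    vapply(toks, function(t) f %in% t, logical(1))
  })
  names(out) <- .subcategory_flags
  tibble::as_tibble(out)
}

empty_products <- function() {
  base <- tibble::tibble(
    product_id = character(0), brand = character(0), name = character(0),
    category = character(0), age_label = character(0),
    lower_age_months = integer(0), age_bucket = bucket_age(integer(0))
  )
  for (f in .subcategory_flags) base[[f]] <- logical(0)
  for (col in numeric_columns()) base[[col]] <- numeric(0)
  base$ingredients <- character(0)
  base$claim_texts <- character(0)
  for (col in boolean_columns()) base[[col]] <- logical(0)
  base
}

#' Write a product table to the canonical CSV schema
#'
#' Inverse of [read_products()]: a table written here and re-read yields
#' identical records.
#'
#' @param products A product tibble as returned by [read_products()] or
#'   [generate_products()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path) {
  flags <- apply(as.matrix(products[, .subcategory_flags, drop = FALSE]), 1, function(r) {
    paste(.subcategory_flags[as.logical(r)], collapse = ";")
  })
  out <- tibble::tibble(
    product_id = products$product_id,
    brand = products$brand,
    name = products$name,
    category = products$category,
    subcategory_flags = flags,
    age_label = products$age_label
  )
  for (col in numeric_columns()) out[[col]] <- products[[col]]
  out$ingredients <- products$ingredients
  out$claim_texts <- products$claim_texts
  for (col in boolean_columns()) out[[col]] <- products[[col]]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

## Ensure a hand-built data frame has every column the rule engine touches.
check_products <- function(products) {
  products <- tibble::as_tibble(products)
  if (!"category" %in% names(products)) {
    stop("product table needs a 'category' column", call. = FALSE)
  }
  bad <- setdiff(unique(products$category), nppm_categories())
  if (length(bad) > 0) {
    stop("unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(products)
  defaults <- c(
    sapply(.subcategory_flags, function(x) FALSE, simplify = FALSE),
    sapply(numeric_columns(), function(x) NA_real_, simplify = FALSE),
    sapply(boolean_columns(), function(x) NA, simplify = FALSE),
    list(product_id = sprintf("p%04d", seq_len(max(n, 1)))[seq_len(n)],
         name = NA_character_, brand = NA_character_,
         lower_age_months = NA_integer_, ingredients = "", claim_texts = "")
  )
  for (col in names(defaults)) {
    if (!col %in% names(products)) products[[col]] <- rep_len(defaults[[col]], n)
  }
  if (!"age_bucket" %in% names(products)) {
    products$age_bucket <- bucket_age(products$lower_age_months)
  }
  products
}

#' Split a packed ingredient field into names and declared percentages
#'
#' The canonical schema stores the ordered ingredient list as
#' `"name[:percent]|name[:percent]|..."`.
#'
#' @param x Character vector of packed ingredient fields.
#' @return A list of tibbles with columns `ingredient` and `percent`.
#' @export
#' @examples
#' parse_ingredients("apple puree:60|banana:30|oat flour")
parse_ingredients <- function(x) {
  lapply(ifelse(is.na(x), "", x), function(s) {
    if (!nzchar(trimws(s))) {
      return(tibble::tibble(ingredient = character(0), percent = numeric(0)))
    }
    parts <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    has_pct <- grepl(":", parts, fixed = TRUE)
    name <- ifelse(has_pct, sub(":.*$", "", parts), parts)
    pct <- rep(NA_real_, length(parts))
    pct[has_pct] <- parse_label_number(sub("^.*:", "", parts[has_pct]))
    tibble::tibble(ingredient = trimws(name), percent = pct)
  })
}

split_claims <- function(x) {
  lapply(ifelse(is.na(x), "", x), function(s) {
    if (!nzchar(trimws(s))) return(character(0))
    out <- trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    out[nzchar(out)]
  })
}
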