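# Independent brute-force evaluator used as an oracle against the rule
# engine. It loops product by product, re-reads thresholds directly from the
# rule-table config, recomputes observed values with plain arithmetic and
# compares with bare <=/>= — sharing no code with the vectorized engine.

brute_force_assess <- function(products, rules, lexicon = default_sugar_lexicon()) {
  flags <- c("is_dry_cereal", "contains_milk", "is_savoury_meal",
             "contains_meat_poultry_fish", "contains_cheese",
             "is_fruit_based_snack", "is_puree_with_spout")
  prohibited <- tolower(lexicon$pattern[lexicon$class %in% c("added", "free")])
  criteria <- unique(rules$criterion[rules$applicable])
  out <- list()
  for (i in seq_len(nrow(products))) {
    p <- as.list(products[i, ])
    env <- p[flags]
    nonmarket <- p$category %in% c("Confectionery", "Drinks")
    for (cr in criteria) {
      cand <- rules[rules$criterion == cr & rules$category == p$category, , drop = FALSE]
      best <- NULL
      for (j in seq_len(nrow(cand))) {
        cond_ok <- if (is.na(cand$condition[j])) TRUE else
          isTRUE(eval(parse(text = cand$condition[j]), envir = env))
        if (cond_ok && (is.null(best) || cand$priority[j] > best$priority)) {
          best <- as.list(cand[j, ])
        }
      }
      if (is.null(best)) next
      applicable <- best$applicable && !(nonmarket && cr != "marketability")
      obs <- NA_real_
      if (applicable) {
        obs <- switch(best$basis,
          kcal_per_100g = p$energy_kcal_100g,
          kcal_per_100g_prepared = if (!is.na(p$prepared_energy_kcal_100g))
            p$prepared_energy_kcal_100g else p$energy_kcal_100g,
          kcal_per_serving = p$energy_kcal_100g * p$serving_g / 100,
          g_per_100kcal = {
            col <- c(protein = "protein_g_100g", fat = "fat_g_100g",
                     salt = "salt_g_100g")[[cr]]
            if (is.na(p$energy_kcal_100g) || p$energy_kcal_100g <= 0) NA_real_
            else p[[col]] * 100 / p$energy_kcal_100g
          },
          pct_energy = if (is.na(p$energy_kcal_100g) || p$energy_kcal_100g <= 0)
            NA_real_ else p$total_sugar_g_100g * 4 / p$energy_kcal_100g * 100,
          marketable = as.numeric(!nonmarket),
          prohibited_ingredient_count = {
            ings <- strsplit(p$ingredients, "|", fixed = TRUE)[[1]]
            ings <- tolower(sub(":.*$", "", trimws(ings)))
            sum(vapply(ings, function(s)
              any(vapply(prohibited, function(pp) grepl(pp, s, fixed = TRUE),
                         logical(1))), logical(1)))
          })
      }
      passed <- if (!applicable || is.na(obs)) NA else
        if (best$direction == "le") obs <= best$threshold else obs >= best$threshold
      out[[length(out) + 1]] <- data.frame(
        product_id = p$product_id, criterion = cr,
        applicable = applicable, passed = passed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  verdict <- tapply(seq_len(nrow(res)), res$product_id, function(idx) {
    r <- res[idx, ]
    all(r$passed[r$applicable & !is.na(r$passed)])
  })
  nonmarket <- products$category %in% c("Confectionery", "Drinks")
  names(nonmarket) <- products$product_id
  verdict[names(verdict)] <- verdict[names(verdict)] & !nonmarket[names(verdict)]
  list(results = res, verdicts = verdict)
}

# Grid of synthetic products spanning each enabled threshold +/-10 % in 1 %
# steps, for every applicable category/condition, replicated with varied
# background nutrients and ingredient lists.
make_grid_products <- function(rules, n_variants = 4, seed = 202) {
  set.seed(seed)
  enabled <- rules[rules$applicable & !is.na(rules$threshold) &
                     !rules$basis %in% c("marketable", "prohibited_ingredient_count"), ,
                   drop = FALSE]
  flags_for_condition <- function(cond) {
    if (is.na(cond)) return(character(0))
    pos <- regmatches(cond, gregexpr("[a-z_]+", cond))[[1]]
    neg <- sub("^!\\s*", "",
               regmatches(cond, gregexpr("!\\s*[a-z_]+", cond))[[1]], perl = TRUE)
    setdiff(pos, neg)
  }
  all_flags <- c("is_dry_cereal", "contains_milk", "is_savoury_meal",
                 "contains_meat_poultry_fish", "contains_cheese",
                 "is_fruit_based_snack", "is_puree_with_spout")
  ing_pool <- c("water", "apple", "carrot", "sugar", "honey", "whole milk", "oat flour")
  rows <- list()
  for (i in seq_len(nrow(enabled))) {
    e <- enabled[i, ]
    fl <- flags_for_condition(e$condition)
    for (mult in seq(0.90, 1.10, by = 0.01)) {
      v <- e$threshold * mult
      for (k in seq_len(n_variants)) {
        r <- data.frame(
          product_id = sprintf("grid_%03d_%0.2f_%d", i, mult, k),
          name = "grid", category = e$category,
          energy_kcal_100g = 100,
          prepared_energy_kcal_100g = NA_real_,
          protein_g_100g = round(runif(1, 0, 8), 2),
          fat_g_100g = round(runif(1, 0, 7), 2),
          total_sugar_g_100g = round(runif(1, 0, 20), 2),
          salt_g_100g = round(runif(1, 0, 0.4), 3),
          serving_g = round(runif(1, 5, 40), 1),
          ingredients = paste(sample(ing_pool, sample(2:4, 1)), collapse = "|"),
          stringsAsFactors = FALSE)
        for (f in all_flags) r[[f]] <- f %in% fl
        if (e$basis == "kcal_per_100g") r$energy_kcal_100g <- v
        if (e$basis == "kcal_per_100g_prepared") {
          r$energy_kcal_100g <- 391
          r$prepared_energy_kcal_100g <- v
        }
        if (e$basis == "kcal_per_serving") {
          r$energy_kcal_100g <- 400
          r$serving_g <- v / 4
        }
        if (e$basis == "g_per_100kcal") {
          col <- c(protein = "protein_g_100g", fat = "fat_g_100g",
                   salt = "salt_g_100g")[[e$criterion]]
          r[[col]] <- v
        }
        if (e$basis == "pct_energy") r$total_sugar_g_100g <- v / 4
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  dplyr::bind_rows(rows)
}
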