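#' Mean with a t-based 95 percent confidence interval
#'
#' mean +/- t(1 - alpha/2, n - 1) x sd / sqrt(n). With one observation the
#' interval is undefined and `NA` bounds are returned; missing values are
#' dropped.
#'
#' @param values Numeric vector.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `n`, `mean`, `lower`, `upper`.
#' @export
#' @examples
#' mean_ci(c(1, 3))
mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("mean_ci needs at least one non-missing value", call. = FALSE)
  m <- mean(values)
  if (n == 1) {
    return(tibble::tibble(n = n, mean = m, lower = NA_real_, upper = NA_real_))
  }
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  tibble::tibble(n = n, mean = m, lower = m - half, upper = m + half)
}

#' One-way analysis of variance across groups
#'
#' Classical equal-variance one-way ANOVA (between/within decomposition of
#' the sum of squares), used to compare nutrient content across product
#' categories. Groups with fewer than `min_group_n` observations are
#' excluded (the single-product ingredients category in a realistic
#' assortment cannot contribute a within-group variance).
#'
#' @param groups A named list of numeric vectors, one per group.
#' @param min_group_n Minimum group size to enter the comparison (default 2).
#' @return A tibble with `f`, `df_between`, `df_within`, `p_value`,
#'   `n_groups`, `n_total`, and `degenerate` (`TRUE` when every within-group
#'   variance is zero but means differ, in which case `p_value` is reported
#'   as 0 with this flag raised).
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
one_way_anova <- function(groups, min_group_n = 2) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) >= min_group_n]
  k <- length(groups)
  if (k < 2) stop("one_way_anova needs at least two groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), vapply(groups, length, integer(1))))
  n <- length(values)
  within_var <- vapply(groups, function(x) stats::var(x), numeric(1))
  means <- vapply(groups, mean, numeric(1))
  if (all(within_var == 0) && length(unique(means)) > 1) {
    return(tibble::tibble(f = Inf, df_between = k - 1, df_within = n - k,
                          p_value = 0, n_groups = k, n_total = n,
                          degenerate = TRUE))
  }
  fit <- oneway.test(values ~ g, var.equal = TRUE)
  tibble::tibble(
    f = unname(fit$statistic),
    df_between = unname(fit$parameter[1]),
    df_within = unname(fit$parameter[2]),
    p_value = unname(fit$p.value),
    n_groups = k, n_total = n, degenerate = FALSE
  )
}

#' Per-category nutrient summary with confidence intervals and ANOVA
#'
#' Reproduces the shape of a published nutrient-composition table: for each
#' category, n and mean (95 percent CI) of energy, protein, fat, total
#' sugar and salt, on the per-100 g or per-100 kcal basis, plus a one-way
#' ANOVA p-value per nutrient comparing categories. On the per-100 kcal
#' basis energy stays in kcal/100 g and sugar is expressed as percent of
#' energy, matching reporting practice for this model. Non-marketable
#' categories (confectionery, drinks) are excluded — they are not assessed —
#' as are categories below `min_group_n`.
#'
#' @param products A product tibble.
#' @param basis `"per_100g"` or `"per_100kcal"`.
#' @param level Confidence level for the intervals.
#' @param min_group_n Minimum category size to be summarised (default 2).
#' @return A list with `summary` (category x nutrient tibble of n, mean,
#'   lower, upper) and `anova` (one row per nutrient).
#' @export
nutrient_summary <- function(products, basis = c("per_100g", "per_100kcal"),
                             level = 0.95, min_group_n = 2) {
  basis <- match.arg(basis)
  products <- check_products(products)
  products <- products[!products$category %in% non_marketable_categories(), , drop = FALSE]
  vals <- tibble::tibble(
    category = products$category,
    energy = products$energy_kcal_100g,
    protein = products$protein_g_100g,
    fat = products$fat_g_100g,
    sugar = products$total_sugar_g_100g,
    salt = products$salt_g_100g
  )
  if (basis == "per_100kcal") {
    e <- products$energy_kcal_100g
    vals$protein <- per_100kcal(vals$protein, e)
    vals$fat <- per_100kcal(vals$fat, e)
    vals$salt <- per_100kcal(vals$salt, e)
    vals$sugar <- pct_energy_from_sugar(vals$sugar, e)
  }
  keep <- names(which(table(vals$category) >= min_group_n))
  vals <- vals[vals$category %in% keep, , drop = FALSE]
  if (nrow(vals) == 0) {
    empty_sum <- tibble::tibble(category = character(0), nutrient = character(0),
                                n = integer(0), mean = numeric(0),
                                lower = numeric(0), upper = numeric(0))
    empty_anova <- tibble::tibble(nutrient = character(0), f = numeric(0),
                                  df_between = numeric(0), df_within = numeric(0),
                                  p_value = numeric(0), n_groups = integer(0),
                                  n_total = integer(0), degenerate = logical(0))
    return(list(summary = empty_sum, anova = empty_anova, basis = basis))
  }
  long <- tidyr::pivot_longer(vals, -"category",
                              names_to = "nutrient", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$category, .data$nutrient) |>
    dplyr::reframe(mean_ci(.data$value, level = level)) |>
    dplyr::arrange(match(.data$category, nppm_categories()),
                   match(.data$nutrient, c("energy", "protein", "fat", "sugar", "salt")))
  anova <- long |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::reframe(one_way_anova(split(.data$value, .data$category),
                                 min_group_n = min_group_n))
  list(summary = summary, anova = anova, basis = basis)
}

#' Compliance counts and rates by stratum
#'
#' Aggregates an assessment (see [assess_products()]) into the compliance
#' tables the model's reports print: per stratum and criterion, the number
#' of products the criterion applies to, how many fail, and the fail
#' percentage (rounded half-up to whole percent for report parity), plus an
#' `overall` row per stratum using the any-fail verdict. Not-applicable and
#' not-assessable rule results are excluded from denominators.
#'
#' @param assessment The list returned by [assess_products()].
#' @param by Stratifier: `"category"`, `"age_bucket"`, or `"criterion"`
#'   (no stratification; one row per criterion over all products).
#' @param which `"nutrient"`, `"promotion"`, or `"both"` (default) — which
#'   rule family to tabulate.
#' @return A tibble with `stratum`, `criterion`, `n_applicable`, `n_fail`,
#'   `pct_fail`, `pct_pass`. Overall rows carry criterion `"overall"` and
#'   use all products in the stratum as denominator (non-marketable
#'   products count as failing overall, since they must not be marketed at
#'   all). Empty strata are omitted.
#' @export
compliance_table <- function(assessment, by = c("category", "age_bucket", "criterion"),
                             which = c("both", "nutrient", "promotion")) {
  by <- match.arg(by)
  which <- match.arg(which)
  results <- switch(which,
    nutrient = assessment$nutrient_results,
    promotion = assessment$promotion_results,
    both = dplyr::bind_rows(assessment$nutrient_results, assessment$promotion_results)
  )
  verdicts <- assessment$verdicts
  strat <- switch(by,
    category = verdicts |> dplyr::select("product_id", stratum = "category"),
    age_bucket = verdicts |>
      dplyr::mutate(stratum = as.character(.data$age_bucket)) |>
      dplyr::select("product_id", "stratum"),
    criterion = verdicts |>
      dplyr::mutate(stratum = "all") |>
      dplyr::select("product_id", "stratum")
  )
  per_criterion <- results |>
    dplyr::inner_join(strat, by = "product_id") |>
    dplyr::filter(.data$applicable, !is.na(.data$passed)) |>
    dplyr::group_by(.data$stratum, .data$criterion) |>
    dplyr::summarise(
      n_applicable = dplyr::n(),
      n_fail = sum(!.data$passed),
      .groups = "drop"
    )
  overall_flag <- switch(which,
    nutrient = !verdicts$nutrient_compliant,
    promotion = !verdicts$promotion_compliant,
    both = !(verdicts$nutrient_compliant & verdicts$promotion_compliant)
  )
  overall <- tibble::tibble(product_id = verdicts$product_id, fail = overall_flag) |>
    dplyr::inner_join(strat, by = "product_id") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(criterion = "overall", n_applicable = dplyr::n(),
                     n_fail = sum(.data$fail), .groups = "drop")
  out <- dplyr::bind_rows(per_criterion, overall) |>
    dplyr::filter(!is.na(.data$stratum)) |>
    dplyr::mutate(
      pct_fail = round_half_up(100 * .data$n_fail / .data$n_applicable),
      pct_pass = round_half_up(100 * (.data$n_applicable - .data$n_fail) / .data$n_applicable)
    ) |>
    dplyr::arrange(.data$stratum, .data$criterion)
  out
}

#' Category and age-band product counts
#'
#' The descriptive breakdown of an assortment: how many products fall in
#' each category and each lower-age band, with percentages of the total.
#'
#' @param products A product tibble.
#' @return A tibble with `dimension` (`category`/`age_band`), `level`,
#'   `n`, `pct`.
#' @export
product_counts <- function(products) {
  products <- check_products(products)
  n_total <- nrow(products)
  cat_tab <- products |>
    dplyr::count(level = .data$category) |>
    dplyr::mutate(dimension = "category")
  age_tab <- products |>
    dplyr::filter(!is.na(.data$age_bucket)) |>
    dplyr::count(level = as.character(.data$age_bucket)) |>
    dplyr::mutate(dimension = "age_band")
  dplyr::bind_rows(cat_tab, age_tab) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / n_total)) |>
    dplyr::select("dimension", "level", "n", "pct")
}

#' Write report tables to CSV
#'
#' Writes the standard outputs of an assessment run as deterministic CSV
#' files: product counts, per-100 g and per-100 kcal nutrient summaries
#' with ANOVA, and compliance tables by category, age band and criterion.
#'
#' @param products A product tibble.
#' @param assessment The list from [assess_products()]; computed if `NULL`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of files written.
#' @export
report <- function(products, assessment = NULL, dir = ".") {
  products <- check_products(products)
  if (is.null(assessment)) assessment <- assess_products(products)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    counts = "product_counts.csv",
    per100g = "nutrient_summary_per100g.csv",
    per100kcal = "nutrient_summary_per100kcal.csv",
    anova = "anova_per100g.csv",
    by_category = "compliance_by_category.csv",
    by_age = "compliance_by_age.csv",
    by_criterion = "compliance_by_criterion.csv"
  )
  files <- vapply(files, function(f) file.path(dir, f), character(1))
  readr::write_csv(product_counts(products), files["counts"], progress = FALSE)
  s_g <- nutrient_summary(products, "per_100g")
  s_k <- nutrient_summary(products, "per_100kcal")
  readr::write_csv(s_g$summary, files["per100g"], progress = FALSE)
  readr::write_csv(s_k$summary, files["per100kcal"], progress = FALSE)
  readr::write_csv(s_g$anova, files["anova"], progress = FALSE)
  readr::write_csv(compliance_table(assessment, "category"), files["by_category"], progress = FALSE)
  readr::write_csv(compliance_table(assessment, "age_bucket"), files["by_age"], progress = FALSE)
  readr::write_csv(compliance_table(assessment, "criterion"), files["by_criterion"], progress = FALSE)
  invisible(files)
}

#' Plot category nutrient means with confidence intervals
#'
#' Point-and-errorbar panels of per-category means (95 percent CI) for each
#' nutrient, on either reporting basis, with optional horizontal reference
#' lines at criterion thresholds.
#'
#' @param summary_obj The list from [nutrient_summary()].
#' @param thresholds Optional named numeric vector (nutrient -> reference
#'   line).
#' @return A ggplot object.
#' @export
plot_nutrient_summary <- function(summary_obj, thresholds = NULL) {
  dat <- summary_obj$summary
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.2) +
    ggplot2::facet_wrap(~nutrient, scales = "free_y") +
    ggplot2::labs(x = NULL, y = if (summary_obj$basis == "per_100g")
      "per 100 g (energy: kcal/100 g)" else "per 100 kcal (sugar: % energy)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(thresholds)) {
    ref <- tibble::tibble(nutrient = names(thresholds), yintercept = unname(thresholds))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$yintercept),
                                 colour = "red", linetype = 2)
  }
  p
}
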