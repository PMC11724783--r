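#' Default sugar-source lexicon
#'
#' Term patterns mapped to sugar classes, used to scan ordered ingredient
#' lists. Classes follow the model's sugar taxonomy:
#' \describe{
#'   \item{added}{mono/disaccharides and sweeteners added during processing
#'     (sucrose, glucose syrup, honey, ...). Prohibited.}
#'   \item{free}{sugars naturally present in honey, syrups, fruit juices and
#'     concentrates, and fruit powders. Prohibited.}
#'   \item{liberated}{sugars released from plant cells by processing (fruit
#'     purees and pastes used as ingredients). Reported; prohibited only in
#'     strict mode.}
#'   \item{milk_intrinsic}{lactose and other sugars naturally present in
#'     milk ingredients. Allowed.}
#'   \item{plant_intrinsic}{sugars inside intact plant cell walls (whole or
#'     pieces of fruit and vegetables). Allowed.}
#' }
#' Matching is case-insensitive on whitespace-normalized text,
#' longest-pattern-first, substring containment; the lexicon is
#' user-extensible via [read_sugar_lexicon()].
#'
#' @return A tibble with columns `pattern` and `class`.
#' @export
default_sugar_lexicon <- function() {
  lex <- function(class, patterns) tibble::tibble(pattern = patterns, class = class)
  dplyr::bind_rows(
    lex("added", c(
      "sugar", "sucrose", "glucose", "dextrose", "fructose", "maltose",
      "maltodextrin", "glucose syrup", "glucose-fructose syrup", "corn syrup",
      "rice syrup", "brown rice syrup", "invert sugar", "golden syrup",
      "agave syrup", "agave nectar", "maple syrup", "honey", "molasses",
      "treacle", "cane juice", "coconut sugar", "barley malt extract",
      "malt extract", "sweetener", "syrup", "caramel"
    )),
    lex("free", c(
      "fruit juice", "apple juice", "grape juice", "orange juice",
      "lemon juice", "pear juice", "juice concentrate", "fruit juice concentrate",
      "apple juice concentrate", "grape juice concentrate", "from concentrate",
      "concentrated apple", "concentrated grape", "fruit concentrate",
      "fruit puree powder", "fruit powder", "apple powder", "banana powder",
      "date paste", "raisin paste", "fruit nectar"
    )),
    lex("liberated", c(
      "fruit puree", "apple puree", "pear puree", "banana puree",
      "mango puree", "strawberry puree", "fruit pulp", "fruit paste",
      "dried fruit pieces ground"
    )),
    lex("milk_intrinsic", c(
      "milk", "whole milk", "skimmed milk", "milk powder", "whey",
      "lactose", "yogurt", "yoghurt", "cream", "cheese", "fromage frais"
    )),
    lex("plant_intrinsic", c(
      "apple", "pear", "banana", "mango", "strawberry", "raspberry",
      "blueberry", "apricot", "peach", "raisin", "sultana", "date",
      "carrot", "sweet potato", "parsnip", "butternut squash", "pea",
      "sweetcorn", "tomato", "beetroot", "pumpkin"
    ))
  )
}

#' Read / write a sugar lexicon
#'
#' The lexicon file is a two-column CSV (`pattern`, `class`) and round-trips
#' exactly.
#'
#' @param path CSV path.
#' @return For `read_sugar_lexicon`, a lexicon tibble; for
#'   `write_sugar_lexicon`, `path` invisibly.
#' @export
read_sugar_lexicon <- function(path) {
  lex <- readr::read_csv(path, col_types = "cc", progress = FALSE, show_col_types = FALSE)
  validate_lexicon(lex, c("added", "free", "liberated", "milk_intrinsic", "plant_intrinsic"))
  lex
}

#' @rdname read_sugar_lexicon
#' @param lexicon A lexicon tibble.
#' @export
write_sugar_lexicon <- function(lexicon, path) {
  readr::write_csv(lexicon, path, progress = FALSE)
  invisible(path)
}

validate_lexicon <- function(lex, classes) {
  if (!all(c("pattern", "class") %in% names(lex))) {
    stop("lexicon needs 'pattern' and 'class' columns", call. = FALSE)
  }
  if (anyDuplicated(normalize_text(lex$pattern))) {
    stop("lexicon patterns must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(lex$class), classes)
  if (length(bad) > 0) {
    stop("unknown lexicon classes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(lex)
}

#' Classify ingredients by sugar source
#'
#' Matches each ingredient string against the sugar lexicon. Matching is
#' case-insensitive on normalized whitespace and longest-pattern-first, so
#' "apple juice concentrate" is classified by the longer "apple juice
#' concentrate"/"juice concentrate" patterns (free sugar) rather than the
#' bare "apple" (plant-intrinsic); ties in pattern length keep lexicon
#' order. Unmatched ingredients carry class `NA` (no sugar class).
#'
#' @param ingredients Character vector of ingredient names (one product's
#'   ordered list).
#' @param lexicon A sugar lexicon tibble; defaults to
#'   [default_sugar_lexicon()].
#' @return A tibble with columns `ingredient`, `class`, `pattern`.
#' @export
#' @examples
#' classify_ingredients(c("apple juice concentrate", "whole milk", "oat flour"))
classify_ingredients <- function(ingredients, lexicon = default_sugar_lexicon()) {
  ord <- order(-nchar(lexicon$pattern), seq_len(nrow(lexicon)))
  pats <- normalize_text(lexicon$pattern[ord])
  cls <- lexicon$class[ord]
  norm <- normalize_text(ingredients)
  idx <- vapply(norm, function(s) {
    hit <- which(vapply(pats, function(p) grepl(p, s, fixed = TRUE), logical(1)))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1), USE.NAMES = FALSE)
  tibble::tibble(
    ingredient = ingredients,
    class = ifelse(is.na(idx), NA_character_, cls[idx]),
    pattern = ifelse(is.na(idx), NA_character_, lexicon$pattern[ord][idx])
  )
}

#' Percent of energy from total sugar
#'
#' Converts a total sugar declaration (g/100 g) and energy density
#' (kcal/100 g) into percent of energy from sugar, using the standard
#' 4 kcal/g carbohydrate conversion factor.
#'
#' @param sugar_g_100g Total sugar, g per 100 g.
#' @param energy_kcal_100g Energy, kcal per 100 g.
#' @return Percent of energy from sugar; `NA` when energy is missing or
#'   non-positive (not assessable).
#' @export
#' @examples
#' pct_energy_from_sugar(8.6, 64) # fruit puree, about 54 percent
pct_energy_from_sugar <- function(sugar_g_100g, energy_kcal_100g) {
  ifelse(is.na(energy_kcal_100g) | energy_kcal_100g <= 0, NA_real_,
         sugar_g_100g * 4 / energy_kcal_100g * 100)
}

#' Is a front-of-pack high-sugar flag required?
#'
#' Fruit/vegetable products and cereals exceeding 30 percent of energy from
#' total sugar — or dairy products exceeding 40 percent — are recommended to
#' carry a front-of-pack high-sugar warning. "Exceeding" is strict
#' (exactly 30 or 40 percent does not trigger the flag), unlike the
#' inclusive nutrient thresholds.
#'
#' @param category Character vector of category codes.
#' @param pctE Percent of energy from sugar (see [pct_energy_from_sugar()]).
#' @param thresholds Named numeric vector of strict cut-offs per category;
#'   categories absent from it never require the flag.
#' @return Logical vector; `FALSE` (with a warning) where `pctE` is not
#'   assessable.
#' @export
#' @examples
#' fop_flag_required(c("FruitVeg", "Dairy", "Meals"), c(31, 39, 90))
fop_flag_required <- function(category, pctE,
                              thresholds = c(FruitVeg = 30, Cereals = 30, Dairy = 40)) {
  cut <- unname(thresholds[category])
  out <- !is.na(cut) & !is.na(pctE) & pctE > cut
  if (any(is.na(pctE) & !is.na(cut))) {
    warning("percent energy from sugar not assessable for some products; ",
            "front-of-pack flag requirement set to FALSE for them", call. = FALSE)
  }
  out
}

#' Sugar profile of each product
#'
#' Combines ingredient classification and the energy share of sugar into one
#' per-product profile: percent of energy from total sugar, whether any
#' prohibited (added or free; optionally liberated) sugar ingredient is
#' present, and whether a front-of-pack high-sugar flag is required.
#'
#' @param products A product tibble.
#' @param lexicon Sugar lexicon (see [default_sugar_lexicon()]).
#' @param liberated `"report"` (default) counts liberated sugars as reported
#'   matches only; `"prohibit"` treats them like added/free sugars.
#' @param fop_thresholds Passed to [fop_flag_required()].
#' @return A tibble with `product_id`, `pct_energy_from_sugar`,
#'   `has_added_or_prohibited_sugar`, `n_prohibited_ingredients`,
#'   `matched_terms` (list column of classification tibbles) and
#'   `fop_flag_required`.
#' @export
sugar_profile <- function(products, lexicon = default_sugar_lexicon(),
                          liberated = c("report", "prohibit"),
                          fop_thresholds = c(FruitVeg = 30, Cereals = 30, Dairy = 40)) {
  liberated <- match.arg(liberated)
  products <- check_products(products)
  prohibited_classes <- c("added", "free", if (liberated == "prohibit") "liberated")
  ing <- parse_ingredients(products$ingredients)
  matched <- lapply(ing, function(tab) classify_ingredients(tab$ingredient, lexicon))
  n_prohibited <- vapply(matched, function(m) sum(m$class %in% prohibited_classes, na.rm = TRUE), numeric(1))
  pctE <- pct_energy_from_sugar(products$total_sugar_g_100g, products$energy_kcal_100g)
  tibble::tibble(
    product_id = products$product_id,
    pct_energy_from_sugar = pctE,
    n_prohibited_ingredients = n_prohibited,
    has_added_or_prohibited_sugar = n_prohibited > 0,
    matched_terms = matched,
    fop_flag_required = suppressWarnings(
      fop_flag_required(products$category, pctE, fop_thresholds))
  )
}
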