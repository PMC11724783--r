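#' The eight NPPM product categories
#'
#' Canonical category codes used throughout the package, in the order the
#' model lists them: cereals; dairy; fruit and vegetables; meals and meal
#' components; snacks and finger foods; ingredients; confectionery; drinks.
#'
#' @return Character vector of the eight category codes.
#' @export
nppm_categories <- function() {
  c("Cereals", "Dairy", "FruitVeg", "Meals", "Snacks",
    "Ingredients", "Confectionery", "Drinks")
}

#' Categories that must not be marketed as foods for infants and young children
#'
#' Confectionery and drinks fail the marketability requirement outright and
#' their nutrient composition is not assessed.
#'
#' @return Character vector of non-marketable category codes.
#' @export
non_marketable_categories <- function() {
  c("Confectionery", "Drinks")
}

.subcategory_flags <- c(
  "is_dry_cereal", "contains_milk", "is_savoury_meal",
  "contains_meat_poultry_fish", "contains_cheese",
  "is_fruit_based_snack", "is_puree_with_spout"
)

#' Round half away from zero
#'
#' Rounds .5 upward (for positive values), matching how percentages are
#' conventionally rounded in printed compliance tables, rather than R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

normalize_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

## Tokenize free text into word tokens (letters incl. accents), dropping
## connectives that never carry food meaning.
tokenize_words <- function(x) {
  x <- normalize_text(x)
  toks <- strsplit(x, "[^\\p{L}]+", perl = TRUE)
  lapply(toks, function(t) setdiff(t[nzchar(t)], c("and", "with", "in", "of", "the", "a", "n")))
}

## Truncated-normal sampler by inverse CDF; exact within [lower, upper].
## Degenerate intervals (negligible normal mass) fall back to uniform draws
## inside the interval so planted outcomes remain attainable.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower >= upper)) {
    stop("infeasible truncation interval: lower >= upper", call. = FALSE)
  }
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  out <- qnorm(runif(n, pl, pu), mean, sd)
  degen <- !is.finite(out) | (pu - pl) < 1e-12
  if (any(degen)) {
    lo <- pmax(lower[degen], mean[degen] - 10 * sd[degen])
    hi <- pmin(upper[degen], mean[degen] + 10 * sd[degen])
    bad <- lo >= hi
    lo[bad] <- lower[degen][bad]
    hi[bad] <- upper[degen][bad]
    out[degen] <- runif(sum(degen), lo, hi)
  }
  pmin(pmax(out, lower), upper)
}

## Inclusive threshold comparison with relative tolerance.
cmp_threshold <- function(observed, threshold, direction) {
  tol <- .nppm_tol * pmax(1, abs(threshold))
  ifelse(direction == "le", observed <= threshold + tol, observed >= threshold - tol)
}
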