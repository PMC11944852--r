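#' Parameters of the discretionary-food rules
#'
#' An FFQ item is classified discretionary when strictly more than
#' `proportion_threshold` of its matched database records carry the
#' discretionary flag (default 20%). Discretionary servings per 100 g are
#' the mean energy density of the matched records divided by
#' `kj_per_serving` (default 600 kJ, the guideline-defined energy content of
#' one discretionary serving).
#'
#' @param proportion_threshold Strict lower bound on the flagged proportion,
#'   in (0, 1).
#' @param kj_per_serving Energy per discretionary serving, kJ (> 0).
#' @param energy_over Which matched records contribute to the mean energy:
#'   all of them (default) or only the discretionary-flagged ones.
#' @return List of class `adgat_disc_params`.
#' @export
discretionary_params <- function(proportion_threshold = 0.20,
                                 kj_per_serving = 600,
                                 energy_over = c("all", "flagged")) {
  if (!is.numeric(proportion_threshold) || length(proportion_threshold) != 1 ||
      proportion_threshold <= 0 || proportion_threshold >= 1) {
    abort("proportion_threshold must lie strictly between 0 and 1",
          class = "adgat_validation_error")
  }
  if (!is.numeric(kj_per_serving) || length(kj_per_serving) != 1 ||
      kj_per_serving <= 0) {
    abort("kj_per_serving must be positive", class = "adgat_validation_error")
  }
  structure(list(proportion_threshold = proportion_threshold,
                 kj_per_serving = kj_per_serving,
                 energy_over = match.arg(energy_over)),
            class = "adgat_disc_params")
}

check_matched <- function(matched) {
  if (!inherits(matched, "data.frame") || nrow(matched) == 0) {
    abort("matched record set must contain at least one record",
          class = "adgat_validation_error")
  }
  matched
}

#' Component-wise mean food-group servings of matched records
#'
#' The unweighted arithmetic mean, per food group, of servings per 100 g
#' across all matched records. (Consumption-weighted averaging would need
#' population consumption data that a questionnaire protocol does not
#' carry.)
#'
#' @param matched Tibble of matched database records (columns of
#'   [read_adg_database()]).
#' @return Named numeric vector over [adg_food_groups()].
#' @export
average_groups <- function(matched) {
  check_matched(matched)
  colMeans(as.matrix(matched[adg_food_groups()]))
}

#' Classify an item as discretionary from its matched records
#'
#' `TRUE` iff the proportion of discretionary-flagged records among the
#' matched set strictly exceeds the threshold (default: > 20%; exactly 20%
#' does not trigger).
#'
#' @inheritParams average_groups
#' @param params A [discretionary_params()].
#' @return Logical scalar.
#' @export
#' @examples
#' recs <- generate_synthetic_adg_db(synthetic_db_spec(seed = 1))$db[1:5, ]
#' recs$discretionary_flag <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
#' classify_discretionary(recs)  # exactly 20% -> FALSE
classify_discretionary <- function(matched, params = discretionary_params()) {
  check_matched(matched)
  mean(matched$discretionary_flag) > params$proportion_threshold
}

#' Discretionary servings per 100 g of an item
#'
#' Zero for a non-discretionary item; otherwise the mean energy density
#' (kJ/100 g) of the matched records divided by the energy content of one
#' discretionary serving.
#'
#' @inheritParams classify_discretionary
#' @param is_discretionary Classification from [classify_discretionary()].
#' @return Non-negative scalar, servings per 100 g.
#' @export
discretionary_servings <- function(matched, is_discretionary,
                                   params = discretionary_params()) {
  check_matched(matched)
  if (!isTRUE(is_discretionary)) return(0)
  energy <- if (params$energy_over == "flagged" &&
                any(matched$discretionary_flag)) {
    matched$energy_kj_per_100g[matched$discretionary_flag]
  } else {
    matched$energy_kj_per_100g
  }
  mean(energy) / params$kj_per_serving
}

#' Collapse one match result into a summary-table row
#'
#' @param result An `adg_match` from [match_item()].
#' @param params A [discretionary_params()].
#' @return One-row tibble with the columns of [as_adgat_table()].
#' @export
build_adgat_row <- function(result, params = discretionary_params()) {
  stopifnot(inherits(result, "adg_match"))
  groups <- average_groups(result$matched)
  disc <- classify_discretionary(result$matched, params)
  out <- tibble(item_name = result$item$item_name,
                form = result$item$expected_form,
                method = result$method)
  for (g in adg_food_groups()) out[[g]] <- unname(groups[g])
  out$discretionary <- discretionary_servings(result$matched, disc, params)
  out
}

#' Build the full food-group summary table from match results
#'
#' One row per match result, input order preserved.
#'
#' @param results List of `adg_match` objects (e.g. from [match_items()]).
#' @param params A [discretionary_params()].
#' @return Tibble of class `adgat_tbl`.
#' @export
build_adgat_table <- function(results, params = discretionary_params()) {
  if (length(results) == 0) {
    abort("no match results supplied", class = "adgat_validation_error")
  }
  bad <- !map_lgl(results, inherits, "adg_match")
  if (any(bad)) {
    abort(paste0(sum(bad), " element(s) are not match results"),
          class = "adgat_validation_error")
  }
  as_adgat_table(bind_rows(map(results, build_adgat_row, params = params)))
}
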