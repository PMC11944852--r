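#' Tidy the audit trail of a match result
#'
#' One row per database record ever considered for the item, with its
#' disposition (`kept` or `excluded:<rule>`) and the rule citation.
#'
#' @param x An `adg_match` from [match_item()].
#' @param ... Unused.
#' @return Tibble: `item_name`, `food_id`, `disposition`, `rule`.
#' @export
tidy.adg_match <- function(x, ...) {
  mutate(x$audit, item_name = x$item$item_name, .before = 1)
}

#' One-row summary of a match result
#'
#' @param x An `adg_match`.
#' @param ... Unused.
#' @return Tibble: `item_name`, `method`, `n_considered`, `n_matched`,
#'   `n_excluded`.
#' @export
glance.adg_match <- function(x, ...) {
  tibble(item_name = x$item$item_name,
         method = x$method,
         n_considered = nrow(x$audit),
         n_matched = nrow(x$matched),
         n_excluded = sum(x$audit$disposition != "kept"))
}

#' Pivot per-person daily servings to long format
#'
#' @param x An `adg_daily` from [aggregate_daily_servings()] or
#'   [score_intakes()].
#' @param ... Unused.
#' @return Tibble: `person_id`, `component`, `servings_per_day`.
#' @export
tidy.adg_daily <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x),
    cols = c(all_of(adg_food_groups()), "discretionary_servings_per_day"),
    names_to = "component", values_to = "servings_per_day")
  long$component <- sub("^discretionary_servings_per_day$", "discretionary",
                        long$component)
  long
}

#' Plot a food-group summary table
#'
#' Horizontal stacked bars of servings per 100 g by food group (plus
#' discretionary servings) for a selection of items.
#'
#' @param object An `adgat_tbl`, e.g. [load_reference_table()].
#' @param items Optional character vector of item names to show (default:
#'   the first 20 rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adgat_tbl <- function(object, items = NULL, ...) {
  tab <- as_adgat_table(object)
  if (is.null(items)) items <- head(tab$item_name, 20)
  tab <- tab[tab$item_name %in% items, ]
  long <- tidyr::pivot_longer(tab,
                              cols = c(all_of(adg_food_groups()), "discretionary"),
                              names_to = "component", values_to = "servings")
  long$component <- factor(long$component,
                           levels = c(adg_food_groups(), "discretionary"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$servings,
                               y = stats::reorder(.data$item_name, .data$servings,
                                                  FUN = sum),
                               fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "servings per 100 g", y = NULL, fill = "food group") +
    ggplot2::theme_minimal()
}

#' Plot daily servings against a recommendation profile
#'
#' Bars of consumed servings/day per component, with the recommended
#' servings (or discretionary limit) marked when a profile is given.
#'
#' @param servings An `adg_daily`.
#' @param profile Optional one-row profile tibble
#'   ([read_recommendation_profiles()]).
#' @return A ggplot object.
#' @export
plot_daily_servings <- function(servings, profile = NULL) {
  long <- tidy.adg_daily(servings)
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$component,
                                    y = .data$servings_per_day)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~person_id) +
    ggplot2::labs(x = NULL, y = "servings per day") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(profile)) {
    ref <- tibble(component = c(adg_food_groups(), "discretionary"),
                  reference = c(map_dbl(adg_food_groups(), ~ profile[[.x]]),
                                as.numeric(profile$discretionary_max)))
    ref <- ref[!is.na(ref$reference), ]
    p <- p + ggplot2::geom_point(data = ref,
                                 ggplot2::aes(y = .data$reference),
                                 shape = 95, size = 8, colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
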