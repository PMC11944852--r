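#' Servings/day contribution of one intake record
#'
#' A summary-table row carries servings per 100 g; an intake of `g` grams
#' per day therefore contributes `g * servings_per_100g / 100` servings per
#' day, per food group and for discretionary servings.
#'
#' @param intake One-row data frame (or list) with `item_name` and
#'   `grams_per_day`.
#' @param row The matching summary-table row (same `item_name`).
#' @return One-row tibble: `item_name`, five group columns and
#'   `discretionary`, in servings/day.
#' @export
compute_item_servings <- function(intake, row) {
  if (!identical(as.character(intake$item_name), as.character(row$item_name))) {
    abort(paste0("intake item '", intake$item_name,
                 "' does not match table row '", row$item_name, "'"),
          class = "adgat_validation_error")
  }
  scale <- intake$grams_per_day / 100
  out <- tibble(item_name = as.character(row$item_name))
  for (g in c(adg_food_groups(), "discretionary")) out[[g]] <- row[[g]] * scale
  out
}

#' Total daily food-group servings for one person
#'
#' Sums the per-item servings/day contributions of a person's reported
#' intakes. Duplicate reports of the same item are summed with a warning;
#' an intake item absent from the summary table is an error.
#'
#' @param intakes Tibble with `item_name` and `grams_per_day` (one person;
#'   an optional `person_id` column must be constant).
#' @param table An `adgat_tbl`, e.g. [load_reference_table()].
#' @return One-row tibble of class `adg_daily`: `person_id`, the five group
#'   columns (servings/day) and `discretionary_servings_per_day`.
#' @export
#' @examples
#' tab <- load_reference_table()
#' aggregate_daily_servings(
#'   tibble::tibble(item_name = "Butter", grams_per_day = 20), tab)
aggregate_daily_servings <- function(intakes, table) {
  table <- as_adgat_table(table)
  person <- if ("person_id" %in% names(intakes) && nrow(intakes) > 0) {
    ids <- unique(as.character(intakes$person_id))
    if (length(ids) > 1) {
      abort("intakes span multiple person_id values; use score_intakes()",
            class = "adgat_validation_error")
    }
    ids
  } else {
    NA_character_
  }
  unknown <- setdiff(unique(intakes$item_name), table$item_name)
  if (length(unknown) > 0) {
    abort(paste0("intake item(s) not in the summary table: ",
                 paste(unknown, collapse = "; ")),
          class = "adgat_validation_error")
  }
  dup <- unique(intakes$item_name[duplicated(intakes$item_name)])
  if (length(dup) > 0) {
    warn(paste0("duplicate intake record(s) summed: ", paste(dup, collapse = "; ")))
  }
  cols <- c(adg_food_groups(), "discretionary")
  out <- tibble(person_id = person)
  if (nrow(intakes) == 0) {
    for (g in adg_food_groups()) out[[g]] <- 0
    out$discretionary_servings_per_day <- 0
  } else {
    joined <- left_join(intakes, table, by = "item_name")
    for (g in adg_food_groups()) {
      out[[g]] <- sum(joined$grams_per_day * joined[[g]] / 100)
    }
    out$discretionary_servings_per_day <-
      sum(joined$grams_per_day * joined$discretionary / 100)
  }
  class(out) <- c("adg_daily", class(tibble()))
  out
}

#' Score a multi-person intake file
#'
#' Groups an intake table by `person_id` and computes
#' [aggregate_daily_servings()] per person.
#'
#' @param intakes Tibble from [read_intake()].
#' @param table An `adgat_tbl`.
#' @return Tibble of class `adg_daily`, one row per person, sorted by
#'   `person_id`.
#' @export
score_intakes <- function(intakes, table) {
  table <- as_adgat_table(table)
  if (nrow(intakes) == 0) {
    out <- aggregate_daily_servings(intakes, table)[0, ]
    return(out)
  }
  ids <- sort(unique(as.character(intakes$person_id)))
  rows <- map(ids, function(id) {
    aggregate_daily_servings(intakes[intakes$person_id == id, ], table)
  })
  out <- bind_rows(rows)
  class(out) <- c("adg_daily", class(tibble()))
  out
}

#' Read recommendation profiles
#'
#' Profiles are a YAML list: each entry has an `id` (e.g. an age-sex
#' stratum label), a `recommended` mapping of the five food groups to
#' servings/day (all strictly positive) and an optional `discretionary_max`
#' limit. Recommended serving counts are configuration data, never
#' hard-coded: national guidelines publish them per age-sex stratum.
#'
#' @param path YAML file path.
#' @return Tibble: `profile_id`, five group columns, `discretionary_max`
#'   (`NA` when no limit given).
#' @export
read_recommendation_profiles <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("profile file not found: ", path), class = "adgat_io_error")
  }
  entries <- yaml::read_yaml(path)
  rows <- map(entries, function(e) {
    rec <- e$recommended
    missing <- setdiff(adg_food_groups(), names(rec))
    if (length(missing) > 0) {
      abort(paste0("profile '", e$id, "' missing recommended value(s): ",
                   paste(missing, collapse = ", ")),
            class = "adgat_validation_error")
    }
    vals <- map_dbl(adg_food_groups(), ~ as.numeric(rec[[.x]]))
    if (any(is.na(vals) | vals <= 0)) {
      abort(paste0("profile '", e$id,
                   "' has non-positive recommended servings"),
            class = "adgat_validation_error")
    }
    out <- tibble(profile_id = as.character(e$id))
    for (i in seq_along(adg_food_groups())) out[[adg_food_groups()[i]]] <- vals[i]
    out$discretionary_max <- if (is.null(e$discretionary_max)) NA_real_ else {
      dm <- as.numeric(e$discretionary_max)
      if (is.na(dm) || dm < 0) {
        abort(paste0("profile '", e$id, "' has a negative discretionary limit"),
              class = "adgat_validation_error")
      }
      dm
    }
    out
  })
  out <- bind_rows(rows)
  dup <- unique(out$profile_id[duplicated(out$profile_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate profile id(s): ", paste(dup, collapse = "; ")),
          class = "adgat_integrity_error")
  }
  out
}

#' Compare daily servings against a recommendation profile
#'
#' Food groups are adequacy targets: `met` is `consumed >= recommended`.
#' Discretionary servings are a limit: `met` is `consumed <= limit` (NA when
#' the profile sets no limit). Mixed dishes contribute to both food-group
#' and discretionary servings; the two are reported independently and their
#' joint interpretation is left to the analyst.
#'
#' @param servings An `adg_daily` (one or more persons) from
#'   [aggregate_daily_servings()] or [score_intakes()].
#' @param profile One-row tibble from [read_recommendation_profiles()] (or
#'   equivalent columns).
#' @return Tibble, six rows per person: `person_id`, `profile_id`,
#'   `component` (five groups then `"discretionary"`), `consumed`,
#'   `reference`, `ratio`, `met`.
#' @export
adherence_report <- function(servings, profile) {
  stopifnot(nrow(profile) == 1)
  rec <- map_dbl(adg_food_groups(), ~ profile[[.x]])
  if (any(is.na(rec) | rec <= 0)) {
    abort("recommended servings must all be positive",
          class = "adgat_validation_error")
  }
  limit <- if ("discretionary_max" %in% names(profile)) {
    as.numeric(profile$discretionary_max)
  } else {
    NA_real_
  }
  rows <- map(seq_len(nrow(servings)), function(i) {
    s <- servings[i, ]
    consumed <- c(map_dbl(adg_food_groups(), ~ s[[.x]]),
                  s$discretionary_servings_per_day)
    reference <- c(rec, limit)
    tibble(person_id = as.character(s$person_id),
           profile_id = as.character(profile$profile_id),
           component = c(adg_food_groups(), "discretionary"),
           consumed = consumed,
           reference = reference,
           ratio = consumed / reference,
           met = c(consumed[1:5] >= rec,
                   if (is.na(limit)) NA else consumed[6] <= limit))
  })
  bind_rows(rows)
}
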