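#' Read a food composition database with food-group servings per 100 g
#'
#' Reads a delimited (CSV) export of an ADG-style food composition database:
#' one record per food, carrying an identifier, a comma-separated
#' hierarchical description (most generic term first), servings per 100 g
#' for the five food groups, a discretionary flag and an energy density in
#' kJ/100 g. The publicly downloadable Australian Dietary Guidelines
#' database distributes these fields as a spreadsheet; export it to CSV and,
#' if its column headers differ, remap them with `dialect`.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping canonical column
#'   names (see [adg_food_groups()]; plus `food_id`, `description`,
#'   `discretionary_flag`, `energy_kj_per_100g`) to the header names used in
#'   the file, e.g. `c(food_id = "Food ID")`.
#' @return A tibble of class `adg_db`, one row per food, sorted by
#'   `food_id`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' db <- generate_synthetic_adg_db(synthetic_db_spec(seed = 1))$db
#' readr::write_csv(db, path)
#' read_adg_database(path)
read_adg_database <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("database file not found: ", path), class = "adgat_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    dialect <- dialect[dialect %in% names(raw)]
    raw <- rename(raw, !!!setNames(as.list(unname(dialect)), names(dialect)))
  }
  missing <- setdiff(db_columns(), names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "adgat_format_error")
  }
  as_adg_db(select(raw, all_of(db_columns())))
}

#' Validate a data frame as a food composition database
#'
#' @param x Data frame with the columns of [read_adg_database()].
#' @return Tibble of class `adg_db`, sorted by `food_id`.
#' @export
as_adg_db <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(db_columns(), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "adgat_format_error")
  }
  x$food_id <- as.character(x$food_id)
  x$description <- as.character(x$description)
  dup <- unique(x$food_id[duplicated(x$food_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate food_id: ", paste(dup, collapse = ", ")),
          class = "adgat_integrity_error")
  }
  if (any(!nzchar(x$description) | is.na(x$description))) {
    bad <- which(!nzchar(x$description) | is.na(x$description))
    abort(paste0("empty description at row(s): ", paste(bad, collapse = ", ")),
          class = "adgat_validation_error")
  }
  if (is.numeric(x$discretionary_flag)) {
    x$discretionary_flag <- x$discretionary_flag != 0
  }
  x$discretionary_flag <- as.logical(x$discretionary_flag)
  num_cols <- c(adg_food_groups(), "energy_kj_per_100g")
  for (col in num_cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      abort(paste0("column ", col, " is not numeric"), class = "adgat_format_error")
    }
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(paste0("negative or non-finite ", col, " at row(s): ",
                   paste(bad, collapse = ", ")),
            class = "adgat_validation_error")
    }
  }
  out <- arrange(x[db_columns()], .data$food_id)
  class(out) <- c("adg_db", class(tibble()))
  out
}

#' Read FFQ item definitions
#'
#' Item definitions are a YAML list, one entry per questionnaire item:
#' `name` (display string), `terms` (lowercase search terms), `form` (one of
#' [adg_forms()]) and `specific` (`TRUE` when the item names a specific
#' variety, e.g. wholemeal bread, so that generic summary records must not
#' be matched to it). The package ships a curated 101-item definition file
#' for the Dietary Questionnaire for Epidemiological Studies; see
#' [dqes_items_path()].
#'
#' @param path Path to a YAML item-definition file.
#' @return Tibble with columns `item_name`, `search_terms` (list column),
#'   `expected_form`, `is_specific`, in file order.
#' @export
#' @examples
#' items <- read_ffq_items(dqes_items_path())
#' nrow(items)
read_ffq_items <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("item definition file not found: ", path), class = "adgat_io_error")
  }
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0) {
    abort("item definition file is empty", class = "adgat_validation_error")
  }
  items <- map(entries, function(e) {
    ffq_item(name = e$name, terms = e$terms, form = e$form,
             specific = isTRUE(e$specific))
  })
  out <- bind_rows(items)
  dup <- unique(out$item_name[duplicated(out$item_name)])
  if (length(dup) > 0) {
    abort(paste0("duplicate item name(s): ", paste(dup, collapse = "; ")),
          class = "adgat_integrity_error")
  }
  out
}

#' Construct a single FFQ item definition
#'
#' @param name Display name of the questionnaire item.
#' @param terms Character vector of lowercase search terms (at least one).
#' @param form Expected consumption form, one of [adg_forms()].
#' @param specific `TRUE` when the item names a specific variety.
#' @return One-row tibble with the columns of [read_ffq_items()].
#' @export
#' @examples
#' ffq_item("Butter", "butter", "processed")
ffq_item <- function(name, terms, form, specific = FALSE) {
  terms <- as.character(terms)
  if (is.null(name) || !nzchar(name)) {
    abort("item name must be non-empty", class = "adgat_validation_error")
  }
  if (length(terms) == 0 || any(!nzchar(terms))) {
    abort(paste0("item '", name, "' has no usable search terms"),
          class = "adgat_validation_error")
  }
  if (length(form) != 1 || !form %in% adg_forms()) {
    abort(paste0("item '", name, "': unknown form '", paste(form, collapse = ","),
                 "' (expected one of ", paste(adg_forms(), collapse = ", "), ")"),
          class = "adgat_validation_error")
  }
  tibble(item_name = name, search_terms = list(terms),
         expected_form = form, is_specific = isTRUE(specific))
}

#' Read a per-person intake file
#'
#' @param path CSV with columns `person_id`, `item_name`,
#'   `grams_per_day` (g/day, non-negative).
#' @return Tibble with those columns.
#' @export
read_intake <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("intake file not found: ", path), class = "adgat_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("person_id", "item_name", "grams_per_day"), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "adgat_format_error")
  }
  bad <- which(is.na(x$grams_per_day) | x$grams_per_day < 0)
  if (length(bad) > 0) {
    abort(paste0("negative or missing grams_per_day at row(s): ",
                 paste(bad, collapse = ", ")),
          class = "adgat_validation_error")
  }
  x$person_id <- as.character(x$person_id)
  as_tibble(x[c("person_id", "item_name", "grams_per_day")])
}

adgat_columns <- function() {
  c("item_name", "form", "method", adg_food_groups(), "discretionary")
}

#' Validate a data frame as a food-group summary table
#'
#' A summary table has one row per FFQ item: display name, expected form,
#' resolution method, servings per 100 g for the five food groups and
#' discretionary servings per 100 g.
#'
#' @param x Data frame with columns `item_name`, `form`, `method`, the five
#'   food groups and `discretionary`.
#' @return Tibble of class `adgat_tbl`.
#' @export
as_adgat_table <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(adgat_columns(), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing summary-table column(s): ", paste(missing, collapse = ", ")),
          class = "adgat_format_error")
  }
  dup <- unique(x$item_name[duplicated(x$item_name)])
  if (length(dup) > 0) {
    abort(paste0("duplicate item name(s): ", paste(dup, collapse = "; ")),
          class = "adgat_integrity_error")
  }
  if (!all(x$form %in% adg_forms())) {
    abort("form outside the closed set", class = "adgat_validation_error")
  }
  if (!all(x$method %in% adg_methods())) {
    abort("method outside the closed set", class = "adgat_validation_error")
  }
  num_cols <- c(adg_food_groups(), "discretionary")
  for (col in num_cols) {
    if (nrow(x) == 0) x[[col]] <- numeric(0)
    v <- x[[col]]
    if (!is.numeric(v) || any(is.na(v) | !is.finite(v) | v < 0)) {
      abort(paste0("column ", col, " must be finite and non-negative"),
            class = "adgat_validation_error")
    }
  }
  out <- x[adgat_columns()]
  class(out) <- c("adgat_tbl", class(tibble()))
  out
}

#' Write a food-group summary table to CSV
#'
#' Numeric cells are rendered to one decimal place with half-up rounding
#' (presentation precision); pass `full_precision = TRUE` to append a
#' sidecar column per numeric field carrying the unrounded value.
#'
#' @param table An `adgat_tbl` (see [as_adgat_table()]).
#' @param path Output path.
#' @param full_precision Append `<column>_full` sidecar columns.
#' @return `path`, invisibly.
#' @export
write_adgat_table <- function(table, path, full_precision = FALSE) {
  table <- as_adgat_table(table)
  num_cols <- c(adg_food_groups(), "discretionary")
  out <- table
  for (col in num_cols) {
    out[[col]] <- sprintf("%.1f", round_half_up(table[[col]], 1))
  }
  if (full_precision) {
    for (col in num_cols) out[[paste0(col, "_full")]] <- table[[col]]
  }
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) {
      abort(paste0("cannot write summary table to ", path, ": ",
                   conditionMessage(e)), class = "adgat_io_error")
    }
  )
  invisible(path)
}

#' Read a food-group summary table written by [write_adgat_table()]
#'
#' Prefers the full-precision sidecar columns when present.
#'
#' @param path CSV path.
#' @return Tibble of class `adgat_tbl`.
#' @export
read_adgat_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("summary table not found: ", path), class = "adgat_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  num_cols <- c(adg_food_groups(), "discretionary")
  full <- paste0(num_cols, "_full")
  if (all(full %in% names(x))) {
    for (i in seq_along(num_cols)) x[[num_cols[i]]] <- x[[full[i]]]
    x <- x[setdiff(names(x), full)]
  }
  as_adgat_table(x)
}
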