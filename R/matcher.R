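#' Normalize a food description for matching
#'
#' Lowercases, collapses punctuation other than commas (dashes, slashes,
#' ampersands, brackets...) to single spaces and squeezes whitespace, while
#' preserving the comma structure that separates descriptor levels
#' (most-generic descriptor first). Idempotent.
#'
#' @param text Character vector.
#' @return Normalized character vector of the same length.
#' @export
#' @examples
#' normalize_description("  Cheese—Ricotta  ")
normalize_description <- function(text) {
  x <- tolower(as.character(text))
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N},]+", " ")
  x <- stringr::str_replace_all(x, "\\s*,\\s*", ", ")
  x <- stringr::str_replace_all(x, "(, )+", ", ")   # collapse empty descriptors
  x <- stringr::str_squish(x)
  x <- stringr::str_remove(x, "^(, )+|^,")
  x <- stringr::str_remove(x, "(, |,)+$")
  stringr::str_squish(x)
}

nfd_token <- "not further defined"

#' Matching configuration
#'
#' Keyword vocabularies driving the exclusion rules, plus per-item overrides.
#' The rule set mirrors the published matching protocol: records are
#' excluded when (a) all five group servings are zero and the record is not
#' discretionary-flagged; (b) the record is in a raw form while the item is
#' consumed cooked/processed and names an animal protein or starchy
#' vegetable/pulse; (c) the record is a mixed dish while the item implies a
#' single food; (d) the record is a general "not further defined" summary
#' while the item names a specific variety.
#'
#' @param raw_keywords Words marking a raw-form record (rule b).
#' @param dish_keywords Words marking a mixed-dish record (rule c). Keywords
#'   that occur in an item's own search terms are ignored for that item (an
#'   item that itself names a pie is not "implying a single food").
#' @param protein_starchy_terms Category words; an item whose search terms
#'   contain one of these is treated as an animal protein or starchy
#'   vegetable/pulse for rule (b).
#' @param prefer_nfd Prefer a primary-position "not further defined" summary
#'   record over multiple specific records for generic items.
#' @param overrides Named list: item name -> character vector of food IDs to
#'   pin as the match, bypassing the automated pipeline.
#' @return List of class `adgat_match_config`.
#' @export
match_config <- function(raw_keywords = c("raw", "uncooked"),
                         dish_keywords = c("stuffed", "casserole", "with",
                                           "dish", "pie", "soup"),
                         protein_starchy_terms = c(
                           "beef", "chicken", "pork", "lamb", "veal", "turkey",
                           "fish", "seafood", "prawn", "egg", "eggs", "bacon",
                           "ham", "sausage", "sausages", "salami", "meat",
                           "mince", "potato", "potatoes", "pulse", "bean",
                           "beans", "lentil", "lentils", "chickpea",
                           "chick pea", "pea", "peas", "corn", "legume"),
                         prefer_nfd = TRUE,
                         overrides = list()) {
  structure(
    list(raw_keywords = tolower(raw_keywords),
         dish_keywords = tolower(dish_keywords),
         protein_starchy_terms = tolower(protein_starchy_terms),
         prefer_nfd = isTRUE(prefer_nfd),
         overrides = overrides),
    class = "adgat_match_config"
  )
}

# does normalized text contain any of `words` as a whole word?
has_word <- function(text, words) {
  if (length(words) == 0) return(rep(FALSE, length(text)))
  pat <- paste0("\\b(", paste(stringr::str_escape(words), collapse = "|"), ")\\b")
  stringr::str_detect(text, pat)
}

item_as_list <- function(item) {
  if (inherits(item, "data.frame")) {
    stopifnot(nrow(item) == 1)
    list(item_name = item$item_name, search_terms = item$search_terms[[1]],
         expected_form = item$expected_form, is_specific = item$is_specific)
  } else {
    item
  }
}

#' Search a database for candidate records of one FFQ item
#'
#' A record is a candidate when its normalized description contains at least
#' one of the item's normalized search terms as a substring. For each
#' candidate the search also notes whether a term sits in the primary
#' position (the first comma-delimited descriptor begins with it) and
#' whether the record is a "not further defined" summary. Candidates are
#' ordered by descending matched-term count, then food ID.
#'
#' @param item One-row tibble from [read_ffq_items()] or [ffq_item()].
#' @param db An `adg_db` (see [read_adg_database()]).
#' @param config A [match_config()].
#' @return Object of class `adg_candidates`: list with the item, a candidate
#'   tibble and an audit trail.
#' @export
string_search <- function(item, db, config = match_config()) {
  it <- item_as_list(item)
  if (!inherits(db, "adg_db")) db <- as_adg_db(db)
  if (nrow(db) == 0) {
    abort("database is empty", class = "adgat_validation_error")
  }
  terms <- normalize_description(it$search_terms)
  desc <- normalize_description(db$description)
  first_desc <- stringr::str_trim(stringr::str_extract(desc, "^[^,]*"))
  hits <- map(terms, ~ stringr::str_detect(desc, stringr::fixed(.x)))
  hit_mat <- do.call(cbind, hits)
  any_hit <- rowSums(hit_mat) > 0
  primary <- rep(FALSE, nrow(db))
  for (t in terms) primary <- primary | stringr::str_starts(first_desc, stringr::fixed(t))
  cand <- db[any_hit, , drop = FALSE]
  cand <- mutate(as_tibble(cand),
                 matched_terms = map(which(any_hit), ~ terms[hit_mat[.x, ]]),
                 n_terms = lengths(.data$matched_terms),
                 primary_position = primary[any_hit],
                 is_nfd = stringr::str_detect(desc[any_hit], stringr::fixed(nfd_token)))
  cand <- arrange(cand, desc(.data$n_terms), .data$food_id)
  structure(list(item = it, candidates = cand,
                 audit = tibble(food_id = character(), disposition = character(),
                                rule = character()),
                 nfd_branch = FALSE),
            class = "adg_candidates")
}

exclusion_rules <- function() {
  c(all_zero = "all five group servings zero and record not discretionary-flagged",
    raw_form = "raw-form record for an item consumed cooked/processed",
    mixed_dish = "mixed-dish record for an item implying a single food",
    general_vs_specific = "general (not further defined) record for a specific item")
}

#' Apply the exclusion criteria to a candidate set
#'
#' Removes candidates under the four exclusion rules (see [match_config()]),
#' recording every removal in the audit trail. May return an empty set.
#'
#' @param cands An `adg_candidates` from [string_search()].
#' @param config A [match_config()].
#' @return The filtered `adg_candidates`.
#' @export
apply_exclusions <- function(cands, config = match_config()) {
  stopifnot(inherits(cands, "adg_candidates"))
  it <- cands$item
  cc <- cands$candidates
  if (nrow(cc) == 0) return(cands)
  desc <- normalize_description(cc$description)
  groups <- as.matrix(cc[adg_food_groups()])

  protein_starchy <- any(has_word(normalize_description(it$search_terms),
                                  config$protein_starchy_terms))
  # dish keywords named by the item itself do not signal a mixed dish for it
  term_words <- unique(unlist(strsplit(
    normalize_description(it$search_terms), "[ ,]+")))
  dish_kw <- setdiff(config$dish_keywords, term_words)

  rule <- rep(NA_character_, nrow(cc))
  zero_all <- rowSums(groups) == 0 & !cc$discretionary_flag
  rule[is.na(rule) & zero_all] <- "all_zero"
  if (it$expected_form %in% c("cooked", "processed") && protein_starchy) {
    raw_hit <- has_word(desc, config$raw_keywords)
    rule[is.na(rule) & raw_hit] <- "raw_form"
  }
  if (!identical(it$expected_form, "mixed")) {
    dish_hit <- has_word(desc, dish_kw)
    rule[is.na(rule) & dish_hit] <- "mixed_dish"
  }
  if (isTRUE(it$is_specific)) {
    rule[is.na(rule) & cc$is_nfd] <- "general_vs_specific"
  }

  dropped <- !is.na(rule)
  audit_add <- tibble(food_id = cc$food_id[dropped],
                      disposition = paste0("excluded:", rule[dropped]),
                      rule = unname(exclusion_rules()[rule[dropped]]))
  cands$candidates <- cc[!dropped, , drop = FALSE]
  cands$audit <- bind_rows(cands$audit, audit_add)
  cands
}

#' Apply the selection criteria to a surviving candidate set
#'
#' For a generic item with a primary-position "not further defined" summary
#' among the survivors, that summary is selected (lowest food ID when
#' several qualify). Otherwise, primary-position candidates are preferred
#' when any exist; otherwise the set is unchanged.
#'
#' @inheritParams apply_exclusions
#' @return The selected `adg_candidates`; `nfd_branch` records whether the
#'   summary-record route resolved the item.
#' @export
apply_selection <- function(cands, config = match_config()) {
  stopifnot(inherits(cands, "adg_candidates"))
  cc <- cands$candidates
  if (nrow(cc) == 0) return(cands)
  it <- cands$item
  nfd_ok <- config$prefer_nfd && !isTRUE(it$is_specific) &&
    any(cc$is_nfd & cc$primary_position)
  if (nfd_ok) {
    pick <- which(cc$is_nfd & cc$primary_position)
    pick <- pick[order(cc$food_id[pick])][1]
    keep <- logical(nrow(cc)); keep[pick] <- TRUE
    why <- "non-summary record dropped in favour of the not-further-defined summary"
    cands$nfd_branch <- TRUE
  } else if (any(cc$primary_position)) {
    keep <- cc$primary_position
    why <- "record without a search term in the primary position dropped"
  } else {
    return(cands)
  }
  audit_add <- tibble(food_id = cc$food_id[!keep],
                      disposition = "excluded:selection",
                      rule = why)
  cands$candidates <- cc[keep, , drop = FALSE]
  cands$audit <- bind_rows(cands$audit, audit_add)
  cands
}

#' Classify how an item was resolved
#'
#' @inheritParams apply_exclusions
#' @return `"not further defined"` when the summary-record route resolved
#'   the item, `"single"` for exactly one ordinary record, `"average"` for
#'   two or more.
#' @export
classify_method <- function(cands) {
  stopifnot(inherits(cands, "adg_candidates"))
  n <- nrow(cands$candidates)
  if (n == 0) {
    abort(
      message = paste0(
        "no database record survived matching for item '",
        cands$item$item_name, "'\n",
        paste0("  ", cands$audit$food_id, ": ", cands$audit$disposition,
               " (", cands$audit$rule, ")", collapse = "\n")),
      class = "adgat_unmatched_error",
      audit = cands$audit, item = cands$item$item_name)
  }
  if (cands$nfd_branch) return("not further defined")
  if (n == 1) "single" else "average"
}

#' Match one FFQ item against a food composition database
#'
#' Composes the full pipeline: candidate string search, exclusion criteria,
#' selection criteria and method classification. Deterministic for fixed
#' inputs and configuration; ties always break on the lexicographically
#' lowest food ID. If `config$overrides` pins food IDs for the item, those
#' records are used directly.
#'
#' @inheritParams string_search
#' @return Object of class `adg_match`: list with the item, the matched
#'   record tibble, the method label and a complete audit trail covering
#'   every candidate ever considered.
#' @export
#' @examples
#' db <- generate_synthetic_adg_db(synthetic_db_spec(seed = 1))$db
#' match_item(ffq_item("Butter", "butter", "processed"), db)
match_item <- function(item, db, config = match_config()) {
  it <- item_as_list(item)
  if (!inherits(db, "adg_db")) db <- as_adg_db(db)
  ov <- config$overrides[[it$item_name]]
  if (!is.null(ov)) {
    ov <- as.character(ov)
    missing <- setdiff(ov, db$food_id)
    if (length(missing) > 0) {
      abort(paste0("override food_id not in database: ",
                   paste(missing, collapse = ", ")),
            class = "adgat_validation_error")
    }
    matched <- db[match(sort(ov), db$food_id), , drop = FALSE]
    is_nfd <- stringr::str_detect(normalize_description(matched$description),
                                  stringr::fixed(nfd_token))
    method <- if (nrow(matched) >= 2) "average"
              else if (is_nfd[1]) "not further defined" else "single"
    audit <- tibble(food_id = matched$food_id, disposition = "kept",
                    rule = "pinned by per-item override")
    return(structure(list(item = it, matched = as_tibble(matched),
                          method = method, audit = audit),
                     class = "adg_match"))
  }
  cands <- string_search(it, db, config)
  n_considered <- nrow(cands$candidates)
  cands <- apply_exclusions(cands, config)
  cands <- apply_selection(cands, config)
  method <- classify_method(cands)
  kept <- tibble(food_id = cands$candidates$food_id,
                 disposition = "kept", rule = "survived all criteria")
  audit <- arrange(bind_rows(kept, cands$audit), .data$food_id)
  stopifnot(nrow(audit) == n_considered)  # audit conservation
  structure(list(item = it,
                 matched = select(as_tibble(cands$candidates), all_of(db_columns())),
                 method = method, audit = audit),
            class = "adg_match")
}

#' @export
print.adg_match <- function(x, ...) {
  cat("<adg_match> ", x$item$item_name, " [", x$method, "]\n", sep = "")
  cat("  matched: ", paste(x$matched$food_id, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Match every FFQ item in a definition table
#'
#' @param items Tibble from [read_ffq_items()].
#' @param db An `adg_db`.
#' @param config A [match_config()].
#' @return Named list of [match_item()] results; items that could not be
#'   matched carry the error condition instead (inspect with
#'   `inherits(x, "adgat_unmatched_error")`).
#' @export
match_items <- function(items, db, config = match_config()) {
  if (!inherits(db, "adg_db")) db <- as_adg_db(db)
  res <- map(seq_len(nrow(items)), function(i) {
    tryCatch(match_item(items[i, ], db, config),
             adgat_unmatched_error = function(e) e)
  })
  setNames(res, items$item_name)
}
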