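# Independent brute-force implementation of the matching rules, written as
# plain loops over every record. Used as the oracle against match_item();
# deliberately shares no code with the package internals.

oracle_normalize <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9,]+", " ", x)
  x <- gsub(" *, *", ", ", x)
  x <- gsub("(, )+", ", ", x)
  x <- gsub(" +", " ", x)
  x <- sub("^[, ]+", "", x)
  x <- sub("[, ]+$", "", x)
  x
}

oracle_has_word <- function(text, words) {
  for (w in words) {
    if (grepl(paste0("\\b", w, "\\b"), text)) return(TRUE)
  }
  FALSE
}

# returns list(ids = sorted food_ids, method = label) or NULL when unmatched
oracle_match <- function(item, db, config = match_config()) {
  terms <- oracle_normalize(item$search_terms[[1]])
  form <- item$expected_form
  specific <- isTRUE(item$is_specific)
  term_words <- unique(unlist(strsplit(terms, "[ ,]+")))
  dish_kw <- setdiff(config$dish_keywords, term_words)
  protein <- FALSE
  for (t in terms) {
    if (oracle_has_word(t, config$protein_starchy_terms)) protein <- TRUE
  }

  keep <- list()
  for (i in seq_len(nrow(db))) {
    desc <- oracle_normalize(db$description[i])
    hit <- FALSE
    for (t in terms) if (grepl(t, desc, fixed = TRUE)) hit <- TRUE
    if (!hit) next
    first <- sub(",.*$", "", desc)
    primary <- FALSE
    for (t in terms) if (startsWith(first, t)) primary <- TRUE
    nfd <- grepl("not further defined", desc, fixed = TRUE)
    # exclusion rules
    gsum <- 0
    for (g in adg_food_groups()) gsum <- gsum + db[[g]][i]
    if (gsum == 0 && !db$discretionary_flag[i]) next
    if (form %in% c("cooked", "processed") && protein &&
        oracle_has_word(desc, config$raw_keywords)) next
    if (form != "mixed" && oracle_has_word(desc, dish_kw)) next
    if (specific && nfd) next
    keep[[length(keep) + 1]] <- list(id = db$food_id[i], primary = primary,
                                     nfd = nfd)
  }
  if (length(keep) == 0) return(NULL)
  prim <- vapply(keep, `[[`, TRUE, "primary")
  nfd <- vapply(keep, `[[`, TRUE, "nfd")
  ids <- vapply(keep, `[[`, "", "id")
  if (config$prefer_nfd && !specific && any(nfd & prim)) {
    chosen <- sort(ids[nfd & prim])[1]
    return(list(ids = chosen, method = "not further defined"))
  }
  if (any(prim)) ids <- ids[prim]
  ids <- sort(ids)
  list(ids = ids, method = if (length(ids) == 1) "single" else "average")
}

# random small database + item pair exercising every branch of the rules
random_match_case <- function(vocab = c("butter", "bread", "bean", "chicken"),
                              max_records = 10) {
  n <- sample.int(max_records, 1)
  qualifiers <- c("plain", "salted", "raw", "stuffed with rice",
                  "not further defined", "premium", "soup, condensed")
  words <- sample(c(vocab, "quandong", "tamarillo"), n, replace = TRUE)
  desc <- paste0(toupper(substring(words, 1, 1)), substring(words, 2), ", ",
                 sample(qualifiers, n, replace = TRUE))
  zero <- runif(n) < 0.2
  groups <- matrix(round(runif(n * 5, 0, 2), 1), n, 5)
  groups[zero, ] <- 0
  db <- mini_db(desc, groups = groups,
                flag = runif(n) < 0.3,
                energy = round(runif(n, 100, 3000)))
  item <- ffq_item(name = "Probe",
                   terms = sample(vocab, sample.int(3, 1)),
                   form = sample(adg_forms(), 1),
                   specific = runif(1) < 0.3)
  list(item = item, db = db)
}

expect_matches_oracle <- function(item, db, config = match_config()) {
  expected <- oracle_match(item, db, config)
  if (is.null(expected)) {
    expect_error(match_item(item, db, config), class = "adgat_unmatched_error")
  } else {
    got <- match_item(item, db, config)
    expect_identical(sort(got$matched$food_id), expected$ids)
    expect_identical(got$method, expected$method)
  }
}
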