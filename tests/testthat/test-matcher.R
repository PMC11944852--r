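test_that("normalize_description lowercases and collapses punctuation", {
  expect_identical(normalize_description("Beef, all cuts, separable fat"),
                   "beef, all cuts, separable fat")
  expect_identical(normalize_description("  Cheese—Ricotta  "),
                   "cheese ricotta")
  expect_identical(normalize_description("Fish & chips (take-away)"),
                   "fish chips take away")
  expect_identical(normalize_description(""), "")
})

test_that("normalize_description is idempotent on random strings", {
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, ",", ".", "-", "—", "&", "(", ")",
                " ", "  ", "/", "'")
  for (i in 1:1000) {
    s <- paste(sample(alphabet, sample.int(30, 1), replace = TRUE),
               collapse = "")
    once <- normalize_description(s)
    expect_identical(normalize_description(once), once)
  }
})

test_that("string_search finds substring candidates with position and NFD flags", {
  db <- mini_db(c("Butter, plain, not further defined",
                  "Peanut butter, smooth",
                  "Bread, white"))
  cs <- string_search(ffq_item("Butter", "butter", "processed"), db)
  expect_equal(sort(cs$candidates$food_id), c("F001", "F002"))
  c1 <- cs$candidates[cs$candidates$food_id == "F001", ]
  expect_true(c1$primary_position)
  expect_true(c1$is_nfd)
  c2 <- cs$candidates[cs$candidates$food_id == "F002", ]
  expect_false(c2$primary_position)  # "peanut butter" does not begin with it
  expect_false(c2$is_nfd)
})

test_that("mixed-dish records are still candidates at the search stage", {
  db <- mini_db(c("Capsicum, stuffed with meat & rice"))
  cs <- string_search(ffq_item("Peppers (capsicum)", "capsicum", "raw/cooked"), db)
  expect_equal(cs$candidates$food_id, "F001")
})

test_that("string_search on an empty database errors", {
  db <- mini_db("Butter, plain")[0, ]
  expect_error(string_search(ffq_item("Butter", "butter", "processed"), db),
               class = "adgat_validation_error")
})

test_that("candidate recall equals an independent brute-force scan", {
  set.seed(11)
  gen <- generate_synthetic_adg_db(
    synthetic_db_spec(seed = 5, n_foods = 50,
                      term_vocabulary = c("butter", "bread", "cheese")))
  db <- gen$db
  for (terms in list("butter", c("bread", "cheese"), "quandong")) {
    cs <- string_search(ffq_item("Probe", terms, "processed"), db)
    desc <- oracle_normalize(db$description)
    want <- db$food_id[vapply(desc, function(d) {
      any(vapply(terms, function(t) grepl(t, d, fixed = TRUE), TRUE))
    }, TRUE)]
    expect_setequal(cs$candidates$food_id, want)
  }
})

test_that("exclusion rules drop the documented record classes", {
  zero <- matrix(0, 1, 5)
  # (a) all group servings zero, not discretionary
  db <- mini_db("Beef, all cuts, separable fat, grilled or roasted without fat",
                groups = zero, flag = FALSE)
  cs <- string_search(ffq_item("Beef", "beef", "cooked"), db)
  out <- apply_exclusions(cs)
  expect_equal(nrow(out$candidates), 0)
  expect_match(out$audit$disposition, "excluded:all_zero")

  # zero-vector records with a discretionary flag are retained (beverages)
  db2 <- mini_db("Beer, full strength", groups = zero, flag = TRUE)
  cs2 <- apply_exclusions(string_search(
    ffq_item("Beer—full strength", c("beer", "full strength"),
             "processed", specific = TRUE), db2))
  expect_equal(cs2$candidates$food_id, "F001")

  # (b) raw form of an animal protein consumed cooked
  db3 <- mini_db(c("Chicken, breast, flesh, raw", "Chicken, breast, grilled"))
  cs3 <- apply_exclusions(string_search(ffq_item("Chicken", "chicken", "cooked"),
                                        db3))
  expect_equal(cs3$candidates$food_id, "F002")
  expect_identical(cs3$audit$disposition, "excluded:raw_form")

  # (b) does not fire for plant foods eaten raw
  db3b <- mini_db("Apple, raw")
  cs3b <- apply_exclusions(string_search(ffq_item("Apples", "apple", "raw"),
                                         db3b))
  expect_equal(nrow(cs3b$candidates), 1)

  # (c) mixed dish when the item implies a single food
  db4 <- mini_db(c("Capsicum, stuffed with meat & rice", "Capsicum, grilled"))
  cs4 <- apply_exclusions(string_search(
    ffq_item("Peppers (capsicum)", "capsicum", "raw/cooked"), db4))
  expect_equal(cs4$candidates$food_id, "F002")

  # (c) suspended when the item itself names the dish keyword
  db4b <- mini_db("Meat pie, individual")
  cs4b <- apply_exclusions(string_search(
    ffq_item("Meat pies", c("meat pie", "pastie"), "cooked"), db4b))
  expect_equal(nrow(cs4b$candidates), 1)

  # (d) NFD summary when the item is specific
  db5 <- mini_db(c("Bread, commercial, fresh, not further defined",
                   "Bread, wholemeal"))
  cs5 <- apply_exclusions(string_search(
    ffq_item("Bread—wholemeal", c("bread", "wholemeal"), "processed",
             specific = TRUE), db5))
  expect_equal(cs5$candidates$food_id, "F002")
  expect_identical(cs5$audit$disposition, "excluded:general_vs_specific")
})

test_that("selection prefers the NFD summary for generic items", {
  db <- mini_db(c("Butter, plain, not further defined", "Butter, garlic",
                  "Butter, herb", "Butter, salt reduced", "Butter, clarified"))
  cs <- apply_selection(apply_exclusions(string_search(
    ffq_item("Butter", "butter", "processed"), db)))
  expect_equal(cs$candidates$food_id, "F001")
  expect_true(cs$nfd_branch)
})

test_that("selection keeps primary-position candidates otherwise", {
  db <- mini_db(c("Butter, garlic", "Peanut butter, smooth"))
  cs <- apply_selection(apply_exclusions(string_search(
    ffq_item("Butter", "butter", "processed"), db)))
  expect_equal(cs$candidates$food_id, "F001")
  expect_false(cs$nfd_branch)
})

test_that("selection is a no-op when no candidate is in primary position", {
  db <- mini_db(c("Peanut butter, smooth", "Garlic butter, tub"))
  cs0 <- apply_exclusions(string_search(
    ffq_item("Butter", "butter", "processed"), db))
  cs <- apply_selection(cs0)
  expect_setequal(cs$candidates$food_id, cs0$candidates$food_id)
})

test_that("classify_method labels the three resolution routes", {
  db <- mini_db(c("Butter, plain, not further defined", "Butter, garlic"))
  cs <- apply_selection(apply_exclusions(string_search(
    ffq_item("Butter", "butter", "processed"), db)))
  expect_identical(classify_method(cs), "not further defined")

  db2 <- mini_db("Apricot, fresh")
  cs2 <- apply_selection(apply_exclusions(string_search(
    ffq_item("Apricots", "apricot", "raw"), db2)))
  expect_identical(classify_method(cs2), "single")

  db3 <- mini_db(c("Bacon, grilled", "Bacon, fried", "Bacon, middle rasher"))
  cs3 <- apply_selection(apply_exclusions(string_search(
    ffq_item("Bacon", "bacon", "cooked"), db3)))
  expect_identical(classify_method(cs3), "average")
})

test_that("match_item resolves the butter family to the NFD summary", {
  db <- mini_db(c("Butter, plain, not further defined", "Butter, garlic",
                  "Butter, herb", "Butter, reduced salt", "Butter, raw milk",
                  "Bread, white"))
  m <- match_item(ffq_item("Butter", "butter", "processed"), db)
  expect_identical(m$matched$food_id, "F001")
  expect_identical(m$method, "not further defined")
  # audit covers every candidate ever considered
  expect_equal(nrow(m$audit), 5)
  expect_equal(sum(m$audit$disposition == "kept"), 1)
})

test_that("an item whose only candidate is excluded raises an unmatched error", {
  db <- mini_db("Butter, plain", groups = matrix(0, 1, 5), flag = FALSE)
  err <- expect_error(match_item(ffq_item("Butter", "butter", "processed"), db),
                      class = "adgat_unmatched_error")
  expect_equal(nrow(err$audit), 1)
  expect_match(err$audit$disposition, "excluded:all_zero")
})

test_that("per-item overrides pin the match directly", {
  db <- mini_db(c("Butter, plain, not further defined", "Butter, garlic"))
  cfg <- match_config(overrides = list(Butter = "F002"))
  m <- match_item(ffq_item("Butter", "butter", "processed"), db, cfg)
  expect_identical(m$matched$food_id, "F002")
  expect_identical(m$method, "single")
})

test_that("match_item agrees with the brute-force oracle on small databases", {
  set.seed(101)
  for (i in 1:300) {
    case <- random_match_case()
    expect_matches_oracle(case$item, case$db)
  }
})

test_that("matching is deterministic and ignores non-matching additions", {
  set.seed(33)
  case <- random_match_case()
  ok <- !is.null(oracle_match(case$item, case$db))
  if (ok) {
    m1 <- match_item(case$item, case$db)
    m2 <- match_item(case$item, case$db)
    expect_identical(m1$matched$food_id, m2$matched$food_id)
    expect_identical(m1$audit, m2$audit)
    # monotonicity: a record matching no search term never changes the result
    extra <- mini_db("Zzyzx, inert")
    extra$food_id <- "F999"
    bigger <- as_adg_db(dplyr::bind_rows(tibble::as_tibble(case$db),
                                         tibble::as_tibble(extra)))
    m3 <- match_item(case$item, bigger)
    expect_identical(m3$matched$food_id, m1$matched$food_id)
    expect_identical(m3$method, m1$method)
  } else {
    expect_error(match_item(case$item, case$db), class = "adgat_unmatched_error")
  }
})

test_that("audit conserves candidates at every stage", {
  set.seed(55)
  for (i in 1:50) {
    case <- random_match_case()
    cs <- string_search(case$item, case$db)
    n0 <- nrow(cs$candidates)
    cs <- apply_exclusions(cs)
    expect_equal(nrow(cs$candidates) + nrow(cs$audit), n0)
    cs <- apply_selection(cs)
    expect_equal(nrow(cs$candidates) + nrow(cs$audit), n0)
  }
})

test_that("all 101 packaged items match a synthetic db built to cover them", {
  items <- read_ffq_items(dqes_items_path())
  vocab <- vapply(items$search_terms, `[[`, "", 1)
  spec <- synthetic_db_spec(seed = 9, n_foods = 5 * length(unique(vocab)) + 30,
                            term_vocabulary = vocab)
  db <- generate_synthetic_adg_db(spec)$db
  res <- match_items(items, db)
  expect_length(res, 101)
  expect_true(all(vapply(res, inherits, TRUE, "adg_match")))
})
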