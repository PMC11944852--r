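#' Specification of a synthetic food composition database
#'
#' The generator plants, for every word in `term_vocabulary`, a family of
#' records emulating the structure of the real database: a "not further
#' defined" summary record, two named variants, one raw-form decoy and one
#' mixed-dish decoy. Around the families it adds all-zero decoy records
#' (zero servings in every group, non-discretionary) and generic filler
#' foods, topping up "not further defined" markers and discretionary flags
#' to the requested fractions. The result is deterministic in `seed` and
#' ships with a manifest naming every planted record, so matcher tests have
#' ground truth by construction.
#'
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param n_foods Total number of records.
#' @param fraction_nfd Target fraction of records marked "not further
#'   defined" (at least one per planted family).
#' @param fraction_discretionary Target fraction of discretionary-flagged
#'   records.
#' @param fraction_all_zero Fraction of all-zero decoy records (honored
#'   exactly: `round(fraction_all_zero * n_foods)` records).
#' @param energy_range Numeric length-2, kJ/100 g range for energy
#'   densities.
#' @param term_vocabulary Base food words to plant families for.
#' @return List of class `adgat_db_spec`.
#' @export
synthetic_db_spec <- function(seed = 1L,
                              n_foods = 120L,
                              fraction_nfd = 0.10,
                              fraction_discretionary = 0.20,
                              fraction_all_zero = 0.05,
                              energy_range = c(100, 3000),
                              term_vocabulary = c("butter", "bread", "cheese",
                                                  "apple", "beef", "milk",
                                                  "carrot", "rice")) {
  fr <- c(fraction_nfd, fraction_discretionary, fraction_all_zero)
  if (any(fr < 0 | fr > 1)) {
    abort("fractions must lie in [0, 1]", class = "adgat_spec_error")
  }
  if (length(energy_range) != 2 || energy_range[1] > energy_range[2] ||
      any(energy_range < 0)) {
    abort("energy_range must be a non-negative (min, max) pair",
          class = "adgat_spec_error")
  }
  term_vocabulary <- unique(tolower(term_vocabulary))
  n_family <- 5L  # NFD + 2 variants + raw decoy + dish decoy
  need <- n_family * length(term_vocabulary) + round(fraction_all_zero * n_foods)
  if (n_foods < need) {
    abort(paste0("n_foods = ", n_foods, " cannot hold ",
                 length(term_vocabulary), " planted families plus decoys (need >= ",
                 need, ")"),
          class = "adgat_spec_error")
  }
  structure(list(seed = as.integer(seed), n_foods = as.integer(n_foods),
                 fraction_nfd = fraction_nfd,
                 fraction_discretionary = fraction_discretionary,
                 fraction_all_zero = fraction_all_zero,
                 energy_range = as.numeric(energy_range),
                 term_vocabulary = term_vocabulary),
            class = "adgat_db_spec")
}

# capitalized display form of a lowercase word
cap1 <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

filler_words <- function() {
  c("quandong", "tamarillo", "jackfruit", "salsify", "kohlrabi", "amaranth",
    "teff", "spelt", "lupin", "wakame", "nori", "galangal", "jicama",
    "plantain", "cassava", "taro", "durian", "rambutan", "cloudberry",
    "medlar", "sorrel", "chervil", "lovage", "skirret", "scorzonera",
    "arrowroot", "pandanus", "riberry")
}

# random group-serving vector concentrated on one dominant group
random_groups <- function(n_rows) {
  g <- matrix(0, n_rows, length(adg_food_groups()),
              dimnames = list(NULL, adg_food_groups()))
  dom <- sample.int(ncol(g), n_rows, replace = TRUE)
  g[cbind(seq_len(n_rows), dom)] <- round(runif(n_rows, 0.3, 3.5), 1)
  minor <- runif(n_rows) < 0.3
  if (any(minor)) {
    m2 <- (dom[minor] %% ncol(g)) + 1L
    g[cbind(which(minor), m2)] <- round(runif(sum(minor), 0.1, 0.8), 1)
  }
  g
}

#' Generate a synthetic food composition database with ground truth
#'
#' @param spec A [synthetic_db_spec()].
#' @return List with `db` (an `adg_db`) and `manifest` (tibble: one row per
#'   planted target word giving the intended best-match record, the family
#'   structure and the decoys; all-zero decoy IDs are attached as rows with
#'   `role = "all_zero"`).
#' @export
#' @examples
#' gen <- generate_synthetic_adg_db(synthetic_db_spec(seed = 1, n_foods = 60))
#' nrow(gen$db)
generate_synthetic_adg_db <- function(spec) {
  stopifnot(inherits(spec, "adgat_db_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)

  vocab <- spec$term_vocabulary
  k <- length(vocab)
  n_zero <- round(spec$fraction_all_zero * spec$n_foods)
  n_planted <- 5L * k
  n_fill <- spec$n_foods - n_planted - n_zero
  variants <- c("salt reduced", "extra tasty", "homestyle", "traditional",
                "light", "premium", "organic", "smoked")
  dishes <- c("stuffed with vegetables & rice", "casserole, prepared",
              "soup, condensed", "pie, commercial")

  rows <- list()
  manifest <- list()
  next_id <- 1L
  new_id <- function() {
    id <- sprintf("F%05d", next_id)
    next_id <<- next_id + 1L
    id
  }
  energy <- function(n) round(runif(n, spec$energy_range[1], spec$energy_range[2]))

  for (w in vocab) {
    W <- cap1(w)
    fam_groups <- random_groups(4L)  # nfd + 2 variants + dish decoy
    vs <- sample(variants, 2)
    nfd_id <- new_id()
    v1_id <- new_id(); v2_id <- new_id()
    raw_id <- new_id(); dish_id <- new_id()
    fam <- tibble(
      food_id = c(nfd_id, v1_id, v2_id, raw_id, dish_id),
      description = c(paste0(W, ", plain, not further defined"),
                      paste0(W, ", ", vs[1]),
                      paste0(W, ", ", vs[2]),
                      paste0(W, ", raw"),
                      paste0(W, ", ", sample(dishes, 1))),
      discretionary_flag = FALSE,
      energy_kj_per_100g = energy(5))
    gm <- rbind(fam_groups[1:3, , drop = FALSE],
                fam_groups[1, , drop = FALSE],  # raw decoy mirrors the summary
                fam_groups[4, , drop = FALSE])
    for (g in adg_food_groups()) fam[[g]] <- unname(gm[, g])
    rows[[length(rows) + 1L]] <- fam
    manifest[[length(manifest) + 1L]] <- tibble(
      target_word = w, role = "family", intended_match = nfd_id,
      nfd_id = nfd_id, variant_ids = paste(v1_id, v2_id, sep = ";"),
      raw_decoy_id = raw_id, dish_decoy_id = dish_id)
  }

  if (n_zero > 0) {
    zwords <- vocab[((seq_len(n_zero) - 1L) %% max(k, 1L)) + 1L]
    if (k == 0) zwords <- rep("food", n_zero)
    zids <- vapply(seq_len(n_zero), function(i) new_id(), character(1))
    zero <- tibble(food_id = zids,
                   description = paste0(cap1(zwords),
                                        ", separable fat, discarded"),
                   discretionary_flag = FALSE,
                   energy_kj_per_100g = energy(n_zero))
    for (g in adg_food_groups()) zero[[g]] <- 0
    rows[[length(rows) + 1L]] <- zero
    manifest[[length(manifest) + 1L]] <- tibble(
      target_word = zwords, role = "all_zero", intended_match = NA_character_,
      nfd_id = NA_character_, variant_ids = zids,
      raw_decoy_id = NA_character_, dish_decoy_id = NA_character_)
  }

  if (n_fill > 0) {
    fwords <- sample(filler_words(), n_fill, replace = TRUE)
    fq <- sample(variants, n_fill, replace = TRUE)
    fids <- vapply(seq_len(n_fill), function(i) new_id(), character(1))
    fill <- tibble(food_id = fids,
                   description = paste0(cap1(fwords), ", ", fq),
                   discretionary_flag = FALSE,
                   energy_kj_per_100g = energy(n_fill))
    fg <- random_groups(n_fill)
    for (g in adg_food_groups()) fill[[g]] <- unname(fg[, g])
    # top up NFD markers to the requested fraction
    n_nfd_target <- round(spec$fraction_nfd * spec$n_foods)
    extra_nfd <- min(max(0L, n_nfd_target - k), n_fill)
    if (extra_nfd > 0) {
      idx <- sample.int(n_fill, extra_nfd)
      fill$description[idx] <- paste0(cap1(fwords[idx]),
                                      ", not further defined")
    }
    rows[[length(rows) + 1L]] <- fill
  }

  db <- bind_rows(rows)[, db_columns()]
  # top up discretionary flags to the requested fraction (never on all-zero
  # decoys, whose exclusion rule requires a clear flag)
  n_disc_target <- round(spec$fraction_discretionary * spec$n_foods)
  eligible <- which(rowSums(as.matrix(db[adg_food_groups()])) > 0)
  n_flag <- min(n_disc_target, length(eligible))
  if (n_flag > 0) {
    db$discretionary_flag[sample(eligible, n_flag)] <- TRUE
  }
  list(db = as_adg_db(db), manifest = bind_rows(manifest))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic per-person intake table
#'
#' Draws grams/day per person and item from a right-skewed log-normal
#' distribution (the conventional shape for dietary intake data), with a
#' configurable zero-inflation probability for items not consumed.
#' Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param items Item definition tibble ([read_ffq_items()]) or character
#'   vector of item names.
#' @param n_persons Number of persons (0 gives an empty, header-only table).
#' @param meanlog,sdlog Log-normal parameters of grams/day.
#' @param p_zero Probability an item is not consumed (recorded as 0 g/day).
#' @param path Optional CSV path; when given the table is also written
#'   (byte-identical across runs for a fixed seed).
#' @return Tibble with `person_id`, `item_name`, `grams_per_day`.
#' @export
generate_intake_profile <- function(seed, items, n_persons,
                                    meanlog = log(30), sdlog = 0.8,
                                    p_zero = 0.2, path = NULL) {
  names_ <- if (is.character(items)) items else items$item_name
  if (length(names_) == 0) {
    abort("at least one item is required", class = "adgat_spec_error")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  if (n_persons == 0) {
    out <- tibble(person_id = character(), item_name = character(),
                  grams_per_day = numeric())
  } else {
    out <- tidyr::expand_grid(
      person_id = sprintf("P%04d", seq_len(n_persons)),
      item_name = names_)
    g <- rlnorm(nrow(out), meanlog, sdlog)
    g[runif(nrow(out)) < p_zero] <- 0
    out$grams_per_day <- round(g, 2)
  }
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
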