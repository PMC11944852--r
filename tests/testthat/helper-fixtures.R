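# In-code fixtures shared across test files.

# a tiny database builder: descriptions plus optional per-record overrides
mini_db <- function(descriptions, groups = NULL, flag = FALSE, energy = 1000) {
  n <- length(descriptions)
  db <- tibble::tibble(
    food_id = sprintf("F%03d", seq_len(n)),
    description = descriptions,
    discretionary_flag = rep_len(flag, n),
    energy_kj_per_100g = rep_len(energy, n))
  if (is.null(groups)) {
    groups <- matrix(1, n, 5)
  }
  colnames(groups) <- adg_food_groups()
  for (g in adg_food_groups()) db[[g]] <- groups[, g]
  as_adg_db(db)
}

# matched-record set with given flags and energies (for aggregator tests)
mini_matched <- function(flags, energy = NULL, groups = NULL) {
  n <- length(flags)
  if (is.null(energy)) energy <- rep(1000, n)
  mini_db(sprintf("Food %d, test", seq_len(n)), groups = groups,
          flag = flags, energy = energy)
}

write_db_csv <- function(db, path = tempfile(fileext = ".csv")) {
  readr::write_csv(db, path, progress = FALSE)
  path
}
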