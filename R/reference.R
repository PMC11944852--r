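#' Paths to the packaged data files
#'
#' `adgat_reference_path()` locates the packaged 101-item food-group summary
#' table (servings per 100 g per FFQ item of the Dietary Questionnaire for
#' Epidemiological Studies); `dqes_items_path()` locates the curated item
#' definition file for the same questionnaire.
#'
#' @return File path.
#' @export
adgat_reference_path <- function() {
  system.file("extdata", "adgat_reference_table.csv", package = "adgat",
              mustWork = TRUE)
}

#' @rdname adgat_reference_path
#' @export
dqes_items_path <- function() {
  system.file("extdata", "dqes_items.yaml", package = "adgat", mustWork = TRUE)
}

#' Load the packaged reference summary table
#'
#' Returns the 101-row Australian Dietary Guidelines Adherence Tool
#' (ADG-AT): for each FFQ item, servings per 100 g of the five food groups
#' plus discretionary servings per 100 g, its expected form, and the method
#' by which it was matched. The packaged file is integrity-checked against
#' a pinned checksum so that transcription drift fails loudly.
#'
#' @param check Verify checksum and row count against the packaged
#'   manifest (default `TRUE`).
#' @return Tibble of class `adgat_tbl`, 101 rows.
#' @export
#' @examples
#' tab <- load_reference_table()
#' tab[tab$item_name == "Apples", ]
load_reference_table <- function(check = TRUE) {
  path <- adgat_reference_path()
  if (check) {
    manifest <- yaml::read_yaml(
      system.file("extdata", "reference_manifest.yaml", package = "adgat",
                  mustWork = TRUE))
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, manifest$md5)) {
      abort(paste0("reference table checksum mismatch: ", md5,
                   " != ", manifest$md5),
            class = "adgat_integrity_error")
    }
  }
  tab <- as_adgat_table(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  if (check && nrow(tab) != manifest$n_rows) {
    abort(paste0("reference table has ", nrow(tab), " rows; expected ",
                 manifest$n_rows),
          class = "adgat_integrity_error")
  }
  tab
}
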