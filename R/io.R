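#' Write a cohort to CSV plus a JSON data dictionary
#'
#' The CSV holds one row per participant with missing cells left empty; the
#' dictionary records each feature column's modality tag, value type, units
#' and plausibility bounds, plus the categorical level sets needed for a
#' lossless round trip.
#'
#' @param cohort A `cohort_tbl`.
#' @param dir Output directory (created if absent).
#' @param name Basename for the two files (`<name>.csv`,
#'   `<name>_dictionary.json`).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, name = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dict <- cohort_dictionary(cohort)
  if (is.null(dict)) abort_schema("cohort carries no data dictionary")
  csv <- file.path(dir, paste0(name, ".csv"))
  dict_path <- file.path(dir, paste0(name, "_dictionary.json"))
  readr::write_csv(cohort, csv, na = "")
  levels_map <- purrr::map(
    purrr::set_names(names(cohort)[vapply(cohort, is.factor, logical(1))]),
    ~ levels(cohort[[.x]])
  )
  jsonlite::write_json(
    list(columns = dict, factor_levels = levels_map),
    dict_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(csv = csv, dictionary = dict_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the files.
#' @param name Basename used when writing.
#' @return A `cohort_tbl` equal to the one written, including missing cells,
#'   factor levels and the dictionary attribute.
#' @export
read_cohort <- function(dir, name = "cohort") {
  csv <- file.path(dir, paste0(name, ".csv"))
  dict_path <- file.path(dir, paste0(name, "_dictionary.json"))
  if (!file.exists(csv) || !file.exists(dict_path)) {
    abort_arg(sprintf("no cohort named '%s' under '%s'", name, dir))
  }
  meta <- jsonlite::read_json(dict_path, simplifyVector = TRUE)
  dict <- tibble::as_tibble(meta$columns)

  tbl <- readr::read_csv(csv, na = "", show_col_types = FALSE, progress = FALSE)
  expected <- c("participant_id", "diagnosis", "subtype", dict$column)
  unknown <- setdiff(names(tbl), expected)
  if (length(unknown) > 0) {
    abort_schema(sprintf("CSV columns absent from the dictionary: %s",
                         paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(dict$column, names(tbl))
  if (length(missing_cols) > 0) {
    abort_schema(sprintf("dictionary columns absent from the CSV: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  for (cn in names(meta$factor_levels)) {
    tbl[[cn]] <- factor(tbl[[cn]], levels = meta$factor_levels[[cn]])
  }
  int_cols <- dict$column[dict$value_type %in% c("ordinal", "binary")]
  for (cn in intersect(int_cols, names(tbl))) tbl[[cn]] <- as.integer(tbl[[cn]])
  tbl$diagnosis <- as.integer(tbl$diagnosis)
  if (!"subtype" %in% names(tbl)) tbl$subtype <- NA_character_
  tbl$subtype <- as.character(tbl$subtype)
  tbl <- tbl[, expected]
  attr(tbl, "dictionary") <- dict
  class(tbl) <- c("cohort_tbl", class(tbl))
  tbl
}
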