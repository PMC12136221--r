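#' Validate a subject covariate table
#'
#' A subject table is a data frame with one row per subject and columns
#' `subject_id`, `age` (years), `sex`, `race`, `bmi` (kg/m^2), `handedness`
#' (laterality score), `rms_motion` (mm), plus one `acc_<epoch>` column per
#' scored epoch holding percent-correct accuracy in `[0, 100]` (missing
#' values allowed and dropped pairwise in correlations).
#'
#' @param table A data frame.
#' @param dataset Optional `contrast_dataset`; if given, every dataset
#'   subject must appear exactly once in the table.
#' @return The validated table, invisibly usable downstream.
#' @export
validate_subject_table <- function(table, dataset = NULL) {
  needed <- c("subject_id", "age", "sex", "race", "bmi", "handedness",
              "rms_motion")
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("schema error: subject table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(table$subject_id))
    stop("schema error: duplicated subject ids in table", call. = FALSE)
  if (any(table$age <= 0, na.rm = TRUE))
    stop("schema error: non-positive age", call. = FALSE)
  if (any(table$rms_motion < 0, na.rm = TRUE))
    stop("schema error: negative rms_motion", call. = FALSE)
  acc <- accuracy_columns(table)
  if (length(acc)) {
    vals <- as.matrix(table[acc])
    if (any(vals < 0 | vals > 100, na.rm = TRUE))
      stop("schema error: accuracy outside [0, 100]", call. = FALSE)
  }
  if (!is.null(dataset)) {
    pos <- match(dataset$subject_ids, table$subject_id)
    if (anyNA(pos))
      stop("schema error: dataset subjects missing from table: ",
           paste(dataset$subject_ids[is.na(pos)], collapse = ", "),
           call. = FALSE)
  }
  table
}

accuracy_columns <- function(table) grep("^acc_", names(table), value = TRUE)

#' Read/write the subject covariate table (tab-separated, header row)
#'
#' @param path File path.
#' @return `read_subject_table` returns a validated data frame.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  tab$subject_id <- as.character(tab$subject_id)
  validate_subject_table(tab)
}

#' @rdname read_subject_table
#' @param table A subject table.
#' @export
write_subject_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exclude subjects by head motion
#'
#' Retains only subjects whose root-mean-square head displacement is
#' *strictly* below `threshold` (a subject at exactly the threshold is
#' excluded), preserving subject order in both the table and the dataset.
#'
#' @param table Subject table.
#' @param dataset A `contrast_dataset` covering the same subjects.
#' @param threshold Motion threshold in mm (default 2, the conventional cut).
#' @return A list with elements `table` and `dataset`, both filtered.
#' @export
filter_by_motion <- function(table, dataset, threshold = 2) {
  stopifnot(threshold > 0)
  validate_subject_table(table, dataset)
  keep_ids <- table$subject_id[table$rms_motion < threshold]
  keep_ids <- keep_ids[keep_ids %in% dataset$subject_ids]
  if (!length(keep_ids))
    stop("empty-cohort error: all subjects excluded at threshold ",
         threshold, " mm", call. = FALSE)
  tab <- table[table$subject_id %in% keep_ids, , drop = FALSE]
  rownames(tab) <- NULL
  sel <- which(dataset$subject_ids %in% keep_ids)
  ds <- dataset
  ds$subject_ids <- dataset$subject_ids[sel]
  ds$left_values <- dataset$left_values[sel, , , drop = FALSE]
  ds$right_values <- dataset$right_values[sel, , , drop = FALSE]
  list(table = tab, dataset = validate_contrast_dataset(ds))
}
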