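# Per-object annotation tables: one row per traced filament or microtubule.
# Lengths are in micrometres to match how lumen-occupancy statistics are
# reported; use um_to_nm() when a nanometre value is needed.

.annotation_cols <- c("tomogram_id", "object_id", "object_kind",
                      "class_label", "length_um", "host_microtubule_id")

#' Construct an annotation table
#'
#' Validates a data frame of per-object records: traced filaments and
#' microtubules, their class labels, lengths (micrometres) and, for lumenal
#' filaments, the microtubule that hosts them. Extra columns are preserved.
#'
#' @param df data frame with columns `tomogram_id`, `object_id`,
#'   `object_kind` (`"filament"` or `"microtubule"`), `class_label`,
#'   `length_um` and optionally `host_microtubule_id`.
#' @return The validated data frame with class `annotation_table`.
#' @export
annotation_table <- function(df) {
  df <- as.data.frame(df)
  if (!"host_microtubule_id" %in% names(df)) df$host_microtubule_id <- NA
  missing_cols <- setdiff(.annotation_cols, names(df))
  if (length(missing_cols) > 0)
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$object_kind %in% c("filament", "microtubule")))
    stop("`object_kind` must be \"filament\" or \"microtubule\"")
  bad <- which(!is.finite(df$length_um) | df$length_um < 0)
  if (length(bad) > 0)
    stop("negative or non-finite length_um in row(s): ",
         paste(bad, collapse = ", "))
  fil <- df[df$object_kind == "filament", , drop = FALSE]
  has_host <- !is.na(fil$host_microtubule_id) & fil$host_microtubule_id != ""
  if (any(has_host)) {
    mt <- df[df$object_kind == "microtubule", , drop = FALSE]
    key <- paste(mt$tomogram_id, mt$object_id)
    ref <- paste(fil$tomogram_id, fil$host_microtubule_id)[has_host]
    orphan <- !(ref %in% key)
    if (any(orphan))
      stop("host_microtubule_id does not match any microtubule in the same ",
           "tomogram for filament row(s): ",
           paste(which(df$object_kind == "filament")[has_host][orphan],
                 collapse = ", "))
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read an annotation table from CSV
#'
#' @param path CSV file with a header row naming at least the columns listed
#'   in [annotation_table()]. Unknown columns are kept.
#' @return An [annotation_table].
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_table(df)
}

#' Write an annotation table to CSV
#'
#' @param table an [annotation_table] (or coercible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  table <- annotation_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert micrometres to nanometres
#' @param um length in micrometres.
#' @return length in nanometres.
#' @export
um_to_nm <- function(um) um * 1000
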