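# Delimited-text I/O for every pipeline schema. All files are plain CSV/TSV
# so intermediate results stay inspectable with command-line tools.

#' Validate a plate feature table against the screen schema
#'
#' Checks the columns `plate`, `well`, `target`, `role` and at least one
#' numeric `feature_*` column, uniqueness of wells within a plate
#' (and replicate, when present), and that the feature set is identical
#' across plates (guaranteed by the wide layout).
#'
#' @param table A plate table data frame.
#' @return The table, invisibly; errors name the offending column.
#' @export
validate_plate_table <- function(table) {
  for (col in c("plate", "well", "target", "role")) {
    if (!col %in% names(table)) {
      stop(sprintf("plate table is missing column '%s'", col), call. = FALSE)
    }
  }
  feats <- feature_columns(table)
  if (length(feats) == 0) {
    stop("plate table has no 'feature_*' columns", call. = FALSE)
  }
  for (f in feats) {
    if (!is.numeric(table[[f]])) {
      stop(sprintf("feature column '%s' is not numeric", f), call. = FALSE)
    }
  }
  key <- if ("replicate" %in% names(table)) {
    interaction(table$plate, table$replicate, table$well, drop = TRUE)
  } else {
    interaction(table$plate, table$well, drop = TRUE)
  }
  if (anyDuplicated(key)) {
    stop("duplicate well ids within a plate", call. = FALSE)
  }
  invisible(table)
}

#' Write / read plate feature tables
#'
#' @param tables Long plate table (see [generate_screen()]).
#' @param path CSV file path.
#' @return `read_plate_tables()` returns the validated table.
#' @export
write_plate_tables <- function(tables, path) {
  validate_plate_table(tables)
  utils::write.csv(tables, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_tables
#' @export
read_plate_tables <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate_table(tab)
  tab
}

#' Write / read a gene-by-sample count matrix
#'
#' Tab-separated text with a leading `gene` column.
#'
#' @param counts Gene-by-sample matrix.
#' @param path TSV file path.
#' @return `read_count_matrix()` returns the matrix.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  m
}

#' Write / read a sample sheet
#'
#' @param samples Data frame with at least `sample`, `condition`, `day`.
#' @param path CSV file path.
#' @return `read_sample_sheet()` returns the data frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample", "condition")) {
    if (!col %in% names(s)) {
      stop(sprintf("sample sheet is missing column '%s'", col), call. = FALSE)
    }
  }
  s
}

#' Write / read colony-count tables
#'
#' @param counts Data frame `condition`, `replicate`, `count`.
#' @param path CSV file path.
#' @return `read_colony_counts()` returns the data frame.
#' @export
write_colony_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_colony_counts
#' @export
read_colony_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("condition", "replicate", "count") %in% names(x))) {
    stop("colony table must have columns condition, replicate, count",
         call. = FALSE)
  }
  x
}
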