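# Spreadsheet-style IO: one column per set, first row = set names. XLSX reads
# touch only the first sheet of the workbook; CSV/TSV are read as text so
# numeric-looking identifiers survive verbatim.

detect_format <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "csv", "tsv", "xlsx"))
  if (format != "auto") return(format)
  switch(tolower(tools::file_ext(path)),
         xlsx = "xlsx", csv = "csv", tsv = "tsv", txt = "tsv",
         stop_cogwheel("format", sprintf(
           "cannot infer format of '%s'; pass format = csv/tsv/xlsx", path)))
}

read_cells <- function(path, format) {
  if (!file.exists(path)) {
    stop_cogwheel("format", sprintf("input file not found: %s", path))
  }
  if (format == "xlsx") return(read_xlsx_first_sheet(path))
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE, colClasses = "character",
                      check.names = FALSE, fill = TRUE, quote = "\"",
                      na.strings = character(0), blank.lines.skip = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop_cogwheel("format", sprintf(
      "failed to parse '%s' as %s: %s", path, format, conditionMessage(e))))
  as.matrix(df)
}

#' Read a set collection from a spreadsheet or delimited file
#'
#' Each column is one set, in column order (the first column is set 1). With
#' `header = TRUE` (default) the first row carries the set names; otherwise
#' sets are named `Set1 .. SetN`. XLSX workbooks are read from their first
#' sheet only; additional sheets are ignored. Cells are canonicalized via
#' [canonicalize_entries()], so blank cells and duplicates are dropped.
#'
#' @param path input file (`.csv`, `.tsv`/`.txt`, or `.xlsx`).
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"xlsx"`.
#' @param header logical; is the first row the set names?
#' @param case_sensitive,strip label comparison options, see
#'   [canonicalize_entries()].
#' @return a [set_collection()].
#' @export
read_collection <- function(path, format = "auto", header = TRUE,
                            case_sensitive = TRUE, strip = TRUE) {
  format <- detect_format(path, format)
  mat <- read_cells(path, format)
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    stop_cogwheel("format", sprintf("'%s' contains no data", path))
  }
  # drop columns that are entirely blank (trailing separators etc.)
  blank <- apply(mat, 2, function(col) all(is.na(col) | !nzchar(trimws(col))))
  mat <- mat[, !blank, drop = FALSE]
  n <- ncol(mat)
  if (n < 2L || n > 6L) {
    stop_cogwheel("set_count", sprintf(
      "'%s' has %d data column(s); 2 to 6 sets are supported", path, n))
  }
  if (header) {
    nm <- trimws(mat[1L, ])
    if (any(is.na(nm)) || any(!nzchar(nm))) {
      stop_cogwheel("format", "header row has a blank set name")
    }
    body <- mat[-1L, , drop = FALSE]
  } else {
    nm <- paste0("Set", seq_len(n))
    body <- mat
  }
  if (anyDuplicated(nm)) {
    stop_cogwheel("format", sprintf("duplicate set names in header: %s",
                                    paste(unique(nm[duplicated(nm)]),
                                          collapse = ", ")))
  }
  sets <- stats::setNames(lapply(seq_len(n), function(j) body[, j]), nm)
  set_collection(sets, case_sensitive = case_sensitive, strip = strip)
}

cols_to_matrix <- function(cols, headers = names(cols)) {
  depth <- max(vapply(cols, length, integer(1)), 0L)
  mat <- matrix(NA_character_, depth + 1L, length(cols))
  mat[1L, ] <- headers
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    if (length(v)) mat[1L + seq_along(v), j] <- v
  }
  mat
}

write_table_file <- function(cols, headers, path) {
  mat <- cols_to_matrix(cols, headers)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    write_xlsx_sheets(list(Sheet1 = mat), path)
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    out <- mat
    out[is.na(out)] <- ""
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write a collection back to disk, one column per set
#'
#' @param collection a [set_collection()].
#' @param path output file; `.csv`, `.tsv`, or `.xlsx` by extension.
#' @return the path, invisibly.
#' @export
write_collection <- function(collection, path) {
  write_table_file(collection$sets, names(collection$sets), path)
}

#' Export the per-region membership table
#'
#' One column per region, ordered by ascending region index. Column headers
#' are `"<index>:<set names joined by the intersection sign>"`, mirroring the
#' numerical set order of the master diagram. Empty regions are omitted
#' unless `include_empty = TRUE` restores all `2^n - 1` columns.
#'
#' @param partition a `venn_partition`.
#' @param path output file (`.csv`, `.tsv`, or `.xlsx`); `NULL` to skip
#'   writing.
#' @param include_empty keep empty regions as empty columns?
#' @return invisibly, a `region_table`: list with `region_index`,
#'   `signature`, `header`, and `members` (a list of member vectors), in
#'   strictly increasing region-index order.
#' @export
write_region_table <- function(partition, path = NULL, include_empty = FALSE) {
  nm <- names(partition$collection$sets)
  idx <- seq_len(2L^partition$n - 1L)
  sizes <- region_sizes(partition)
  if (!include_empty) idx <- idx[sizes[idx] > 0L]
  sig <- vapply(idx, signature_label, character(1), set_names = nm)
  headers <- sprintf("%d:%s", idx, sig)
  members <- lapply(idx, function(i) region_members(partition, i))
  if (!is.null(path)) write_table_file(members, headers, path)
  invisible(structure(
    list(region_index = idx, signature = sig, header = headers,
         members = members),
    class = "region_table"))
}

#' Write the region summary (the histogram behind the category bar charts)
#'
#' One CSV row per region: index, signature, size, and five-colour category
#' code relative to the reference set.
#'
#' @param partition a `venn_partition`.
#' @param reference_index reference set (index or name); default set 1.
#' @param path output CSV; `NULL` to skip writing.
#' @return invisibly, a data.frame with columns `region_index`, `signature`,
#'   `size`, `category`.
#' @export
write_summary <- function(partition, reference_index = 1L, path = NULL) {
  ref <- resolve_reference(partition$collection, reference_index)
  df <- category_histogram(partition, ref)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(df)
}
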