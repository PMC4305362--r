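# Reading and validation of two-factor long-format tables.

GREEK_MAP <- c(
  "α" = "alpha",  "β" = "beta",  "γ" = "gamma",
  "δ" = "delta",  "ε" = "epsilon", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu",    "σ" = "sigma",
  "τ" = "tau",    "ω" = "omega",
  "Α" = "Alpha",  "Β" = "Beta",  "Γ" = "Gamma",
  "Δ" = "Delta",  "Σ" = "Sigma", "Ω" = "Omega"
)

#' Sanitize a column or factor-level name into a valid identifier
#'
#' Valid names consist of letters, digits, dots and underscores, and start
#' with a letter or with a dot not followed by a digit. Spaces become
#' underscores, Greek letters are transliterated to their ASCII names
#' (tables render them poorly), any other invalid character becomes a dot,
#' and names with an invalid leading pattern (e.g. `".2Ala"`) are prefixed
#' with `"X"`. The mapping is deterministic and idempotent; names are never
#' abbreviated, however long.
#'
#' @param raw Character vector of non-empty raw names.
#' @return Character vector of valid identifiers, same length as `raw`.
#' @examples
#' sanitize_name(c(".2Ala", "amino acid", "Asp"))
#' @export
sanitize_name <- function(raw) {
  if (!is.character(raw) || length(raw) == 0 || any(is.na(raw)) ||
      any(!nzchar(raw))) {
    stop("`raw` must be a character vector of non-empty names", call. = FALSE)
  }
  out <- raw
  for (g in names(GREEK_MAP)) out <- gsub(g, GREEK_MAP[[g]], out, fixed = TRUE)
  out <- gsub("[ \t]+", "_", out)
  out <- gsub("[^A-Za-z0-9._]", ".", out)
  bad_start <- grepl("^\\.[0-9]", out) | !grepl("^[A-Za-z.]", out)
  out[bad_start] <- paste0("X", out[bad_start])
  out
}

#' Order factor levels
#'
#' Levels are ordered lexicographically ascending by code point (C locale),
#' so the digit-prefix trick works: prefixing the level to be shown first
#' with `"1"`, the next with `"2"`, and so on, overrides the alphabetical
#' default with no special casing.
#'
#' @param levels Character vector (or set) of observed levels.
#' @return The distinct levels in code-point order.
#' @examples
#' order_levels(c("LF", "HF"))           # HF first
#' order_levels(c("2Lean", "1Overweight"))
#' @export
order_levels <- function(levels) {
  lv <- unique(as.character(levels))
  if (length(lv) < 2) {
    stop("a factor must have at least 2 distinct levels", call. = FALSE)
  }
  sort(lv, method = "radix")
}

# TRUE for columns in which at least one non-missing value fails numeric
# parsing; such columns are treated as factors, everything else (including
# integer-coded columns) as numeric responses.
is_factor_column <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(FALSE)
  if (is.numeric(x)) return(FALSE)
  any(is.na(suppressWarnings(as.numeric(as.character(x)))))
}

#' Infer the two-factor schema of a raw table
#'
#' Text-valued columns (any value failing numeric parsing) become factors —
#' exactly two are required — and numeric columns become responses. Factor
#' order follows column order in the table; level order within each factor
#' is lexicographic ascending ([order_levels()]). Factor levels should be
#' described using letters, not numbers: a factor coded 0/1 parses as
#' numeric and the schema error states that two factors could not be found.
#'
#' @param raw_table A data frame with a header row, at least 3 columns and
#'   1 data row.
#' @param sheet Sheet label used in error messages.
#' @return A list with `factor_columns` (length-2 character),
#'   `response_columns`, and `level_order` (named list of level orderings),
#'   of class `"tw_schema"`.
#' @export
infer_schema <- function(raw_table, sheet = "data") {
  raw_table <- as.data.frame(raw_table)
  if (ncol(raw_table) < 3 || nrow(raw_table) < 1) {
    stop(sprintf("sheet '%s': need at least 3 columns and 1 data row", sheet),
         call. = FALSE)
  }
  is_fac <- vapply(raw_table, is_factor_column, logical(1))
  if (sum(is_fac) != 2) {
    stop(sprintf(paste0(
      "sheet '%s': unable to find two factors (found %d text-valued ",
      "column%s); factor levels should be described using letters, ",
      "not numbers"), sheet, sum(is_fac), if (sum(is_fac) == 1) "" else "s"),
      call. = FALSE)
  }
  factor_columns <- names(raw_table)[is_fac]
  response_columns <- names(raw_table)[!is_fac]
  if (length(response_columns) == 0) {
    stop(sprintf("sheet '%s': no numeric response columns found", sheet),
         call. = FALSE)
  }
  for (fc in factor_columns) {
    if (any(is.na(raw_table[[fc]]) | !nzchar(as.character(raw_table[[fc]])))) {
      stop(sprintf("sheet '%s': factor column '%s' has missing values",
                   sheet, fc), call. = FALSE)
    }
  }
  level_order <- lapply(factor_columns, function(fc) {
    lv <- unique(as.character(raw_table[[fc]]))
    if (length(lv) < 2) {
      stop(sprintf("sheet '%s': factor '%s' has fewer than 2 levels",
                   sheet, fc), call. = FALSE)
    }
    order_levels(lv)
  })
  names(level_order) <- factor_columns
  structure(list(factor_columns = factor_columns,
                 response_columns = response_columns,
                 level_order = level_order),
            class = "tw_schema")
}

#' Construct a two-factor dataset from a raw table
#'
#' Internal workhorse shared by [read_dataset()] and the synthetic
#' generator: sanitizes names, infers the schema and assembles the
#' validated container.
#'
#' @param raw_table Data frame with two text factor columns and numeric
#'   responses.
#' @param source_sheet Label of the originating sheet.
#' @return A `two_way_dataset` object: list with `data` (tibble; factor
#'   columns as character, responses as double), `factor_names`,
#'   `responses`, `levels` (named list), `source_sheet` and `name_changes`.
#' @export
as_two_way_dataset <- function(raw_table, source_sheet = "data") {
  raw_table <- as.data.frame(raw_table, check.names = FALSE)
  raw_names <- names(raw_table)
  clean <- sanitize_name(raw_names)
  changes <- raw_names != clean
  if (anyDuplicated(clean)) {
    stop(sprintf("sheet '%s': sanitized column names collide", source_sheet),
         call. = FALSE)
  }
  names(raw_table) <- clean
  schema <- infer_schema(raw_table, sheet = source_sheet)
  data <- raw_table[, c(schema$factor_columns, schema$response_columns),
                    drop = FALSE]
  for (fc in schema$factor_columns) data[[fc]] <- as.character(data[[fc]])
  for (rc in schema$response_columns) {
    data[[rc]] <- as.numeric(as.character(data[[rc]]))
  }
  structure(list(
    data = tibble::as_tibble(data),
    factor_names = schema$factor_columns,
    responses = schema$response_columns,
    levels = schema$level_order,
    source_sheet = source_sheet,
    name_changes = tibble::tibble(raw = raw_names[changes],
                                  sanitized = clean[changes])
  ), class = "two_way_dataset")
}

#' @export
print.two_way_dataset <- function(x, ...) {
  cat(sprintf("<two_way_dataset '%s': %d records>\n", x$source_sheet,
              nrow(x$data)))
  cat(sprintf("  factors:   %s (%s) x %s (%s)\n",
              x$factor_names[1], paste(x$levels[[1]], collapse = ", "),
              x$factor_names[2], paste(x$levels[[2]], collapse = ", ")))
  cat(sprintf("  responses: %s\n", paste(x$responses, collapse = ", ")))
  invisible(x)
}

read_sheet_raw <- function(source, sheet) {
  ext <- tolower(tools::file_ext(source))
  if (ext == "csv") {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  } else {
    readxl::read_excel(source, sheet = sheet)
  }
}

#' Read one dataset from a workbook sheet or CSV file
#'
#' Reads a long-format table — two text factor columns plus one or more
#' numeric response columns — from an `.xlsx`/`.xls` sheet or a CSV file,
#' and validates it. Column names are sanitized ([sanitize_name()]); any
#' renaming is recorded in the returned object's `name_changes`.
#'
#' @param source Path to a workbook (`.xlsx`, `.xls`) or `.csv` file.
#' @param sheet Sheet name or 1-based index (ignored for CSV).
#' @return A `two_way_dataset` (see [as_two_way_dataset()]).
#' @examples
#' \donttest{
#' ds <- generate_dataset(generator_spec(seed = 1))
#' f <- tempfile(fileext = ".xlsx")
#' write_fixture_workbook(list(ds), f)
#' read_dataset(f)
#' }
#' @export
read_dataset <- function(source, sheet = 1) {
  if (!file.exists(source)) {
    stop(sprintf("file '%s' does not exist or is not readable", source),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(source))
  sheet_name <- as.character(sheet)
  if (ext != "csv") {
    sheets <- readxl::excel_sheets(source)
    if (is.numeric(sheet)) {
      if (sheet < 1 || sheet > length(sheets)) {
        stop(sprintf("sheet index %d out of range for '%s'", sheet, source),
             call. = FALSE)
      }
      sheet_name <- sheets[[sheet]]
    } else if (!sheet %in% sheets) {
      stop(sprintf("sheet '%s' not found in '%s'", sheet, source),
           call. = FALSE)
    } else {
      sheet_name <- sheet
    }
  } else {
    sheet_name <- basename(source)
  }
  raw <- read_sheet_raw(source, sheet_name)
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop(sprintf("sheet '%s' of '%s' is empty", sheet_name, source),
         call. = FALSE)
  }
  as_two_way_dataset(raw, source_sheet = sheet_name)
}

#' Read every non-empty sheet of a workbook
#'
#' @param source Path to a workbook; for CSV files the result is a
#'   singleton list.
#' @return List of `two_way_dataset`, one per non-empty sheet in sheet
#'   order; sheet names are preserved for table titling. Any sheet that
#'   fails validation aborts with an error naming that sheet.
#' @export
read_workbook <- function(source) {
  if (!file.exists(source)) {
    stop(sprintf("file '%s' does not exist or is not readable", source),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(source))
  if (ext == "csv") return(list(read_dataset(source)))
  sheets <- readxl::excel_sheets(source)
  if (length(sheets) == 0) stop("workbook has no sheets", call. = FALSE)
  out <- list()
  for (s in sheets) {
    raw <- readxl::read_excel(source, sheet = s)
    if (nrow(raw) == 0 || ncol(raw) == 0) next  # skip empty sheets
    out[[s]] <- as_two_way_dataset(raw, source_sheet = s)
  }
  if (length(out) == 0) stop("workbook has no non-empty sheets", call. = FALSE)
  out
}
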