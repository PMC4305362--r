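# End-to-end pipeline: workbook -> per-sheet, per-response ANOVA + MCP +
# letters -> RTF (+ optional PDF interaction plots).

#' Run the full table pipeline on a workbook
#'
#' For each selected sheet: validate, then per response compute cell
#' summaries, the two-way fit (both factor orders when `both_orders` and
#' the design is unbalanced), the cell-means fit, the chosen pairwise
#' procedure with its letter display (when `options$phc`) and the pooled
#' SEM (pooled format); assemble the tables and render them into one RTF
#' document. A sheet with exactly one observation per treatment triggers
#' an alert that two-way ANOVA will not be conducted and no table is
#' generated for it; other sheets still produce output.
#'
#' @param input Path to an `.xlsx`/`.xls` workbook or `.csv` file.
#' @param out Output RTF path, or `NULL` to skip writing.
#' @param sheets `"all"` or a character vector of sheet names.
#' @param options A [table_options()].
#' @param config An [mcp_config()] (defaults to `options$test`).
#' @param both_orders Emit a second table with the reversed factor order
#'   for unbalanced sheets (sequential sums of squares depend on the
#'   order there)?
#' @param plots Optional PDF path for interaction plots.
#' @param plot_sheet Sheet (index into the selection) to plot; default
#'   the first, matching the usual single-sheet workflow.
#' @param quiet Suppress informational messages?
#' @return A run report: list with `tables` (the `summary_table` objects),
#'   `rtf` (the `rtf_document` or `NULL`), `sheets` (tibble of sheet,
#'   status, message), `files` (paths written) and `exit_code`
#'   (0 = all sheets ok, 1 = partial, 2 = nothing succeeded).
#' @export
run_twoway <- function(input, out = NULL, sheets = "all",
                       options = table_options(), config = NULL,
                       both_orders = FALSE, plots = NULL,
                       plot_sheet = 1L, quiet = FALSE) {
  if (is.null(config)) {
    config <- mcp_config(test = options$test, alpha = options$alpha)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  datasets <- read_workbook(input)
  if (!identical(sheets, "all")) {
    missing_sheets <- setdiff(sheets, names(datasets))
    if (length(missing_sheets) > 0) {
      stop(sprintf("sheet(s) not found: %s",
                   paste(missing_sheets, collapse = ", ")), call. = FALSE)
    }
    datasets <- datasets[sheets]
  }
  status <- character(0); msgs <- character(0)
  tables <- list()
  plotted_ds <- NULL
  for (si in seq_along(datasets)) {
    ds <- datasets[[si]]
    if (nrow(ds$name_changes) > 0) {
      for (nc in seq_len(nrow(ds$name_changes))) {
        say("sheet '%s': renamed '%s' to '%s'", ds$source_sheet,
            ds$name_changes$raw[nc], ds$name_changes$sanitized[nc])
      }
    }
    design <- check_design(ds)
    for (w in design$warnings) say("sheet '%s': %s", ds$source_sheet, w)
    say("sheet '%s': per-cell n in [%d, %d]%s", ds$source_sheet,
        design$min_n, design$max_n,
        if (design$balanced) " (balanced)" else " (unbalanced)")
    res <- tryCatch({
      tbls <- list(analyze_dataset(ds, options, config))
      if (both_orders && !design$balanced) {
        tbls <- c(tbls, list(analyze_dataset(
          ds, options, config, factor_order = rev(ds$factor_names))))
        tbls[[2]]$title <- paste0(ds$source_sheet, " (factor order: ",
                                  paste(rev(ds$factor_names),
                                        collapse = ", "), ")")
      }
      tbls
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- c(status, "failed")
      msgs <- c(msgs, conditionMessage(res))
      say("sheet '%s': %s; a table will not be generated",
          ds$source_sheet, conditionMessage(res))
    } else {
      status <- c(status, "ok"); msgs <- c(msgs, "")
      tables <- c(tables, res)
      if (si == plot_sheet && is.null(plotted_ds)) plotted_ds <- ds
    }
  }
  report <- list(
    tables = tables,
    rtf = NULL,
    sheets = tibble::tibble(sheet = names(datasets), status = status,
                            message = msgs),
    files = character(0),
    exit_code = if (all(status == "ok")) 0L else
      if (any(status == "ok")) 1L else 2L)
  if (length(tables) > 0) {
    report$rtf <- render_rtf(tables)
    if (!is.null(out)) {
      write_document(report$rtf, out)
      report$files <- c(report$files, out)
      say("wrote %d table%s to '%s'", length(tables),
          if (length(tables) == 1) "" else "s", out)
    }
    if (!is.null(plots) && !is.null(plotted_ds)) {
      render_interaction_plots(plotted_ds, path = plots)
      report$files <- c(report$files, plots)
      say("wrote interaction plots to '%s'", plots)
    }
  }
  if (report$exit_code == 2L && !quiet) {
    warning("no sheet could be analyzed", call. = FALSE)
  }
  report
}

#' Command-line entry point
#'
#' Thin option parser over [run_twoway()]; used by the
#' `inst/scripts/twoway_tables.R` script. Options may also be supplied
#' via `--config`, a YAML file whose keys mirror the flags.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit code (0/1/2), invisibly.
#' @export
twoway_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the command-line interface requires the 'optparse' package",
         call. = FALSE)
  }
  spec <- list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--plots", type = "character", default = NULL),
    optparse::make_option("--sheets", type = "character", default = "all"),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--sig-digits", type = "integer", default = 3L,
                          dest = "sig_digits"),
    optparse::make_option("--p-decimals", type = "integer", default = 3L,
                          dest = "p_decimals"),
    optparse::make_option("--test", type = "character",
                          default = "tukey"),
    optparse::make_option("--adjust", type = "character",
                          default = "none"),
    optparse::make_option("--format", type = "character",
                          default = "per-group"),
    optparse::make_option("--no-phc", action = "store_true",
                          default = FALSE, dest = "no_phc"),
    optparse::make_option("--both-orders", action = "store_true",
                          default = FALSE, dest = "both_orders"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--nsim", type = "integer", default = 10000L),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--quiet", action = "store_true",
                          default = FALSE))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args)
  if (!is.null(opt$config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("--config requires the 'yaml' package", call. = FALSE)
    }
    cfg <- yaml::read_yaml(opt$config)
    for (key in names(cfg)) opt[[gsub("-", "_", key)]] <- cfg[[key]]
  }
  if (is.null(opt$input)) stop("--input is required", call. = FALSE)
  fmt <- if (opt$format %in% c("pooled", "pooled_sem")) "pooled_sem" else
    "per_group_sem"
  options <- table_options(alpha = opt$alpha,
                           sig_digits = opt$sig_digits,
                           p_decimals = opt$p_decimals,
                           format = fmt, phc = !opt$no_phc,
                           test = opt$test)
  config <- mcp_config(test = opt$test, alpha = opt$alpha,
                       adjust = opt$adjust, nsim = opt$nsim,
                       seed = opt$seed)
  sheets <- if (identical(opt$sheets, "all")) "all" else
    strsplit(opt$sheets, ",", fixed = TRUE)[[1]]
  report <- run_twoway(opt$input, out = opt$out, sheets = sheets,
                       options = options, config = config,
                       both_orders = opt$both_orders, plots = opt$plots,
                       quiet = opt$quiet)
  invisible(report$exit_code)
}
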