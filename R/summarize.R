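# Numeric formatting, pooled SEM, and assembly of table rows and captions.

#' Table construction options
#'
#' @param alpha Significance level used for letters and captions.
#' @param sig_digits Significant digits for means and SEMs (default 3).
#' @param p_decimals Decimal places for displayed p-values (default 3).
#' @param format `"per_group_sem"` (mean +/- SEM in every treatment
#'   column) or `"pooled_sem"` (means only plus one pooled-SEM column).
#' @param phc Perform post-hoc pairwise comparisons and superscript the
#'   results? When `FALSE` the table is produced without superscripts.
#' @param test Pairwise test used when `phc` is `TRUE`; see [mcp_config()].
#' @return A list of class `table_options`.
#' @export
table_options <- function(alpha = 0.05, sig_digits = 3L, p_decimals = 3L,
                          format = c("per_group_sem", "pooled_sem"),
                          phc = TRUE,
                          test = c("tukey", "snk", "duncan", "lsd",
                                   "westfall")) {
  format <- match.arg(format)
  test <- match.arg(test)
  stopifnot(sig_digits >= 1, p_decimals >= 1, alpha > 0, alpha < 1)
  structure(list(alpha = alpha, sig_digits = as.integer(sig_digits),
                 p_decimals = as.integer(p_decimals), format = format,
                 phc = isTRUE(phc), test = test),
            class = "table_options")
}

#' Pooled standard error of the mean for a cell-means fit
#'
#' Balanced designs: `PSEM = sqrt(MSE * 2 / n)`, the common standard error
#' of every pairwise mean difference. Unbalanced designs: the per-pair
#' `sqrt(MSE * (1/n_i + 1/n_j))` is computed for every pair and the
#' largest is reported (a conservative single-column substitute; a pooled
#' SEM is best reserved for balanced designs).
#'
#' @param fit A `cell_means_fit`.
#' @return A single non-negative number in response units.
#' @examples
#' fit <- cell_means_fit_from_summary(c(45.3, 47.6, 46.2, 45.3),
#'                                    c(2.39, 2.97, 2.96, 3.45), n = 9)
#' pooled_sem(fit)  # about 4.20
#' @export
pooled_sem <- function(fit) {
  stopifnot(inherits(fit, "cell_means_fit"))
  n <- fit$cells$n
  if (fit$balanced) return(sqrt(fit$mse * 2 / n[1]))
  p <- pair_index(fit$k)
  max(sqrt(fit$mse * (1 / n[p$i] + 1 / n[p$j])))
}

#' Render a number with a fixed count of significant digits
#'
#' Follows the usual significant-digit rules: all nonzero digits count,
#' zeros between significant digits count, and trailing zeros right of the
#' decimal point count — so `format_sigfigs(3.2, 5)` is `"3.2000"` while
#' an integer result is not padded with decimal zeros (`359.4` at 3
#' digits is `"359"`). With `trim = TRUE` trailing fractional zeros are
#' removed after rounding (`6.40` prints as `"6.4"`), the convention used
#' for table cells.
#'
#' @param x Numeric vector (finite).
#' @param k Number of significant digits (>= 1).
#' @param trim Drop trailing fractional zeros after rounding?
#' @return Character vector.
#' @export
format_sigfigs <- function(x, k = 3L, trim = FALSE) {
  stopifnot(k >= 1)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  out <- vapply(x, function(xi) {
    y <- signif(xi, k)
    e <- if (y == 0) 0L else floor(log10(abs(y)))
    dec <- max(0L, k - 1L - e)
    formatC(y, format = "f", digits = dec)
  }, character(1))
  if (trim) {
    has_dot <- grepl("\\.", out)
    out[has_dot] <- sub("\\.?0+$", "", out[has_dot])
  }
  out
}

#' Render a p-value for display
#'
#' Values below the display resolution `10^-d` are shown as a bound
#' (`"<0.001"` at `d = 3`) so a positive p never prints as zero; larger
#' values are rounded to `d` decimals with trailing zeros trimmed
#' (`0.830` prints `"0.83"`, `1` prints `"1"`).
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @param d Number of decimal places (>= 1).
#' @return Character vector.
#' @export
format_pvalue <- function(p, d = 3L) {
  stopifnot(d >= 1)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  thr <- 10^(-d)
  vapply(p, function(pi) {
    if (pi < thr) {
      paste0("<", formatC(thr, format = "f", digits = d))
    } else {
      s <- formatC(round(pi, d), format = "f", digits = d)
      if (grepl("\\.", s)) s <- sub("\\.?0+$", "", s)
      s
    }
  }, character(1))
}

first_letter_abbrev <- function(x) toupper(substr(x, 1, 1))

#' Assemble a summary table from per-response results
#'
#' Builds the publication-table object: nested factor header (factor A
#' levels spanning factor B levels), one row per response with
#' `mean +/- SEM` cells (or means plus a pooled-SEM column), superscript
#' letters from the post-hoc letter display, the three p-value columns
#' (factor A, factor B, interaction), and an auto-generated caption.
#'
#' @param dataset A `two_way_dataset`.
#' @param results Named list (one entry per response, in order), each a
#'   list with components `cells` ([cell_summaries()] tibble), `anova`
#'   (`two_way_anova`), `letters` (`letter_display` or `NULL`) and `psem`
#'   (number or `NULL`).
#' @param options A [table_options()].
#' @return A `summary_table`: list with `title`, `factor_names`, `levels`,
#'   `responses`, `cell_text` / `cell_sup` (response x treatment character
#'   matrices), `pooled` (character or `NULL`), `p_text` (response x 3),
#'   `p_header`, `caption`, `caption_letters` and `options`.
#' @export
build_table <- function(dataset, results, options = table_options()) {
  if (!setequal(names(results), dataset$responses)) {
    stop("`results` must have one entry per response", call. = FALSE)
  }
  results <- results[dataset$responses]
  fa <- dataset$factor_names[1]; fb <- dataset$factor_names[2]
  grid <- treatment_grid(dataset)
  k <- nrow(grid)
  nr <- length(dataset$responses)
  pooled <- if (options$format == "pooled_sem") character(nr) else NULL
  cell_text <- matrix("", nr, k,
                      dimnames = list(dataset$responses, grid$treatment))
  cell_sup <- cell_text
  p_text <- matrix("", nr, 3, dimnames = list(dataset$responses, NULL))
  letters_used <- character(0)
  n_all <- integer(0)

  for (r in seq_len(nr)) {
    res <- results[[r]]
    cells <- res$cells
    stopifnot(identical(cells$treatment, grid$treatment))
    m_str <- format_sigfigs(cells$mean, options$sig_digits, trim = TRUE)
    if (options$format == "per_group_sem") {
      s_str <- ifelse(is.na(cells$sem), "NA",
                      format_sigfigs(ifelse(is.na(cells$sem), 0, cells$sem),
                                     options$sig_digits, trim = TRUE))
      cell_text[r, ] <- paste0(m_str, " ± ", s_str)
    } else {
      cell_text[r, ] <- m_str
      pooled[r] <- format_sigfigs(res$psem, options$sig_digits, trim = TRUE)
    }
    if (options$phc && !is.null(res$letters) &&
        res$letters$any_significant) {
      sup <- res$letters$assignment[cells$treatment]
      cell_sup[r, ] <- sup
      letters_used <- c(letters_used,
                        unlist(strsplit(sup[nzchar(sup)], "")))
    }
    at <- res$anova$table
    ord <- res$anova$factor_order
    p_for <- function(term) format_pvalue(at$p_value[at$term == term],
                                          options$p_decimals)
    p_text[r, ] <- c(p_for(fa), p_for(fb),
                     p_for(paste(ord[1], ord[2], sep = ":")))
    n_all <- c(n_all, cells$n)
  }

  letters_used <- sort(unique(letters_used))
  caption <- build_caption(options, n_all, letters_used,
                           dataset$factor_names)
  structure(list(
    title = dataset$source_sheet,
    factor_names = dataset$factor_names,
    levels = dataset$levels[dataset$factor_names],
    responses = dataset$responses,
    treatments = grid$treatment,
    cell_text = cell_text,
    cell_sup = cell_sup,
    pooled = pooled,
    p_text = p_text,
    p_header = c(fa, fb,
                 paste(first_letter_abbrev(fa), "×",
                       first_letter_abbrev(fb))),
    caption = caption$text,
    caption_letters = caption$letters,
    options = options
  ), class = "summary_table")
}

#' Auto-generate a table caption
#'
#' States the summary type (means +/- SEM, or means and pooled SEM), the
#' per-treatment sample size (a single n when uniform, a range otherwise),
#' the letter sentence (range of letters actually used, alpha, and the
#' test name) when superscripts appear, and the interaction-abbreviation
#' footnote.
#'
#' @param options A [table_options()].
#' @param n_info Integer vector (or grid) of per-cell sample sizes.
#' @param letters_used Character vector of letters appearing in the table.
#' @param factor_names Character pair of factor names.
#' @return List with `text` (full caption) and `letters` (the letter-range
#'   token to be superscripted, or `NULL`).
#' @export
build_caption <- function(options, n_info, letters_used, factor_names) {
  n_info <- as.integer(n_info)
  n_part <- if (length(unique(n_info)) == 1) {
    sprintf("n = %d per treatment group", n_info[1])
  } else {
    sprintf("n = %d-%d per treatment group", min(n_info), max(n_info))
  }
  lead <- if (options$format == "per_group_sem") {
    "Values are means ± SEM"
  } else {
    "Values are means and pooled SEM"
  }
  text <- sprintf("%s, %s.", lead, n_part)
  letters_tok <- NULL
  if (length(letters_used) > 0) {
    letters_tok <- if (length(letters_used) == 1) letters_used else
      paste0(letters_used[1], "-", letters_used[length(letters_used)])
    text <- paste0(text, sprintf(
      paste0(" %sMeans in a row without a common superscript letter ",
             "differ (P < %s) as analyzed by two-way ANOVA and the ",
             "%s test."),
      letters_tok,
      format_sigfigs(options$alpha, 2, trim = TRUE),
      toupper(options$test)))
  }
  abbr <- paste(first_letter_abbrev(factor_names[1]), "×",
                first_letter_abbrev(factor_names[2]))
  text <- paste0(text, sprintf(" %s = %s × %s interaction effect.",
                               abbr, factor_names[1], factor_names[2]))
  list(text = text, letters = letters_tok)
}

#' Number of display columns of a summary table
#'
#' `ab` treatment columns, plus one pooled-SEM column in pooled format,
#' plus the three p-value columns (the leading response-name column is not
#' counted).
#'
#' @param table A `summary_table`.
#' @return Integer column count.
#' @export
n_table_columns <- function(table) {
  length(table$treatments) + (!is.null(table$pooled)) + 3L
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("Summary table '%s' (%d responses x %d columns)\n",
              x$title, length(x$responses), n_table_columns(x)))
  body <- x$cell_text
  sup <- ifelse(nzchar(x$cell_sup), paste0("^", x$cell_sup), "")
  body[] <- paste0(body, sup)
  df <- data.frame(Variable = x$responses, body, check.names = FALSE)
  if (!is.null(x$pooled)) df$`Pooled SEM` <- x$pooled
  df[x$p_header] <- x$p_text
  print(df, row.names = FALSE)
  cat(x$caption, "\n")
  invisible(x)
}

#' Analyze one dataset into a summary table
#'
#' Runs the full per-response pipeline: cell summaries, two-way ANOVA,
#' cell-means fit, the configured pairwise procedure plus letter display
#' (when `options$phc`), and the pooled SEM (when pooled format), then
#' assembles everything with [build_table()].
#'
#' @param dataset A `two_way_dataset`.
#' @param options A [table_options()].
#' @param config An [mcp_config()]; its `test` is taken from
#'   `options$test` unless supplied explicitly.
#' @param factor_order Fitting order for the ANOVA; defaults to the order
#'   of appearance.
#' @return A `summary_table`.
#' @export
analyze_dataset <- function(dataset, options = table_options(),
                            config = NULL,
                            factor_order = dataset$factor_names) {
  if (is.null(config)) {
    config <- mcp_config(test = options$test, alpha = options$alpha)
  }
  results <- lapply(dataset$responses, function(r) {
    cells <- cell_summaries(dataset, r)
    an <- fit_two_way(dataset, r, factor_order)
    fit <- fit_cell_means(dataset, r)
    lt <- NULL
    if (options$phc) {
      pw <- pairwise_tests(fit, config)
      lt <- compact_letter_display(significance_matrix(pw),
                                   stats::setNames(cells$mean,
                                                   cells$treatment))
    }
    psem <- if (options$format == "pooled_sem") pooled_sem(fit) else NULL
    list(cells = cells, anova = an, letters = lt, psem = psem)
  })
  names(results) <- dataset$responses
  build_table(dataset, results, options)
}
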