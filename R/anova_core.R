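# Two-way ANOVA (sequential SS) and the cell-means fit behind all
# post-hoc work.

treatment_grid <- function(ds) {
  la <- ds$levels[[ds$factor_names[1]]]
  lb <- ds$levels[[ds$factor_names[2]]]
  g <- expand.grid(level_b = lb, level_a = la, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  # A-major order: all B levels within the first A level first
  tibble::tibble(level_a = g$level_a, level_b = g$level_b,
                 treatment = paste(g$level_a, g$level_b, sep = "-"))
}

response_frame <- function(ds, response) {
  if (!response %in% ds$responses) {
    stop(sprintf("response '%s' not found in dataset '%s'", response,
                 ds$source_sheet), call. = FALSE)
  }
  fa <- ds$factor_names[1]; fb <- ds$factor_names[2]
  d <- data.frame(
    a = factor(ds$data[[fa]], levels = ds$levels[[fa]]),
    b = factor(ds$data[[fb]], levels = ds$levels[[fb]]),
    y = ds$data[[response]])
  d[!is.na(d$y), , drop = FALSE]
}

#' Per-treatment summaries (mean, SEM, n) for one response
#'
#' Missing values are excluded per cell, so `n` counts non-missing
#' observations only. Treatments are listed in A-order x B-order sequence.
#'
#' @param dataset A `two_way_dataset`.
#' @param response Name of a response column.
#' @return Tibble with columns `level_a`, `level_b`, `treatment`, `mean`,
#'   `sem`, `n`; `sem` is the sample standard deviation over `sqrt(n)`
#'   (0 for a constant cell, `NA` when `n = 1`).
#' @export
cell_summaries <- function(dataset, response) {
  d <- response_frame(dataset, response)
  grid <- treatment_grid(dataset)
  stats_for <- function(la, lb) {
    y <- d$y[d$a == la & d$b == lb]
    if (length(y) == 0) {
      stop(sprintf(paste0("incomplete factorial: no observations for ",
                          "treatment %s-%s on response '%s'"),
                   la, lb, response), call. = FALSE)
    }
    c(mean = mean(y),
      sem = if (length(y) > 1) stats::sd(y) / sqrt(length(y)) else NA_real_,
      n = length(y))
  }
  st <- mapply(stats_for, grid$level_a, grid$level_b, USE.NAMES = FALSE)
  grid$mean <- st["mean", ]
  grid$sem <- st["sem", ]
  grid$n <- as.integer(st["n", ])
  grid
}

#' Fit the two-way ANOVA with interaction
#'
#' Sequential (Type I) decomposition in the given factor order:
#' `SS(A)`, `SS(B | A)`, `SS(A:B | A, B)` and the residual. F ratios use
#' the residual mean square; p-values come from the F distribution. In
#' balanced designs the decomposition is invariant to the factor order; in
#' unbalanced designs it is not, which is why the order is an explicit
#' argument (and why [run_twoway()] can emit both orders).
#'
#' @param dataset A `two_way_dataset`.
#' @param response Name of a response column.
#' @param factor_order Character pair giving the fitting order; defaults to
#'   the order of appearance in the source table.
#' @return A `two_way_anova` object: list with `table` (tibble of term,
#'   df, ss, ms, statistic, p_value), `mse`, `df_residual`, `factor_order`
#'   and `response`.
#' @export
fit_two_way <- function(dataset, response,
                        factor_order = dataset$factor_names) {
  stopifnot(length(factor_order) == 2,
            setequal(factor_order, dataset$factor_names))
  d <- response_frame(dataset, response)
  n_cell <- table(d$a, d$b)
  if (any(n_cell == 0)) {
    stop(sprintf("incomplete factorial for response '%s'", response),
         call. = FALSE)
  }
  if (all(n_cell == 1)) {
    stop(paste0("only one observation per treatment: two-way ANOVA will ",
                "not be conducted"), call. = FALSE)
  }
  if (factor_order[1] == dataset$factor_names[1]) {
    f1 <- d$a; f2 <- d$b
  } else {
    f1 <- d$b; f2 <- d$a
  }
  df_resid <- nrow(d) - length(levels(d$a)) * length(levels(d$b))
  if (df_resid < 1) {
    stop(sprintf("no residual degrees of freedom for response '%s'",
                 response), call. = FALSE)
  }
  fit <- stats::lm(y ~ f1 * f2, data = data.frame(y = d$y, f1 = f1, f2 = f2))
  an <- stats::anova(fit)
  term_names <- c(factor_order[1], factor_order[2],
                  paste(factor_order[1], factor_order[2], sep = ":"),
                  "residual")
  tab <- tibble::tibble(
    term = term_names,
    df = as.integer(an$Df),
    ss = an$`Sum Sq`,
    ms = an$`Mean Sq`,
    statistic = an$`F value`,
    p_value = an$`Pr(>F)`)
  structure(list(table = tab,
                 mse = tab$ms[tab$term == "residual"],
                 df_residual = tab$df[tab$term == "residual"],
                 factor_order = factor_order,
                 response = response),
            class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA for '%s' (order: %s, %s)\n", x$response,
              x$factor_order[1], x$factor_order[2]))
  print(as.data.frame(x$table))
  invisible(x)
}

#' Fit the cell-means (one-way) model used for post-hoc comparisons
#'
#' The two factors are collapsed into a single factor with `a * b` levels
#' (one per treatment) and the pooled within-cell variance is the error
#' estimate. This MSE equals the two-way fit's residual mean square on the
#' same data.
#'
#' @inheritParams fit_two_way
#' @return A `cell_means_fit`: list with `cells` (as [cell_summaries()]),
#'   `mse`, `df_error`, `balanced`, `k` (number of treatments),
#'   `factor_names`, `levels` and `response`.
#' @export
fit_cell_means <- function(dataset, response) {
  cells <- cell_summaries(dataset, response)
  if (all(cells$n == 1)) {
    stop(paste0("only one observation per treatment: the cell-means model ",
                "has no within-cell variability"), call. = FALSE)
  }
  d <- response_frame(dataset, response)
  n_total <- nrow(d)
  k <- nrow(cells)
  df_error <- n_total - k
  if (df_error < 1) {
    stop(sprintf("no error degrees of freedom for response '%s'", response),
         call. = FALSE)
  }
  ss_within <- sum(vapply(seq_len(k), function(i) {
    y <- d$y[d$a == cells$level_a[i] & d$b == cells$level_b[i]]
    sum((y - mean(y))^2)
  }, numeric(1)))
  structure(list(cells = cells,
                 mse = ss_within / df_error,
                 df_error = df_error,
                 balanced = length(unique(cells$n)) == 1,
                 k = k,
                 factor_names = dataset$factor_names,
                 levels = dataset$levels,
                 response = response),
            class = "cell_means_fit")
}

#' @export
print.cell_means_fit <- function(x, ...) {
  cat(sprintf("Cell-means fit for '%s': %d treatments, MSE = %.4g, df = %d%s\n",
              x$response, x$k, x$mse, x$df_error,
              if (x$balanced) " (balanced)" else " (unbalanced)"))
  print(as.data.frame(x$cells))
  invisible(x)
}

#' Build a cell-means fit from published summary statistics
#'
#' Reconstructs the post-hoc machinery from a printed table: per-treatment
#' means, SEMs and sample sizes are enough to recover the pooled MSE
#' (`MSE = sum((n_i - 1) * n_i * sem_i^2) / sum(n_i - 1)`, which reduces to
#' `n * mean(sem^2)` in balanced designs). Useful for re-analysing tables
#' for which raw data are unavailable.
#'
#' @param means,sems Numeric vectors, one entry per treatment.
#' @param n Integer sample size(s), scalar or per treatment.
#' @param treatments Optional treatment labels.
#' @return A `cell_means_fit` (with `levels`/`factor_names` unset).
#' @examples
#' fit <- cell_means_fit_from_summary(
#'   means = c(359, 294, 353, 292),
#'   sems  = c(10.3, 4.39, 7.43, 3.76), n = 9)
#' fit$mse  # about 438.1
#' @export
cell_means_fit_from_summary <- function(means, sems, n,
                                        treatments = NULL) {
  k <- length(means)
  stopifnot(k >= 2, length(sems) == k, all(sems >= 0))
  n <- as.integer(rep(n, length.out = k))
  stopifnot(all(n >= 2))
  if (is.null(treatments)) treatments <- paste0("T", seq_len(k))
  df_error <- sum(n) - k
  # sem = sd / sqrt(n)  =>  (n-1) s^2 = (n-1) n sem^2
  mse <- sum((n - 1) * n * sems^2) / df_error
  cells <- tibble::tibble(level_a = treatments, level_b = "",
                          treatment = treatments,
                          mean = as.numeric(means), sem = as.numeric(sems),
                          n = n)
  structure(list(cells = cells, mse = mse, df_error = df_error,
                 balanced = length(unique(n)) == 1, k = k,
                 factor_names = NULL, levels = NULL, response = "summary"),
            class = "cell_means_fit")
}

#' Report on the factorial design of a dataset
#'
#' @param dataset A `two_way_dataset`.
#' @return List with `balanced` flag, `n_grid` (per-cell record counts,
#'   a x b matrix), `min_n`, `max_n`, and `warnings` — one per response
#'   whose missing values make its per-cell n differ from the record grid
#'   (SEMs then use response-specific n).
#' @export
check_design <- function(dataset) {
  fa <- dataset$factor_names[1]; fb <- dataset$factor_names[2]
  a <- factor(dataset$data[[fa]], levels = dataset$levels[[fa]])
  b <- factor(dataset$data[[fb]], levels = dataset$levels[[fb]])
  n_grid <- table(a, b)
  warnings <- character(0)
  for (r in dataset$responses) {
    n_miss <- sum(is.na(dataset$data[[r]]))
    if (n_miss > 0) {
      warnings <- c(warnings, sprintf(
        "response '%s' has %d missing value%s; its per-cell n differs from the record grid",
        r, n_miss, if (n_miss == 1) "" else "s"))
    }
  }
  list(balanced = length(unique(as.vector(n_grid))) == 1,
       n_grid = n_grid,
       min_n = min(n_grid), max_n = max(n_grid),
       warnings = warnings)
}
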