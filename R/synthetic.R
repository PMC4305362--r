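# Synthetic two-factor datasets with known ground truth.

#' Specification for the synthetic two-factor generator
#'
#' Encodes the standard two-way ANOVA sampling model: each cell (i, j)
#' yields independent draws from `Normal(cell_means[i, j], sigma^2)` with
#' a common standard deviation across all cells (the homoscedasticity
#' assumption of the analysis). Missingness, when requested, is applied
#' completely at random to response values only.
#'
#' @param levels_a,levels_b Character vectors of factor levels.
#' @param cell_means Numeric `a x b` matrix of true cell means.
#' @param sigma Common within-cell standard deviation (> 0).
#' @param n Per-cell sample size: a scalar or an `a x b` integer matrix,
#'   all entries >= 1.
#' @param missing_rate Probability that a response value is masked.
#' @param seed Integer seed; generation is deterministic given the full
#'   generator specification.
#' @param response Name of the generated response column.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(levels_a = c("A1", "A2"),
                           levels_b = c("B1", "B2"),
                           cell_means = matrix(0, length(levels_a),
                                               length(levels_b)),
                           sigma = 1, n = 9L, missing_rate = 0,
                           seed = 1L, response = "y") {
  a <- length(levels_a); b <- length(levels_b)
  if (is.matrix(cell_means) && !all(dim(cell_means) == c(a, b))) {
    stop("`cell_means` must be an a x b matrix", call. = FALSE)
  }
  if (!is.matrix(cell_means) && !length(cell_means) %in% c(1L, a * b)) {
    stop("`cell_means` must have length 1 or a * b", call. = FALSE)
  }
  cell_means <- matrix(as.numeric(cell_means), a, b)
  if (length(n) == 1) n <- matrix(as.integer(n), a, b)
  n <- matrix(as.integer(n), a, b)
  if (a < 2 || b < 2) stop("each factor needs >= 2 levels", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0",
                                             call. = FALSE)
  if (any(n < 1)) stop("all per-cell sample sizes must be >= 1",
                       call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(list(levels_a = levels_a, levels_b = levels_b,
                 cell_means = cell_means, sigma = sigma, n = n,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 response = response),
            class = "generator_spec")
}

#' Generate a synthetic two-factor dataset
#'
#' @param spec A [generator_spec()].
#' @param factor_names Names for the two factor columns.
#' @param source_sheet Sheet label recorded on the dataset.
#' @return A `two_way_dataset` with one response column.
#' @examples
#' ds <- generate_dataset(generator_spec(cell_means = matrix(c(0, 0, 0, 5),
#'                                                           2, 2)))
#' check_design(ds)$balanced
#' @export
generate_dataset <- function(spec, factor_names = c("FactorA", "FactorB"),
                             source_sheet = "synthetic") {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  rows <- list()
  for (i in seq_along(spec$levels_a)) {
    for (j in seq_along(spec$levels_b)) {
      ni <- spec$n[i, j]
      y <- stats::rnorm(ni, spec$cell_means[i, j], spec$sigma)
      if (spec$missing_rate > 0) {
        y[stats::runif(ni) < spec$missing_rate] <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        a = spec$levels_a[i], b = spec$levels_b[j], y = y,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  names(df) <- c(factor_names, spec$response)
  as_two_way_dataset(df, source_sheet = source_sheet)
}

#' Reconstruct a dataset with exact published summary statistics
#'
#' Builds, for each response, per-cell samples whose sample mean and SEM
#' equal the supplied values exactly (each cell is
#' `mean + sd * standardized sequence`). The reconstruction is synthetic:
#' it reproduces first and second moments, not the original raw data, but
#' every downstream quantity that depends only on cell means, SEMs and n
#' (ANOVA tables, post-hoc tests, pooled SEMs) matches what the published
#' summaries imply.
#'
#' @param summary_tbl Data frame with columns `response`, `level_a`,
#'   `level_b`, `mean`, `sem` (one row per response x treatment).
#' @param n Per-cell sample size (scalar, >= 2).
#' @param factor_names Names for the two factor columns.
#' @param source_sheet Sheet label.
#' @return A `two_way_dataset` with one column per response.
#' @export
dataset_from_summary <- function(summary_tbl, n,
                                 factor_names = c("FactorA", "FactorB"),
                                 source_sheet = "reconstructed") {
  stopifnot(n >= 2,
            all(c("response", "level_a", "level_b", "mean", "sem") %in%
                  names(summary_tbl)))
  z <- scale(seq_len(n))[, 1]  # mean 0, sd exactly 1
  responses <- unique(summary_tbl$response)
  la <- order_levels(summary_tbl$level_a)
  lb <- order_levels(summary_tbl$level_b)
  grid <- expand.grid(level_b = lb, level_a = la,
                      stringsAsFactors = FALSE)[, c("level_a", "level_b")]
  df <- data.frame(
    a = rep(grid$level_a, each = n),
    b = rep(grid$level_b, each = n), stringsAsFactors = FALSE)
  for (r in responses) {
    col <- numeric(0)
    for (g in seq_len(nrow(grid))) {
      row <- summary_tbl[summary_tbl$response == r &
                           summary_tbl$level_a == grid$level_a[g] &
                           summary_tbl$level_b == grid$level_b[g], ]
      if (nrow(row) != 1) {
        stop(sprintf("summary table needs exactly one row for (%s, %s, %s)",
                     r, grid$level_a[g], grid$level_b[g]), call. = FALSE)
      }
      col <- c(col, row$mean + row$sem * sqrt(n) * z)
    }
    df[[r]] <- col
  }
  names(df)[1:2] <- factor_names
  as_two_way_dataset(df, source_sheet = source_sheet)
}

#' Write datasets to an xlsx fixture workbook
#'
#' One sheet per dataset (named after `source_sheet`), header row =
#' factor names followed by response names. The file is a plain OOXML
#' spreadsheet readable by [read_workbook()]; writing is deterministic.
#'
#' @param datasets A list of `two_way_dataset` objects.
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_fixture_workbook <- function(datasets, path) {
  if (inherits(datasets, "two_way_dataset")) datasets <- list(datasets)
  if (!is.list(datasets) || length(datasets) == 0 ||
      !all(vapply(datasets, inherits, logical(1), "two_way_dataset"))) {
    stop("`datasets` must be a non-empty list of two_way_dataset objects",
         call. = FALSE)
  }
  sheets <- lapply(datasets, function(ds) ds$data)
  names(sheets) <- vapply(datasets, function(ds) ds$source_sheet,
                          character(1))
  if (anyDuplicated(names(sheets))) {
    names(sheets) <- make.unique(names(sheets))
  }
  write_xlsx_minimal(sheets, path)
  invisible(path)
}
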