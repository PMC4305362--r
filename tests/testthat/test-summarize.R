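test_that("pooled SEM matches the published excerpt and the balanced identity", {
  # Asp: MSE rebuilt from the per-cell SEMs, n = 9 -> pooled SEM 4.2
  fit <- plasma_fit("Asp")
  expect_equal(fit$mse, 79.193, tolerance = 1e-4)
  expect_equal(signif(pooled_sem(fit), 3), 4.20, tolerance = 1e-12)
  # all SEMs equal s in a balanced design -> PSEM = s * sqrt(2)
  f2 <- cell_means_fit_from_summary(c(1, 2, 3), rep(1.7, 3), 8)
  expect_equal(pooled_sem(f2), 1.7 * sqrt(2), tolerance = 1e-12)
})

test_that("unbalanced pooled SEM is the maximum per-pair value", {
  fit <- cell_means_fit_from_summary(c(0, 0, 0, 0), rep(1, 4),
                                     n = c(9, 9, 9, 4))
  fit$mse <- 100
  fit$balanced <- FALSE
  expect_equal(pooled_sem(fit), sqrt(100 * (1 / 9 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(pooled_sem(fit), 6.01, tolerance = 0.01)
})

test_that("significant-digit rendering follows the counting rules", {
  expect_identical(format_sigfigs(400.06, 5), "400.06")
  expect_identical(format_sigfigs(3.2, 5), "3.2000")
  expect_identical(format_sigfigs(359.4, 3), "359")
  expect_identical(format_sigfigs(0.003, 1), "0.003")
  expect_identical(format_sigfigs(6.4, 3), "6.40")
  expect_identical(format_sigfigs(6.4, 3, trim = TRUE), "6.4")
  expect_identical(format_sigfigs(999.6, 3), "1000")
  expect_error(format_sigfigs(Inf, 3), "finite")
  expect_error(format_sigfigs(NA_real_, 3), "finite")
})

test_that("rendered significant digits round-trip to the rounded value", {
  set.seed(77)
  x <- c(10^runif(200, -3, 4) * sample(c(-1, 1), 200, TRUE), 0)
  for (k in c(2, 3, 5)) {
    s <- format_sigfigs(x, k)
    expect_equal(as.numeric(s), signif(x, k), tolerance = 1e-12)
  }
})

test_that("p-value display bounds small values and trims zeros", {
  expect_identical(format_pvalue(0.0004, 3), "<0.001")
  expect_identical(format_pvalue(0.830, 3), "0.83")
  expect_identical(format_pvalue(1.0, 3), "1")
  expect_identical(format_pvalue(0.42, 3), "0.42")
  expect_identical(format_pvalue(0.05, 2), "0.05")
  # a positive p never renders as zero
  set.seed(13)
  p <- 10^runif(100, -8, 0)
  for (d in 1:4) {
    expect_false(any(format_pvalue(p, d) == "0"))
  }
})

# A stub result set carrying the published Ser row values, so the
# formatting path is tested independently of the reconstruction error in
# the ANOVA p-values.
ser_results <- function(ds, phc = TRUE, pooled = FALSE) {
  cells <- cell_summaries(ds, "Ser")
  an <- fit_two_way(ds, "Ser")
  an$table$p_value[1:3] <- c(0.576, 0.0009, 0.807)
  lt <- NULL
  if (phc) {
    fit <- fit_cell_means(ds, "Ser")
    pw <- tukey_kramer(fit)
    lt <- compact_letter_display(significance_matrix(pw),
                                 setNames(cells$mean, cells$treatment))
  }
  list(Ser = list(cells = cells, anova = an, letters = lt,
                  psem = if (pooled) pooled_sem(fit_cell_means(ds, "Ser"))
                  else NULL))
}

test_that("per-group tables render the published serine row", {
  ds <- plasma_dataset("Ser")
  tbl <- build_table(ds, ser_results(ds), table_options())
  expect_identical(unname(tbl$cell_text["Ser", ]),
                   c("359 ± 10.3", "294 ± 4.39", "353 ± 7.43",
                     "292 ± 3.76"))
  expect_identical(unname(tbl$cell_sup["Ser", ]), c("a", "b", "a", "b"))
  expect_identical(unname(tbl$p_text["Ser", ]),
                   c("0.576", "<0.001", "0.807"))
  expect_identical(n_table_columns(tbl), 7L)
  expect_match(tbl$caption, "means ± SEM")
  expect_match(tbl$caption, "n = 9 per treatment group")
  expect_match(tbl$caption, "TUKEY")
  expect_match(tbl$caption, "a-b")
})

test_that("pooled tables report means plus one pooled SEM column", {
  ds <- plasma_dataset("Ser")
  tbl <- build_table(ds, ser_results(ds, pooled = TRUE),
                     table_options(format = "pooled_sem"))
  expect_identical(unname(tbl$cell_text["Ser", ]),
                   c("359", "294", "353", "292"))
  expect_identical(tbl$pooled, "9.87")
  expect_identical(n_table_columns(tbl), 8L)
  expect_match(tbl$caption, "means and pooled SEM")
})

test_that("phc = FALSE removes every superscript and the letter sentence", {
  ds <- plasma_dataset("Ser")
  tbl <- build_table(ds, ser_results(ds, phc = FALSE),
                     table_options(phc = FALSE))
  expect_true(all(tbl$cell_sup == ""))
  expect_no_match(tbl$caption, "superscript")
  expect_match(tbl$caption, "interaction effect")
})

test_that("captions adapt to n ranges, tests and letter usage", {
  cap <- build_caption(table_options(test = "duncan"), c(9, 9, 8, 9),
                       c("a", "b", "c"), c("Diet", "Weight"))
  expect_match(cap$text, "n = 8-9 per treatment group")
  expect_match(cap$text, "DUNCAN")
  expect_identical(cap$letters, "a-c")
  expect_match(cap$text, "D × W = Diet × Weight interaction effect")
  cap2 <- build_caption(table_options(), 9, character(0),
                        c("Diet", "Weight"))
  expect_no_match(cap2$text, "superscript")
})

test_that("table column count invariant holds across generated tables", {
  set.seed(31)
  for (fmt in c("per_group_sem", "pooled_sem")) {
    ds <- generate_dataset(generator_spec(
      levels_a = c("x", "y", "z"), levels_b = c("u", "v"),
      cell_means = matrix(rnorm(6, 20, 4), 3, 2), n = 4L, seed = 61))
    tbl <- analyze_dataset(ds, table_options(format = fmt))
    expect_identical(n_table_columns(tbl),
                     6L + (fmt == "pooled_sem") + 3L)
  }
})
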