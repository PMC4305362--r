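test_that("cell summaries recover hand-computed means, SEMs and n", {
  cs <- cell_summaries(toy_dataset(), "y")
  expect_identical(cs$treatment,
                   c("a1-b1", "a1-b2", "a2-b1", "a2-b2"))
  expect_equal(cs$mean, c(2, 3, 6, 7))
  # each cell is (x, x + 2): s = sqrt(2), so sem = s / sqrt(2) = 1
  expect_equal(cs$sem, rep(1, 4), tolerance = 1e-12)
  expect_identical(cs$n, rep(2L, 4))

  const <- as_two_way_dataset(data.frame(
    A = rep(c("x", "y"), each = 3), B = rep(c("u", "v", "u"), 2),
    y = c(5, 5, 5, 1, 2, 3)))
  cc <- cell_summaries(const, "y")
  expect_equal(cc$mean[cc$treatment == "x-u"], 5)
  expect_equal(cc$sem[cc$treatment == "x-u"], 0)
  expect_identical(cc$n[cc$treatment == "x-u"], 2L)
})

test_that("missing response values are dropped per cell", {
  df <- data.frame(A = rep(c("x", "y"), each = 3),
                   B = rep("u", 6), y = c(1, 2, NA, 4, 5, 6))
  df$B[c(2, 3, 5, 6)] <- "v"
  ds <- as_two_way_dataset(df)
  cs <- cell_summaries(ds, "y")
  expect_identical(cs$n[cs$treatment == "x-v"], 1L)
  expect_identical(sum(cs$n), 5L)
})

test_that("two-way fit reproduces the hand-computed toy decomposition", {
  an <- fit_two_way(toy_dataset(), "y")
  expect_equal(an$table$ss, c(32, 2, 0, 8), tolerance = 1e-10)
  expect_equal(an$table$df, c(1L, 1L, 1L, 4L))
  expect_equal(an$mse, 2)
  expect_equal(an$table$statistic[1], 16)
  expect_equal(an$table$p_value[1], 0.01613009, tolerance = 1e-6)
  expect_equal(an$table$statistic[2], 1)
  expect_equal(an$table$p_value[2], 0.373901, tolerance = 1e-6)
  expect_equal(an$table$p_value[3], 1, tolerance = 1e-10)
  # t/F relation: the factor-A F equals the squared pooled t for the
  # A-margin comparison with 4 df
  expect_equal(an$table$p_value[1],
               2 * pt(-sqrt(an$table$statistic[1]), 4), tolerance = 1e-10)
})

test_that("balanced designs are invariant to factor order", {
  ds <- toy_dataset()
  a1 <- fit_two_way(ds, "y", c("A", "B"))
  a2 <- fit_two_way(ds, "y", c("B", "A"))
  expect_equal(sort(a1$table$ss), sort(a2$table$ss), tolerance = 1e-10)
  expect_equal(a1$mse, a2$mse)
})

test_that("sequential SS match the design-matrix oracle, both orders, unbalanced", {
  set.seed(21)
  for (rep in 1:15) {
    a <- sample(2:3, 1)
    spec <- generator_spec(
      levels_a = c("a1", "a2", "a3")[1:a],
      levels_b = c("b1", "b2"),
      cell_means = matrix(rnorm(a * 2, 10, 3), a, 2),
      sigma = 1.5, n = 5L, seed = rep)
    ds <- generate_dataset(spec)
    # unbalance by dropping the first record
    ds$data <- ds$data[-1, ]
    for (ord in list(ds$factor_names, rev(ds$factor_names))) {
      an <- fit_two_way(ds, "y", ord)
      orc <- seq_ss_oracle(ds, "y", ord)
      expect_equal(an$table$ss, orc$ss, tolerance = 1e-8)
      expect_equal(an$table$df, as.integer(orc$df))
      expect_equal(an$table$statistic[1:3], orc$f[1:3], tolerance = 1e-8)
      expect_equal(an$table$p_value[1:3], orc$p[1:3], tolerance = 1e-8)
    }
    a1 <- fit_two_way(ds, "y", ds$factor_names)
    a2 <- fit_two_way(ds, "y", rev(ds$factor_names))
    # order matters for the first sequential term in unbalanced designs
    expect_false(isTRUE(all.equal(a1$table$ss[1],
                                  a2$table$ss[2], tolerance = 1e-6)) &&
                   isTRUE(all.equal(a1$table$ss[2], a2$table$ss[1],
                                    tolerance = 1e-6)))
  }
})

test_that("the sequential decomposition always sums to the total SS", {
  set.seed(33)
  for (rep in 1:10) {
    ds <- generate_dataset(generator_spec(
      cell_means = matrix(rnorm(4, 0, 5), 2, 2), sigma = 2,
      n = matrix(sample(3:9, 4, TRUE), 2, 2), seed = 100 + rep))
    an <- fit_two_way(ds, "y")
    y <- ds$data$y
    total <- sum((y - mean(y))^2)
    expect_equal(sum(an$table$ss), total, tolerance = 1e-9 * total)
    expect_true(all(an$table$p_value[1:3] >= 0 &
                      an$table$p_value[1:3] <= 1))
    expect_true(all(an$table$statistic[1:3] >= 0))
  }
})

test_that("cell-means fit agrees with the two-way residual mean square", {
  ds <- toy_dataset()
  fit <- fit_cell_means(ds, "y")
  expect_equal(fit$mse, 2)
  expect_identical(fit$df_error, 4L)
  expect_true(fit$balanced)
  set.seed(55)
  ds2 <- generate_dataset(generator_spec(
    cell_means = matrix(rnorm(4), 2, 2),
    n = matrix(c(9, 9, 9, 4), 2, 2), seed = 56))
  f2 <- fit_cell_means(ds2, "y")
  a2 <- fit_two_way(ds2, "y")
  expect_equal(f2$mse, a2$mse, tolerance = 1e-12)
  expect_false(f2$balanced)
  # between-treatment SS of the cell-means fit = sum of the three
  # two-way terms (balanced case)
  an <- fit_two_way(ds, "y")
  y <- ds$data$y
  between <- sum((ave(y, paste(ds$data$A, ds$data$B)) - mean(y))^2)
  expect_equal(sum(an$table$ss[1:3]), between, tolerance = 1e-9)
})

test_that("one observation per treatment refuses the two-way ANOVA", {
  df <- data.frame(A = c("x", "x", "y", "y"), B = c("u", "v", "u", "v"),
                   y = 1:4)
  ds <- as_two_way_dataset(df)
  expect_error(fit_two_way(ds, "y"),
               "two-way ANOVA will not be conducted")
  expect_error(fit_cell_means(ds, "y"), "one observation")
})

test_that("an empty treatment cell is an incomplete factorial", {
  df <- data.frame(A = c("x", "x", "y", "y"), B = c("u", "u", "u", "v"),
                   y = c(1, 2, 3, 4))
  df <- rbind(df, data.frame(A = "y", B = "v", y = 5))
  ds <- as_two_way_dataset(df)
  expect_error(cell_summaries(ds, "y"), "incomplete factorial")
  expect_error(fit_two_way(ds, "y"), "incomplete factorial")
})

test_that("summary-statistics fits match fits of reconstructed raw data", {
  fitS <- plasma_fit("Ser")
  expect_equal(fitS$mse, 438.0854, tolerance = 1e-4)
  ds <- plasma_dataset("Ser")
  fitR <- fit_cell_means(ds, "Ser")
  expect_equal(fitR$mse, fitS$mse, tolerance = 1e-9)
  expect_equal(fitR$cells$mean, fitS$cells$mean, tolerance = 1e-9)
  expect_equal(fitR$cells$sem, fitS$cells$sem, tolerance = 1e-9)
})

test_that("check_design reports balance, n grid and missing-value warnings", {
  ds <- plasma_dataset(c("Ser", "Asp"))
  rep1 <- check_design(ds)
  expect_true(rep1$balanced)
  expect_true(all(rep1$n_grid == 9))
  expect_length(rep1$warnings, 0)

  ds2 <- toy_dataset()
  ds2$data <- ds2$data[-1, ]
  rep2 <- check_design(ds2)
  expect_false(rep2$balanced)
  expect_identical(c(rep2$min_n, rep2$max_n), c(1L, 2L))

  ds3 <- toy_dataset()
  ds3$data$y[2] <- NA
  expect_match(check_design(ds3)$warnings, "missing value")
})
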