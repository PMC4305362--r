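test_that("LSD reproduces hand-computed t tests with the pooled MSE", {
  fit <- fit_cell_means(toy_dataset(), "y")
  pw <- lsd_pairwise(fit)
  expect_identical(nrow(pw), 6L)  # 4 treatments -> 6 pairs
  row <- pw[pw$treatment_1 == "a1-b1" & pw$treatment_2 == "a2-b1", ]
  expect_equal(abs(row$statistic), 2.828427, tolerance = 1e-6)
  expect_equal(row$p_raw, 0.04742066, tolerance = 1e-6)
  # equal means -> t = 0, p = 1
  fit0 <- cell_means_fit_from_summary(c(5, 5), c(1, 1), 9)
  pw0 <- lsd_pairwise(fit0)
  expect_equal(pw0$statistic, 0)
  expect_equal(pw0$p_raw, 1)
})

test_that("a zero MSE is rejected as degenerate", {
  fit <- cell_means_fit_from_summary(c(1, 2), c(0.5, 0.5), 9)
  fit$mse <- 0
  expect_error(lsd_pairwise(fit), "MSE is zero")
})

test_that("p-value adjustment follows the stated rules", {
  expect_equal(adjust_pvalues(c(0.01, 0.5), "none"), c(0.01, 0.5))
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(rep(0.01, 6), "bonferroni")[1], 0.06)
  # hand step-down with monotonicity: (0.01,0.02,0.03) -> (0.03,0.04,0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "holm"),
               c(0.03, 0.04, 0.04))
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "\\[0, 1\\]")
})

test_that("holm and bonferroni adjustments are monotone in the input", {
  set.seed(91)
  for (rep in 1:25) {
    p <- runif(6)
    bump <- p
    i <- sample(6, 1)
    bump[i] <- min(1, bump[i] + runif(1, 0, 1 - bump[i]))
    for (m in c("holm", "bonferroni")) {
      expect_true(all(adjust_pvalues(bump, m) >=
                        adjust_pvalues(p, m) - 1e-12))
    }
  }
})

test_that("Tukey-Kramer uses the studentized range with k groups", {
  # critical value q(0.05; 4, 32) from published studentized-range tables
  expect_equal(qtukey(0.95, 4, 32), 3.83, tolerance = 0.005)
  fit <- plasma_fit("Ser")
  pw <- tukey_kramer(fit)
  sig <- pw[pw$significant, ]
  # exactly the Lean-vs-Overweight pairs, within and across diets
  expect_identical(nrow(sig), 4L)
  lean <- grepl("Lean$", c(sig$treatment_1, sig$treatment_2))
  over <- grepl("Overweight$", c(sig$treatment_1, sig$treatment_2))
  expect_true(all(xor(lean[1:4], lean[5:8])))
  expect_true(all(lean | over))
})

test_that("Tukey significance implies unadjusted LSD significance", {
  set.seed(17)
  for (rep in 1:20) {
    fit <- fit_cell_means(generate_dataset(generator_spec(
      cell_means = matrix(rnorm(4, 0, 1.5), 2, 2), seed = 300 + rep)),
      "y")
    tk <- tukey_kramer(fit)
    lsd <- lsd_pairwise(fit)
    expect_true(all(!tk$significant | lsd$significant))
  }
})

test_that("SNK at span 2 agrees with the unadjusted LSD for adjacent means", {
  set.seed(71)
  for (rep in 1:10) {
    fit <- fit_cell_means(generate_dataset(generator_spec(
      cell_means = matrix(rnorm(4, 0, 2), 2, 2), seed = 400 + rep)), "y")
    snk <- range_test(fit, mcp_config(test = "snk"))
    lsd <- lsd_pairwise(fit)
    ord <- order(-fit$cells$mean)
    # adjacent pairs in the mean ordering span 2 positions:
    # q(alpha, 2, df) = sqrt(2) t(alpha/2, df), so decisions coincide
    # whenever the pair is actually tested (protection can only veto)
    for (a in 1:3) {
      i <- ord[a]; j <- ord[a + 1]
      t1 <- fit$cells$treatment[min(i, j)]
      t2 <- fit$cells$treatment[max(i, j)]
      srow <- snk[snk$treatment_1 == t1 & snk$treatment_2 == t2, ]
      lrow <- lsd[lsd$treatment_1 == t1 & lsd$treatment_2 == t2, ]
      if (srow$significant) expect_true(lrow$significant)
    }
  }
})

test_that("Duncan protection levels follow 1 - (1 - alpha)^(p - 1)", {
  alpha <- 0.05
  expect_equal(1 - (1 - alpha)^(2 - 1), 0.05)
  expect_equal(1 - (1 - alpha)^(3 - 1), 0.0975)
  # a Duncan test of span 3 therefore uses a smaller critical value
  # than SNK at the same span
  expect_lt(qtukey(1 - 0.0975, 3, 30), qtukey(1 - 0.05, 3, 30))
})

test_that("range tests report decisions, not p-values, with step-down protection", {
  fit <- plasma_fit("Ser")
  snk <- range_test(fit, mcp_config(test = "snk"))
  expect_true(all(is.na(snk$p_raw)))
  expect_true(all(is.na(snk$p_adj)))
  # full range non-significant -> nothing significant at all
  fit0 <- cell_means_fit_from_summary(c(10, 10.1, 10.2, 10.3),
                                      c(2, 2, 2, 2), 9)
  for (test in c("snk", "duncan")) {
    r <- range_test(fit0, mcp_config(test = test))
    expect_false(any(r$significant))
  }
})

test_that("step-down max-t resampling is deterministic, floored at raw p", {
  fit <- plasma_fit("Cit")
  cfg <- mcp_config(test = "westfall", nsim = 5000, seed = 99)
  w1 <- westfall_adjust(fit, cfg)
  w2 <- westfall_adjust(fit, cfg)
  expect_identical(w1$p_adj, w2$p_adj)
  expect_true(all(w1$p_adj >= w1$p_raw))
  # a single pair needs no adjustment
  fit2 <- cell_means_fit_from_summary(c(10, 11), c(0.8, 0.8), 9)
  w3 <- westfall_adjust(fit2, mcp_config(test = "westfall",
                                         nsim = 50000, seed = 3))
  expect_equal(w3$p_adj, w3$p_raw, tolerance = 0.01)
})

test_that("max-t adjusted p-values undercut Holm on a fixed fit", {
  fit <- cell_means_fit_from_summary(c(10, 10.5, 11.2, 12.4),
                                     c(0.6, 0.6, 0.6, 0.6), 9)
  w <- westfall_adjust(fit, mcp_config(test = "westfall", nsim = 100000,
                                       seed = 12))
  holm <- adjust_pvalues(w$p_raw, "holm")
  expect_true(all(w$p_adj <= holm + 0.01))
})

test_that("procedures are equivariant under treatment relabeling", {
  fit <- plasma_fit("Cit")
  perm <- c(3, 1, 4, 2)
  fitp <- cell_means_fit_from_summary(
    fit$cells$mean[perm], fit$cells$sem[perm], 9,
    treatments = fit$cells$treatment[perm])
  for (test in c("tukey", "snk", "duncan", "lsd")) {
    cfg <- mcp_config(test = test)
    m1 <- significance_matrix(pairwise_tests(fit, cfg))
    m2 <- significance_matrix(pairwise_tests(fitp, cfg))
    expect_identical(m1[rownames(m2), colnames(m2)], m2)
  }
})

test_that("mcp_config validates its fields", {
  expect_error(mcp_config(alpha = 0), "alpha")
  expect_error(mcp_config(test = "tukey", adjust = "holm"), "LSD")
  expect_error(mcp_config(test = "westfall", nsim = 10), "1000")
  expect_silent(mcp_config(test = "lsd", adjust = "holm"))
})
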