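# All-pairwise comparisons of the ab treatment means under the cell-means
# model: LSD (with p-adjustment), Tukey-Kramer, SNK, Duncan, and a
# resampling step-down max-t procedure.

#' Configuration for pairwise multiple-comparison procedures
#'
#' @param test One of `"tukey"` (Tukey-Kramer; Tukey HSD in balanced
#'   designs), `"snk"` (Student-Newman-Keuls), `"duncan"`, `"lsd"`
#'   (Fisher's least significant difference) or `"westfall"` (step-down
#'   max-t resampling).
#' @param alpha Familywise significance level, in (0, 1).
#' @param adjust p-value adjustment for the LSD test only: `"none"`
#'   (the default, i.e. plain LSD), `"bonferroni"` or `"holm"`.
#' @param nsim Number of resampling draws for `"westfall"` (>= 1000).
#' @param seed Integer seed making the resampling deterministic.
#' @return A list of class `mcp_config`.
#' @export
mcp_config <- function(test = c("tukey", "snk", "duncan", "lsd", "westfall"),
                       alpha = 0.05,
                       adjust = c("none", "bonferroni", "holm"),
                       nsim = 10000L, seed = 1L) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (adjust != "none" && test != "lsd") {
    stop("p-value adjustment applies only to the LSD test", call. = FALSE)
  }
  if (test == "westfall" && (!is.numeric(nsim) || nsim < 1000)) {
    stop("`nsim` must be at least 1000", call. = FALSE)
  }
  structure(list(test = test, alpha = alpha, adjust = adjust,
                 nsim = as.integer(nsim), seed = as.integer(seed)),
            class = "mcp_config")
}

check_fit_for_mcp <- function(fit) {
  stopifnot(inherits(fit, "cell_means_fit"))
  if (fit$df_error < 1) stop("fit has no error degrees of freedom",
                             call. = FALSE)
  if (fit$mse <= 0) {
    stop("MSE is zero: no within-cell variability to test against",
         call. = FALSE)
  }
}

pair_index <- function(k) {
  idx <- utils::combn(k, 2)
  tibble::tibble(i = idx[1, ], j = idx[2, ])
}

pairwise_skeleton <- function(fit) {
  p <- pair_index(fit$k)
  cells <- fit$cells
  tibble::tibble(
    treatment_1 = cells$treatment[p$i],
    treatment_2 = cells$treatment[p$j],
    estimate = cells$mean[p$i] - cells$mean[p$j],
    se = sqrt(fit$mse * (1 / cells$n[p$i] + 1 / cells$n[p$j])))
}

#' Adjust p-values for multiplicity
#'
#' Thin, validated wrapper over [stats::p.adjust()] for the adjustments
#' offered with the LSD test: `"none"` (identity), `"bonferroni"`
#' (`min(1, m * p)`) and `"holm"` (step-down Bonferroni).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method `"none"`, `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Fisher's LSD: all pairwise t tests with the pooled MSE
#'
#' Per pair, `t = (m_i - m_j) / sqrt(MSE * (1/n_i + 1/n_j))` with the
#' cell-means error df; two-sided p, optionally Bonferroni/Holm adjusted.
#'
#' @param fit A `cell_means_fit`.
#' @param config An [mcp_config()] (its `adjust` and `alpha` are used).
#' @return A `pairwise_results` tibble: `treatment_1`, `treatment_2`,
#'   `estimate`, `se`, `statistic`, `p_raw`, `p_adj`, `significant`.
#' @export
lsd_pairwise <- function(fit, config = mcp_config(test = "lsd")) {
  check_fit_for_mcp(fit)
  out <- pairwise_skeleton(fit)
  out$statistic <- out$estimate / out$se
  out$p_raw <- 2 * stats::pt(-abs(out$statistic), df = fit$df_error)
  out$p_adj <- adjust_pvalues(out$p_raw, config$adjust)
  out$significant <- out$p_adj < config$alpha
  new_pairwise_results(out, fit, config)
}

#' Tukey-Kramer all-pairwise comparisons
#'
#' Per pair, the studentized range statistic
#' `q = |m_i - m_j| / sqrt((MSE/2) * (1/n_i + 1/n_j))` is referred to the
#' studentized range distribution with `k` groups and the error df
#' (Tukey HSD when balanced; the Kramer standard error makes the unbalanced
#' case exact per pair).
#'
#' @inheritParams lsd_pairwise
#' @return A `pairwise_results` tibble (`statistic` is q; `p_raw` and
#'   `p_adj` both carry the single-step adjusted p).
#' @export
tukey_kramer <- function(fit, config = mcp_config(test = "tukey")) {
  check_fit_for_mcp(fit)
  out <- pairwise_skeleton(fit)
  out$statistic <- abs(out$estimate) / (out$se / sqrt(2))
  p <- stats::ptukey(out$statistic, nmeans = fit$k, df = fit$df_error,
                     lower.tail = FALSE)
  out$p_raw <- p
  out$p_adj <- p
  out$significant <- p < config$alpha
  new_pairwise_results(out, fit, config)
}

#' Student-Newman-Keuls and Duncan multiple range tests
#'
#' Means are ordered (descending, ties broken by treatment order); a pair
#' spanning `p` positions in that ordering is tested against
#' `q(gamma_p, p, df)` times its Kramer standard error over `sqrt(2)`,
#' with `gamma_p = alpha` for SNK and `gamma_p = 1 - (1 - alpha)^(p - 1)`
#' for Duncan. Step-down protection applies: once a range is declared
#' non-significant every sub-range it contains is declared non-significant
#' without testing. Range tests yield decisions, not per-pair p-values, so
#' `p_raw`/`p_adj` are `NA`.
#'
#' @param fit A `cell_means_fit`.
#' @param config An [mcp_config()] with `test` `"snk"` or `"duncan"`.
#' @return A `pairwise_results` tibble.
#' @export
range_test <- function(fit, config = mcp_config(test = "snk")) {
  check_fit_for_mcp(fit)
  if (!config$test %in% c("snk", "duncan")) {
    stop('`config$test` must be "snk" or "duncan"', call. = FALSE)
  }
  cells <- fit$cells
  k <- fit$k
  ord <- order(-cells$mean, seq_len(k))  # descending mean, ties by order
  pos <- match(seq_len(k), ord)          # treatment -> position
  # decide[u, v]: decision for the range from position u to v (u < v)
  sig <- matrix(NA, k, k)
  for (span in k:2) {
    for (u in seq_len(k - span + 1)) {
      v <- u + span - 1
      blocked <- FALSE
      if (span < k) {
        for (u2 in 1:u) for (v2 in v:k) {
          if ((v2 - u2 + 1) > span && isFALSE(sig[u2, v2])) blocked <- TRUE
        }
      }
      if (blocked) { sig[u, v] <- FALSE; next }
      ti <- ord[u]; tj <- ord[v]
      se_q <- sqrt((fit$mse / 2) * (1 / cells$n[ti] + 1 / cells$n[tj]))
      gamma_p <- if (config$test == "snk") config$alpha else
        1 - (1 - config$alpha)^(span - 1)
      crit <- stats::qtukey(1 - gamma_p, nmeans = span, df = fit$df_error)
      q_obs <- abs(cells$mean[ti] - cells$mean[tj]) / se_q
      sig[u, v] <- q_obs > crit
    }
  }
  out <- pairwise_skeleton(fit)
  p <- pair_index(k)
  u <- pmin(pos[p$i], pos[p$j]); v <- pmax(pos[p$i], pos[p$j])
  out$statistic <- abs(out$estimate) / (out$se / sqrt(2))
  out$p_raw <- NA_real_
  out$p_adj <- NA_real_
  out$significant <- sig[cbind(u, v)]
  new_pairwise_results(out, fit, config)
}

#' Step-down max-t resampling adjustment ("free" Westfall-style)
#'
#' Raw pairwise t statistics as in [lsd_pairwise()]; adjusted p-values come
#' from `nsim` parametric draws of the complete null (treatment means
#' normal with variance `MSE / n_i`, error variance rescaled by a
#' chi-squared with the error df), combined by the free step-down maxT
#' rule: hypotheses are ordered by decreasing `|t|` and the h-th adjusted p
#' is the (monotonicity-enforced) resampling probability that the maximum
#' `|t*|` over the h-th and less extreme hypotheses exceeds the observed
#' `|t|`. This is the free (unconstrained) step-down variant; it does not
#' exploit the logical constraints among pairwise hypotheses, which makes
#' it slightly conservative relative to truncated closed testing, but it
#' does account for the correlation between pairs. Deterministic given
#' `config$seed`; adjusted p-values are floored at the raw p.
#'
#' @param fit A `cell_means_fit`.
#' @param config An [mcp_config()] with `test = "westfall"`; `nsim` and
#'   `seed` control the resampling.
#' @return A `pairwise_results` tibble.
#' @export
westfall_adjust <- function(fit, config = mcp_config(test = "westfall")) {
  check_fit_for_mcp(fit)
  cells <- fit$cells
  out <- pairwise_skeleton(fit)
  out$statistic <- out$estimate / out$se
  out$p_raw <- 2 * stats::pt(-abs(out$statistic), df = fit$df_error)
  m <- nrow(out)
  p <- pair_index(fit$k)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  z <- matrix(stats::rnorm(config$nsim * fit$k), config$nsim, fit$k)
  v <- stats::rchisq(config$nsim, df = fit$df_error) / fit$df_error
  tstar <- matrix(0, config$nsim, m)
  for (l in seq_len(m)) {
    i <- p$i[l]; j <- p$j[l]
    num <- z[, i] / sqrt(cells$n[i]) - z[, j] / sqrt(cells$n[j])
    tstar[, l] <- abs(num) / sqrt(v * (1 / cells$n[i] + 1 / cells$n[j]))
  }
  ord <- order(-abs(out$statistic))
  padj_ord <- numeric(m)
  suffix_max <- rep(-Inf, config$nsim)
  for (h in m:1) {
    suffix_max <- pmax(suffix_max, tstar[, ord[h]])
    padj_ord[h] <- mean(suffix_max >= abs(out$statistic[ord[h]]))
  }
  padj_ord <- cummax(padj_ord)
  out$p_adj <- numeric(m)
  out$p_adj[ord] <- padj_ord
  out$p_adj <- pmax(out$p_adj, out$p_raw)
  out$significant <- out$p_adj < config$alpha
  new_pairwise_results(out, fit, config)
}

new_pairwise_results <- function(tbl, fit, config) {
  tbl <- tbl[, c("treatment_1", "treatment_2", "estimate", "se",
                 "statistic", "p_raw", "p_adj", "significant")]
  structure(tbl, class = c("pairwise_results", class(tbl)),
            config = config, treatments = fit$cells$treatment,
            means = stats::setNames(fit$cells$mean, fit$cells$treatment))
}

#' Run the configured pairwise procedure
#'
#' Dispatches on `config$test` to [tukey_kramer()], [range_test()],
#' [lsd_pairwise()] or [westfall_adjust()].
#'
#' @inheritParams lsd_pairwise
#' @return A `pairwise_results` tibble covering all `k * (k - 1) / 2`
#'   treatment pairs.
#' @export
pairwise_tests <- function(fit, config = mcp_config()) {
  switch(config$test,
         tukey = tukey_kramer(fit, config),
         snk = ,
         duncan = range_test(fit, config),
         lsd = lsd_pairwise(fit, config),
         westfall = westfall_adjust(fit, config))
}

#' Significance matrix of a pairwise result set
#'
#' @param pw A `pairwise_results` object.
#' @return Symmetric logical matrix (diagonal `FALSE`) with treatment
#'   dimnames, suitable for [compact_letter_display()].
#' @export
significance_matrix <- function(pw) {
  trts <- attr(pw, "treatments")
  k <- length(trts)
  m <- matrix(FALSE, k, k, dimnames = list(trts, trts))
  for (l in seq_len(nrow(pw))) {
    m[pw$treatment_1[l], pw$treatment_2[l]] <- pw$significant[l]
    m[pw$treatment_2[l], pw$treatment_1[l]] <- pw$significant[l]
  }
  m
}
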