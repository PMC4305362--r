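# Fixtures and independent oracles shared across the test files.

# 2x2 design, n = 2 per cell, hand-checkable: cell values
# (1,3), (2,4), (5,7), (6,8) -> cell means 2, 3, 6, 7.
toy_dataset <- function() {
  df <- data.frame(
    A = rep(c("a1", "a2"), each = 4),
    B = rep(rep(c("b1", "b2"), each = 2), 2),
    y = c(1, 3, 2, 4, 5, 7, 6, 8))
  as_two_way_dataset(df, source_sheet = "toy")
}

plasma_summary <- function() {
  read.csv(system.file("extdata", "plasma_table1.csv",
                       package = "twowaytables"),
           stringsAsFactors = FALSE)
}

plasma_pvalues <- function() {
  read.csv(system.file("extdata", "plasma_table1_pvalues.csv",
                       package = "twowaytables"),
           colClasses = "character")
}

plasma_pooled <- function() {
  read.csv(system.file("extdata", "plasma_table3_pooled_sem.csv",
                       package = "twowaytables"),
           stringsAsFactors = FALSE)
}

# Rat plasma dataset rebuilt from the published summary statistics
# (exact cell means and SEMs, n = 9); synthetic raw values.
plasma_dataset <- function(responses = NULL) {
  s <- plasma_summary()
  if (!is.null(responses)) s <- s[s$response %in% responses, ]
  dataset_from_summary(s, n = 9, factor_names = c("Diet", "Weight"),
                       source_sheet = "Plasma")
}

# Summary-based cell-means fit for one plasma response, treatments in
# Table order (HF-Lean, HF-Overweight, LF-Lean, LF-Overweight).
plasma_fit <- function(response) {
  s <- plasma_summary()
  s <- s[s$response == response, ]
  ord <- order(s$level_a, s$level_b)
  s <- s[ord, ]
  cell_means_fit_from_summary(
    s$mean, s$sem, n = 9,
    treatments = paste(s$level_a, s$level_b, sep = "-"))
}

# Independent sequential-SS oracle: explicit dummy-coded design matrices
# and QR projections, no model-formula machinery.
seq_ss_oracle <- function(dataset, response, factor_order) {
  fa <- factor_order[1]; fb <- factor_order[2]
  d <- dataset$data[!is.na(dataset$data[[response]]), ]
  y <- d[[response]]
  lv1 <- dataset$levels[[fa]]; lv2 <- dataset$levels[[fb]]
  dummy <- function(values, lv) {
    if (length(lv) < 2) return(NULL)
    sapply(lv[-1], function(l) as.numeric(values == l))
  }
  X0 <- matrix(1, nrow(d), 1)
  D1 <- dummy(d[[fa]], lv1)
  D2 <- dummy(d[[fb]], lv2)
  Dint <- NULL
  for (i in seq_len(ncol(D1))) {
    for (j in seq_len(ncol(D2))) {
      Dint <- cbind(Dint, D1[, i] * D2[, j])
    }
  }
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  r0 <- rss(X0)
  r1 <- rss(cbind(X0, D1))
  r2 <- rss(cbind(X0, D1, D2))
  r3 <- rss(cbind(X0, D1, D2, Dint))
  n <- length(y)
  df <- c(ncol(D1), ncol(D2), ncol(Dint),
          n - 1 - ncol(D1) - ncol(D2) - ncol(Dint))
  ss <- c(r0 - r1, r1 - r2, r2 - r3, r3)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  list(ss = ss, df = df, ms = ms, f = f, p = p, mse = ms[4])
}

# Exhaustive minimum letter count: smallest set of cliques of the
# non-significance graph covering every vertex and every non-significant
# pair. Only for small treatment counts.
min_letter_count_oracle <- function(sig) {
  k <- nrow(sig)
  nonsig <- !sig
  diag(nonsig) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected")
  mc <- lapply(igraph::max_cliques(g), as.integer)
  edges <- which(upper.tri(nonsig) & nonsig, arr.ind = TRUE)
  covers_all <- function(sel) {
    cl <- mc[sel]
    if (!all(seq_len(k) %in% unlist(cl))) return(FALSE)
    if (nrow(edges) == 0) return(TRUE)
    all(apply(edges, 1, function(e) {
      any(vapply(cl, function(c) all(e %in% c), logical(1)))
    }))
  }
  for (t in seq_along(mc)) {
    sel_sets <- utils::combn(length(mc), t, simplify = FALSE)
    for (sel in sel_sets) if (covers_all(sel)) return(t)
  }
  length(mc)
}

# Random symmetric significance matrix on k treatments.
random_sig_matrix <- function(k, p_sig = 0.4) {
  trts <- paste0("T", seq_len(k))
  m <- matrix(FALSE, k, k, dimnames = list(trts, trts))
  up <- upper.tri(m)
  m[up] <- stats::runif(sum(up)) < p_sig
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Count pages of a PDF written by grDevices::pdf() (NUL-safe).
count_pdf_pages <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(r[r != as.raw(0)])
  length(gregexpr("/Type /Page[^s]", txt, useBytes = TRUE)[[1]])
}

expect_letters <- function(cld, expected) {
  expect_identical(unname(cld$assignment), expected)
}
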