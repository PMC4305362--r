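# Compact letter display by insert-and-absorb.

#' Compact letter display from a pairwise significance pattern
#'
#' Encodes an all-pairwise significance pattern as superscript letters:
#' two treatments share at least one letter if and only if their pair is
#' not significantly different. Uses the insert-and-absorb algorithm:
#' starting from a single column holding every treatment, each significant
#' pair splits every column containing both members into two copies (one
#' member removed from each), and columns contained in another column are
#' absorbed. Columns become letters `a`, `b`, ... ordered by descending
#' column-maximum mean, so `a` attaches to the largest mean. By convention,
#' when no pair is significant no letters are shown at all.
#'
#' @param sig Symmetric logical matrix with treatment dimnames
#'   (`TRUE` = significantly different), e.g. from
#'   [significance_matrix()]; alternatively a data frame with columns
#'   `treatment_1`, `treatment_2`, `significant` listing every pair once
#'   (conflicting duplicate pairs are an error).
#' @param means Named numeric vector of treatment means (all treatments).
#' @return A `letter_display`: list with `assignment` (named character;
#'   sorted, duplicate-free letter strings, empty when nothing differs)
#'   and `any_significant`.
#' @examples
#' m <- c(A = 359, B = 294, C = 353, D = 292)
#' sig <- outer(names(m), names(m),
#'              function(x, y) (x %in% c("A", "C")) != (y %in% c("A", "C")))
#' dimnames(sig) <- list(names(m), names(m))
#' compact_letter_display(sig, m)$assignment  # a b a b
#' @export
compact_letter_display <- function(sig, means) {
  if (is.data.frame(sig)) sig <- pairs_to_matrix(sig, names(means))
  trts <- names(means)
  if (is.null(trts) || is.null(rownames(sig))) {
    stop("`means` and `sig` must be named by treatment", call. = FALSE)
  }
  if (!setequal(rownames(sig), trts) || !setequal(colnames(sig), trts)) {
    stop("`sig` dimnames must match the treatments in `means`",
         call. = FALSE)
  }
  sig <- sig[trts, trts, drop = FALSE]
  if (!isTRUE(all(sig == t(sig)))) {
    stop("inconsistent significance input: matrix is not symmetric",
         call. = FALSE)
  }
  diag(sig) <- FALSE
  k <- length(trts)

  if (!any(sig)) {
    return(structure(list(
      assignment = stats::setNames(rep("", k), trts),
      any_significant = FALSE), class = "letter_display"))
  }

  # significant pairs ordered by (larger-mean member, smaller-mean member)
  # position in the descending-mean ordering, for determinism
  rank_desc <- match(trts, trts[order(-means, seq_len(k))])
  pr <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  hi <- ifelse(rank_desc[pr[, 1]] <= rank_desc[pr[, 2]], pr[, 1], pr[, 2])
  lo <- ifelse(rank_desc[pr[, 1]] <= rank_desc[pr[, 2]], pr[, 2], pr[, 1])
  o <- order(rank_desc[hi], rank_desc[lo])
  hi <- hi[o]; lo <- lo[o]

  cols <- list(seq_len(k))
  for (e in seq_along(hi)) {
    both <- vapply(cols, function(cl) hi[e] %in% cl && lo[e] %in% cl,
                   logical(1))
    if (!any(both)) next
    new_cols <- list()
    for (ci in seq_along(cols)) {
      cl <- cols[[ci]]
      if (both[ci]) {
        new_cols <- c(new_cols, list(setdiff(cl, hi[e])),
                      list(setdiff(cl, lo[e])))
      } else {
        new_cols <- c(new_cols, list(cl))
      }
    }
    # absorb columns contained in (or equal to) another column
    keep <- rep(TRUE, length(new_cols))
    for (ci in seq_along(new_cols)) {
      for (cj in seq_along(new_cols)) {
        if (ci == cj || !keep[cj]) next
        if (all(new_cols[[ci]] %in% new_cols[[cj]]) &&
            (length(new_cols[[ci]]) < length(new_cols[[cj]]) || ci > cj)) {
          keep[ci] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }

  # internal consistency check (the algorithm guarantees both directions)
  for (e in seq_along(hi)) {
    if (any(vapply(cols, function(cl) hi[e] %in% cl && lo[e] %in% cl,
                   logical(1)))) {
      stop("internal error: significant pair left sharing a column",
           call. = FALSE)
    }
  }
  # Final reduction: insert-and-absorb ends with (a subset of) the maximal
  # cliques of the non-significance graph, which can be redundant — e.g. a
  # perfect-matching significance pattern on 6 treatments yields all 8
  # triangles where 4 suffice. Keep the smallest sub-collection that still
  # covers every treatment and every non-significant pair (exact search
  # for small column sets, greedy redundancy elimination otherwise).
  nonsig_pairs <- which(upper.tri(sig) & !sig, arr.ind = TRUE)
  cols <- prune_columns(cols, k, nonsig_pairs)
  if (length(cols) > 26) {
    stop("letter display would need more than 26 letters", call. = FALSE)
  }

  col_max <- vapply(cols, function(cl) max(means[cl]), numeric(1))
  col_first <- vapply(cols, function(cl) min(rank_desc[cl]), numeric(1))
  cols <- cols[order(-col_max, col_first)]
  assignment <- stats::setNames(rep("", k), trts)
  for (ci in seq_along(cols)) {
    lt <- letters[ci]
    for (t in cols[[ci]]) {
      assignment[t] <- paste0(assignment[t], lt)
    }
  }
  assignment[] <- vapply(assignment, function(s)
    paste(sort(unique(strsplit(s, "")[[1]])), collapse = ""), character(1))
  structure(list(assignment = assignment, any_significant = TRUE),
            class = "letter_display")
}

covers_requirements <- function(cols, k, nonsig_pairs) {
  if (!all(seq_len(k) %in% unlist(cols))) return(FALSE)
  if (nrow(nonsig_pairs) == 0) return(TRUE)
  for (e in seq_len(nrow(nonsig_pairs))) {
    i <- nonsig_pairs[e, 1]; j <- nonsig_pairs[e, 2]
    if (!any(vapply(cols, function(cl) i %in% cl && j %in% cl,
                    logical(1)))) {
      return(FALSE)
    }
  }
  TRUE
}

prune_columns <- function(cols, k, nonsig_pairs) {
  n <- length(cols)
  if (n <= 1) return(cols)
  if (n <= 16) {
    for (t in seq_len(n - 1)) {
      if (choose(n, t) > 50000) break
      sel_sets <- utils::combn(n, t, simplify = FALSE)
      for (sel in sel_sets) {
        if (covers_requirements(cols[sel], k, nonsig_pairs)) {
          return(cols[sel])
        }
      }
    }
    return(cols)
  }
  # greedy: drop any column whose vertices and pairs are covered elsewhere
  repeat {
    dropped <- FALSE
    for (ci in seq_along(cols)) {
      if (covers_requirements(cols[-ci], k, nonsig_pairs)) {
        cols <- cols[-ci]
        dropped <- TRUE
        break
      }
    }
    if (!dropped || length(cols) == 1) return(cols)
  }
}

pairs_to_matrix <- function(df, trts) {
  stopifnot(all(c("treatment_1", "treatment_2", "significant") %in%
                  names(df)))
  m <- matrix(NA, length(trts), length(trts), dimnames = list(trts, trts))
  for (l in seq_len(nrow(df))) {
    i <- df$treatment_1[l]; j <- df$treatment_2[l]
    prev <- m[i, j]
    if (!is.na(prev) && prev != df$significant[l]) {
      stop(sprintf("inconsistent significance input for pair (%s, %s)",
                   i, j), call. = FALSE)
    }
    m[i, j] <- df$significant[l]
    m[j, i] <- df$significant[l]
  }
  if (any(is.na(m[upper.tri(m)]))) {
    stop("significance input does not cover all pairs", call. = FALSE)
  }
  diag(m) <- FALSE
  m
}

#' @export
print.letter_display <- function(x, ...) {
  if (!x$any_significant) {
    cat("<letter_display: no significant pairs, no letters>\n")
  } else {
    cat("<letter_display>\n")
    print(x$assignment)
  }
  invisible(x)
}
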