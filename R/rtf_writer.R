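# Serialization of summary tables into a minimal, widely readable RTF
# dialect: plain row/cell control words, merged two-row factor headers,
# superscripts via \super, captions as paragraphs. Output is pure 7-bit
# ASCII; extended characters are emitted as \uN with a "?" fallback so
# any RTF 1.x reader renders the document.

rtf_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("{", "\\{", x, fixed = TRUE)
  x <- gsub("}", "\\}", x, fixed = TRUE)
  vapply(x, function(s) {
    cp <- utf8ToInt(s)
    if (all(cp < 128)) return(s)
    paste(vapply(cp, function(ci) {
      if (ci < 128) return(intToUtf8(ci))
      if (ci > 32767) ci <- ci - 65536  # \u takes a signed 16-bit value
      sprintf("\\u%d?", ci)
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# A header cell spanning `span` columns: first physical cell \clmgf,
# the rest \clmrg.
rtf_row <- function(cells, widths, merges = NULL, bold = FALSE) {
  total <- 9360
  w <- round(total * widths / sum(widths))
  defs <- character(0)
  right <- 0
  for (i in seq_along(w)) {
    m <- if (is.null(merges)) "" else merges[i]
    right <- right + w[i]
    defs <- c(defs, paste0(m, "\\cellx", right))
  }
  fmt <- if (bold) "\\b " else ""
  body <- paste0(fmt, cells, "\\cell", collapse = "")
  paste0("\\trowd\\trgaph108", paste(defs, collapse = ""),
         "\\pard\\intbl\\qc ", body, "\\row")
}

render_one_table <- function(tbl) {
  la <- tbl$levels[[1]]; lb <- tbl$levels[[2]]
  a <- length(la); b <- length(lb)
  has_pooled <- !is.null(tbl$pooled)
  # physical columns: Variable | a*b treatment | [pooled] | 3 p-value
  header2 <- c("Variable", rep(rtf_escape(lb), a),
               if (has_pooled) "Pooled SEM",
               rtf_escape(tbl$p_header))
  widths <- pmax(nchar(header2), 6)
  nc <- length(header2)

  # header row 1: factor A levels spanning b columns; P-value spanning 3
  h1_cells <- c("", rep("", a * b), if (has_pooled) "",
                rep("", 3))
  h1_merge <- rep("", nc)
  pos <- 2
  for (i in seq_len(a)) {
    h1_cells[pos] <- rtf_escape(la[i])
    h1_merge[pos] <- "\\clmgf"
    if (b > 1) h1_merge[(pos + 1):(pos + b - 1)] <- "\\clmrg"
    pos <- pos + b
  }
  if (has_pooled) pos <- pos + 1
  h1_cells[pos] <- "P-value"
  h1_merge[pos] <- "\\clmgf"
  h1_merge[(pos + 1):(pos + 2)] <- "\\clmrg"

  h2_cells <- header2
  h2_cells[1] <- "Variable"

  rows <- c(
    paste0("{\\pard\\b ", rtf_escape(tbl$title), "\\b0\\par}"),
    rtf_row(h1_cells, widths, h1_merge, bold = TRUE),
    rtf_row(h2_cells, widths, bold = TRUE))

  for (r in seq_along(tbl$responses)) {
    cells <- rtf_escape(tbl$cell_text[r, ])
    sup <- tbl$cell_sup[r, ]
    cells <- ifelse(nzchar(sup),
                    paste0(cells, "{\\super ", rtf_escape(sup), "}"),
                    cells)
    row_cells <- c(rtf_escape(tbl$responses[r]), cells,
                   if (has_pooled) rtf_escape(tbl$pooled[r]),
                   rtf_escape(tbl$p_text[r, ]))
    rows <- c(rows, rtf_row(row_cells, widths))
  }

  caption <- rtf_escape(tbl$caption)
  if (!is.null(tbl$caption_letters)) {
    tok <- rtf_escape(tbl$caption_letters)
    caption <- sub(paste0(tok, "Means"),
                   paste0("{\\super ", tok, "}Means"), caption,
                   fixed = TRUE)
  }
  rows <- c(rows, paste0("{\\pard ", caption, "\\par}"), "{\\pard\\par}")
  paste(rows, collapse = "\n")
}

#' Render summary tables as a single RTF document
#'
#' One RTF table per `summary_table` (one per input sheet), each with a
#' nested two-row factor header, superscripted letters, and its caption
#' paragraph; the sheet name becomes the table title.
#'
#' @param tables A `summary_table` or a list of them.
#' @return An `rtf_document`: list with `content` (the RTF control
#'   stream, pure ASCII, starting with `{\rtf1`) and `tables` (count).
#' @export
render_rtf <- function(tables) {
  if (inherits(tables, "summary_table")) tables <- list(tables)
  if (!is.list(tables) || length(tables) == 0 ||
      !all(vapply(tables, inherits, logical(1), "summary_table"))) {
    stop("`tables` must be one or more summary_table objects",
         call. = FALSE)
  }
  body <- vapply(tables, render_one_table, character(1))
  content <- paste0(
    "{\\rtf1\\ansi\\deff0\n",
    "{\\fonttbl{\\f0 Times New Roman;}}\n",
    "\\fs20\n",
    paste(body, collapse = "\n"),
    "\n}")
  if (!all(utf8ToInt(content) < 128)) {
    stop("internal error: RTF stream contains unescaped non-ASCII",
         call. = FALSE)
  }
  structure(list(content = content, tables = length(tables)),
            class = "rtf_document")
}

#' @export
print.rtf_document <- function(x, ...) {
  cat(sprintf("<rtf_document: %d table%s, %d characters>\n", x$tables,
              if (x$tables == 1) "" else "s", nchar(x$content)))
  invisible(x)
}

#' Write an RTF document to disk
#'
#' Bytes on disk are exactly `content` encoded as ASCII; writing is
#' deterministic and idempotent (identical input yields bit-identical
#' files).
#'
#' @param doc An `rtf_document` from [render_rtf()].
#' @param path Output file path (conventionally `.rtf`).
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path) {
  stopifnot(inherits(doc, "rtf_document"))
  if (dir.exists(path)) {
    stop(sprintf("'%s' is a directory, not a writable file path", path),
         call. = FALSE)
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop(sprintf(
                    "cannot write to '%s': %s", path, conditionMessage(e)),
                    call. = FALSE),
                  warning = function(w) stop(sprintf(
                    "cannot write to '%s'", path), call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw(doc$content), con)
  invisible(path)
}
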