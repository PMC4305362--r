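# Minimal OOXML spreadsheet writer used by the fixture generator.
#
# Only what a round-trip through readxl needs: one worksheet XML per
# dataset with inline strings and plain numbers, the workbook manifest,
# and a zip container with stored (uncompressed) entries. The CRC32 and
# the zip record layout are written directly; timestamps are fixed so a
# given input always produces byte-identical files.

crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320, the reflected CRC-32 polynomial
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  u <- as.numeric(crc)
  if (u < 0) u + 2^32 else u
}

le_bytes <- function(value, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

# Zip archive with stored entries only; fixed DOS timestamp (2020-01-01).
zip_store <- function(entries, path) {
  dos_date <- (2020 - 1980) * 512 + 1 * 32 + 1
  locals <- list()
  centrals <- list()
  offset <- 0
  for (name in names(entries)) {
    data <- entries[[name]]
    nm <- charToRaw(name)
    crc <- crc32(data)
    local <- c(le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
               le_bytes(0, 2), le_bytes(0, 2), le_bytes(dos_date, 2),
               le_bytes(crc, 4), le_bytes(length(data), 4),
               le_bytes(length(data), 4), le_bytes(length(nm), 2),
               le_bytes(0, 2), nm, data)
    central <- c(le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(dos_date, 2), le_bytes(crc, 4),
                 le_bytes(length(data), 4), le_bytes(length(data), 4),
                 le_bytes(length(nm), 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
                 le_bytes(offset, 4), nm)
    locals[[name]] <- local
    centrals[[name]] <- central
    offset <- offset + length(local)
  }
  central_blob <- do.call(c, centrals)
  eocd <- c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(entries), 2), le_bytes(length(entries), 2),
            le_bytes(length(central_blob), 4), le_bytes(offset, 4),
            le_bytes(0, 2))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(do.call(c, locals), central_blob, eocd), con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    out <- paste0(LETTERS[(j - 1) %% 26 + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

sheet_xml <- function(df) {
  rows <- character(nrow(df) + 1)
  header <- vapply(seq_along(df), function(j) sprintf(
    '<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
    col_letter(j), xml_escape(names(df)[j])), character(1))
  rows[1] <- paste0('<row r="1">', paste(header, collapse = ""), "</row>")
  for (i in seq_len(nrow(df))) {
    cells <- character(0)
    for (j in seq_along(df)) {
      v <- df[[j]][i]
      if (is.na(v)) next
      ref <- paste0(col_letter(j), i + 1)
      cells <- c(cells, if (is.numeric(v)) {
        sprintf('<c r="%s"><v>%s</v></c>', ref,
                format(v, digits = 17, scientific = FALSE, trim = TRUE))
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref,
                xml_escape(as.character(v)))
      })
    }
    rows[i + 1] <- paste0(sprintf('<row r="%d">', i + 1),
                          paste(cells, collapse = ""), "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), "</sheetData></worksheet>")
}

write_xlsx_minimal <- function(sheets, path) {
  stopifnot(length(sheets) >= 1, !is.null(names(sheets)))
  ct_sheets <- paste(sprintf(paste0(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.',
    'worksheet+xml"/>'), seq_along(sheets)), collapse = "")
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/',
    'content-types">',
    '<Default Extension="rels" ContentType="application/vnd.',
    'openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/',
    'vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    ct_sheets, "</Types>")
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/',
    '2006/relationships"><Relationship Id="rId1" Type="http://schemas.',
    'openxmlformats.org/officeDocument/2006/relationships/',
    'officeDocument" Target="xl/workbook.xml"/></Relationships>')
  wb_sheets <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xml_escape(names(sheets)), seq_along(sheets), seq_along(sheets)),
    collapse = "")
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/',
    '2006/main" xmlns:r="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships"><sheets>', wb_sheets,
    "</sheets></workbook>")
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/',
    '2006/relationships">',
    paste(sprintf(paste0(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.',
      'org/officeDocument/2006/relationships/worksheet" Target=',
      '"worksheets/sheet%d.xml"/>'), seq_along(sheets),
      seq_along(sheets)), collapse = ""),
    "</Relationships>")
  entries <- list()
  entries[["[Content_Types].xml"]] <- charToRaw(content_types)
  entries[["_rels/.rels"]] <- charToRaw(rels)
  entries[["xl/workbook.xml"]] <- charToRaw(workbook)
  entries[["xl/_rels/workbook.xml.rels"]] <- charToRaw(wb_rels)
  for (i in seq_along(sheets)) {
    entries[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(enc2utf8(sheet_xml(as.data.frame(sheets[[i]]))))
  }
  zip_store(entries, path)
}
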