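## Minimal XLSX (SpreadsheetML) writer. No spreadsheet-writing package is
## part of this package's dependency set, and the export needs only one
## inline-string/number sheet, so the workbook is assembled directly: a
## zip container with stored (uncompressed) entries and a table-driven
## CRC-32. Verified against openpyxl in the test suite.

## CRC-32 on 32-bit integer patterns (bitwShiftR is a logical shift in R)
.crc32MakeTable <- function() {
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
  tab <- integer(256L)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
}

.crc32CacheEnv <- new.env(parent = emptyenv())

.crc32 <- function(bytes) {
  if (is.null(.crc32CacheEnv$tab)) .crc32CacheEnv$tab <- .crc32MakeTable()
  tab <- .crc32CacheEnv$tab
  c <- -1L
  for (x in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L), tab[bitwAnd(bitwXor(c, x), 255L) + 1L])
  }
  c <- bitwXor(c, -1L)
  if (c < 0) c + 2^32 else as.numeric(c)
}

.le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- floor(x / 256)
  }
  out
}

## write a zip archive of stored entries; files = named list of raw vectors
.writeStoredZip <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  central <- list()
  pos <- 0
  for (i in seq_along(files)) {
    nm <- charToRaw(names(files)[i])
    dat <- files[[i]]
    crc <- .crc32(dat)
    offsets[i] <- pos
    hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), .le(20, 2), .le(0, 2),
             .le(0, 2), .le(0, 2), .le(0x21, 2), .le(crc, 4),
             .le(length(dat), 4), .le(length(dat), 4),
             .le(length(nm), 2), .le(0, 2), nm)
    writeBin(c(hdr, dat), con)
    pos <- pos + length(hdr) + length(dat)
    central[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), .le(20, 2),
                      .le(20, 2), .le(0, 2), .le(0, 2), .le(0, 2),
                      .le(0x21, 2), .le(crc, 4), .le(length(dat), 4),
                      .le(length(dat), 4), .le(length(nm), 2), .le(0, 2),
                      .le(0, 2), .le(0, 2), .le(0, 2), .le(0, 4),
                      .le(offsets[i], 4), nm)
  }
  cd <- do.call(c, central)
  writeBin(cd, con)
  end <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .le(0, 2), .le(0, 2),
           .le(length(files), 2), .le(length(files), 2),
           .le(length(cd), 4), .le(pos, 4), .le(0, 2))
  writeBin(end, con)
  invisible(path)
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

## write a data.frame as a single-sheet xlsx workbook
.writeXlsx <- function(df, path, sheet = "Sheet1") {
  isNum <- vapply(df, is.numeric, TRUE)
  cellRef <- function(col, row) {
    letters <- ""
    n <- col
    while (n > 0) {
      letters <- paste0(LETTERS[(n - 1) %% 26 + 1], letters)
      n <- (n - 1) %/% 26
    }
    paste0(letters, row)
  }
  rows <- character(nrow(df) + 1L)
  hdr <- vapply(seq_along(df), function(j) sprintf(
    '<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', cellRef(j, 1),
    .xmlEscape(names(df)[j])), "")
  rows[1L] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j) {
      v <- df[i, j]
      if (isNum[j]) sprintf('<c r="%s"><v>%.15g</v></c>',
                            cellRef(j, i + 1L), as.numeric(v))
      else sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                   cellRef(j, i + 1L), .xmlEscape(as.character(v)))
    }, "")
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  decl <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>'
  ns <- "http://schemas.openxmlformats.org/spreadsheetml/2006/main"
  sheetXml <- sprintf(
    '%s\n<worksheet xmlns="%s"><sheetData>%s</sheetData></worksheet>',
    decl, ns, paste(rows, collapse = ""))
  workbook <- sprintf(paste0(
    '%s\n<workbook xmlns="%s" xmlns:r="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships"><sheets>',
    '<sheet name="%s" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    decl, ns, .xmlEscape(sheet))
  wbRels <- paste0(decl, '\n<Relationships xmlns="http://schemas.',
    'openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships/worksheet" ',
    'Target="worksheets/sheet1.xml"/></Relationships>')
  rootRels <- paste0(decl, '\n<Relationships xmlns="http://schemas.',
    'openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships/officeDocument" ',
    'Target="xl/workbook.xml"/></Relationships>')
  contentTypes <- paste0(decl, '\n<Types xmlns="http://schemas.',
    'openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.',
    'openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.',
    'openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType=',
    '"application/vnd.openxmlformats-officedocument.spreadsheetml.',
    'worksheet+xml"/></Types>')
  files <- list(
    "[Content_Types].xml" = charToRaw(contentTypes),
    "_rels/.rels" = charToRaw(rootRels),
    "xl/workbook.xml" = charToRaw(workbook),
    "xl/_rels/workbook.xml.rels" = charToRaw(wbRels),
    "xl/worksheets/sheet1.xml" = charToRaw(sheetXml))
  .writeStoredZip(files, path)
}
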