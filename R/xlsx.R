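# Minimal OOXML spreadsheet support: enough to round-trip one-column-per-set
# string tables. Cells are written as inline strings (no shared-string table,
# no number formatting), so identifiers that look numeric survive verbatim.
# The zip container is written with deflate streams and CRC32 values harvested
# from memCompress(type = "gzip") (RFC 1952: the gzip trailer carries the
# CRC32 of the uncompressed data), and zero timestamps, so output is
# byte-deterministic.

le_bytes <- function(value, size) {
  value <- as.numeric(value)
  raws <- raw(size)
  for (i in seq_len(size)) {
    raws[i] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  raws
}

deflate_parts <- function(data) {
  # Compress through a gzfile() connection: a true gzip (RFC 1952) stream
  # whose trailer carries the CRC32 of the uncompressed data, and whose body
  # between header and trailer is the raw deflate stream zip entries expect.
  # (memCompress(type = "gzip") emits zlib/RFC 1950 framing, which has only
  # an Adler-32, so it cannot be used here.)
  if (length(data) == 0L) {
    return(list(deflate = raw(0), crc32 = raw(4), size = 0L, stored = TRUE))
  }
  tf <- tempfile("cwgz")
  on.exit(unlink(tf))
  con <- gzfile(tf, "wb")
  writeBin(data, con)
  close(con)
  gz <- readBin(tf, "raw", n = file.size(tf))
  L <- length(gz)
  stopifnot(L > 18L, gz[1] == as.raw(0x1f), gz[2] == as.raw(0x8b),
            gz[3] == as.raw(0x08))
  flg <- as.integer(gz[4])
  off <- 10L
  if (bitwAnd(flg, 4L) > 0L) {                     # FEXTRA
    xlen <- as.integer(gz[off + 1L]) + 256L * as.integer(gz[off + 2L])
    off <- off + 2L + xlen
  }
  for (bit in c(8L, 16L)) {                        # FNAME, FCOMMENT
    if (bitwAnd(flg, bit) > 0L) {
      while (gz[off + 1L] != as.raw(0)) off <- off + 1L
      off <- off + 1L
    }
  }
  if (bitwAnd(flg, 2L) > 0L) off <- off + 2L       # FHCRC
  list(deflate = gz[(off + 1L):(L - 8L)], crc32 = gz[(L - 7L):(L - 4L)],
       size = length(data), stored = FALSE)
}

zip_write <- function(path, files) {
  # files: named list, values character (UTF-8 XML) or raw
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  parts <- vector("list", length(files))
  pos <- 0L
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    if (is.character(data)) data <- charToRaw(enc2utf8(paste(data, collapse = "")))
    p <- deflate_parts(data)
    parts[[i]] <- p
    offsets[i] <- pos
    method <- if (p$stored) 0L else 8L
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      le_bytes(20, 2), le_bytes(0, 2), le_bytes(method, 2),
      le_bytes(0, 2), le_bytes(0x21, 2),          # time 0, date 1980-01-01
      p$crc32, le_bytes(length(p$deflate), 4), le_bytes(p$size, 4),
      le_bytes(length(name), 2), le_bytes(0, 2), name
    )
    writeBin(header, con)
    if (length(p$deflate)) writeBin(p$deflate, con)
    pos <- pos + length(header) + length(p$deflate)
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    p <- parts[[i]]
    method <- if (p$stored) 0L else 8L
    entry <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2), le_bytes(method, 2),
      le_bytes(0, 2), le_bytes(0x21, 2),
      p$crc32, le_bytes(length(p$deflate), 4), le_bytes(p$size, 4),
      le_bytes(length(name), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4), le_bytes(offsets[i], 4),
      name
    )
    writeBin(entry, con)
    cd_len <- cd_len + length(entry)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(files), 2), le_bytes(length(files), 2),
    le_bytes(cd_len, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  out <- character(length(j))
  for (k in seq_along(j)) {
    n <- j[k]
    s <- ""
    while (n > 0L) {
      s <- paste0(LETTERS[(n - 1L) %% 26L + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

letter_col <- function(s) {
  vapply(strsplit(toupper(s), ""), function(ch) {
    sum(match(ch, LETTERS) * 26L^rev(seq_along(ch) - 1L))
  }, numeric(1))
}

sheet_xml <- function(mat) {
  # mat: character matrix, NA = absent cell
  rows <- character(0)
  for (r in seq_len(nrow(mat))) {
    cells <- character(0)
    for (j in seq_len(ncol(mat))) {
      v <- mat[r, j]
      if (is.na(v)) next
      cells <- c(cells, sprintf(
        '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
        col_letter(j), r, xml_escape(v)))
    }
    if (length(cells)) {
      rows <- c(rows, sprintf('<row r="%d">%s</row>', r,
                              paste(cells, collapse = "")))
    }
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>'
  )
}

write_xlsx_sheets <- function(sheets, path) {
  # sheets: named list of character matrices; first sheet carries the data
  stopifnot(length(sheets) >= 1L, !is.null(names(sheets)))
  ns <- length(sheets)
  sheet_entries <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xml_escape(names(sheets)), seq_len(ns), seq_len(ns)), collapse = "")
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheet_entries, '</sheets></workbook>'
  )
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf(paste0(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/',
      'officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>'),
      seq_len(ns), seq_len(ns)), collapse = ""),
    '</Relationships>'
  )
  types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf(paste0(
      '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType=',
      '"application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>'),
      seq_len(ns)), collapse = ""),
    '</Types>'
  )
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/',
    'officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'
  )
  files <- c(
    list("[Content_Types].xml" = types, "_rels/.rels" = root_rels,
         "xl/workbook.xml" = workbook, "xl/_rels/workbook.xml.rels" = rels),
    stats::setNames(lapply(sheets, sheet_xml),
                    sprintf("xl/worksheets/sheet%d.xml", seq_len(ns)))
  )
  zip_write(path, files)
}

read_xlsx_first_sheet <- function(path) {
  td <- tempfile("cwxlsx")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  ok <- tryCatch({ utils::unzip(path, exdir = td); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  wb_path <- file.path(td, "xl", "workbook.xml")
  if (!ok || !file.exists(wb_path)) {
    stop_cogwheel("format", sprintf("'%s' is not a readable .xlsx workbook", path))
  }
  wb <- xml2::xml_ns_strip(xml2::read_xml(wb_path))
  sheets <- xml2::xml_find_all(wb, ".//sheet")
  if (length(sheets) == 0L) stop_cogwheel("format", "workbook has no sheets")
  rid <- xml2::xml_attr(sheets[[1]], "id")
  rels <- xml2::xml_ns_strip(
    xml2::read_xml(file.path(td, "xl", "_rels", "workbook.xml.rels")))
  rel_nodes <- xml2::xml_find_all(rels, ".//Relationship")
  targets <- stats::setNames(xml2::xml_attr(rel_nodes, "Target"),
                             xml2::xml_attr(rel_nodes, "Id"))
  target <- targets[[rid]]
  target <- sub("^/", "", target)
  sheet_path <- if (startsWith(target, "xl/")) file.path(td, target)
                else file.path(td, "xl", target)
  shared <- character(0)
  ss_path <- file.path(td, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::xml_ns_strip(xml2::read_xml(ss_path))
    shared <- vapply(xml2::xml_find_all(ss, ".//si"), xml2::xml_text,
                     character(1))
  }
  sh <- xml2::xml_ns_strip(xml2::read_xml(sheet_path))
  cells <- xml2::xml_find_all(sh, ".//sheetData/row/c")
  if (length(cells) == 0L) return(matrix(NA_character_, 0, 0))
  refs <- xml2::xml_attr(cells, "r")
  types <- xml2::xml_attr(cells, "t")
  vals <- vapply(seq_along(cells), function(k) {
    ty <- types[k]
    if (!is.na(ty) && ty == "inlineStr") {
      return(xml2::xml_text(xml2::xml_find_first(cells[[k]], "./is")))
    }
    v <- xml2::xml_text(xml2::xml_find_first(cells[[k]], "./v"))
    if (!is.na(ty) && ty == "s") return(shared[as.integer(v) + 1L])
    v
  }, character(1))
  rowi <- as.integer(sub("^[A-Za-z]+", "", refs))
  coli <- as.integer(letter_col(sub("[0-9]+$", "", refs)))
  mat <- matrix(NA_character_, max(rowi), max(coli))
  mat[cbind(rowi, coli)] <- vals
  mat
}
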