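# Minimal single-sheet OOXML (.xlsx) writer. Cells are written as inline
# strings, which every spreadsheet reader (including readxl) understands;
# styling, formulas and multiple sheets are out of scope. Reading goes
# through readxl.

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# grid: character matrix (header row included); NA cells are written empty.
write_xlsx_grid <- function(grid, path) {
  stopifnot(is.matrix(grid))
  cell_xml <- function(v) {
    if (is.na(v) || !nzchar(v)) return("<c/>")
    paste0('<c t="inlineStr"><is><t xml:space="preserve">', xml_escape(v),
           "</t></is></c>")
  }
  row_xml <- vapply(seq_len(nrow(grid)), function(i) {
    paste0("<row>",
           paste0(vapply(grid[i, ], cell_xml, ""), collapse = ""),
           "</row>")
  }, "")
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste0(row_xml, collapse = ""), "</sheetData></worksheet>")

  root <- tempfile("xlsx")
  on.exit(unlink(root, recursive = TRUE), add = TRUE)
  dir.create(file.path(root, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(root, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(root, "_rels"), recursive = TRUE)

  put <- function(rel, content) {
    con <- file(file.path(root, rel), open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(content, con, sep = "", useBytes = TRUE)
  }
  put("xl/worksheets/sheet1.xml", sheet)
  put("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"))
  put("_rels/.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"))
  put("xl/workbook.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'))
  put("xl/_rels/workbook.xml.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"))

  out <- normalizePath(path, mustWork = FALSE)
  if (file.exists(out)) unlink(out)
  old <- setwd(root)
  on.exit(setwd(old), add = TRUE)
  zip::zip(out, files = c("[Content_Types].xml", "_rels/.rels",
                          "xl/workbook.xml", "xl/_rels/workbook.xml.rels",
                          "xl/worksheets/sheet1.xml"),
           include_directories = FALSE)
  invisible(path)
}

read_xlsx_grid <- function(path) {
  df <- readxl::read_xlsx(path, col_names = FALSE, col_types = "text",
                          .name_repair = "minimal")
  as.matrix(df)
}
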