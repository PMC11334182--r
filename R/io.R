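# Reading and writing the two BioRECIPE layouts from/to CSV, TSV and XLSX.
#
# Dialect decisions: CSV is UTF-8, comma-separated, RFC-4180 quoted; TSV is
# unquoted and cells may not contain tabs or newlines; XLSX uses the first
# (only) worksheet. An empty cell means "attribute absent" and is read as NA.

detect_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "xlsx")) return(ext)
  rlang::abort(sprintf(
    "cannot infer format from extension '%s'; pass format = csv|tsv|xlsx",
    ext))
}

# Returns a character matrix including the header row; empty cells are NA.
read_grid <- function(path, format) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "xlsx") return(read_xlsx_grid(path))
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  df <- suppressWarnings(reader(
    path, col_names = FALSE, col_types = readr::cols(.default = "c"),
    na = "", progress = FALSE, name_repair = "minimal",
    show_col_types = FALSE))
  if (nrow(df) == 0) rlang::abort(sprintf("no header row in %s", path))
  as.matrix(df)
}

split_list_cell <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

parse_boolean_cell <- function(x) {
  if (is.na(x)) return(NA)
  v <- vocabulary()$booleans
  lx <- tolower(trimws(x))
  if (lx %in% v$true_values) return(TRUE)
  if (lx %in% v$false_values) return(FALSE)
  NA
}

# Shared front half of both readers: grid -> header mapping + raw columns.
open_sheet <- function(path, format, expect_layout) {
  format <- detect_format(path, format)
  grid <- read_grid(path, format)
  header <- as.character(grid[1, ])
  keep <- seq_len(max(which(!is.na(header) & nzchar(header)), 1))
  grid <- grid[, keep, drop = FALSE]
  header <- header[keep]
  blank <- is.na(header) | !nzchar(header)
  header[blank] <- paste0("column_", which(blank))
  nh <- normalize_header(header)
  if (is.na(nh$layout) || nh$layout != expect_layout) {
    got <- if (is.na(nh$layout)) "no known columns"
           else sprintf("the %s layout (%d matching columns)",
                        nh$layout, nh$score)
    rlang::abort(sprintf("expected the %s layout in %s, but header matches %s",
                         expect_layout, path, got))
  }
  body <- if (nrow(grid) > 1) grid[-1, , drop = FALSE]
          else matrix(NA_character_, 0, length(header))
  column <- function(internal, canon) {
    hdr <- canon[[internal]]
    if (hdr %in% names(nh$mapping)) body[, nh$mapping[[hdr]]]
    else rep(NA_character_, nrow(body))
  }
  extras <- tibble::as_tibble(
    lapply(stats::setNames(as.list(nh$extras), names(nh$extras)),
           function(j) unname(body[, j])),
    .name_repair = "minimal")
  if (length(nh$extras) == 0) extras <- tibble::tibble(.rows = nrow(body))
  list(column = column, extras = extras, issues = nh$issues,
       n = nrow(body))
}

#' Read an interaction list
#'
#' Reads the event-based layout from a CSV, TSV or XLSX file. All parseable
#' records are returned even when individual rows carry error-level issues;
#' inspect the issue table to find them. A file whose header matches the
#' element layout (or no layout) raises an error.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, `"xlsx"`, or `"auto"` (by extension).
#' @return List with `interactions` (a `biorecipe_interactions`) and
#'   `issues` (tibble).
#' @export
read_interaction_list <- function(path, format = "auto") {
  sh <- open_sheet(path, format, "interaction")
  canon <- .interaction_columns
  cols <- lapply(stats::setNames(names(canon), names(canon)),
                 function(f) sh$column(f, canon))
  issues <- sh$issues

  score_raw <- cols$score
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(!is.na(score_raw) & is.na(score))
  for (i in bad) {
    issues <- bind_issues(issues, issue(
      "error", sprintf("Score is not a number: '%s'", score_raw[i]),
      i, "Score"))
  }
  records <- tibble::as_tibble(cols[setdiff(names(canon),
                                            c("score", "paper_ids"))])
  records$score <- score
  records$paper_ids <- lapply(cols$paper_ids, split_list_cell)
  # canonicalize controlled terms where they match the vocabulary
  v <- vocabulary()
  canonize <- function(x, terms) {
    m <- unname(vapply(x, match_term, "", terms = terms))
    ifelse(is.na(x) | is.na(m), x, m)
  }
  records$sign <- canonize(records$sign, v$signs)
  records$connection_type <- canonize(records$connection_type,
                                      v$connection_types)
  for (f in c("regulator_type", "regulated_type"))
    records[[f]] <- canonize(records[[f]], v$entity_types)

  il <- interaction_list(records, extras = sh$extras,
                         source_annotation = path)
  issues <- bind_issues(issues, validate_interactions(il))
  list(interactions = il, issues = issues)
}

#' Write an interaction list
#'
#' Emits the canonical 26-column header (plus any preserved extra columns);
#' absent optional fields become empty cells; `Paper IDs` is written as a
#' comma-separated cell. Refuses to write a list that validates with
#' error-level issues. `read_interaction_list(write_interaction_list(x))`
#' reproduces `x` field for field.
#'
#' @inheritParams read_interaction_list
#' @param x A `biorecipe_interactions`.
#' @return `path`, invisibly.
#' @export
write_interaction_list <- function(x, path, format = "auto") {
  stopifnot(inherits(x, "biorecipe_interactions"))
  issues <- validate_interactions(x)
  if (has_errors(issues)) {
    rlang::abort(c("interaction list has validation errors; not writing",
                   utils::head(issues$message[issues$severity == "error"], 5)))
  }
  recs <- x$records
  out <- list()
  for (f in names(.interaction_columns)) {
    out[[.interaction_columns[[f]]]] <- switch(
      f,
      score = ifelse(is.na(recs$score), NA_character_,
                     format_number(recs$score)),
      paper_ids = vapply(recs$paper_ids, paste, "", collapse = ","),
      as.character(recs[[f]]))
  }
  grid <- c(out, as.list(x$extras))
  write_sheet(grid, nrow(recs), path, format)
}

#' Read an executable model
#'
#' Reads the element-based layout from CSV, TSV or XLSX. Regulation-rule
#' cells are parsed with [parse_rule()] and parse failures are returned as
#' row-anchored error issues; the same holds for the other typed cells
#' (`Levels`, `Initial Values`, `Constant`, ...). All rows are returned,
#' flagged or not.
#'
#' @inheritParams read_interaction_list
#' @return List with `model` (a `biorecipe_model`) and `issues` (tibble).
#' @export
read_executable_model <- function(path, format = "auto") {
  sh <- open_sheet(path, format, "element")
  canon <- .element_columns
  cols <- lapply(stats::setNames(names(canon), names(canon)),
                 function(f) sh$column(f, canon))
  issues <- sh$issues
  add <- function(msg, row, col) {
    issues <<- bind_issues(issues, issue("error", msg, row, col))
  }

  int_col <- function(f, header) {
    raw <- cols[[f]]
    val <- suppressWarnings(as.integer(raw))
    for (i in which(!is.na(raw) & is.na(val)))
      add(sprintf("%s is not an integer: '%s'", header, raw[i]), i, header)
    val
  }
  levels <- int_col("levels", "Levels")
  increment <- int_col("increment", "Increment")
  update_rate <- int_col("update_rate", "Update Rate")

  constant <- logical(sh$n)
  for (i in seq_len(sh$n)) {
    raw <- cols$constant[i]
    b <- parse_boolean_cell(raw)
    if (!is.na(raw) && is.na(b))
      add(sprintf("Constant is not a boolean: '%s'", raw), i, "Constant")
    constant[i] <- isTRUE(b)
  }

  initial_values <- lapply(seq_len(sh$n), function(i) {
    parts <- split_list_cell(cols$initial_values[i])
    if (length(parts) == 0) return(0L)
    iv <- suppressWarnings(as.integer(parts))
    if (any(is.na(iv))) {
      add(sprintf("Initial Values is not a list of integers: '%s'",
                  cols$initial_values[i]), i, "Initial Values")
      return(0L)
    }
    iv
  })

  v <- vocabulary()
  spont <- unname(vapply(cols$spontaneous, function(s) {
    m <- match_term(s, v$spontaneous)
    if (is.na(s)) "none" else if (!is.na(m)) m else s
  }, ""))

  elements <- tibble::tibble(
    element_name = cols$element_name, element_type = cols$element_type,
    element_subtype = cols$element_subtype, element_ids = cols$element_ids,
    element_database = cols$element_database,
    compartment = cols$compartment, compartment_id = cols$compartment_id,
    variable = cols$variable,
    positive_rule = cols$positive_rule, negative_rule = cols$negative_rule,
    levels = levels, initial_values = initial_values, constant = constant,
    spontaneous = spont, increment = increment, update_rate = update_rate,
    update_group = cols$update_group)

  model <- executable_model(elements, extras = sh$extras)
  issues <- bind_issues(issues, validate_model(model))
  list(model = model, issues = issues)
}

#' Write an executable model
#'
#' Regulation rules are re-serialized in canonical form (see
#' [serialize_rule()]); `Constant` is written as TRUE/FALSE; `Initial Values`
#' as a comma-separated list with one entry per scenario. Refuses to write a
#' model with error-level issues.
#'
#' @inheritParams read_interaction_list
#' @param model A `biorecipe_model`.
#' @return `path`, invisibly.
#' @export
write_executable_model <- function(model, path, format = "auto") {
  stopifnot(inherits(model, "biorecipe_model"))
  issues <- validate_model(model)
  if (has_errors(issues)) {
    rlang::abort(c("model has validation errors; not writing",
                   utils::head(issues$message[issues$severity == "error"], 5)))
  }
  el <- model$elements
  canon_rule <- function(txt) {
    if (is.na(txt)) NA_character_ else serialize_rule(parse_rule(txt))
  }
  out <- list()
  for (f in names(.element_columns)) {
    out[[.element_columns[[f]]]] <- switch(
      f,
      positive_rule = vapply(el$positive_rule, canon_rule, ""),
      negative_rule = vapply(el$negative_rule, canon_rule, ""),
      levels = as.character(el$levels),
      initial_values = vapply(el$initial_values, paste, "", collapse = ","),
      constant = ifelse(el$constant, "TRUE", "FALSE"),
      increment = as.character(el$increment),
      update_rate = as.character(el$update_rate),
      as.character(el[[f]]))
  }
  grid <- c(out, as.list(model$extras))
  write_sheet(grid, nrow(el), path, format)
}

format_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, "")
}

# grid: named list of character vectors (names are headers), n rows.
write_sheet <- function(grid, n, path, format) {
  format <- detect_format(path, format)
  headers <- names(grid)
  cells <- lapply(grid, function(col) {
    col <- as.character(col)
    length(col) <- n
    col
  })
  if (format == "xlsx") {
    m <- rbind(headers,
               if (n > 0) do.call(cbind, cells) else NULL)
    m <- matrix(as.character(m), nrow = n + 1)
    write_xlsx_grid(m, path)
    return(invisible(path))
  }
  df <- tibble::as_tibble(stats::setNames(cells, headers),
                          .name_repair = "minimal")
  if (format == "csv") {
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    flat <- c(headers, unlist(cells, use.names = FALSE))
    if (any(grepl("[\t\n\r]", flat[!is.na(flat)]))) {
      rlang::abort("TSV cells may not contain tabs or newlines")
    }
    readr::write_tsv(df, path, na = "", progress = FALSE,
                     quote = "none", escape = "none")
  }
  invisible(path)
}
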