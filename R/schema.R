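# Canonical column sets, controlled vocabularies, and record-level validation
# for the two BioRECIPE spreadsheet layouts.

# Internal name -> spreadsheet header, in canonical order.
.interaction_columns <- c(
  regulator_name           = "Regulator Name",
  regulator_type           = "Regulator Type",
  regulator_subtype        = "Regulator Subtype",
  regulator_id             = "Regulator ID",
  regulator_database       = "Regulator Database",
  regulator_compartment    = "Regulator Compartment",
  regulator_compartment_id = "Regulator Compartment ID",
  regulated_name           = "Regulated Name",
  regulated_type           = "Regulated Type",
  regulated_subtype        = "Regulated Subtype",
  regulated_id             = "Regulated ID",
  regulated_database       = "Regulated Database",
  regulated_compartment    = "Regulated Compartment",
  regulated_compartment_id = "Regulated Compartment ID",
  sign                     = "Sign",
  connection_type          = "Connection Type",
  mechanism                = "Mechanism",
  site                     = "Site",
  cell_line                = "Cell Line",
  cell_type                = "Cell Type",
  tissue_type              = "Tissue Type",
  organism                 = "Organism",
  score                    = "Score",
  source                   = "Source",
  statements               = "Statements",
  paper_ids                = "Paper IDs"
)

.element_columns <- c(
  element_name     = "Element Name",
  element_type     = "Element Type",
  element_subtype  = "Element Subtype",
  element_ids      = "Element IDs",
  element_database = "Element Database",
  compartment      = "Compartment",
  compartment_id   = "Compartment ID",
  variable         = "Variable",
  positive_rule    = "Positive Regulation Rule",
  negative_rule    = "Negative Regulation Rule",
  levels           = "Levels",
  initial_values   = "Initial Values",
  constant         = "Constant",
  spontaneous      = "Spontaneous",
  increment        = "Increment",
  update_rate      = "Update Rate",
  update_group     = "Update Group"
)

#' Canonical BioRECIPE column headers
#'
#' Returns the canonical spreadsheet headers of one of the two BioRECIPE
#' layouts, in the order they are written by [write_interaction_list()] /
#' [write_executable_model()].
#'
#' @param layout `"interaction"` (event-based, one interaction per row) or
#'   `"element"` (element-based, one model element per row).
#' @return Named character vector mapping internal field names to headers.
#' @export
#' @examples
#' biorecipe_columns("element")[["positive_rule"]]
biorecipe_columns <- function(layout = c("interaction", "element")) {
  layout <- match.arg(layout)
  if (layout == "interaction") .interaction_columns else .element_columns
}

# Controlled vocabularies live in a human-editable YAML file so curators can
# extend them without touching code.
the <- new.env(parent = emptyenv())

#' Controlled vocabularies
#'
#' The controlled term lists used during validation and conversion (entity
#' types, signs, connection types, spontaneous behaviours, SIF relation and
#' triplet predicate synonyms, boolean spellings). Loaded once per session
#' from the YAML file shipped in `inst/extdata/vocabulary.yaml`.
#'
#' @return Named list of character vectors / lists.
#' @export
vocabulary <- function() {
  if (is.null(the$vocab)) {
    path <- system.file("extdata", "vocabulary.yaml", package = "biorecipe",
                        mustWork = TRUE)
    the$vocab <- yaml::read_yaml(path)
  }
  the$vocab
}

# ---- Issues ----------------------------------------------------------------

issue <- function(severity, message, row = NA_integer_, column = NA_character_) {
  tibble::tibble(severity = severity, row = as.integer(row),
                 column = as.character(column), message = message)
}

no_issues <- function() {
  tibble::tibble(severity = character(), row = integer(),
                 column = character(), message = character())
}

bind_issues <- function(...) {
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  if (length(dots) == 0) return(no_issues())
  do.call(rbind, c(list(no_issues()), dots))
}

#' Does an issue table contain error-level issues?
#'
#' @param issues Issue tibble as returned by the validators
#'   (columns `severity`, `row`, `column`, `message`).
#' @return `TRUE` if any row has `severity == "error"`.
#' @export
has_errors <- function(issues) {
  nrow(issues) > 0 && any(issues$severity == "error")
}

# ---- Header normalization ---------------------------------------------------

fold_header <- function(x) gsub("[ _-]", "", tolower(trimws(x)))

#' Match a raw spreadsheet header against the canonical column sets
#'
#' Matching is case-insensitive and ignores spaces, underscores and hyphens.
#' The layout (interaction vs element) is chosen by the larger number of
#' matched canonical columns. Source columns matching no canonical name are
#' reported as warnings and preserved as extras.
#'
#' @param raw_columns Character vector of header cells as read from a file.
#' @return List with `layout` (`"interaction"`, `"element"`, or `NA` when
#'   nothing matches), `score` (matches for the winning layout), `mapping`
#'   (named integer vector: canonical header -> source position), `extras`
#'   (named integer vector of unmatched columns), and `issues`.
#'   Two source columns mapping to one canonical name raise an error.
#' @export
#' @examples
#' normalize_header(c("regulator name", "Regulated_Name", "SIGN"))$layout
normalize_header <- function(raw_columns) {
  stopifnot(length(raw_columns) > 0)
  folded <- fold_header(raw_columns)
  score_layout <- function(canon) sum(folded %in% fold_header(canon))
  scores <- c(interaction = score_layout(.interaction_columns),
              element     = score_layout(.element_columns))
  layout <- if (max(scores) == 0) NA_character_ else names(which.max(scores))
  canon <- if (is.na(layout)) character() else biorecipe_columns(layout)

  mapping <- integer()
  extras <- integer()
  issues <- no_issues()
  canon_folded <- fold_header(canon)
  for (i in seq_along(folded)) {
    hit <- which(canon_folded == folded[i])
    if (length(hit) == 1) {
      header <- unname(canon[hit])
      if (header %in% names(mapping)) {
        rlang::abort(sprintf(
          "ambiguous header: columns %d and %d both map to canonical '%s'",
          mapping[[header]], i, header))
      }
      mapping[[header]] <- i
    } else {
      extras[[raw_columns[i]]] <- i
      issues <- bind_issues(issues, issue(
        "warning", sprintf("unrecognized column '%s' preserved as extra",
                           raw_columns[i]),
        column = raw_columns[i]))
    }
  }
  list(layout = layout, score = unname(max(scores)), scores = scores,
       mapping = mapping, extras = extras, issues = issues)
}

# ---- Vocabulary helpers -----------------------------------------------------

# Case-insensitive match against a controlled list; returns the canonical
# (lower-case) term or NA when the value is not in the vocabulary.
match_term <- function(value, terms) {
  if (is.na(value)) return(NA_character_)
  hit <- match(tolower(trimws(value)), tolower(terms))
  if (is.na(hit)) NA_character_ else tolower(terms[[hit]])
}

# ---- Interaction validation -------------------------------------------------

validate_entity <- function(rec, role, row) {
  v <- vocabulary()
  g <- function(field) rec[[paste0(role, "_", field)]]
  col <- function(field) {
    .interaction_columns[[paste0(role, "_", field)]]
  }
  issues <- no_issues()
  name <- g("name")
  if (is.na(name) || !nzchar(trimws(name))) {
    issues <- bind_issues(issues, issue(
      "error", sprintf("%s is required and must be non-empty", col("name")),
      row, col("name")))
  }
  type <- g("type")
  if (!is.na(type) && is.na(match_term(type, v$entity_types))) {
    issues <- bind_issues(issues, issue(
      "warning",
      sprintf("%s '%s' is not a known entity type (%s)", col("type"), type,
              paste(v$entity_types, collapse = ", ")),
      row, col("type")))
  }
  if (!is.na(g("id")) && is.na(g("database"))) {
    issues <- bind_issues(issues, issue(
      "error",
      sprintf("%s required when %s is present", col("database"), col("id")),
      row, col("id")))
  }
  issues
}

#' Validate a single interaction record
#'
#' Checks one row of an interaction list against the record invariants:
#' non-empty regulator and regulated names, `Sign` in \{positive, negative\},
#' `Connection Type` in \{direct, indirect\} when present, a database named
#' whenever an identifier is given, and a non-negative numeric `Score`.
#' All failures are returned as issues; nothing is thrown.
#'
#' @param record One-row tibble (or named list) with the internal interaction
#'   fields (see `names(biorecipe_columns("interaction"))`).
#' @param row 1-based row index used to anchor the issues.
#' @return Issue tibble; empty when the record is valid.
#' @export
validate_interaction_record <- function(record, row = NA_integer_) {
  v <- vocabulary()
  issues <- bind_issues(validate_entity(record, "regulator", row),
                        validate_entity(record, "regulated", row))
  sign <- record[["sign"]]
  if (is.na(sign) || !nzchar(trimws(sign))) {
    issues <- bind_issues(issues, issue(
      "error", "Sign is required", row, "Sign"))
  } else if (is.na(match_term(sign, v$signs))) {
    issues <- bind_issues(issues, issue(
      "error", sprintf("Sign must be one of: %s (got '%s')",
                       paste(v$signs, collapse = "|"), sign),
      row, "Sign"))
  }
  ct <- record[["connection_type"]]
  if (!is.null(ct) && !is.na(ct) && is.na(match_term(ct, v$connection_types))) {
    issues <- bind_issues(issues, issue(
      "error", sprintf("Connection Type must be one of: %s (got '%s')",
                       paste(v$connection_types, collapse = "|"), ct),
      row, "Connection Type"))
  }
  score <- record[["score"]]
  if (!is.null(score) && !is.na(score)) {
    num <- suppressWarnings(as.numeric(score))
    if (is.na(num) || num < 0) {
      issues <- bind_issues(issues, issue(
        "error", sprintf("Score must be a non-negative number (got '%s')",
                         as.character(score)),
        row, "Score"))
    }
  }
  issues
}

#' Validate an interaction list
#'
#' Runs [validate_interaction_record()] on every row.
#'
#' @param x A `biorecipe_interactions` object (see [interaction_list()]).
#' @return Issue tibble; empty when every record is valid.
#' @export
validate_interactions <- function(x) {
  stopifnot(inherits(x, "biorecipe_interactions"))
  recs <- x$records
  out <- lapply(seq_len(nrow(recs)), function(i) {
    validate_interaction_record(recs[i, ], row = i)
  })
  do.call(bind_issues, out)
}

# ---- Model validation -------------------------------------------------------

.variable_re <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Validate an executable model
#'
#' Checks variable-token syntax and uniqueness, that every variable
#' referenced by a regulation rule resolves to an element, that levels,
#' increments and update rates are in range, that every initial value lies
#' in `[0, levels - 1]`, that all elements carry the same number of
#' initial-value scenarios, and controlled terms for `Spontaneous`.
#'
#' @param model A `biorecipe_model` (see [executable_model()]).
#' @return Issue tibble; empty when the model is valid.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "biorecipe_model"))
  v <- vocabulary()
  el <- model$elements
  issues <- no_issues()
  add <- function(...) issues <<- bind_issues(issues, issue(...))

  for (i in seq_len(nrow(el))) {
    name <- el$element_name[i]
    if (is.na(name) || !nzchar(trimws(name)))
      add("error", "Element Name is required", i, "Element Name")
    var <- el$variable[i]
    if (is.na(var) || !grepl(.variable_re, var)) {
      add("error", sprintf("Variable '%s' is not a valid token",
                           as.character(var)), i, "Variable")
    }
    if (is.na(el$levels[i]) || el$levels[i] < 2)
      add("error", sprintf("Levels must be an integer >= 2 (got %s)",
                           as.character(el$levels[i])), i, "Levels")
    if (is.na(el$increment[i]) || el$increment[i] < 1)
      add("error", "Increment must be an integer >= 1", i, "Increment")
    if (is.na(el$update_rate[i]) || el$update_rate[i] < 1)
      add("error", "Update Rate must be an integer >= 1", i, "Update Rate")
    sp <- el$spontaneous[i]
    if (!is.na(sp) && is.na(match_term(sp, v$spontaneous)))
      add("error", sprintf("Spontaneous must be one of: %s (got '%s')",
                           paste(v$spontaneous, collapse = "|"), sp),
          i, "Spontaneous")
    iv <- el$initial_values[[i]]
    if (length(iv) == 0) {
      add("error", "Initial Values must contain at least one scenario",
          i, "Initial Values")
    } else if (!is.na(el$levels[i]) && el$levels[i] >= 2 &&
               any(is.na(iv) | iv < 0 | iv > el$levels[i] - 1)) {
      add("error", sprintf(
        "initial value out of range [0, %d]: %s", el$levels[i] - 1,
        paste(iv, collapse = ",")), i, "Initial Values")
    }
    tp <- el$element_type[i]
    if (!is.na(tp) && is.na(match_term(tp, v$entity_types)))
      add("warning", sprintf("Element Type '%s' is not a known entity type",
                             tp), i, "Element Type")
  }

  dup <- el$variable[duplicated(el$variable) & !is.na(el$variable)]
  for (d in unique(dup)) {
    rows <- which(el$variable == d)
    add("error", sprintf("duplicate variable '%s' (rows %s)", d,
                         paste(rows, collapse = ", ")),
        rows[2], "Variable")
  }

  known <- el$variable[!is.na(el$variable)]
  for (i in seq_len(nrow(el))) {
    for (side in c("positive_rule", "negative_rule")) {
      txt <- el[[side]][i]
      if (is.na(txt)) next
      colname <- .element_columns[[side]]
      ast <- tryCatch(parse_rule(txt), error = function(e) e)
      if (inherits(ast, "error")) {
        add("error", sprintf("%s: %s", colname, conditionMessage(ast)),
            i, colname)
        next
      }
      missing <- setdiff(rule_variables(ast), known)
      if (length(missing) > 0)
        add("error", sprintf("unresolved regulator(s) in %s: %s", colname,
                             paste(missing, collapse = ", ")),
            i, colname)
    }
  }

  n_scen <- lengths(el$initial_values)
  if (nrow(el) > 0 && length(unique(n_scen)) > 1) {
    add("error", sprintf(
      "all elements must carry the same number of initial-value scenarios (found %s)",
      paste(sort(unique(n_scen)), collapse = ", ")),
      which(n_scen != n_scen[1])[1], "Initial Values")
  }
  issues
}
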