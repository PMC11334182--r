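# Core containers: interaction lists and executable models, plus small
# row-construction helpers used by the fixtures and by user code.

empty_interaction_records <- function() {
  tibble::tibble(
    regulator_name = character(), regulator_type = character(),
    regulator_subtype = character(), regulator_id = character(),
    regulator_database = character(), regulator_compartment = character(),
    regulator_compartment_id = character(),
    regulated_name = character(), regulated_type = character(),
    regulated_subtype = character(), regulated_id = character(),
    regulated_database = character(), regulated_compartment = character(),
    regulated_compartment_id = character(),
    sign = character(), connection_type = character(),
    mechanism = character(), site = character(), cell_line = character(),
    cell_type = character(), tissue_type = character(),
    organism = character(), score = numeric(), source = character(),
    statements = character(), paper_ids = list()
  )
}

empty_element_records <- function() {
  tibble::tibble(
    element_name = character(), element_type = character(),
    element_subtype = character(), element_ids = character(),
    element_database = character(), compartment = character(),
    compartment_id = character(), variable = character(),
    positive_rule = character(), negative_rule = character(),
    levels = integer(), initial_values = list(), constant = logical(),
    spontaneous = character(), increment = integer(),
    update_rate = integer(), update_group = character()
  )
}

complete_columns <- function(records, template) {
  for (nm in names(template)) {
    if (!nm %in% names(records)) {
      proto <- template[[nm]]
      records[[nm]] <- if (is.list(proto)) {
        rep(list(if (nm == "paper_ids") character() else integer()),
            nrow(records))
      } else {
        rep(proto[NA_integer_][1], nrow(records))
      }
    }
  }
  records[, names(template), drop = FALSE]
}

#' Construct an interaction list
#'
#' An interaction list is the event-based BioRECIPE layout: one signed,
#' directed interaction per row, with node, edge, context and provenance
#' attribute blocks. Missing columns are filled with `NA`; `paper_ids` is a
#' list-column of character vectors; `score` is numeric.
#'
#' @param records Tibble/data.frame whose columns are (a subset of) the
#'   internal interaction fields, see `names(biorecipe_columns("interaction"))`.
#' @param extras Optional tibble of unrecognized columns preserved verbatim
#'   on round trip (same number of rows as `records`).
#' @param source_annotation Optional free-text provenance for the whole file.
#' @return Object of class `biorecipe_interactions`.
#' @export
#' @examples
#' il <- interaction_list(tibble::tibble(
#'   regulator_name = "AKT1", regulated_name = "FOXO1", sign = "negative"))
#' validate_interactions(il)
interaction_list <- function(records = empty_interaction_records(),
                             extras = NULL, source_annotation = NULL) {
  records <- complete_columns(tibble::as_tibble(records),
                              empty_interaction_records())
  records$score <- as.numeric(records$score)
  records$sign <- tolower(records$sign)
  if (is.null(extras)) extras <- tibble::tibble(.rows = nrow(records))
  stopifnot(nrow(extras) == nrow(records))
  structure(list(records = records, extras = tibble::as_tibble(extras),
                 source_annotation = source_annotation),
            class = "biorecipe_interactions")
}

#' Construct a single interaction record
#'
#' Convenience wrapper building a one-row records tibble for
#' [interaction_list()].
#'
#' @param regulator,regulated Entity names (required).
#' @param sign `"positive"` or `"negative"`.
#' @param ... Further interaction fields by internal name
#'   (e.g. `regulator_type`, `mechanism`, `score`, `paper_ids = c("PMID1")`).
#' @return One-row tibble.
#' @export
new_interaction <- function(regulator, regulated, sign, ...) {
  dots <- list(...)
  rec <- tibble::tibble(regulator_name = regulator,
                        regulated_name = regulated, sign = sign)
  for (nm in names(dots)) {
    rec[[nm]] <- if (nm == "paper_ids") list(dots[[nm]]) else dots[[nm]]
  }
  complete_columns(rec, empty_interaction_records())
}

#' Construct an executable model
#'
#' An executable model is the element-based BioRECIPE layout: one discrete
#' variable per row, combining every interaction that targets the element,
#' plus the attributes needed for simulation (levels, rules, initial values,
#' scheduling). Defaults are filled for missing columns: `levels = 2`,
#' `constant = FALSE`, `spontaneous = "none"`, `increment = 1`,
#' `update_rate = 1`, initial value 0.
#'
#' @param elements Tibble/data.frame of element rows (internal names, see
#'   `names(biorecipe_columns("element"))`); `initial_values` may be a
#'   list-column of integer vectors (one entry per scenario).
#' @param extras Optional tibble of unrecognized columns preserved on round
#'   trip.
#' @return Object of class `biorecipe_model` with a `scenario_count` field.
#' @export
#' @examples
#' m <- executable_model(tibble::tibble(
#'   element_name = c("A", "B"), variable = c("A", "B"),
#'   negative_rule = c("B", "A"), spontaneous = "increase"))
#' validate_model(m)
executable_model <- function(elements = empty_element_records(),
                             extras = NULL) {
  elements <- tibble::as_tibble(elements)
  if (!"variable" %in% names(elements) && "element_name" %in% names(elements))
    elements$variable <- elements$element_name
  elements <- complete_columns(elements, empty_element_records())
  elements$levels <- ifelse(is.na(elements$levels), 2L,
                            as.integer(elements$levels))
  elements$constant <- ifelse(is.na(elements$constant), FALSE,
                              elements$constant)
  elements$spontaneous <- ifelse(is.na(elements$spontaneous), "none",
                                 tolower(elements$spontaneous))
  elements$increment <- ifelse(is.na(elements$increment), 1L,
                               as.integer(elements$increment))
  elements$update_rate <- ifelse(is.na(elements$update_rate), 1L,
                                 as.integer(elements$update_rate))
  elements$initial_values <- lapply(elements$initial_values, function(iv) {
    if (length(iv) == 0 || all(is.na(iv))) 0L else as.integer(iv)
  })
  if (is.null(extras)) extras <- tibble::tibble(.rows = nrow(elements))
  stopifnot(nrow(extras) == nrow(elements))
  structure(list(elements = elements, extras = tibble::as_tibble(extras),
                 scenario_count = if (nrow(elements) == 0) 1L
                                  else max(lengths(elements$initial_values))),
            class = "biorecipe_model")
}

#' @export
print.biorecipe_interactions <- function(x, ...) {
  cat(sprintf("<BioRECIPE interaction list: %d interactions", nrow(x$records)))
  if (ncol(x$extras) > 0)
    cat(sprintf(", %d extra column(s)", ncol(x$extras)))
  cat(">\n")
  if (nrow(x$records) > 0) {
    print(x$records[, c("regulator_name", "sign", "regulated_name")], ...)
  }
  invisible(x)
}

#' @export
print.biorecipe_model <- function(x, ...) {
  cat(sprintf("<BioRECIPE executable model: %d elements, %d scenario(s)>\n",
              nrow(x$elements), x$scenario_count))
  if (nrow(x$elements) > 0) {
    print(x$elements[, c("variable", "levels", "positive_rule",
                         "negative_rule", "constant", "spontaneous")], ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
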