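# Conversion between BioRECIPE and neighboring lightweight formats:
# SIF edge lists, subject-predicate-object triplet tables, and generic
# node/edge tables.

#' Convert an interaction list to SIF text
#'
#' One tab-separated line per interaction: regulator, relation, regulated,
#' with relation `activates` for positive and `inhibits` for negative signs.
#' Tabs and newlines inside names are replaced by spaces. SIF carries only
#' the signed edge; the names of the non-empty context/provenance columns
#' that are dropped are reported alongside.
#'
#' @param interactions A `biorecipe_interactions`.
#' @return List with `lines` (character vector, one line per record) and
#'   `dropped` (canonical headers of non-empty columns SIF cannot carry).
#' @export
to_sif <- function(interactions) {
  stopifnot(inherits(interactions, "biorecipe_interactions"))
  recs <- interactions$records
  clean <- function(x) gsub("[\t\n\r]+", " ", x)
  relation <- ifelse(recs$sign == "positive", "activates", "inhibits")
  lines <- if (nrow(recs) == 0) character() else
    paste(clean(recs$regulator_name), relation, clean(recs$regulated_name),
          sep = "\t")
  carried <- c("regulator_name", "regulated_name", "sign")
  nonempty <- vapply(setdiff(names(.interaction_columns), carried),
                     function(f) {
    col <- recs[[f]]
    if (is.list(col)) any(lengths(col) > 0) else any(!is.na(col))
  }, logical(1))
  dropped <- unname(.interaction_columns[names(nonempty)[nonempty]])
  list(lines = lines, dropped = dropped)
}

#' Parse SIF text into an interaction list
#'
#' Recognized relations: activates/activate/positive/+ map to a positive
#' sign, inhibits/inhibit/negative/- to a negative one (case-insensitive).
#' Lines with an unknown relation are skipped with a warning issue. Only
#' names and sign are populated.
#'
#' @param text Character vector of SIF lines, or a single string with
#'   embedded newlines, or a file path (when `is_path = TRUE`).
#' @param is_path Treat `text` as a file to read.
#' @return List with `interactions` and `issues`.
#' @export
from_sif <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  v <- vocabulary()$sif_relations
  issues <- no_issues()
  rows <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      issues <- bind_issues(issues, issue(
        "warning", sprintf("line %d has %d fields (expected 3); skipped",
                           i, length(parts)), i))
      next
    }
    rel <- tolower(trimws(parts[2]))
    sign <- if (rel %in% v$positive) "positive"
            else if (rel %in% v$negative) "negative"
            else NA_character_
    if (is.na(sign)) {
      issues <- bind_issues(issues, issue(
        "warning", sprintf("unknown relation '%s' at line %d; skipped",
                           parts[2], i), i))
      next
    }
    rows[[length(rows) + 1L]] <- new_interaction(trimws(parts[1]),
                                                 trimws(parts[3]), sign)
  }
  records <- if (length(rows) == 0) empty_interaction_records()
             else do.call(rbind, rows)
  list(interactions = interaction_list(records), issues = issues)
}

#' Convert an interaction list to a triplet table
#'
#' Subject-predicate-object statements with predicate `increases` for
#' positive and `decreases` for negative interactions; evidence text and
#' paper identifiers are carried in the `evidence` and `paper_ids` columns.
#'
#' @param interactions A `biorecipe_interactions`.
#' @return List with `triplets` (tibble: subject, predicate, object,
#'   evidence, paper_ids) and `dropped` (headers of non-empty columns the
#'   triplet table cannot carry).
#' @export
to_triplets <- function(interactions) {
  stopifnot(inherits(interactions, "biorecipe_interactions"))
  recs <- interactions$records
  pv <- vocabulary()$triplet_predicates
  triplets <- tibble::tibble(
    subject = recs$regulator_name,
    predicate = ifelse(recs$sign == "positive", pv$positive, pv$negative),
    object = recs$regulated_name,
    evidence = recs$statements,
    paper_ids = vapply(recs$paper_ids, paste, "", collapse = ","))
  carried <- c("regulator_name", "regulated_name", "sign", "statements",
               "paper_ids")
  nonempty <- vapply(setdiff(names(.interaction_columns), carried),
                     function(f) any(!is.na(recs[[f]])), logical(1))
  list(triplets = triplets,
       dropped = unname(.interaction_columns[names(nonempty)[nonempty]]))
}

#' Parse a triplet table into an interaction list
#'
#' Predicates `increases`/`decreases` (case-insensitive) map to positive/
#' negative signs; rows with any other predicate (correlative or associative
#' statements) are skipped with a warning issue. `evidence` and `paper_ids`
#' columns, when present, populate Statements and Paper IDs.
#'
#' @param table Data frame with columns `subject`, `predicate`, `object` and
#'   optionally `evidence`, `paper_ids`.
#' @return List with `interactions` and `issues`.
#' @export
from_triplets <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("subject", "predicate", "object") %in% names(table)))
  pv <- vocabulary()$triplet_predicates
  issues <- no_issues()
  rows <- list()
  for (i in seq_len(nrow(table))) {
    pred <- tolower(trimws(as.character(table$predicate[i])))
    sign <- if (pred == pv$positive) "positive"
            else if (pred == pv$negative) "negative"
            else NA_character_
    if (is.na(sign)) {
      issues <- bind_issues(issues, issue(
        "warning", sprintf("unknown predicate '%s' at row %d; skipped",
                           table$predicate[i], i), i, "predicate"))
      next
    }
    rows[[length(rows) + 1L]] <- new_interaction(
      as.character(table$subject[i]), as.character(table$object[i]), sign,
      statements = if ("evidence" %in% names(table))
        as.character(table$evidence[i]) else NA_character_,
      paper_ids = if ("paper_ids" %in% names(table))
        split_list_cell(as.character(table$paper_ids[i])) else character())
  }
  records <- if (length(rows) == 0) empty_interaction_records()
             else do.call(rbind, rows)
  list(interactions = interaction_list(records), issues = issues)
}

#' Export node and edge tables
#'
#' Produces plain node/edge tables for generic network tools from either an
#' interaction list (edges = records) or an executable model (edges = rule
#' leaves, signed by the rule they sit in). Ordering is deterministic:
#' nodes in first-appearance (interaction list) or row (model) order, edges
#' in record/rule order.
#'
#' @param x A `biorecipe_interactions` or `biorecipe_model`.
#' @return List with `nodes` (tibble: id, name, type, compartment) and
#'   `edges` (tibble: source, target, sign) where source/target reference
#'   node ids.
#' @export
to_graph <- function(x) {
  if (inherits(x, "biorecipe_model")) {
    el <- x$elements
    nodes <- tibble::tibble(id = el$variable, name = el$element_name,
                            type = el$element_type,
                            compartment = el$compartment)
    edges <- list()
    for (i in seq_len(nrow(el))) {
      for (side in c("positive_rule", "negative_rule")) {
        txt <- el[[side]][i]
        if (is.na(txt)) next
        sign <- if (side == "positive_rule") "positive" else "negative"
        for (v in rule_variables(parse_rule(txt))) {
          edges[[length(edges) + 1L]] <- tibble::tibble(
            source = v, target = el$variable[i], sign = sign)
        }
      }
    }
    edges <- if (length(edges) == 0)
      tibble::tibble(source = character(), target = character(),
                     sign = character())
    else do.call(rbind, edges)
    return(list(nodes = nodes, edges = edges))
  }
  stopifnot(inherits(x, "biorecipe_interactions"))
  recs <- x$records
  rkey <- record_keys(recs, "regulator")
  tkey <- record_keys(recs, "regulated")
  keys <- unique(as.vector(rbind(rkey, tkey)))
  first_of <- function(key) {
    i <- match(key, rkey)
    if (!is.na(i)) return(list(role = "regulator", row = i))
    list(role = "regulated", row = match(key, tkey))
  }
  nodes <- do.call(rbind, lapply(keys, function(k) {
    f <- first_of(k)
    g <- function(field) recs[[paste0(f$role, "_", field)]][f$row]
    tibble::tibble(id = k, name = g("name"), type = g("type"),
                   compartment = g("compartment"))
  }))
  if (is.null(nodes))
    nodes <- tibble::tibble(id = character(), name = character(),
                            type = character(), compartment = character())
  edges <- tibble::tibble(source = rkey, target = tkey, sign = recs$sign)
  list(nodes = nodes, edges = edges)
}

#' Signed edge set of an interaction list or model
#'
#' Utility used to check conservation across conversions: the distinct
#' (source, target, sign) triples, ordered deterministically. For
#' interaction lists the node key is the entity-identity key used by
#' [assemble_model()]; for models it is the variable token.
#'
#' @param x A `biorecipe_interactions` or `biorecipe_model`.
#' @param by_name For interaction lists, key edges by regulator/regulated
#'   name instead of the full identity key (useful when comparing against
#'   formats that only carry names).
#' @return Tibble `source`, `target`, `sign`, unique rows, sorted.
#' @export
signed_edges <- function(x, by_name = FALSE) {
  if (inherits(x, "biorecipe_model")) {
    e <- to_graph(x)$edges
  } else {
    recs <- x$records
    e <- if (by_name) {
      tibble::tibble(source = recs$regulator_name,
                     target = recs$regulated_name, sign = recs$sign)
    } else {
      to_graph(x)$edges
    }
  }
  e <- unique(e)
  e[order(e$source, e$target, e$sign), ]
}
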