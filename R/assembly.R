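# Conversion between the event-based interaction list and the element-based
# executable model, and merging of curated interaction lists.

# Identity key for an entity: authoritative (database, identifier) when both
# are curated, otherwise case-folded name plus entity type.
entity_key <- function(name, type, id, database) {
  if (!is.na(id) && !is.na(database)) {
    paste0("id:", tolower(database), ":", id)
  } else {
    paste0("name:", tolower(trimws(name)), ":",
           tolower(ifelse(is.na(type), "", type)))
  }
}

record_keys <- function(recs, role) {
  g <- function(f) recs[[paste0(role, "_", f)]]
  vapply(seq_len(nrow(recs)), function(i) {
    entity_key(g("name")[i], g("type")[i], g("id")[i], g("database")[i])
  }, "")
}

sanitize_variable <- function(name) {
  v <- gsub("[^A-Za-z0-9_]+", "_", trimws(name))
  v <- gsub("^_+|_+$", "", v)
  if (!nzchar(v)) v <- "element"
  if (grepl("^[0-9]", v)) v <- paste0("v_", v)
  v
}

#' Assemble an executable model from an interaction list
#'
#' Builds one element per distinct entity (identified by database+identifier
#' when curated, otherwise by case-folded name and type). Every positive
#' interaction targeting an element contributes one regulator leaf to its
#' positive regulation rule, negatives likewise, combined with the `max`
#' combinator (any active regulator suffices) and de-duplicated: repeating an
#' interaction does not repeat the leaf. Entities never appearing as a
#' target become input elements with no rules. All elements get
#' `levels = default_levels`, increment 1, update rate 1, initial value 0;
#' merged provenance (Source, Paper IDs) is concatenated into a preserved
#' `Notes` column. Element order follows first appearance in the list.
#'
#' @param interactions A `biorecipe_interactions` that validates without
#'   errors.
#' @param default_levels Number of discrete levels given to every element
#'   (default 2 = Boolean).
#' @return List with `model` (a `biorecipe_model`) and `issues` (warnings
#'   about conflicting entity attributes; first occurrence wins).
#' @export
assemble_model <- function(interactions, default_levels = 2) {
  stopifnot(inherits(interactions, "biorecipe_interactions"))
  pre <- validate_interactions(interactions)
  if (has_errors(pre)) {
    rlang::abort(c("interaction list has validation errors; fix before assembly",
                   utils::head(pre$message[pre$severity == "error"], 5)))
  }
  recs <- interactions$records
  issues <- no_issues()

  rkey <- record_keys(recs, "regulator")
  tkey <- record_keys(recs, "regulated")

  # first-appearance entity registry, row-major (regulator then regulated)
  keys <- character()
  attrs <- list()
  fields <- c("name", "type", "subtype", "id", "database", "compartment",
              "compartment_id")
  register <- function(key, role, i) {
    vals <- lapply(fields, function(f) recs[[paste0(role, "_", f)]][i])
    names(vals) <- fields
    if (!key %in% keys) {
      keys <<- c(keys, key)
      attrs[[key]] <<- vals
    } else {
      old <- attrs[[key]]
      for (f in fields) {
        if (!is.na(vals[[f]]) && !is.na(old[[f]]) &&
            tolower(vals[[f]]) != tolower(old[[f]])) {
          issues <<- bind_issues(issues, issue(
            "warning", sprintf(
              "conflicting %s for entity '%s' at row %d ('%s' vs '%s'); first occurrence wins",
              f, old$name, i, old[[f]], vals[[f]]), i))
        } else if (is.na(old[[f]]) && !is.na(vals[[f]])) {
          attrs[[key]][[f]] <<- vals[[f]]  # fill gaps, never overwrite
        }
      }
    }
  }
  for (i in seq_len(nrow(recs))) {
    register(rkey[i], "regulator", i)
    register(tkey[i], "regulated", i)
  }

  # variable tokens: sanitized names with numeric suffixes on collision
  vars <- character(length(keys))
  names(vars) <- keys
  seen <- character()
  for (k in keys) {
    v <- sanitize_variable(attrs[[k]]$name)
    if (v %in% seen) {
      j <- 2
      while (paste0(v, "_", j) %in% seen) j <- j + 1
      v <- paste0(v, "_", j)
    }
    seen <- c(seen, v)
    vars[[k]] <- v
  }

  regulators_of <- function(key, want_sign) {
    idx <- which(tkey == key & recs$sign == want_sign)
    unique(vars[rkey[idx]])
  }
  notes_of <- function(key) {
    idx <- which(tkey == key | rkey == key)
    bits <- unique(c(recs$source[idx], unlist(recs$paper_ids[idx])))
    bits <- bits[!is.na(bits) & nzchar(bits)]
    if (length(bits) == 0) NA_character_ else paste(bits, collapse = "; ")
  }

  rows <- lapply(keys, function(k) {
    a <- attrs[[k]]
    pos <- regulators_of(k, "positive")
    neg <- regulators_of(k, "negative")
    tibble::tibble(
      element_name = a$name, element_type = a$type,
      element_subtype = a$subtype, element_ids = a$id,
      element_database = a$database, compartment = a$compartment,
      compartment_id = a$compartment_id, variable = vars[[k]],
      positive_rule = if (length(pos)) paste(pos, collapse = ", ")
                      else NA_character_,
      negative_rule = if (length(neg)) paste(neg, collapse = ", ")
                      else NA_character_,
      levels = as.integer(default_levels), initial_values = list(0L),
      constant = FALSE, spontaneous = "none", increment = 1L,
      update_rate = 1L, update_group = NA_character_)
  })
  elements <- do.call(rbind, c(list(empty_element_records()), rows))
  extras <- tibble::tibble(
    Notes = vapply(keys, notes_of, ""))
  if (nrow(elements) == 0) extras <- tibble::tibble(.rows = 0)
  model <- executable_model(elements, extras = extras)
  list(model = model, issues = issues)
}

#' Disassemble an executable model into an interaction list
#'
#' The inverse of [assemble_model()] on the signed directed graph: one
#' interaction per (regulator leaf, element) pair across both regulation
#' rules, with the sign given by which rule the leaf sits in. Entity
#' attributes are copied onto both participants.
#'
#' @param model A valid `biorecipe_model`.
#' @return A `biorecipe_interactions`.
#' @export
disassemble_model <- function(model) {
  stopifnot(inherits(model, "biorecipe_model"))
  el <- model$elements
  by_var <- stats::setNames(seq_len(nrow(el)), el$variable)
  entity_cols <- function(i, prefix) {
    out <- list(el$element_name[i], el$element_type[i],
                el$element_subtype[i], el$element_ids[i],
                el$element_database[i], el$compartment[i],
                el$compartment_id[i])
    names(out) <- paste0(prefix, "_", c("name", "type", "subtype", "id",
                                        "database", "compartment",
                                        "compartment_id"))
    out
  }
  rows <- list()
  for (i in seq_len(nrow(el))) {
    for (side in c("positive_rule", "negative_rule")) {
      txt <- el[[side]][i]
      if (is.na(txt)) next
      sign <- if (side == "positive_rule") "positive" else "negative"
      for (v in rule_variables(parse_rule(txt))) {
        j <- by_var[[v]]
        rows[[length(rows) + 1L]] <- tibble::as_tibble(
          c(entity_cols(j, "regulator"), entity_cols(i, "regulated"),
            list(sign = sign)))
      }
    }
  }
  records <- if (length(rows) == 0) empty_interaction_records()
             else do.call(rbind, lapply(rows, complete_columns,
                                        template = empty_interaction_records()))
  interaction_list(records)
}

#' Merge two interaction lists
#'
#' Union with de-duplication on (regulator identity, regulated identity,
#' sign, mechanism). Provenance fields of duplicates (`paper_ids`,
#' `statements`, `source`) are unioned; other differing optional attributes
#' count as conflicts and the first occurrence wins. Record order follows
#' `a` then the new records of `b`.
#'
#' @param a,b `biorecipe_interactions` objects that validate without errors.
#' @return List with `interactions` (merged list) and `report`
#'   (`n_a`, `n_b`, `kept`, `merged`, `conflicting`).
#' @export
merge_interaction_lists <- function(a, b) {
  stopifnot(inherits(a, "biorecipe_interactions"),
            inherits(b, "biorecipe_interactions"))
  recs <- rbind(a$records, b$records)
  key <- paste(record_keys(recs, "regulator"), record_keys(recs, "regulated"),
               recs$sign,
               tolower(ifelse(is.na(recs$mechanism), "", recs$mechanism)),
               sep = "\r")
  merged <- 0L
  conflicting <- 0L
  keep <- !duplicated(key)
  out <- recs[keep, ]
  union_chr <- function(x, y, sep = "; ") {
    bits <- unique(c(unlist(strsplit(x %||% "", sep, fixed = TRUE)),
                     unlist(strsplit(y %||% "", sep, fixed = TRUE))))
    bits <- bits[!is.na(bits) & nzchar(bits)]
    if (length(bits) == 0) NA_character_ else paste(bits, collapse = sep)
  }
  dup_rows <- which(!keep)
  compare_fields <- setdiff(names(empty_interaction_records()),
                            c("paper_ids", "statements", "source"))
  for (i in dup_rows) {
    j <- match(key[i], key[keep])
    merged <- merged + 1L
    out$paper_ids[[j]] <- unique(c(out$paper_ids[[j]], recs$paper_ids[[i]]))
    out$statements[j] <- union_chr(out$statements[j], recs$statements[i])
    out$source[j] <- union_chr(out$source[j], recs$source[i])
    same <- vapply(compare_fields, function(f) {
      identical(out[[f]][j], recs[[f]][i]) ||
        (is.na(out[[f]][j]) && is.na(recs[[f]][i]))
    }, logical(1))
    if (!all(same)) conflicting <- conflicting + 1L
  }
  list(interactions = interaction_list(out),
       report = list(n_a = nrow(a$records), n_b = nrow(b$records),
                     kept = nrow(out), merged = merged,
                     conflicting = conflicting))
}
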