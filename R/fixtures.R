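# Deterministic network motifs and seeded random generators. Every other
# module is tested against these, so no external data is ever needed.

motif_elements <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, complete_columns,
                        template = empty_element_records()))
}

el_row <- function(name, variable = name, type = "protein", levels = 2L,
                   positive_rule = NA_character_,
                   negative_rule = NA_character_, initial = 0L,
                   constant = FALSE, spontaneous = "none") {
  tibble::tibble(element_name = name, element_type = type,
                 variable = variable, levels = as.integer(levels),
                 positive_rule = positive_rule, negative_rule = negative_rule,
                 initial_values = list(as.integer(initial)),
                 constant = constant, spontaneous = spontaneous,
                 increment = 1L, update_rate = 1L)
}

#' Canonical network motifs
#'
#' Small, fully specified executable models used throughout the test suite
#' and documentation:
#'
#' * `toggle` — two Boolean elements repressing each other
#'   (negative rule = the other variable, `spontaneous = "increase"`, the
#'   idiomatic encoding of Boolean NOT); two scenarios start it at (0,0)
#'   and (0,1).
#' * `repressilator` — three-element Boolean negative ring A -| B -| C -| A,
#'   same encoding; scenario 1 starts at (1,0,0).
#' * `cascade3` — three-level chain S -> A -> B with the source clamped
#'   (constant) at level 2 and `spontaneous = "decrease"` downstream, so the
#'   signal decays when the source is removed.
#' * `ffl_coherent` — coherent feed-forward loop: S -> A, and B requires both
#'   S and A (positive rule `(S, A)`, a min); S constant at 1.
#' * `ffl_incoherent` — incoherent feed-forward loop: S -> A, S -> B, A -| B;
#'   S constant at 1.
#'
#' @param name Motif name.
#' @return A `biorecipe_model` that validates with zero issues.
#' @export
#' @examples
#' motif("repressilator")
motif <- function(name = c("toggle", "repressilator", "cascade3",
                           "ffl_coherent", "ffl_incoherent")) {
  name <- match.arg(name)
  elements <- switch(
    name,
    toggle = motif_elements(
      el_row("A", negative_rule = "B", spontaneous = "increase",
             initial = c(0L, 0L)),
      el_row("B", negative_rule = "A", spontaneous = "increase",
             initial = c(0L, 1L))),
    repressilator = motif_elements(
      el_row("A", negative_rule = "C", spontaneous = "increase",
             initial = 1L),
      el_row("B", negative_rule = "A", spontaneous = "increase",
             initial = 0L),
      el_row("C", negative_rule = "B", spontaneous = "increase",
             initial = 0L)),
    cascade3 = motif_elements(
      el_row("S", levels = 3L, initial = 2L, constant = TRUE),
      el_row("A", levels = 3L, positive_rule = "S",
             spontaneous = "decrease"),
      el_row("B", levels = 3L, positive_rule = "A",
             spontaneous = "decrease")),
    ffl_coherent = motif_elements(
      el_row("S", initial = 1L, constant = TRUE),
      el_row("A", positive_rule = "S", spontaneous = "decrease"),
      el_row("B", positive_rule = "(S, A)", spontaneous = "decrease")),
    ffl_incoherent = motif_elements(
      el_row("S", initial = 1L, constant = TRUE),
      el_row("A", positive_rule = "S", spontaneous = "decrease"),
      el_row("B", positive_rule = "S", negative_rule = "A")))
  executable_model(elements)
}

#' Random interaction list
#'
#' Seeded generator of interaction lists over `n_entities` entities named
#' `E1..En` with random entity types. Directed pairs are sampled without
#' replacement (no self-loops, no duplicate edges); each gets a positive
#' sign with probability `p_positive`. With `fill_context = TRUE`,
#' plausible-looking context and provenance attributes (cell line, organism,
#' score, paper identifiers, evidence text) are filled in. The ground-truth
#' signed edge set is attached as attribute `"edges"`.
#'
#' @param n_entities Number of distinct entities.
#' @param n_interactions Number of interactions; must not exceed
#'   `n_entities * (n_entities - 1)`.
#' @param p_positive Probability of a positive sign.
#' @param seed Integer seed; the same seed reproduces the same list.
#' @param fill_context Also generate context/provenance filler.
#' @return A `biorecipe_interactions` (validates cleanly) with attribute
#'   `"edges"`: a tibble of (source, target, sign) ground truth by name.
#' @export
random_interaction_list <- function(n_entities, n_interactions,
                                    p_positive = 0.5, seed = 1,
                                    fill_context = FALSE) {
  stopifnot(n_entities >= 2, n_interactions >= 1)
  if (n_interactions > n_entities * (n_entities - 1)) {
    rlang::abort(sprintf(
      "cannot place %d distinct directed interactions among %d entities (max %d)",
      n_interactions, n_entities, n_entities * (n_entities - 1)))
  }
  local_seed(seed, {
    types <- sample(vocabulary()$entity_types, n_entities, replace = TRUE)
    names <- paste0("E", seq_len(n_entities))
    pairs <- expand.grid(from = seq_len(n_entities), to = seq_len(n_entities))
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample.int(nrow(pairs), n_interactions), ]
    sign <- ifelse(stats::runif(n_interactions) < p_positive,
                   "positive", "negative")
    records <- tibble::tibble(
      regulator_name = names[pick$from], regulator_type = types[pick$from],
      regulated_name = names[pick$to], regulated_type = types[pick$to],
      sign = sign)
    if (fill_context) {
      records$connection_type <- sample(c("direct", "indirect"),
                                        n_interactions, replace = TRUE)
      records$cell_line <- sample(c("HeLa", "HEK293", "MCF7"),
                                  n_interactions, replace = TRUE)
      records$organism <- "Homo sapiens"
      records$score <- round(stats::runif(n_interactions), 3)
      records$source <- sample(c("curation", "reading"), n_interactions,
                               replace = TRUE)
      records$statements <- sprintf("%s %ss %s.", records$regulator_name,
                                    ifelse(sign == "positive", "activate",
                                           "inhibit"),
                                    records$regulated_name)
      records$paper_ids <- lapply(seq_len(n_interactions), function(i) {
        sprintf("PMID:%d", sample.int(99999999, sample.int(2, 1)))
      })
    }
    il <- interaction_list(complete_columns(records,
                                            empty_interaction_records()))
    attr(il, "edges") <- tibble::tibble(
      source = records$regulator_name, target = records$regulated_name,
      sign = sign)
    il
  })
}

# Random rule AST over the given variables, exercising the full grammar.
random_ast <- function(vars, depth = 2) {
  leaf <- function() {
    kind <- sample(c("plain", "weighted", "complemented", "highest"), 1,
                   prob = c(0.55, 0.15, 0.15, 0.15))
    rule_leaf(sample(vars, 1),
              weight = if (kind == "weighted") sample(2:4, 1) else 1L,
              complemented = kind == "complemented",
              highest = kind == "highest")
  }
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.5) return(leaf())
    op <- sample(c("min", "max", "sum"), 1)
    k <- sample(1:3, 1)
    rule_op(op, lapply(seq_len(k), function(i) build(d - 1)))
  }
  build(depth)
}

#' Random executable model
#'
#' Seeded generator of valid executable models with variables `V1..Vn`.
#' Each element draws up to `max_regulators` regulators and random positive
#' and/or negative rules from the full grammar (nested min/max/sum, weights,
#' complements, highest-level markers); initial values are uniform in
#' `[0, levels - 1]`. Every output validates with zero error issues, and the
#' same seed reproduces the same model.
#'
#' @param n_elements Number of elements.
#' @param max_regulators Maximum regulators available to each rule.
#' @param levels Number of levels for every element.
#' @param seed Integer seed.
#' @return A `biorecipe_model`.
#' @export
random_model <- function(n_elements, max_regulators = 3, levels = 2,
                         seed = 1) {
  stopifnot(n_elements >= 1, levels >= 2)
  local_seed(seed, {
    vars <- paste0("V", seq_len(n_elements))
    types <- sample(vocabulary()$entity_types, n_elements, replace = TRUE)
    rows <- lapply(seq_len(n_elements), function(i) {
      k <- sample.int(min(max_regulators, n_elements), 1)
      regs <- sample(vars, k)
      has_pos <- stats::runif(1) < 0.7
      has_neg <- stats::runif(1) < 0.5
      mk <- function() serialize_rule(random_ast(regs))
      el_row(paste0("Element ", i), variable = vars[i], type = types[i],
             levels = levels,
             positive_rule = if (has_pos) mk() else NA_character_,
             negative_rule = if (has_neg) mk() else NA_character_,
             initial = sample.int(levels, 1) - 1L,
             spontaneous = sample(c("none", "increase", "decrease"), 1))
    })
    executable_model(do.call(motif_elements, rows))
  })
}
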