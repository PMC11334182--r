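test_that("assembly merges interactions targeting the same element", {
  il <- interaction_list(rbind(
    new_interaction("A", "B", "positive"),
    new_interaction("C", "B", "negative")))
  res <- assemble_model(il)
  expect_no_issues(res$issues)
  el <- res$model$elements
  expect_equal(el$variable, c("A", "B", "C"))  # first-appearance order
  b <- el[el$variable == "B", ]
  expect_equal(b$positive_rule, "A")
  expect_equal(b$negative_rule, "C")
  inputs <- el[el$variable != "B", ]
  expect_true(all(is.na(inputs$positive_rule)))
  expect_true(all(is.na(inputs$negative_rule)))
  expect_true(all(inputs$spontaneous == "none"))
  expect_true(all(el$levels == 2L))
  expect_equal(unlist(el$initial_values), rep(0L, 3))
})

test_that("duplicate interactions collapse to a single rule leaf", {
  il <- interaction_list(rbind(
    new_interaction("A", "B", "positive"),
    new_interaction("A", "B", "positive")))
  res <- assemble_model(il)
  b <- res$model$elements[res$model$elements$variable == "B", ]
  expect_equal(b$positive_rule, "A")
})

test_that("element count equals the number of distinct participants", {
  il <- random_interaction_list(8, 10, seed = 21)
  truth <- attr(il, "edges")
  res <- assemble_model(il)
  expect_equal(nrow(res$model$elements),
               length(unique(c(truth$source, truth$target))))
  expect_no_issues(validate_model(res$model))
})

test_that("conflicting entity attributes warn and first occurrence wins", {
  il <- interaction_list(rbind(
    new_interaction("A", "B", "positive", regulator_compartment = "nucleus"),
    new_interaction("A", "C", "positive", regulator_compartment = "cytosol")))
  res <- assemble_model(il)
  expect_true(any(res$issues$severity == "warning" &
                    grepl("conflicting compartment", res$issues$message)))
  expect_equal(res$model$elements$compartment[1], "nucleus")
})

test_that("entities with the same name but different types stay distinct", {
  # the identity key is (database, id) or name + entity type, so the gene
  # and the protein form of the same symbol are separate nodes
  il <- interaction_list(rbind(
    new_interaction("AKT1", "B", "positive", regulator_type = "protein"),
    new_interaction("AKT1", "C", "positive", regulator_type = "gene")))
  res <- assemble_model(il)
  expect_equal(nrow(res$model$elements), 4)
  expect_equal(anyDuplicated(res$model$elements$variable), 0)
})

test_that("entities keyed by database id merge across differing names", {
  il <- interaction_list(rbind(
    new_interaction("AKT", "B", "positive",
                    regulator_id = "P31749", regulator_database = "UniProt"),
    new_interaction("AKT1", "C", "positive",
                    regulator_id = "P31749", regulator_database = "uniprot")))
  res <- assemble_model(il)
  expect_equal(nrow(res$model$elements), 3)  # AKT, B, C
})

test_that("disassembly inverts assembly on the signed edge set", {
  m <- motif("toggle")
  il <- disassemble_model(m)
  expect_equal(nrow(il$records), 2)
  expect_true(all(il$records$sign == "negative"))

  m2 <- executable_model(tibble::tibble(
    element_name = c("A", "B", "X"), variable = c("A", "B", "X"),
    positive_rule = c(NA, NA, "max(A, B)")))
  il2 <- disassemble_model(m2)
  expect_equal(nrow(il2$records), 2)
  expect_true(all(il2$records$sign == "positive"))
  expect_equal(il2$records$regulator_name, c("A", "B"))

  for (seed in 1:5) {
    il3 <- random_interaction_list(6, 9, seed = seed)
    round <- disassemble_model(assemble_model(il3)$model)
    expect_equal(edge_key(signed_edges(round, by_name = TRUE)),
                 edge_key(signed_edges(il3, by_name = TRUE)))
  }
})

test_that("merging is idempotent and unions provenance of duplicates", {
  il <- random_interaction_list(5, 6, seed = 3, fill_context = TRUE)
  self <- merge_interaction_lists(il, il)
  expect_equal(nrow(self$interactions$records), nrow(il$records))
  expect_equal(self$report$merged, nrow(il$records))
  expect_identical(self$interactions$records$paper_ids, il$records$paper_ids)

  a <- interaction_list(new_interaction("A", "B", "positive",
                                        paper_ids = "PMID:1"))
  b <- interaction_list(new_interaction("A", "B", "positive",
                                        paper_ids = c("PMID:1", "PMID:2")))
  res <- merge_interaction_lists(a, b)
  expect_equal(nrow(res$interactions$records), 1)
  expect_setequal(res$interactions$records$paper_ids[[1]],
                  c("PMID:1", "PMID:2"))

  d1 <- random_interaction_list(4, 3, seed = 8)
  d2 <- interaction_list(rbind(
    new_interaction("Z1", "Z2", "positive"),
    new_interaction("Z2", "Z3", "negative"),
    new_interaction("Z3", "Z4", "positive"),
    new_interaction("Z4", "Z1", "negative")))
  res2 <- merge_interaction_lists(d1, d2)
  expect_equal(nrow(res2$interactions$records), 7)
  expect_equal(res2$report$merged, 0)
})

test_that("variable tokens are sanitized and deduplicated", {
  il <- interaction_list(rbind(
    new_interaction("NF-kB", "IL-6", "positive"),
    new_interaction("NF kB", "IL-6", "positive", regulator_type = "complex")))
  res <- assemble_model(il)
  vars <- res$model$elements$variable
  expect_true(all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", vars)))
  expect_equal(anyDuplicated(vars), 0)
})
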