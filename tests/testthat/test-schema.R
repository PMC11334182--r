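test_that("header matching folds case, spaces, underscores and hyphens", {
  nh <- normalize_header(c("regulator name", "Regulated_Name", "SIGN"))
  expect_equal(nh$layout, "interaction")
  expect_equal(nh$mapping,
               c("Regulator Name" = 1L, "Regulated Name" = 2L, "Sign" = 3L))
  expect_equal(nrow(nh$issues), 0)

  nh2 <- normalize_header(c("Variable", "Levels", "Positive Regulation Rule"))
  expect_equal(nh2$layout, "element")
  expect_equal(nh2$score, 3)
})

test_that("unmatched columns become warnings and extras, duplicates abort", {
  nh <- normalize_header(c("Regulator Name", "Sign", "Regulated Name",
                           "My Notes"))
  expect_equal(unname(nh$extras), 4L)
  expect_equal(nh$issues$severity, "warning")
  expect_match(nh$issues$message, "My Notes")

  expect_error(normalize_header(c("Sign", "sign")), "ambiguous header")
  expect_error(normalize_header(c("Regulated Name", "Sign", "Regulator Name",
                                  "regulator_name")),
               "columns 3 and 4")
})

test_that("normalize_header on a canonical header is the identity mapping", {
  for (layout in c("interaction", "element")) {
    canon <- biorecipe_columns(layout)
    nh <- normalize_header(unname(canon))
    expect_equal(nh$layout, layout)
    expect_equal(nh$mapping,
                 stats::setNames(seq_along(canon), unname(canon)))
    expect_equal(length(nh$extras), 0)
  }
})

test_that("a minimal record validates cleanly; vocabulary violations do not", {
  ok <- new_interaction("A", "B", "positive")
  expect_no_issues(validate_interaction_record(ok, 1))

  bad_sign <- new_interaction("A", "B", "up")
  iss <- validate_interaction_record(bad_sign, 3)
  expect_true(has_errors(iss))
  expect_match(iss$message[iss$severity == "error"], "positive|negative")
  expect_equal(iss$row[iss$severity == "error"], 3L)

  no_db <- new_interaction("A", "B", "positive", regulated_id = "Q9Y243")
  iss2 <- validate_interaction_record(no_db, 1)
  expect_true(has_errors(iss2))
  expect_match(iss2$message[iss2$severity == "error"], "Database")

  missing_sign <- new_interaction("A", "B", NA_character_)
  expect_true(has_errors(validate_interaction_record(missing_sign, 1)))

  neg_score <- new_interaction("A", "B", "negative", score = -1)
  expect_true(has_errors(validate_interaction_record(neg_score, 1)))
})

test_that("every error issue pinpoints a row or a column", {
  il <- interaction_list(rbind(
    new_interaction("", "B", "positive"),
    new_interaction("A", "B", "sideways"),
    new_interaction("A", "B", "negative", regulator_id = "X1")))
  iss <- validate_interactions(il)
  errs <- iss[iss$severity == "error", ]
  expect_gte(nrow(errs), 3)
  expect_true(all(!is.na(errs$row) | !is.na(errs$column)))
})

test_that("model validation catches the structural invariants", {
  dup <- executable_model(tibble::tibble(
    element_name = c("AKT", "AKT2"), variable = c("AKT", "AKT")))
  iss <- validate_model(dup)
  expect_true(any(grepl("duplicate variable 'AKT'", iss$message)))

  unresolved <- executable_model(tibble::tibble(
    element_name = "A", variable = "A", positive_rule = "FOXO1"))
  iss2 <- validate_model(unresolved)
  expect_true(any(grepl("unresolved regulator", iss2$message)))
  expect_equal(iss2$column[grepl("unresolved", iss2$message)],
               "Positive Regulation Rule")

  oob <- executable_model(tibble::tibble(
    element_name = "A", variable = "A", levels = 3L,
    initial_values = list(3L)))
  iss3 <- validate_model(oob)
  expect_true(any(grepl("initial value out of range", iss3$message)))

  ragged <- executable_model(tibble::tibble(
    element_name = c("A", "B"), variable = c("A", "B"),
    initial_values = list(c(0L, 1L), 0L)))
  expect_true(any(grepl("same number of initial-value scenarios",
                        validate_model(ragged)$message)))
})

test_that("validation is idempotent and side-effect free", {
  il <- random_interaction_list(5, 8, seed = 11, fill_context = TRUE)
  expect_identical(validate_interactions(il), validate_interactions(il))
  m <- random_model(4, seed = 11, levels = 3)
  expect_identical(validate_model(m), validate_model(m))
  expect_no_issues(validate_model(m))
})
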