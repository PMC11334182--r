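test_that("the grammar parses commas, weights, groups and markers", {
  ast <- parse_rule("A, B")
  expect_equal(ast$op, "max")
  expect_equal(vapply(ast$children, `[[`, "", "var"), c("A", "B"))

  ast2 <- parse_rule("2*A, (B, !C)")
  expect_equal(ast2$op, "max")
  expect_equal(ast2$children[[1]]$weight, 2L)
  expect_equal(ast2$children[[2]]$op, "min")
  expect_true(ast2$children[[2]]$children[[2]]$complemented)
  expect_equal(ast2$children[[2]]$children[[2]]$var, "C")

  ast3 <- parse_rule("sum(A, 3*B^)")
  expect_equal(ast3$op, "sum")
  expect_equal(ast3$children[[2]]$weight, 3L)
  expect_true(ast3$children[[2]]$highest)

  # whitespace-insensitive
  expect_identical(parse_rule(" sum( A ,3 * B^ ) "), ast3)
})

test_that("malformed rules fail with positioned messages", {
  expect_error(parse_rule("min(A,"), "end of")
  expect_error(parse_rule("A, , B"), "position")
  expect_error(parse_rule("0*A"), "weight 0")
  expect_error(parse_rule("2*(A, B)"), "variable")
  expect_error(parse_rule("!A^"), "plain variables")
  expect_error(parse_rule("A & B"), "unexpected character")
  expect_error(parse_rule(""), "empty rule")
})

test_that("serialization is canonical and inverts parsing", {
  expect_equal(serialize_rule(parse_rule("max(A,B)")), "A, B")
  expect_equal(serialize_rule(parse_rule("min(B, !C)")), "(B, !C)")
  expect_equal(serialize_rule(parse_rule("sum(2*A, B^)")), "sum(2*A, B^)")

  set.seed(404)
  for (i in 1:200) {
    ast <- gen_ast(c("A", "B", "C_1", "xY"))
    expect_identical(parse_rule(serialize_rule(ast)), ast)
  }
})

test_that("evaluation matches the hand-worked examples", {
  lv <- c(A = 2, B = 3)
  expect_equal(evaluate_rule(parse_rule("max(A, B)"), c(A = 0, B = 2), lv), 2)
  expect_equal(evaluate_rule(parse_rule("!A"), c(A = 1), c(A = 2)), 0)
  expect_equal(evaluate_rule(parse_rule("!A"), c(A = 0), c(A = 2)), 1)
  expect_equal(evaluate_rule(parse_rule("sum(2*A, B^)"), c(A = 1, B = 2), lv),
               3)
  expect_equal(evaluate_rule(parse_rule("B^"), c(B = 1), c(B = 3)), 0)
  expect_error(evaluate_rule(parse_rule("Z"), c(A = 1), c(A = 2)),
               "unresolved variable")
})

test_that("evaluation agrees with a naive recursive oracle on random rules", {
  set.seed(77)
  vars <- c("A", "B", "C", "D")
  for (i in 1:300) {
    levels_of <- stats::setNames(sample(2:4, 4, replace = TRUE), vars)
    state <- stats::setNames(
      vapply(vars, function(v) sample(0:(levels_of[[v]] - 1), 1), 0L), vars)
    ast <- gen_ast(vars)
    expect_equal(evaluate_rule(ast, state, levels_of),
                 oracle_eval(ast, state, levels_of))
  }
})

test_that("next_value implements the net-regulation semantics", {
  lv <- c(A = 2, B = 2, S = 3)
  elem <- function(...) {
    utils::modifyList(list(variable = "X", levels = 2L, constant = FALSE,
                           spontaneous = "none", increment = 1L),
                      list(...))
  }

  # both rules: compare P and N, ties hold
  e <- elem(positive_rule = "A", negative_rule = "B")
  lv2 <- c(A = 2, B = 2, X = 2)
  expect_equal(next_value(e, c(A = 1, B = 0, X = 0), lv2), 1)
  expect_equal(next_value(e, c(A = 0, B = 1, X = 1), lv2), 0)
  expect_equal(next_value(e, c(A = 1, B = 1, X = 1), lv2), 1)

  # graded step with increment clamping
  e3 <- list(variable = "X", levels = 3L, constant = FALSE,
             spontaneous = "none", increment = 1L, positive_rule = "S")
  lv3 <- c(S = 3, X = 3)
  expect_equal(next_value(e3, c(S = 2, X = 0), lv3), 1)
  expect_equal(next_value(e3, c(S = 2, X = 2), lv3), 2)
  e3$increment <- 2L
  expect_equal(next_value(e3, c(S = 1, X = 1), lv3), 2)

  # constant elements never move
  ec <- elem(constant = TRUE, positive_rule = "A")
  expect_equal(next_value(ec, c(A = 1, X = 0), lv2), 0)
})

test_that("negative-only + spontaneous increase is Boolean NOT; max is OR", {
  lvB <- c(A = 2, B = 2, X = 2)
  e_not <- list(variable = "X", levels = 2L, constant = FALSE,
                spontaneous = "increase", increment = 1L,
                negative_rule = "B")
  for (x in 0:1) for (b in 0:1) {
    expect_equal(next_value(e_not, c(B = b, X = x), lvB), 1 - b,
                 info = sprintf("x=%d b=%d", x, b))
  }

  e_or <- list(variable = "X", levels = 2L, constant = FALSE,
               spontaneous = "decrease", increment = 1L,
               positive_rule = "A, B")
  for (a in 0:1) for (b in 0:1) for (x in 0:1) {
    expect_equal(next_value(e_or, c(A = a, B = b, X = x), lvB),
                 as.integer(a | b), info = sprintf("a=%d b=%d x=%d", a, b, x))
  }
})

test_that("next_value always stays within [0, L-1]", {
  for (L in 2:4) for (d in 1:3) for (x in 0:(L - 1)) {
    for (sp in c("none", "increase", "decrease")) {
      for (p in list(NULL, "A")) for (n in list(NULL, "B")) {
        e <- list(variable = "X", levels = L, constant = FALSE,
                  spontaneous = sp, increment = d)
        e$positive_rule <- if (!is.null(p)) p else NA_character_
        e$negative_rule <- if (!is.null(n)) n else NA_character_
        for (a in 0:1) for (b in 0:1) {
          v <- next_value(e, c(A = a, B = b, X = x),
                          c(A = 2, B = 2, X = L))
          expect_true(v >= 0 && v <= L - 1)
        }
      }
    }
  }
})
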