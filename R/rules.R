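# The discrete update-rule notation: parser, canonical serializer, evaluator,
# and the per-element next-level function.
#
# Grammar (whitespace-insensitive):
#   rule  := list
#   list  := term (',' term)*          combinator given by context:
#                                      top level = max, '(...)' = min,
#                                      'min|max|sum(...)' = that function
#   term  := INT '*' atom | atom       weight, positive integer, leaves only
#   atom  := '!' atom                  complement (leaves only)
#          | VAR '^'                   highest-level indicator
#          | VAR
#          | ('min'|'max'|'sum') '(' list ')'
#          | '(' list ')'
#
# A leaf cannot be both complemented and highest-level.

rule_leaf <- function(var, weight = 1L, complemented = FALSE,
                      highest = FALSE) {
  structure(list(kind = "leaf", var = var, weight = as.integer(weight),
                 complemented = complemented, highest = highest),
            class = "biorecipe_rule")
}

rule_op <- function(op, children) {
  stopifnot(op %in% c("min", "max", "sum"), length(children) >= 1)
  structure(list(kind = "op", op = op, children = children),
            class = "biorecipe_rule")
}

tokenize_rule <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c(",", "(", ")", "!", "*", "^")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(m) == 1 && nzchar(m)) {
      tokens[[length(tokens) + 1L]] <- list(type = "INT", value = m, pos = i)
      i <- i + nchar(m)
      next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m) == 1 && nzchar(m)) {
      tokens[[length(tokens) + 1L]] <- list(type = "NAME", value = m, pos = i)
      i <- i + nchar(m)
      next
    }
    stop(sprintf("unexpected character '%s' at position %d", ch, i),
         call. = FALSE)
  }
  tokens
}

#' Parse an update-rule expression
#'
#' Parses the rule notation used inside the `Positive Regulation Rule` and
#' `Negative Regulation Rule` cells of an executable model. A top-level
#' comma list means `max` (any active regulator suffices), a bare
#' parenthesized list means `min` (all regulators required), and
#' `min(...)`, `max(...)`, `sum(...)` are explicit. `!X` is the multi-level
#' complement of `X`, `X^` is 1 only when `X` sits at its highest level,
#' and `k*X` weights a leaf by the positive integer `k` (typically inside
#' `sum`).
#'
#' @param text Rule text, e.g. `"2*A, (B, !C)"`.
#' @return A `biorecipe_rule` AST (nested lists with `kind` `"leaf"`/`"op"`).
#' @export
#' @examples
#' ast <- parse_rule("sum(A, 3*B^)")
#' serialize_rule(ast)
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  tokens <- tokenize_rule(text)
  if (length(tokens) == 0) stop("empty rule", call. = FALSE)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    tok <- peek()
    if (is.null(tok) || tok$type != type) {
      at <- if (is.null(tok)) "end of input"
            else sprintf("'%s' at position %d", tok$value, tok$pos)
      stop(sprintf("expected '%s', found %s", type, at), call. = FALSE)
    }
    advance()
  }

  parse_list <- function() {
    items <- list(parse_term())
    while (!is.null(peek()) && peek()$type == ",") {
      advance()
      items[[length(items) + 1L]] <- parse_term()
    }
    items
  }

  parse_term <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "INT") {
      weight <- as.integer(advance()$value)
      if (weight == 0)
        stop(sprintf("weight 0 at position %d (weights must be >= 1)",
                     tok$pos), call. = FALSE)
      expect("*")
      atom <- parse_atom()
      if (atom$kind != "leaf")
        stop(sprintf("weight at position %d must precede a variable", tok$pos),
             call. = FALSE)
      atom$weight <- atom$weight * weight
      return(atom)
    }
    parse_atom()
  }

  parse_atom <- function() {
    tok <- peek()
    if (is.null(tok)) stop("unexpected end of rule", call. = FALSE)
    if (tok$type == "!") {
      advance()
      inner <- parse_atom()
      if (inner$kind != "leaf" || inner$highest)
        stop(sprintf(
          "'!' at position %d applies only to plain variables", tok$pos),
          call. = FALSE)
      inner$complemented <- !inner$complemented
      return(inner)
    }
    if (tok$type == "NAME") {
      advance()
      if (tok$value %in% c("min", "max", "sum") &&
          !is.null(peek()) && peek()$type == "(") {
        advance()
        children <- parse_list()
        expect(")")
        return(rule_op(tok$value, children))
      }
      highest <- FALSE
      if (!is.null(peek()) && peek()$type == "^") { advance(); highest <- TRUE }
      return(rule_leaf(tok$value, highest = highest))
    }
    if (tok$type == "(") {
      advance()
      children <- parse_list()
      expect(")")
      if (length(children) == 1) return(children[[1]])
      return(rule_op("min", children))
    }
    stop(sprintf("unexpected '%s' at position %d", tok$value, tok$pos),
         call. = FALSE)
  }

  items <- parse_list()
  if (pos <= length(tokens)) {
    tok <- tokens[[pos]]
    stop(sprintf("unexpected '%s' at position %d", tok$value, tok$pos),
         call. = FALSE)
  }
  if (length(items) == 1) items[[1]] else rule_op("max", items)
}

#' Serialize a rule AST to canonical text
#'
#' Produces the minimal-parenthesization canonical form:
#' a top-level `max` prints as a bare comma list, `min` as `(...)`
#' (or `min(...)` when it has one child), `sum` always as `sum(...)`.
#' `parse_rule(serialize_rule(ast))` reproduces `ast` exactly.
#'
#' @param ast A `biorecipe_rule`.
#' @return Rule text.
#' @export
serialize_rule <- function(ast) {
  render <- function(node, top) {
    if (node$kind == "leaf") {
      paste0(if (node$weight != 1) paste0(node$weight, "*"),
             if (node$complemented) "!", node$var,
             if (node$highest) "^")
    } else {
      args <- paste(vapply(node$children, render, "", top = FALSE),
                    collapse = ", ")
      if (node$op == "max") {
        if (top && length(node$children) > 1) args
        else paste0("max(", args, ")")
      } else if (node$op == "min") {
        if (length(node$children) > 1) paste0("(", args, ")")
        else paste0("min(", args, ")")
      } else {
        paste0("sum(", args, ")")
      }
    }
  }
  render(ast, top = TRUE)
}

#' Variables referenced by a rule
#'
#' @param ast A `biorecipe_rule`.
#' @return Character vector of distinct variable tokens, in first-appearance
#'   order.
#' @export
rule_variables <- function(ast) {
  if (ast$kind == "leaf") return(ast$var)
  unique(unlist(lapply(ast$children, rule_variables)))
}

#' Evaluate a rule against a state
#'
#' Leaf value is the variable's current level; a complemented leaf `!X`
#' evaluates to `(levels(X) - 1) - X`; a highest-level leaf `X^` to 1 when
#' `X` is at its top level and 0 otherwise; a weight multiplies the leaf
#' value. Combinators apply `min`, `max` or `sum` over their children.
#'
#' @param ast A `biorecipe_rule`.
#' @param state Named integer vector/list: variable -> current level.
#' @param levels_of Named integer vector/list: variable -> number of levels
#'   (needed for `!` and `^` leaves).
#' @return Non-negative integer.
#' @export
#' @examples
#' evaluate_rule(parse_rule("sum(2*A, B^)"),
#'               state = c(A = 1, B = 2), levels_of = c(A = 2, B = 3))
evaluate_rule <- function(ast, state, levels_of) {
  if (ast$kind == "leaf") {
    i <- match(ast$var, names(state))
    if (is.na(i) || is.na(state[[i]]))
      stop(sprintf("unresolved variable '%s'", ast$var), call. = FALSE)
    v <- as.integer(state[[i]])
    if (ast$complemented || ast$highest) {
      j <- match(ast$var, names(levels_of))
      L <- if (is.na(j)) NA else levels_of[[j]]
      if (is.na(L))
        stop(sprintf("levels unknown for variable '%s'", ast$var),
             call. = FALSE)
      if (ast$complemented) v <- (as.integer(L) - 1L) - v
      else v <- as.integer(v == as.integer(L) - 1L)
    }
    return(ast$weight * v)
  }
  vals <- vapply(ast$children, evaluate_rule, integer(1),
                 state = state, levels_of = levels_of)
  switch(ast$op, min = min(vals), max = max(vals), sum = sum(vals))
}

#' Next level of an element
#'
#' Computes one update of an element from the current state. With current
#' level `x`, `L` levels and increment `d`:
#' a constant element keeps `x`. Otherwise let `P`/`N` be the values of the
#' positive/negative regulation rules when present. With both rules:
#' `P > N` steps up, `P < N` steps down, a tie holds. With only a positive
#' rule: `P > 0` steps up; `P = 0` steps down when `spontaneous = "decrease"`,
#' else holds. With only a negative rule: `N > 0` steps down; `N = 0` steps up
#' when `spontaneous = "increase"`, else holds. With no rules, the element
#' drifts according to `spontaneous`. Steps are `x + d` / `x - d`, clamped
#' to `[0, L - 1]`.
#'
#' @param element One element row as a list/one-row tibble with fields
#'   `variable`, `levels`, `constant`, `spontaneous`, `increment`, and either
#'   rule texts (`positive_rule`, `negative_rule`) or pre-parsed ASTs
#'   (`positive_ast`, `negative_ast`).
#' @param state Named integer vector: variable -> current level (must include
#'   the element itself and all its regulators).
#' @param levels_of Named integer vector: variable -> number of levels.
#' @return Integer in `[0, L - 1]`.
#' @export
next_value <- function(element, state, levels_of) {
  x <- as.integer(state[[element$variable]])
  if (isTRUE(element$constant)) return(x)
  L <- as.integer(element$levels)
  d <- as.integer(element$increment %||% 1L)
  up <- function() min(x + d, L - 1L)
  down <- function() max(x - d, 0L)

  get_ast <- function(which) {
    ast <- element[[paste0(which, "_ast")]]
    if (!is.null(ast)) {
      if (is.list(ast) && !inherits(ast, "biorecipe_rule")) ast <- ast[[1]]
      if (inherits(ast, "biorecipe_rule")) return(ast)
    }
    txt <- element[[paste0(which, "_rule")]]
    if (is.null(txt) || is.na(txt)) return(NULL)
    parse_rule(txt)
  }
  pos <- get_ast("positive")
  neg <- get_ast("negative")
  sp <- element$spontaneous %||% "none"

  if (!is.null(pos) && !is.null(neg)) {
    P <- evaluate_rule(pos, state, levels_of)
    N <- evaluate_rule(neg, state, levels_of)
    if (P > N) return(up())
    if (P < N) return(down())
    return(x)
  }
  if (!is.null(pos)) {
    P <- evaluate_rule(pos, state, levels_of)
    if (P > 0) return(up())
    if (identical(sp, "decrease")) return(down())
    return(x)
  }
  if (!is.null(neg)) {
    N <- evaluate_rule(neg, state, levels_of)
    if (N > 0) return(down())
    if (identical(sp, "increase")) return(up())
    return(x)
  }
  switch(sp, increase = up(), decrease = down(), x)
}
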