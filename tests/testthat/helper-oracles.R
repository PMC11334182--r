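# Independent oracles and small generators used across the suite. These are
# deliberately written from first principles, without reusing the package's
# evaluation or enumeration code paths.

# Naive recursive rule evaluator: the reference for evaluate_rule().
oracle_eval <- function(node, state, levels_of) {
  if (node$kind == "leaf") {
    x <- state[[node$var]]
    top <- levels_of[[node$var]] - 1
    val <- x
    if (node$complemented) val <- top - x
    if (node$highest) val <- if (x == top) 1 else 0
    return(node$weight * val)
  }
  vals <- sapply(node$children, oracle_eval, state = state,
                 levels_of = levels_of)
  if (node$op == "min") return(min(vals))
  if (node$op == "max") return(max(vals))
  sum(vals)
}

# Independent random AST generator over the full grammar.
gen_ast <- function(vars, max_depth = 3) {
  if (max_depth == 0 || runif(1) < 0.45) {
    style <- sample(4, 1)
    leaf <- list(kind = "leaf", var = sample(vars, 1), weight = 1L,
                 complemented = FALSE, highest = FALSE)
    if (style == 2) leaf$weight <- sample(2:5, 1)
    if (style == 3) leaf$complemented <- TRUE
    if (style == 4) leaf$highest <- TRUE
    class(leaf) <- "biorecipe_rule"
    return(leaf)
  }
  node <- list(kind = "op", op = sample(c("min", "max", "sum"), 1),
               children = lapply(seq_len(sample(1:3, 1)), function(i) {
                 gen_ast(vars, max_depth - 1)
               }))
  class(node) <- "biorecipe_rule"
  node
}

# Brute-force attractor enumeration of an explicitly given Boolean successor
# function, independent of find_attractors(). `succ` maps a 0/1 vector to the
# next 0/1 vector; returns list of cycles (each a matrix, canonical rotation)
# and basin sizes keyed by cycle.
oracle_attractors <- function(n_vars, succ) {
  states <- as.matrix(expand.grid(rep(list(0:1), n_vars)))
  key <- function(v) paste(v, collapse = ",")
  keys <- apply(states, 1, key)
  next_key <- vapply(seq_len(nrow(states)), function(i) {
    key(succ(as.integer(states[i, ])))
  }, "")
  succ_idx <- match(next_key, keys)
  target <- integer(nrow(states))   # attractor id reached from each state
  cycles <- list()
  for (s in seq_len(nrow(states))) {
    path <- integer(0)
    cur <- s
    while (target[cur] == 0 && !(cur %in% path)) {
      path <- c(path, cur)
      cur <- succ_idx[cur]
    }
    if (target[cur] != 0) {
      aid <- target[cur]
    } else {
      cyc <- path[which(path == cur):length(path)]
      cycles[[length(cycles) + 1]] <- cyc
      aid <- length(cycles)
    }
    target[path] <- aid
  }
  list(cycles = lapply(cycles, function(cyc) states[cyc, , drop = FALSE]),
       basins = tabulate(target, nbins = length(cycles)))
}

# Sorted signed edge set by plain names, for conservation checks.
edge_key <- function(edges) {
  sort(paste(edges$source, edges$target, edges$sign, sep = "|"))
}

expect_no_issues <- function(issues) {
  expect_equal(nrow(issues), 0, info = paste(issues$message, collapse = "; "))
}
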