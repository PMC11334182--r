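# Discrete simulation of executable models: synchronous (deterministic) and
# random-asynchronous (stochastic) schemes, exhaustive attractor enumeration
# for small state spaces, and trajectory summaries.

# Pre-compiles a model into the pieces the stepping kernel needs.
compile_model <- function(model, scenario) {
  issues <- validate_model(model)
  if (has_errors(issues)) {
    rlang::abort(c("model has validation errors; cannot simulate",
                   utils::head(issues$message[issues$severity == "error"], 5)))
  }
  el <- model$elements
  if (scenario < 1 || scenario > model$scenario_count) {
    rlang::abort(sprintf("scenario must be in 1..%d (got %s)",
                         model$scenario_count, as.character(scenario)))
  }
  parse_or_null <- function(txt) if (is.na(txt)) NULL else parse_rule(txt)
  elements <- lapply(seq_len(nrow(el)), function(i) {
    list(variable = el$variable[i], levels = el$levels[i],
         constant = el$constant[i], spontaneous = el$spontaneous[i],
         increment = el$increment[i], update_rate = el$update_rate[i],
         positive_ast = parse_or_null(el$positive_rule[i]),
         negative_ast = parse_or_null(el$negative_rule[i]))
  })
  init <- vapply(el$initial_values, function(iv) {
    if (scenario <= length(iv)) iv[scenario] else iv[length(iv)]
  }, integer(1))
  list(elements = elements, variables = el$variable,
       levels_of = stats::setNames(el$levels, el$variable),
       init = stats::setNames(init, el$variable))
}

sync_step <- function(cm, state, t) {
  new <- state
  for (e in cm$elements) {
    if (e$constant) next
    if (t %% e$update_rate != 0) next
    new[[e$variable]] <- next_value(e, state, cm$levels_of)
  }
  new
}

#' Simulate an executable model
#'
#' Under the synchronous (deterministic) scheme, every non-constant element
#' whose `update_rate` divides the step number is updated simultaneously
#' from the previous state; exactly one trajectory is returned. Under the
#' random-asynchronous (stochastic) scheme, one non-constant element is
#' chosen per step with probability proportional to `1 / update_rate` and
#' updated in place; `runs` independent trajectories are produced with seeds
#' `seed`, `seed + 1`, ... Identical inputs and seeds give identical output.
#'
#' @param model A valid `biorecipe_model`.
#' @param scheme `"synchronous"` or `"random_asynchronous"`.
#' @param steps Number of update steps (trajectories have `steps + 1` rows).
#' @param runs Number of independent trajectories (asynchronous only).
#' @param seed Integer seed; required for the asynchronous scheme.
#' @param scenario 1-based initial-value scenario index.
#' @return List of trajectories; each is a `biorecipe_trajectory` with
#'   fields `variables`, `states` ((steps+1) x n integer matrix, row 0 = the
#'   scenario's initial state), `scheme`, `seed`, `scenario`.
#' @export
#' @examples
#' tr <- simulate_model(motif("toggle"), steps = 4)[[1]]
#' tr$states
simulate_model <- function(model,
                           scheme = c("synchronous", "random_asynchronous"),
                           steps = 10, runs = 1, seed = NULL, scenario = 1) {
  scheme <- match.arg(scheme)
  stopifnot(steps >= 1, runs >= 1)
  cm <- compile_model(model, scenario)
  n <- length(cm$variables)

  make_traj <- function(states, run_seed) {
    dimnames(states) <- list(step = 0:steps, cm$variables)
    structure(list(variables = cm$variables, states = states,
                   scheme = scheme, seed = run_seed, scenario = scenario),
              class = "biorecipe_trajectory")
  }

  if (scheme == "synchronous") {
    states <- matrix(0L, nrow = steps + 1, ncol = n)
    state <- cm$init
    states[1, ] <- state
    for (t in seq_len(steps)) {
      state <- sync_step(cm, state, t)
      states[t + 1, ] <- state
    }
    return(list(make_traj(states, seed)))
  }

  if (is.null(seed)) {
    rlang::abort("the random_asynchronous scheme requires a seed")
  }
  eligible <- which(!vapply(cm$elements, `[[`, logical(1), "constant"))
  if (length(eligible) == 0) {
    rlang::abort("no non-constant elements to update asynchronously")
  }
  weights <- 1 / vapply(cm$elements[eligible], `[[`, integer(1), "update_rate")
  lapply(seq_len(runs), function(r) {
    run_seed <- as.integer(seed) + r - 1L
    states <- local_seed(run_seed, {
      m <- matrix(0L, nrow = steps + 1, ncol = n)
      state <- cm$init
      m[1, ] <- state
      for (t in seq_len(steps)) {
        pick <- eligible[sample.int(length(eligible), 1, prob = weights)]
        e <- cm$elements[[pick]]
        state[[e$variable]] <- next_value(e, state, cm$levels_of)
        m[t + 1, ] <- state
      }
      m
    })
    make_traj(states, run_seed)
  })
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Trajectory as a tibble
#'
#' @param trajectory A `biorecipe_trajectory`.
#' @return Tibble with a `step` column (0-based) and one column per variable.
#' @export
trajectory_table <- function(trajectory) {
  stopifnot(inherits(trajectory, "biorecipe_trajectory"))
  tibble::as_tibble(cbind(
    tibble::tibble(step = 0:(nrow(trajectory$states) - 1)),
    tibble::as_tibble(trajectory$states, .name_repair = "minimal")))
}

#' @export
print.biorecipe_trajectory <- function(x, ...) {
  cat(sprintf("<BioRECIPE trajectory: %s scheme, %d steps, %d variable(s)%s>\n",
              x$scheme, nrow(x$states) - 1, length(x$variables),
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  print(utils::head(trajectory_table(x), 11), ...)
  invisible(x)
}

#' Summarize trajectories across runs
#'
#' @param trajectories List of `biorecipe_trajectory` objects over the same
#'   variables and horizon (as returned by [simulate_model()]).
#' @return Tibble `step`, `variable`, `mean`, `sd` (sd is 0 for a single
#'   run).
#' @export
summarize_trajectories <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  vars <- trajectories[[1]]$variables
  steps <- nrow(trajectories[[1]]$states)
  arr <- vapply(trajectories, function(tr) tr$states,
                matrix(0L, steps, length(vars)))
  rows <- lapply(seq_along(vars), function(j) {
    slab <- matrix(arr[, j, ], nrow = steps)
    tibble::tibble(
      step = 0:(steps - 1), variable = vars[j],
      mean = rowMeans(slab),
      sd = if (ncol(slab) == 1) rep(0, steps) else apply(slab, 1, stats::sd))
  })
  out <- do.call(rbind, rows)
  out[order(out$step, match(out$variable, vars)), ]
}

# ---- Attractor enumeration --------------------------------------------------

#' Enumerate attractors of the synchronous map
#'
#' Builds the exhaustive synchronous state-transition map (every non-constant
#' element updates at every step; update rates are ignored, with a warning if
#' any differ from 1) and returns all recurrent cycles with their basin
#' sizes. Basins partition the state space, so basin sizes sum to the total
#' number of states.
#'
#' @param model A valid `biorecipe_model`.
#' @param max_states Refuse models whose state-space size (product of levels)
#'   exceeds this bound (default `2^20`).
#' @return List of attractors; each has `states` (period x n integer matrix),
#'   `period` and `basin_size`. Ordered by their lexicographically smallest
#'   state, which is also each cycle's first row.
#' @export
#' @examples
#' length(find_attractors(motif("toggle")))
find_attractors <- function(model, max_states = 2^20) {
  cm <- compile_model(model, scenario = 1)
  n <- length(cm$variables)
  L <- as.integer(cm$levels_of)
  total <- prod(as.numeric(L))
  if (total > max_states) {
    rlang::abort(sprintf(
      "state space has %.0f states (> %.0f); sample trajectories instead",
      total, max_states))
  }
  if (any(vapply(cm$elements, `[[`, integer(1), "update_rate") != 1)) {
    rlang::warn("update rates ignored in attractor enumeration (synchronous map)")
    cm$elements <- lapply(cm$elements, function(e) {
      e$update_rate <- 1L
      e
    })
  }
  total <- as.integer(total)

  # mixed-radix encoding, first variable = least significant digit
  radix <- c(1L, cumprod(L)[-n])
  decode <- function(idx) {
    idx <- idx - 1L
    v <- integer(n)
    for (j in seq_len(n)) {
      v[j] <- (idx %/% radix[j]) %% L[j]
    }
    v
  }
  encode <- function(v) as.integer(sum(v * radix)) + 1L

  succ <- integer(total)
  for (idx in seq_len(total)) {
    state <- stats::setNames(decode(idx), cm$variables)
    succ[idx] <- encode(sync_step(cm, state, t = 1L))
  }

  # functional-graph cycle detection with path coloring
  attractor_of <- integer(total)      # 0 = unassigned
  onpath <- integer(total)            # position on current path, 0 = no
  cycles <- list()
  for (start in seq_len(total)) {
    if (attractor_of[start] != 0) next
    path <- integer(0)
    cur <- start
    while (attractor_of[cur] == 0 && onpath[cur] == 0) {
      path <- c(path, cur)
      onpath[cur] <- length(path)
      cur <- succ[cur]
    }
    if (attractor_of[cur] != 0) {
      aid <- attractor_of[cur]
    } else {
      cyc <- path[onpath[cur]:length(path)]
      # canonical rotation: lexicographically smallest state first
      lexkey <- vapply(cyc, function(idx) {
        paste(sprintf("%04d", decode(idx)), collapse = ",")
      }, "")
      shift <- which(lexkey == min(lexkey))[1]
      cyc <- c(cyc[shift:length(cyc)], cyc[seq_len(shift - 1)])
      cycles[[length(cycles) + 1L]] <- cyc
      aid <- length(cycles)
    }
    attractor_of[path] <- aid
    onpath[path] <- 0L
  }

  basin <- tabulate(attractor_of, nbins = length(cycles))
  out <- lapply(seq_along(cycles), function(a) {
    states <- do.call(rbind, lapply(cycles[[a]], decode))
    colnames(states) <- cm$variables
    structure(list(states = states, period = length(cycles[[a]]),
                   basin_size = basin[a]),
              class = "biorecipe_attractor")
  })
  ord <- order(vapply(out, function(a) {
    paste(sprintf("%04d", a$states[1, ]), collapse = ",")
  }, ""))
  out[ord]
}

#' @export
print.biorecipe_attractor <- function(x, ...) {
  kind <- if (x$period == 1) "fixed point" else sprintf("%d-cycle", x$period)
  cat(sprintf("<attractor: %s, basin %d>\n", kind, x$basin_size))
  print(x$states)
  invisible(x)
}
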