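test_that("the toggle switch holds its fixed point synchronously", {
  tr <- simulate_model(motif("toggle"), steps = 6, scenario = 2)[[1]]
  expect_true(all(tr$states[, "A"] == 0))
  expect_true(all(tr$states[, "B"] == 1))
})

test_that("the repressilator cycles with period 6 from (1,0,0)", {
  tr <- simulate_model(motif("repressilator"), steps = 12)[[1]]
  expect_equal(unname(tr$states[1, ]), c(1, 0, 0))
  expect_equal(tr$states[7, ], tr$states[1, ])
  expect_equal(tr$states[13, ], tr$states[1, ])
  # no return before period 6
  for (t in 2:6) expect_false(all(tr$states[t, ] == tr$states[1, ]))
})

test_that("constant elements never change under any scheme", {
  m <- executable_model(tibble::tibble(
    element_name = c("A", "B"), variable = c("A", "B"),
    constant = c(TRUE, TRUE), initial_values = list(1L, 0L)))
  tr <- simulate_model(m, steps = 1)[[1]]
  expect_equal(tr$states[2, ], tr$states[1, ])
})

test_that("one synchronous step equals element-wise next_value", {
  for (seed in 1:10) {
    m <- random_model(5, levels = 3, seed = seed)
    tr <- simulate_model(m, steps = 1)[[1]]
    state0 <- stats::setNames(tr$states[1, ], m$elements$variable)
    levels_of <- stats::setNames(m$elements$levels, m$elements$variable)
    expected <- vapply(seq_len(nrow(m$elements)), function(i) {
      next_value(as.list(m$elements[i, ]), state0, levels_of)
    }, 0L)
    expect_equal(unname(tr$states[2, ]), expected)
  }
})

test_that("simulated levels always stay within range", {
  for (seed in 1:8) {
    m <- random_model(4, levels = sample(2:4, 1), seed = seed)
    L <- m$elements$levels
    tr <- simulate_model(m, steps = 15)[[1]]
    for (j in seq_along(L)) {
      expect_true(all(tr$states[, j] >= 0 & tr$states[, j] <= L[j] - 1))
    }
    tra <- simulate_model(m, "random_asynchronous", steps = 30, runs = 2,
                          seed = seed)
    for (t in tra) for (j in seq_along(L)) {
      expect_true(all(t$states[, j] >= 0 & t$states[, j] <= L[j] - 1))
    }
  }
})

test_that("update rates gate synchronous updates modularly", {
  m <- executable_model(tibble::tibble(
    element_name = c("fast", "slow"), variable = c("fast", "slow"),
    spontaneous = "increase", levels = 5L,
    update_rate = c(1L, 2L), initial_values = list(0L, 0L)))
  tr <- simulate_model(m, steps = 4)[[1]]
  expect_equal(unname(tr$states[, "fast"]), 0:4)
  expect_equal(unname(tr$states[, "slow"]), c(0, 0, 1, 1, 2))
})

test_that("asynchronous runs are reproducible and scenario-indexed", {
  m <- motif("toggle")
  a <- simulate_model(m, "random_asynchronous", steps = 25, runs = 4, seed = 99)
  b <- simulate_model(m, "random_asynchronous", steps = 25, runs = 4, seed = 99)
  expect_identical(lapply(a, `[[`, "states"), lapply(b, `[[`, "states"))
  expect_equal(vapply(a, `[[`, 0L, "seed"), 99:102)
  expect_error(simulate_model(m, "random_asynchronous", steps = 5),
               "seed")
  expect_error(simulate_model(m, steps = 5, scenario = 3), "scenario")
})

test_that("asynchronous toggle runs absorb into the two fixed points", {
  runs <- 60
  trs <- simulate_model(motif("toggle"), "random_asynchronous", steps = 40,
                        runs = runs, seed = 17, scenario = 1)
  finals <- t(vapply(trs, function(tr) tr$states[41, ], c(A = 0L, B = 0L)))
  absorbed <- (finals[, "A"] == 1 & finals[, "B"] == 0) |
    (finals[, "A"] == 0 & finals[, "B"] == 1)
  expect_true(all(absorbed))
})

test_that("attractor enumeration matches brute force on the toggle switch", {
  atts <- find_attractors(motif("toggle"))
  expect_equal(length(atts), 3)
  expect_equal(sum(vapply(atts, `[[`, 0L, "basin_size")), 4)
  periods <- vapply(atts, `[[`, 0L, "period")
  fixed <- lapply(atts[periods == 1], function(a) unname(a$states[1, ]))
  expect_setequal(lapply(fixed, paste, collapse = ","), list("0,1", "1,0"))
  cyc <- atts[[which(periods == 2)]]
  expect_equal(sort(apply(cyc$states, 1, paste, collapse = ",")),
               c("0,0", "1,1"))

  # independent oracle: successor map written down directly
  oracle <- oracle_attractors(2, function(s) c(1L - s[2], 1L - s[1]))
  expect_equal(sort(oracle$basins),
               sort(vapply(atts, `[[`, 0L, "basin_size")))
  expect_equal(length(oracle$cycles), length(atts))
})

test_that("attractor enumeration matches brute force on the repressilator", {
  atts <- find_attractors(motif("repressilator"))
  periods <- sort(vapply(atts, `[[`, 0L, "period"))
  expect_equal(periods, c(2, 6))
  expect_equal(sum(vapply(atts, `[[`, 0L, "basin_size")), 8)

  oracle <- oracle_attractors(
    3, function(s) c(1L - s[3], 1L - s[1], 1L - s[2]))
  expect_equal(sort(vapply(oracle$cycles, nrow, 0L)), c(2, 6))
  expect_equal(sort(oracle$basins),
               sort(vapply(atts, `[[`, 0L, "basin_size")))
})

test_that("an all-constant model makes every state a fixed point", {
  m <- executable_model(tibble::tibble(
    element_name = c("A", "B"), variable = c("A", "B"),
    constant = TRUE, initial_values = list(0L, 0L)))
  atts <- find_attractors(m)
  expect_equal(length(atts), 4)
  expect_true(all(vapply(atts, `[[`, 0L, "period") == 1))
  expect_true(all(vapply(atts, `[[`, 0L, "basin_size") == 1))
})

test_that("trajectory summaries average across runs", {
  tr <- simulate_model(motif("toggle"), steps = 3, scenario = 2)
  s <- summarize_trajectories(tr)
  expect_equal(s$sd, rep(0, nrow(s)))
  expect_equal(s$mean[s$variable == "B"], rep(1, 4))

  # two mirrored deterministic trajectories average to 0.5
  t1 <- simulate_model(motif("toggle"), steps = 3, scenario = 2)[[1]]
  t2 <- t1
  t2$states <- t1$states[, c(2, 1)]
  colnames(t2$states) <- colnames(t1$states)
  s2 <- summarize_trajectories(list(t1, t2))
  expect_true(all(s2$mean == 0.5))
})

test_that("oversized state spaces are refused with advice", {
  m <- random_model(8, levels = 4, seed = 1)
  expect_error(find_attractors(m, max_states = 100), "sample")
})
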