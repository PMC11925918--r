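# Transition estimation, Markov projection, suitability and CA allocation.

test_that("estimate_transition row-normalizes the cross-tabulation", {
  a <- classmap_from(matrix(c(1, 1, 1, 1, 2, 2), 2, 3))
  b <- classmap_from(matrix(c(1, 1, 2, 2, 2, 2), 2, 3))
  model <- estimate_transition(a, b)
  expect_equal(unname(model$P[1, 1:2]), c(0.5, 0.5))
  expect_equal(unname(model$P[2, 2]), 1)
  # absent classes stay themselves (identity rows)
  expect_equal(unname(diag(model$P)[3:5]), rep(1, 3))
  expect_equal(unname(rowSums(model$P)), rep(1, 5))

  same <- estimate_transition(a, a)
  expect_equal(unname(same$P), diag(5))
})

test_that("transition-estimation error shrinks like a sampling error in n", {
  P <- matrix(c(0.85, 0.10, 0.05,
                0.15, 0.80, 0.05,
                0.05, 0.10, 0.85), 3, 3, byrow = TRUE)
  err <- sapply(c(50, 100, 200), function(side) {
    set.seed(31)
    init <- hr_grid(matrix(sample(1:3, side^2, TRUE) * 1.0, side, side))
    ser <- gen_markov_series(P, init, 1, seed = 31)
    est <- estimate_transition(as_classmap(init, levels = letters[1:3]),
                               as_classmap(ser[[1]], levels = letters[1:3]))
    max(abs(est$P - P))
  })
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1])          # larger maps estimate P better
})

test_that("project_markov conserves area and composes over steps", {
  areas <- c(100, 50, 25, 10, 5)
  expect_equal(unname(project_markov(areas, diag(5), steps = 7)), areas)

  q <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  rank1 <- matrix(q, 5, 5, byrow = TRUE)
  expect_equal(unname(project_markov(areas, rank1, 1)), sum(areas) * q)

  set.seed(32)
  P <- matrix(runif(25), 5, 5)
  P <- P / rowSums(P)
  two <- project_markov(areas, P, steps = 2)
  stepwise <- project_markov(project_markov(areas, P, 1), P, 1)
  expect_equal(two, stepwise, tolerance = 1e-12)
  expect_equal(sum(two), sum(areas), tolerance = 1e-9)
  expect_error(project_markov(c(-1, 1, 1, 1, 1), P), "nonnegative")
})

test_that("suitability surfaces are window class fractions partitioning to 1", {
  uniform <- classmap_from(matrix(2, 10, 10))
  atlas <- build_suitability(uniform, 5)
  expect_true(all(atlas$surfaces[["low"]]$values == 1))
  expect_true(all(atlas$surfaces[["high"]]$values == 0))

  field <- matrix(3, 11, 11)
  field[6, 6] <- 1                      # isolated cell in a field of class 3
  atlas2 <- build_suitability(classmap_from(field), 5)
  expect_equal(atlas2$surfaces[["lowest"]]$values[6, 6], 1 / 25)
  expect_equal(atlas2$surfaces[["medium"]]$values[6, 6], 24 / 25)
  # truncated corner window: 3x3 = 9 cells
  expect_equal(atlas2$surfaces[["medium"]]$values[1, 1], 1)

  set.seed(33)
  m <- matrix(sample(1:5, 144, TRUE), 12, 12)
  m[sample(144, 20)] <- NA
  atlas3 <- build_suitability(classmap_from(m), 5)
  total <- Reduce(`+`, lapply(atlas3$surfaces, function(g) g$values))
  expect_equal(total[!is.na(m)], rep(1, sum(!is.na(m))))
  expect_error(build_suitability(classmap_from(m), 4), "odd")
})

test_that("simulate_ca_markov honours degenerate demands exactly", {
  set.seed(34)
  base <- classmap_from(matrix(sample(1:5, 400, TRUE), 20, 20))
  ident <- estimate_transition(base, base)
  out <- simulate_ca_markov(base, ident, simulation_config(seed = 2))
  expect_identical(out$classes$values, base$classes$values)

  all1 <- classmap_from(matrix(1, 12, 12))
  forced <- ident
  forced$P[1, ] <- c(0, 1, 0, 0, 0)
  out2 <- simulate_ca_markov(all1, forced,
                             simulation_config(iterations = 1, seed = 2))
  expect_true(all(out2$classes$values == 2))
})

test_that("simulation is deterministic, conserves cells, and meets Markov demand", {
  s <- coherent_series(404, shape = c(64, 64), steps = 1)
  model <- estimate_transition(s$maps[[1]], s$maps[[2]])
  cfg <- simulation_config(iterations = 10, seed = 9)
  out1 <- simulate_ca_markov(s$maps[[2]], model, cfg)
  out2 <- simulate_ca_markov(s$maps[[2]], model, cfg)
  expect_identical(out1$classes$values, out2$classes$values)

  v_base <- s$maps[[2]]$classes$values
  v_out <- out1$classes$values
  expect_identical(is.na(v_out), is.na(v_base))    # masked cells never change
  n <- sum(!is.na(v_base))
  counts_base <- sapply(1:5, function(k) sum(v_base == k, na.rm = TRUE))
  demand <- project_markov(counts_base, model, 1)
  counts_out <- sapply(1:5, function(k) sum(v_out == k, na.rm = TRUE))
  expect_true(all(abs(counts_out - demand) <= 0.005 * n + 1))
})

test_that("allocation is spatially coherent relative to a random allocation", {
  mean_suit <- function(map, ref_atlas) {
    v <- map$classes$values
    ok <- !is.na(v)
    s <- sapply(which(ok), function(i)
      ref_atlas$surfaces[[v[i]]]$values[i])
    mean(s)
  }
  wins <- 0L
  for (r in 1:10) {
    s <- coherent_series(500 + r, shape = c(48, 48), steps = 1)
    model <- estimate_transition(s$maps[[1]], s$maps[[2]])
    out <- simulate_ca_markov(s$maps[[2]], model,
                              simulation_config(iterations = 5, seed = r))
    atlas <- build_suitability(out, 5)
    rand <- out
    ok <- !is.na(rand$classes$values)
    set.seed(r)
    rand$classes$values[ok] <- sample(out$classes$values[ok])
    if (mean_suit(out, build_suitability(out, 5)) >=
        mean_suit(rand, build_suitability(rand, 5))) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("predict_pipeline is deterministic and collapses for identical inputs", {
  s <- coherent_series(77, shape = c(48, 48), steps = 1)
  p1 <- predict_risk(s$maps[[1]], s$maps[[2]], simulation_config(seed = 5))
  p2 <- predict_risk(s$maps[[1]], s$maps[[2]], simulation_config(seed = 5))
  expect_identical(p1$classes$values, p2$classes$values)

  same <- predict_risk(s$maps[[2]], s$maps[[2]], simulation_config(seed = 5))
  expect_identical(same$classes$values, s$maps[[2]]$classes$values)
})
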