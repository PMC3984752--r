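test_that("configuration validation rejects degenerate settings", {
  expect_error(ga_config(pop_size = 1))
  expect_error(ga_config(elite = 100, pop_size = 100))
  expect_error(ga_config(crossover_rate = 1.5))
  expect_error(ga_config(mutation_rate = -0.1))
  expect_error(ga_config(rules_per_class = 0))
})

test_that("tournament selection prefers the fitter of two random draws", {
  expect_identical(ga_select(0.3), 1L)  # population of one
  set.seed(5)
  fit <- c(0.9, 0.1)
  picks <- replicate(4000, ga_select(fit))
  # closed form for binary tournament with N = 2: P(best) = 3/4
  expect_equal(mean(picks == 1L), 0.75, tolerance = 0.03)
  # a strictly better member is always returned when both are drawn
  set.seed(6)
  fit4 <- c(0.4, 0.1, 0.9, 0.2)
  picks4 <- replicate(8000, ga_select(fit4))
  p_best <- (1 / 4) * (2 - 1 / 4)
  expect_equal(mean(picks4 == 3L), p_best, tolerance = 0.03)
})

test_that("one-point crossover swaps tails and conserves positional bits", {
  set.seed(1)
  expect_identical(ga_crossover(c(1L,1L,0L), c(0L,0L,1L), 0),
                   list(c(1L,1L,0L), c(0L,0L,1L)))
  set.seed(2)
  kids <- ga_crossover(rep(0L, 4), rep(1L, 4), 1)
  cut <- sum(kids[[1]] == 0L)
  expect_true(cut >= 1 && cut <= 3)
  expect_identical(kids[[1]], c(rep(0L, cut), rep(1L, 4 - cut)))
  expect_identical(kids[[2]], c(rep(1L, cut), rep(0L, 4 - cut)))
  for (i in 1:20) {
    p1 <- stats::rbinom(12, 1, 0.5); p2 <- stats::rbinom(12, 1, 0.5)
    kids <- ga_crossover(p1, p2, 1)
    expect_identical(kids[[1]] + kids[[2]], p1 + p2)  # per-position multiset
  }
  expect_error(ga_crossover(c(1L, 0L), c(1L, 0L, 1L), 1), "length mismatch")
})

test_that("elementwise mutation flips at the configured rate", {
  bits <- stats::rbinom(50, 1, 0.5)
  expect_identical(ga_mutate(bits, 0), bits)
  expect_identical(ga_mutate(bits, 1), 1L - bits)
  set.seed(3)
  flips <- replicate(400, sum(ga_mutate(bits, 0.2) != bits))
  expect_equal(mean(flips), 0.2 * 50, tolerance = 0.5)
})

test_that("mining is reproducible under a fixed seed", {
  d <- table1_fixture()
  parts <- toy_parts()
  cfg <- ga_config(pop_size = 30, generations = 60, seed = 42,
                   rules_per_class = 3)
  rb1 <- mine_rules(d, parts, cfg)
  rb2 <- mine_rules(d, parts, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_rules(rb1, d$schema, f1); write_rules(rb2, d$schema, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("elitism makes best-in-population fitness non-decreasing", {
  d <- table1_fixture()
  parts <- toy_parts()
  for (seed in 1:3) {
    rl <- mine_class(d, parts, "medium-risk",
                     ga_config(pop_size = 20, generations = 80, seed = seed))
    trace <- attr(rl, "best_trace")
    expect_true(all(diff(trace) >= -1e-12))
  }
})

test_that("the miner attains the exhaustive optimum on the toy space", {
  d <- table1_fixture()
  parts <- toy_parts()
  for (cls in risk_levels()) {
    best <- oracle_best_fitness(d, parts, cls)
    rl <- mine_class(d, parts, cls,
                     ga_config(pop_size = 50, generations = 200, seed = 1,
                               min_support = 0))
    expect_equal(rl[[1]]$fitness, best, tolerance = 1e-12)
  }
})

test_that("cached rule statistics match an independent re-evaluation", {
  d <- small_cohort(n = 40, noise = 0.1, seed = 12)
  parts <- partition_all(d)
  rb <- mine_rules(d, parts, ga_config(pop_size = 40, generations = 120,
                                       seed = 2, rules_per_class = 3))
  rules <- rulebase_rules(rb)
  expect_gt(length(rules), 0)
  for (r in rules) {
    again <- evaluate_rule(r, d, parts)
    expect_equal(again$support, r$support, tolerance = 1e-9)
    expect_equal(again$confidence, r$confidence, tolerance = 1e-9)
    expect_gt(r$support, 0)
    expect_false(is.na(r$confidence))
  }
})

test_that("mined rule sets contain no redundant pair", {
  d <- table1_fixture()
  parts <- toy_parts()
  rl <- mine_class(d, parts, "medium-risk",
                   ga_config(pop_size = 40, generations = 150, seed = 9,
                             rules_per_class = 8, min_support = 0))
  if (length(rl) > 1) {
    for (i in seq_along(rl)) for (j in seq_along(rl)) {
      if (i != j) expect_false(is_redundant(rl[[i]], rl[[j]], d, parts))
    }
  }
})

test_that("mine_rules skips absent classes with a warning", {
  d <- table1_fixture()
  parts <- toy_parts()
  keep <- d$labels == "medium-risk"
  one_class <- make_dataset(d$schema, d$data[keep, , drop = FALSE],
                            labels = d$labels[keep], ids = d$ids[keep])
  expect_warning(expect_warning(
    rb <- mine_rules(one_class, partition_all(one_class),
                     ga_config(pop_size = 10, generations = 10, seed = 1)),
    "low-risk"), "high-risk")
  expect_length(rb$rules[["low-risk"]], 0L)
  expect_gt(length(rb$rules[["medium-risk"]]), 0L)
  expect_error(mine_class(one_class, partition_all(one_class), "high-risk",
                          ga_config(pop_size = 10, generations = 10)),
               "no case of class")
})

test_that("rule bases survive a JSON round trip", {
  d <- table1_fixture()
  parts <- toy_parts()
  rb <- mine_rules(d, parts, ga_config(pop_size = 30, generations = 60,
                                       seed = 3, rules_per_class = 2))
  path <- tempfile(fileext = ".json")
  write_rules(rb, d$schema, path)
  rb2 <- read_rules(path, d$schema)
  r1 <- rulebase_rules(rb); r2 <- rulebase_rules(rb2)
  expect_identical(length(r1), length(r2))
  for (i in seq_along(r1)) {
    expect_identical(r2[[i]]$selections, r1[[i]]$selections)
    expect_equal(r2[[i]]$confidence, r1[[i]]$confidence)
  }
  expect_equal(rb2$partitions, rb$partitions)
})
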