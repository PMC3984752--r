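test_that("firing strength sums per-feature maxima (and may exceed 1)", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- fuzzy_rule(list(age = "old", smoke = "no"), "medium-risk",
                  d$schema, parts)
  expect_identical(firing_strength(r, get_case(d, 1), parts, d$schema), 2)
  nofire <- fuzzy_rule(list(age = "young", smoke = "yes"), "low-risk",
                       d$schema, parts)
  expect_identical(firing_strength(nofire, get_case(d, 1), parts, d$schema), 0)
  set.seed(23)
  for (i in 1:30) {
    rr <- random_rule(d$schema, parts)
    b <- firing_strength(rr, get_case(d, sample(6, 1)), parts, d$schema)
    expect_gte(b, 0)
    expect_lte(b, antecedent_size(rr))
  }
})

test_that("scores sum confidence times firing strength per class", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- fuzzy_rule(list(age = "old", smoke = "no"), "medium-risk",
                  d$schema, parts)
  r$confidence <- 0.5
  rb <- gfsrisk:::new_rulebase(list("medium-risk" = list(r)), parts, NULL)
  s <- score_case(rb, get_case(d, 1), d$schema)  # beta = 2
  expect_equal(unname(s), c(0, 1, 0))
  # linearity: doubling every confidence doubles every score
  r2 <- r; r2$confidence <- 1
  rb2 <- gfsrisk:::new_rulebase(list("medium-risk" = list(r2)), parts, NULL)
  expect_equal(score_case(rb2, get_case(d, 1), d$schema), 2 * s)
})

test_that("prediction takes the top score with ties toward higher risk", {
  d <- table1_fixture()
  parts <- toy_parts()
  mk <- function(cls, conf) {
    r <- fuzzy_rule(list(heart_events_recently = "yes"), cls, d$schema, parts)
    r$confidence <- conf
    r
  }
  rb <- gfsrisk:::new_rulebase(
    list("low-risk" = list(mk("low-risk", 0.5)),
         "medium-risk" = list(mk("medium-risk", 0.5))), parts, NULL)
  p <- predict(rb, d)
  expect_identical(p$label[1], "medium-risk")  # tie at (0.5, 0.5, 0)
  expect_false(p$no_rule_fired[1])
  expect_identical(p$label[5], "medium-risk")  # sigma5 fires nothing: fallback
  expect_true(p$no_rule_fired[5])
  p_low <- predict(rb, d, fallback = "low-risk")
  expect_identical(p_low$label[5], "low-risk")
})

test_that("batch prediction equals case-by-case classification", {
  d <- table1_fixture()
  rb <- toy_rulebase(d)
  p <- predict(rb, d)
  expect_identical(nrow(p), 6L)
  expect_identical(p$id, d$ids)
  for (i in seq_len(6)) {
    one <- classify_case(rb, get_case(d, i), d$schema)
    expect_identical(p$label[i], one$label)
    expect_equal(c(p$v_low[i], p$v_medium[i], p$v_high[i]),
                 unname(one$scores))
  }
})

test_that("rule order never changes scores; silent rules never matter", {
  d <- table1_fixture()
  rb <- toy_rulebase(d)
  perm <- rb
  perm$rules <- perm$rules[c("high-risk", "low-risk", "medium-risk")]
  perm$rules[["medium-risk"]] <- rev(perm$rules[["medium-risk"]])
  expect_equal(score_matrix(perm, d), score_matrix(rb, d))

  # adding a rule that fires on no case leaves every prediction unchanged
  silent <- fuzzy_rule(list(age = "young", smoke = "yes",
                            heart_events_recently = "no"),
                       "high-risk", d$schema, rb$partitions)
  silent$confidence <- 0.99
  aug <- rb
  aug$rules[["high-risk"]] <- c(aug$rules[["high-risk"]], list(silent))
  p0 <- predict(rb, d); p1 <- predict(aug, d)
  fired <- vapply(seq_len(6), function(i) {
    firing_strength(silent, get_case(d, i), rb$partitions, d$schema)
  }, numeric(1))
  expect_identical(p1$label[fired == 0], p0$label[fired == 0])
})

test_that("scores respect the confidence-weighted upper bound", {
  d <- small_cohort(n = 25, seed = 3)
  parts <- partition_all(d)
  rb <- mine_rules(d, parts, ga_config(pop_size = 30, generations = 80,
                                       seed = 5, rules_per_class = 2))
  s <- score_matrix(rb, d)
  expect_true(all(s >= 0))
  for (cls in risk_levels()) {
    rules <- rb$rules[[cls]]
    if (!length(rules)) next
    bound <- sum(vapply(rules, function(r) {
      r$confidence * antecedent_size(r)
    }, numeric(1)))
    expect_true(all(s[, cls] <= bound + 1e-9))
  }
})

test_that("normalized firing mode divides by antecedent size", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- fuzzy_rule(list(age = "old", smoke = "no"), "medium-risk",
                  d$schema, parts)
  r$confidence <- 1
  rb <- gfsrisk:::new_rulebase(list("medium-risk" = list(r)), parts, NULL)
  raw <- score_case(rb, get_case(d, 1), d$schema)
  norm <- score_case(rb, get_case(d, 1), d$schema, normalize_beta = TRUE)
  expect_equal(unname(norm["medium-risk"]), unname(raw["medium-risk"]) / 2)
})
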