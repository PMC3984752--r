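test_that("chromosome encoding lays masks out in schema order", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- fuzzy_rule(list(age = c("old", "very old"), smoke = "yes",
                       heart_events_recently = "yes"),
                  "high-risk", d$schema, parts)
  ch <- encode_rule(r, d$schema, parts)
  expect_identical(ch$bits, c(0L,0L,1L,1L, 0L,0L, 1L,0L, 1L,0L))
  expect_identical(ch$class, "high-risk")
})

test_that("decoding drops all-zero and all-one segments", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- decode_chromosome(c(1L,1L,1L,1L, 1L,0L, 1L,0L, 1L,0L), d$schema,
                         parts, class = "low-risk")
  expect_identical(names(r$selections),
                   c("sex", "smoke", "heart_events_recently"))
  expect_null(decode_chromosome(rep(0L, 10), d$schema, parts, class = "low-risk"))
  expect_error(decode_chromosome(rep(0L, 9), d$schema, parts, class = "low-risk"),
               "bit length")
})

test_that("decode after encode is the identity on random valid rules", {
  d <- small_cohort(n = 20, seed = 4)
  parts <- partition_all(d)
  set.seed(13)
  for (i in 1:200) {
    r <- random_rule(d$schema, parts)
    r2 <- decode_chromosome(encode_rule(r, d$schema, parts), d$schema, parts)
    expect_identical(r2$selections, r$selections)
    expect_identical(r2$class, r$class)
  }
})

test_that("antecedent compatibility averages per-feature maxima", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- fuzzy_rule(list(age = "old", smoke = "no"), "medium-risk",
                  d$schema, parts)
  expect_identical(apc(get_case(d, 1), r, parts, d$schema), 1)    # 74y, no
  expect_identical(apc(get_case(d, 3), r, parts, d$schema), 0.5)  # smokes
  young <- fuzzy_rule(list(age = "young", smoke = "yes"), "low-risk",
                      d$schema, parts)
  expect_identical(apc(get_case(d, 1), young, parts, d$schema), 0)
  # a missing value contributes 0 but still counts in the average
  sigma <- list(values = list(age = NA, smoke = "no"), label = "medium-risk")
  expect_identical(apc(sigma, r, parts, d$schema), 0.5)
})

test_that("case support gates compatibility on the physician label", {
  d <- table1_fixture()
  parts <- toy_parts()
  r <- fuzzy_rule(list(age = "old", smoke = "no"), "medium-risk",
                  d$schema, parts)
  expect_identical(case_supp(get_case(d, 1), r, parts, d$schema), 1)  # matches
  expect_identical(case_supp(get_case(d, 4), r, parts, d$schema), 0)  # high
  un <- get_case(d, 1); un$label <- NA
  expect_error(case_supp(un, r, parts, d$schema), "unlabelled")
})

test_that("support and confidence follow the two-case hand example", {
  d <- ab_dataset(c("a", "a"), c("a", "b"), c("low", "medium"))
  parts <- list()
  r <- fuzzy_rule(list(f1 = "a", f2 = "a"), "low-risk", d$schema, parts)
  # apc = {1, 0.5}; supp = {1, 0}
  expect_identical(rule_support(r, d, parts), 0.5)
  expect_equal(rule_confidence(r, d, parts), 1 / 1.5)
  # a rule firing nowhere has undefined confidence
  r0 <- fuzzy_rule(list(f1 = "b"), "low-risk", d$schema, parts)
  expect_identical(rule_support(r0, d, parts), 0)
  expect_true(is.na(rule_confidence(r0, d, parts)))
  expect_identical(combine_fitness(0, NA), 0)
  expect_identical(combine_fitness(1, 1), 1)
})

test_that("confidence never falls below support and both stay in [0,1]", {
  d <- small_cohort(n = 30, noise = 0.2, seed = 6)
  parts <- partition_all(d)
  set.seed(17)
  for (i in 1:50) {
    r <- random_rule(d$schema, parts)
    s <- rule_support(r, d, parts)
    cf <- rule_confidence(r, d, parts)
    expect_gte(s, 0); expect_lte(s, 1)
    if (!is.na(cf)) {
      expect_gte(cf, s - 1e-12)
      expect_lte(cf, 1 + 1e-12)
    } else {
      expect_identical(s, 0)
    }
  }
})

test_that("categorical-only compatibility is a fraction k/n", {
  d <- small_cohort(n = 20, seed = 8)
  parts <- partition_all(d)
  set.seed(19)
  cat_feats <- Filter(function(f) f$kind == "categorical", d$schema)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    sel <- list()
    for (f in sample(cat_feats, k)) {
      mask <- rep(0L, length(f$domain))
      mask[sample(length(f$domain), 1)] <- 1L
      names(mask) <- f$domain
      sel[[f$name]] <- mask
    }
    r <- fuzzy_rule(sel, "low-risk", d$schema, parts)
    n <- antecedent_size(r)
    vals <- vapply(seq_len(n_cases(d)), function(j) {
      apc(get_case(d, j), r, parts, d$schema)
    }, numeric(1))
    expect_true(all(abs(vals * n - round(vals * n)) < 1e-12))
  }
})

test_that("a narrower rule with equal support is redundant", {
  # ages with zero membership in 'middle-aged' (all >= 74), so widening the
  # age selection cannot change the support
  schema <- table1_fixture()$schema
  d <- make_dataset(schema, data.frame(
    age = c(74, 76, 81), sex = c("male", "male", "female"),
    smoke = c("no", "no", "no"),
    heart_events_recently = c("yes", "yes", "no")),
    labels = c("low", "low", "low"))
  parts <- toy_parts()
  narrow <- evaluate_rule(fuzzy_rule(list(age = "old", smoke = "no"),
                                     "low-risk", schema, parts), d, parts)
  wide <- evaluate_rule(fuzzy_rule(list(age = c("young", "old"), smoke = "no"),
                                   "low-risk", schema, parts), d, parts)
  expect_true(is_redundant(narrow, wide, d, parts))
  expect_false(is_redundant(wide, narrow, d, parts))
  other <- evaluate_rule(fuzzy_rule(list(age = "old", smoke = "no"),
                                    "medium-risk", schema, parts), d, parts)
  expect_false(is_redundant(narrow, other, d, parts))       # class differs
  diff_sup <- evaluate_rule(fuzzy_rule(list(age = c("old", "very old"),
                                            smoke = "no"),
                                       "low-risk", schema, parts), d, parts)
  expect_false(is_redundant(narrow, diff_sup, d, parts))    # support differs
})

test_that("rules render as readable IF/THEN statements", {
  d <- table1_fixture()
  r <- fuzzy_rule(list(age = c("old", "very old"), smoke = "yes"),
                  "high-risk", d$schema, toy_parts())
  expect_identical(
    format(r),
    "IF age is (old OR very old) AND smoke is (yes) THEN risk is high-risk")
})
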