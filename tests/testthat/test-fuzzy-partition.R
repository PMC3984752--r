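test_that("cluster distance is the mean absolute cross-pair difference", {
  expect_identical(cluster_distance(74, 81), 7)
  expect_identical(cluster_distance(c(71, 74), c(76, 81)), 6)
  expect_identical(cluster_distance(c(74, 74), 74), 0)
  expect_error(cluster_distance(numeric(0), 1), "non-empty")
  set.seed(1)
  for (i in 1:10) {
    a <- stats::runif(4, 0, 100); b <- stats::runif(3, 0, 100)
    expect_equal(cluster_distance(a, b), cluster_distance(b, a))
    expect_gte(cluster_distance(a, b), 0)
  }
})

test_that("agglomeration merges below epsilon and stops above it", {
  cl <- agglomerate(c(1, 2, 100), 5)
  expect_identical(cluster_members(cl), list(c(1, 2), 100))
  expect_identical(cluster_members(agglomerate(7, 10)), list(7))
  expect_identical(cluster_members(agglomerate(c(3, 1, 2), 0)),
                   list(1, 2, 3))
  expect_error(agglomerate(numeric(0), 1), "non-empty")
})

test_that("agglomeration equals the exhaustive tracer on random inputs", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    values <- round(stats::runif(n, 0, 50), 2)
    eps <- stats::runif(1, 0, 20)
    got <- cluster_members(agglomerate(values, eps))
    want <- oracle_agglomerate(values, eps)$clusters
    expect_identical(got, want)
  }
})

test_that("agglomeration agrees with average-linkage hclust cut at epsilon", {
  set.seed(21)
  for (i in 1:10) {
    values <- stats::runif(sample(5:40, 1), 0, 100)  # continuous: no ties
    eps <- stats::runif(1, 1, 40)
    got <- cluster_members(agglomerate(values, eps))
    hc <- stats::hclust(stats::dist(values), method = "average")
    grp <- stats::cutree(hc, h = eps)
    want <- unname(lapply(split(values, grp), sort))
    want <- want[order(vapply(want, mean, numeric(1)))]
    expect_equal(got, want)
  }
})

test_that("average-linkage merge distances are non-decreasing in 1-D", {
  set.seed(3)
  for (i in 1:15) {
    values <- stats::runif(sample(3:12, 1), 0, 10)
    tr <- oracle_agglomerate(values, Inf)$merge_dists
    expect_true(all(diff(tr) >= -1e-12))
  }
})

test_that("partitions place boundary shoulders and interior apexes", {
  p <- toy_age_partition()
  expect_identical(n_sets(p), 4L)
  expect_identical(membership(p, 2, 74), 1)       # triangle apex
  expect_identical(membership(p, 1, 65), 0.5)     # (74-65)/(74-56)
  expect_identical(membership(p, 0, 25), 1)       # below the domain minimum
  expect_identical(membership(p, 3, 90), 1)       # above the domain maximum
  expect_error(membership(p, 4, 50), "out of range")
})

test_that("derived partitions drop midpoints at the bounds", {
  # toy ages with eps 3: merges (74,74) then 76; centroids 67/71/74.67/81,
  # the two boundary centroids are dropped
  d <- table1_fixture()
  p <- build_partition("age", d$data$age, epsilon = 3)
  expect_equal(p$midpoints, c(71, 74 + 2 / 3), tolerance = 1e-12)
  expect_identical(c(p$min, p$max), c(67, 81))
  expect_identical(n_sets(p), 4L)

  p2 <- build_partition("x", c(1, 1, 5), epsilon = 0)
  expect_identical(n_sets(p2), 2L)  # midpoints coincide with the bounds
  expect_error(build_partition("x", c(3, 3, 3)), "categorical")
})

test_that("every membership family is a partition of unity", {
  set.seed(11)
  parts <- list(toy_age_partition(),
                build_partition("u", stats::runif(40, 0, 1)),
                build_partition("v", stats::rnorm(100, 50, 10)),
                fuzzy_partition("w", 0, 1))
  for (p in parts) {
    x <- seq(p$min, p$max, length.out = 2000)
    expect_lt(max(abs(rowSums(membership_matrix(p, x)) - 1)), 1e-9)
    # interior triangles peak at exactly 1 on their midpoint
    for (j in seq_along(p$midpoints)) {
      expect_identical(membership(p, j, p$midpoints[j]), 1)
    }
    # memberships stay in [0,1] even outside the domain
    xx <- seq(p$min - 5, p$max + 5, length.out = 500)
    mm <- membership_matrix(p, xx)
    expect_true(all(mm >= 0 & mm <= 1))
  }
})

test_that("missing values have zero membership everywhere", {
  p <- toy_age_partition()
  for (j in 0:3) expect_identical(membership(p, j, NA), 0)
})

test_that("partition_all covers exactly the numerical features", {
  d <- table1_fixture()
  parts <- partition_all(d)
  expect_identical(names(parts), "age")
  expect_identical(parts, partition_all(d))  # deterministic

  cohort <- small_cohort(n = 40, seed = 2)
  expect_length(partition_all(cohort), 9L)
  expect_true(all(vapply(partition_all(cohort), n_sets, integer(1)) <= 5L))

  cat_only <- make_dataset(ab_schema(),
                           data.frame(f1 = c("a", "b"), f2 = c("a", "a")),
                           labels = c("low", "high"))
  expect_length(partition_all(cat_only), 0L)
})

test_that("partitions survive a JSON round trip", {
  parts <- partition_all(small_cohort(n = 30, seed = 5))
  path <- tempfile(fileext = ".json")
  write_partitions(parts, path)
  expect_equal(read_partitions(path), parts)
})
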