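# shared fixtures and independent oracles, built in code

toy_parts <- function() list(age = toy_age_partition())

# two-binary-feature schema for hand-checkable support/confidence toys
ab_schema <- function() {
  validate_schema <- getFromNamespace("validate_schema", "gfsrisk")
  validate_schema(list(
    feature_schema("f1", "categorical", domain = c("a", "b")),
    feature_schema("f2", "categorical", domain = c("a", "b"))))
}

ab_dataset <- function(f1, f2, labels) {
  make_dataset(ab_schema(),
               data.frame(f1 = f1, f2 = f2, stringsAsFactors = FALSE),
               labels = labels)
}

# exhaustive average-linkage agglomeration tracer: the independent oracle
# for agglomerate(); recomputes every pairwise distance from the raw members
# at every step and applies the documented tie-breaks
oracle_agglomerate <- function(values, epsilon, max_clusters = Inf) {
  clusters <- lapply(values, function(v) v)
  merge_dists <- numeric(0)
  repeat {
    k <- length(clusters)
    if (k <= 1) break
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- cluster_distance(clusters[[i]], clusters[[j]])
        ci <- mean(clusters[[i]])
        if (is.null(best) || d < best$d || (d == best$d && ci < best$ci)) {
          best <- list(i = i, j = j, d = d, ci = ci)
        }
      }
    }
    if (best$d > epsilon && k <= max_clusters) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
    merge_dists <- c(merge_dists, best$d)
  }
  cents <- vapply(clusters, mean, numeric(1))
  list(clusters = lapply(clusters[order(cents)], sort),
       merge_dists = merge_dists)
}

cluster_members <- function(clusters) lapply(clusters, `[[`, "members")

# exhaustive enumeration of every chromosome over a schema layout: the
# independent oracle for the GA's maximum fitness
oracle_best_fitness <- function(d, partitions, class) {
  layout <- chrom_layout(d$schema, partitions)
  stopifnot(layout$total <= 12L)
  best <- 0
  for (i in seq_len(2^layout$total) - 1L) {
    bits <- as.integer(intToBits(i))[seq_len(layout$total)]
    r <- decode_chromosome(bits, d$schema, partitions, class = class)
    if (is.null(r)) next
    r <- evaluate_rule(r, d, partitions)
    f <- combine_fitness(r$support, r$confidence)
    if (f > best) best <- f
  }
  best
}

# random valid rule over a schema (for round-trip and property tests)
random_rule <- function(schema, partitions, class = sample(risk_levels(), 1)) {
  repeat {
    sel <- list()
    for (f in schema) {
      if (stats::runif(1) < 0.5) next
      terms <- feature_terms(f, partitions)
      mask <- stats::rbinom(length(terms), 1L, 0.5)
      if (all(mask == 0L) || all(mask == 1L)) next
      names(mask) <- terms
      sel[[f$name]] <- mask
    }
    if (length(sel)) return(fuzzy_rule(sel, class, schema, partitions))
  }
}

small_cohort <- function(n = 54, noise = 0, seed = 42) {
  generate_cohort(generator_config(n_cases = n, label_noise = noise,
                                   seed = seed))
}
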