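#' Genetic-miner configuration
#'
#' Defaults follow the mining protocol used throughout the package:
#' population 100, 1000 generations, crossover rate 1.0, mutation rate 0.2,
#' with 2 elites carried unchanged each generation (elitism makes "higher
#' fitness survives" literally true) and the single best non-redundant rule kept
#' per class (configurable; see the methods vignette for why the default is 1).
#'
#' Two mutation semantics are supported. `"single-flip"` (the default)
#' applies mutation to a chromosome with probability `mutation_rate` and
#' flips one randomly selected element; populations then converge and the
#' search can reach compact rules on wide schemas. `"per-bit"` flips every
#' bit independently with probability `mutation_rate`; at rate 0.2 on long
#' chromosomes this behaves like random search and only suits small rule
#' spaces (see the methods vignette).
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations (the stopping criterion).
#' @param crossover_rate probability of one-point crossover per pairing.
#' @param mutation_rate mutation probability (see `mutation_mode`).
#' @param elite number of elites copied unchanged (< pop_size).
#' @param seed integer seed; each per-class run uses `seed + class rank`.
#' @param rules_per_class how many top-ranked rules to keep per class.
#' @param mutation_mode `"single-flip"` or `"per-bit"`.
#' @param min_support minimum support a rule must reach on the training data
#'   to enter the final rule base (standard association-rule hygiene: it
#'   discards near-zero-coverage rules whose confidence is 1 by accident).
#' @return A validated `ga_config` list.
#' @export
ga_config <- function(pop_size = 100L, generations = 1000L,
                      crossover_rate = 1.0, mutation_rate = 0.2,
                      elite = 2L, seed = 1L, rules_per_class = 1L,
                      mutation_mode = c("single-flip", "per-bit"),
                      min_support = 0.02) {
  cfg <- list(pop_size = as.integer(pop_size),
              generations = as.integer(generations),
              crossover_rate = as.numeric(crossover_rate),
              mutation_rate = as.numeric(mutation_rate),
              elite = as.integer(elite), seed = as.integer(seed),
              rules_per_class = as.integer(rules_per_class),
              mutation_mode = match.arg(mutation_mode),
              min_support = as.numeric(min_support))
  stopifnot(cfg$pop_size >= 2L, cfg$generations >= 1L,
            cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            cfg$elite >= 0L, cfg$elite < cfg$pop_size,
            cfg$rules_per_class >= 1L,
            cfg$min_support >= 0, cfg$min_support < 1)
  structure(cfg, class = "ga_config")
}

#' Binary tournament selection
#'
#' Draws two members uniformly at random (with replacement) and returns the
#' index of the fitter one (tie: the first drawn).
#'
#' @param fitness numeric vector of population fitness values.
#' @return Selected index.
#' @export
ga_select <- function(fitness) {
  idx <- sample.int(length(fitness), 2L, replace = TRUE)
  if (fitness[idx[2L]] > fitness[idx[1L]]) idx[2L] else idx[1L]
}

#' One-point crossover
#'
#' With probability `rate`, picks one cut position uniformly in
#' `1 .. L-1` and swaps the tails of the two parents; otherwise returns
#' copies.
#'
#' @param b1,b2 integer 0/1 vectors of equal length.
#' @param rate crossover probability.
#' @return List of two children bit vectors.
#' @export
ga_crossover <- function(b1, b2, rate) {
  if (length(b1) != length(b2)) stop("parent length mismatch", call. = FALSE)
  L <- length(b1)
  if (L > 1L && stats::runif(1) < rate) {
    cut <- sample.int(L - 1L, 1L)
    tail_idx <- (cut + 1L):L
    tmp <- b1[tail_idx]
    b1[tail_idx] <- b2[tail_idx]
    b2[tail_idx] <- tmp
  }
  list(b1, b2)
}

#' Bit-flip mutation
#'
#' Each bit flips independently with probability `rate` (1 becomes 0 and
#' vice versa).
#'
#' @param bits integer 0/1 vector.
#' @param rate per-bit flip probability.
#' @return Mutated bit vector.
#' @export
ga_mutate <- function(bits, rate) {
  flip <- stats::runif(length(bits)) < rate
  bits[flip] <- 1L - bits[flip]
  bits
}

# membership context: n x total_bits matrix over the chromosome layout
mu_matrix <- function(d, partitions) {
  layout <- chrom_layout(d$schema, partitions)
  cols <- lapply(d$schema, function(f) {
    col <- d$data[[f$name]]
    if (f$kind == "categorical") {
      mat <- vapply(f$domain, function(tok) as.numeric(col == tok),
                    numeric(n_cases(d)))
      if (!is.matrix(mat)) mat <- matrix(mat, nrow = n_cases(d))
      mat[is.na(mat)] <- 0
      mat
    } else {
      membership_matrix(partitions[[f$name]], col)
    }
  })
  mu <- do.call(cbind, cols)
  stopifnot(ncol(mu) == layout$total)
  list(mu = mu, layout = layout)
}

#' Mine fuzzy rules for one risk class
#'
#' Runs the genetic algorithm with the consequent fixed to `class`:
#' don't-care-biased random initialisation (each feature segment is
#' irrelevant with probability 1/2; all-irrelevant chromosomes resampled),
#' binary tournament selection, one-point crossover, the configured
#' mutation, and generational replacement with elitism. Every distinct valid rule with
#' positive support and defined confidence that ever appears in a population
#' enters a bounded best-ever archive; after the final generation the archive
#' is de-duplicated (redundant specialisations removed), ranked by fitness
#' (ties: higher confidence, fewer antecedent features, then bit-string
#' order), and the top `rules_per_class` rules are returned.
#'
#' @param d a labelled `ua_dataset` containing at least one case of `class`.
#' @param partitions named list of `ua_partition` for all numerical features.
#' @param class target risk level.
#' @param cfg a [ga_config()].
#' @return List of `ua_rule` with cached support/confidence/fitness, ranked
#'   best first. Attribute `best_trace` holds the best fitness per
#'   generation.
#' @export
mine_class <- function(d, partitions, class, cfg = ga_config()) {
  class <- as_risk_label(class)
  if (anyNA(d$labels)) stop("dataset contains unlabelled cases", call. = FALSE)
  if (!any(d$labels == class)) {
    stop("no case of class '", class, "' in the dataset", call. = FALSE)
  }
  ctx <- mu_matrix(d, partitions)
  labels_int <- risk_rank(d$labels)
  run_seed <- cfg$seed + risk_rank(class)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(run_seed)
  res <- ga_mine_cpp(ctx$mu, as.integer(ctx$layout$lengths), labels_int,
                     risk_rank(class), cfg$pop_size, cfg$generations,
                     cfg$crossover_rate, cfg$mutation_rate, cfg$elite,
                     max(20L * cfg$rules_per_class, 50L),
                     as.integer(identical(cfg$mutation_mode, "per-bit")))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  keep <- which(res$support >= cfg$min_support)
  if (!length(keep)) keep <- seq_len(nrow(res$bits))  # degenerate tiny data
  if (!length(keep)) return(structure(list(), best_trace = res$best_trace))
  bits_chr <- apply(res$bits[keep, , drop = FALSE], 1L, paste, collapse = "")

  rules <- lapply(keep, function(i) {
    r <- decode_chromosome(res$bits[i, ], d$schema, partitions, class = class)
    r$support <- res$support[i]
    r$confidence <- res$confidence[i]
    r$fitness <- res$fitness[i]
    r
  })
  # rank: fitness desc, confidence desc, fewer antecedent features, bit order
  ord <- order(-vapply(rules, `[[`, numeric(1), "fitness"),
               -vapply(rules, `[[`, numeric(1), "confidence"),
               vapply(rules, antecedent_size, integer(1)),
               bits_chr)
  rules <- rules[ord]
  # redundancy pruning: a rule adds nothing if an already kept (or incoming,
  # more general) rule subsumes it at equal support
  kept <- list()
  for (r in rules) {
    if (any(vapply(kept, function(k) is_redundant(r, k, d, partitions),
                   logical(1)))) next
    kept <- Filter(function(k) !is_redundant(k, r, d, partitions), kept)
    kept <- c(kept, list(r))
  }
  out <- kept[seq_len(min(length(kept), cfg$rules_per_class))]
  attr(out, "best_trace") <- res$best_trace
  out
}

#' Mine a full rule base (all classes present in the data)
#'
#' Runs [mine_class()] for each risk level present in `d`; absent classes
#' are skipped with a warning.
#'
#' @inheritParams mine_class
#' @return A `ua_rulebase`: list with `rules` (per-class lists), `partitions`
#'   and `config` provenance.
#' @export
mine_rules <- function(d, partitions, cfg = ga_config()) {
  rules <- list()
  for (cls in risk_levels()) {
    if (!any(!is.na(d$labels) & d$labels == cls)) {
      warning("no case of class '", cls, "': no rules mined for it",
              call. = FALSE)
      rules[[cls]] <- list()
      next
    }
    rl <- mine_class(d, partitions, cls, cfg)
    attr(rl, "best_trace") <- NULL
    rules[[cls]] <- rl
  }
  new_rulebase(rules, partitions, cfg)
}

new_rulebase <- function(rules, partitions, config) {
  structure(list(rules = rules, partitions = partitions, config = config),
            class = "ua_rulebase")
}

#' All rules of a rule base, flattened
#' @param rb a `ua_rulebase`.
#' @return list of `ua_rule`.
#' @export
rulebase_rules <- function(rb) {
  out <- list()
  for (cls in names(rb$rules)) out <- c(out, rb$rules[[cls]])
  out
}

#' @export
print.ua_rulebase <- function(x, ...) {
  total <- length(rulebase_rules(x))
  cat(sprintf("ua_rulebase: %d rules\n", total))
  for (cls in names(x$rules)) {
    cat(sprintf("-- %s (%d rules)\n", cls, length(x$rules[[cls]])))
    for (r in x$rules[[cls]]) {
      cat(sprintf("   [fit %.3f] %s\n", r$fitness, format(r)))
    }
  }
  invisible(x)
}

#' Serialize a rule base to JSON
#'
#' Each rule records its class, bit string over the schema layout, readable
#' statement, and cached statistics; partitions and mining configuration are
#' stored alongside for provenance.
#'
#' @param rb a `ua_rulebase`.
#' @param schema the `ua_schema` the rules were mined over.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rb, schema, path) {
  layout <- chrom_layout(schema, rb$partitions)
  rules <- lapply(rulebase_rules(rb), function(r) {
    chrom <- encode_rule(r, schema, rb$partitions)
    list(class = r$class, bits = paste(chrom$bits, collapse = ""),
         readable = format(r), support = r$support, confidence = r$confidence,
         fitness = r$fitness)
  })
  doc <- list(rules = rules,
              partitions = lapply(unname(rb$partitions), function(p) {
                list(feature = p$feature, min = p$min,
                     midpoints = as.list(p$midpoints), max = p$max,
                     labels = as.list(p$labels))
              }),
              config = unclass(rb$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rule base from JSON
#'
#' @param path path written by [write_rules()].
#' @param schema the `ua_schema` the rules were mined over.
#' @return A `ua_rulebase`.
#' @export
read_rules <- function(path, schema) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  partitions <- lapply(doc$partitions, function(e) {
    fuzzy_partition(e$feature, e$min, e$max, midpoints = unlist(e$midpoints),
                    labels = unlist(e$labels))
  })
  names(partitions) <- vapply(partitions, `[[`, character(1), "feature")
  rules <- stats::setNames(vector("list", length(risk_levels())), risk_levels())
  rules[] <- list(list())
  for (e in doc$rules) {
    bits <- as.integer(strsplit(e$bits, "")[[1]])
    r <- decode_chromosome(bits, schema, partitions, class = e$class)
    r$support <- e$support
    r$confidence <- e$confidence
    r$fitness <- e$fitness
    rules[[e$class]] <- c(rules[[e$class]], list(r))
  }
  cfg <- doc$config
  config <- if (!is.null(cfg)) do.call(ga_config, cfg) else NULL
  new_rulebase(rules, partitions, config)
}
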