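#' Linguistic terms of a feature
#'
#' For a numerical feature these are the labels of its fuzzy partition; for a
#' categorical feature, its domain tokens.
#'
#' @param feature a `ua_feature` schema entry.
#' @param partitions named list of `ua_partition` covering the numerical
#'   features.
#' @return Character vector of terms, in chromosome bit order.
#' @export
feature_terms <- function(feature, partitions) {
  if (feature$kind == "categorical") return(feature$domain)
  p <- partitions[[feature$name]]
  if (is.null(p)) {
    stop("no fuzzy partition available for numerical feature '", feature$name,
         "'", call. = FALSE)
  }
  p$labels
}

#' Chromosome bit layout for a schema
#'
#' @param schema a `ua_schema`.
#' @param partitions named list of `ua_partition`.
#' @return List with `lengths` (named integer, bits per feature in schema
#'   order), `offsets` (0-based), `terms` (named list of term vectors) and
#'   `total` bits.
#' @export
chrom_layout <- function(schema, partitions) {
  terms <- lapply(schema, feature_terms, partitions = partitions)
  lens <- vapply(terms, length, integer(1))
  list(lengths = lens, offsets = cumsum(c(0L, lens[-length(lens)])),
       terms = terms, total = sum(lens))
}

#' Construct a fuzzy classification rule
#'
#' A rule `IF <antecedent> THEN <class>`: the antecedent selects, for each of
#' a subset of features, one or more linguistic terms (an OR within the
#' feature); features combine conjunctively.
#'
#' @param selections named list: feature name -> character vector of selected
#'   terms, or a named 0/1 integer vector over the feature's terms. A
#'   selection of none or of all terms makes the feature irrelevant and is
#'   rejected here (use [decode_chromosome()] for raw bit strings).
#' @param class consequent risk level.
#' @param schema a `ua_schema`.
#' @param partitions named list of `ua_partition`.
#' @param support,confidence,fitness optional cached statistics.
#' @return A `ua_rule`: list with `selections` (named list of named 0/1
#'   masks), `class`, and the cached statistics (`NA` until evaluated).
#' @export
fuzzy_rule <- function(selections, class, schema, partitions,
                       support = NA_real_, confidence = NA_real_,
                       fitness = NA_real_) {
  class <- as_risk_label(class)
  if (!length(selections)) stop("rule needs at least one relevant feature",
                                call. = FALSE)
  sel <- list()
  for (fname in names(selections)) {
    f <- schema[[fname]]
    if (is.null(f)) stop("unknown feature '", fname, "' in rule", call. = FALSE)
    terms <- feature_terms(f, partitions)
    s <- selections[[fname]]
    if (is.character(s)) {
      s <- norm_token(s)
      bad <- setdiff(s, norm_token(terms))
      if (length(bad)) {
        stop("unknown term(s) for '", fname, "': ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      mask <- as.integer(norm_token(terms) %in% s)
    } else {
      mask <- as.integer(s)
      if (length(mask) != length(terms)) {
        stop("mask length mismatch for '", fname, "': got ", length(mask),
             ", expected ", length(terms), call. = FALSE)
      }
    }
    if (all(mask == 0L) || all(mask == 1L)) {
      stop("selection for '", fname,
           "' is all-zero or all-one (feature would be irrelevant)",
           call. = FALSE)
    }
    names(mask) <- terms
    sel[[fname]] <- mask
  }
  structure(list(selections = sel, class = class, support = support,
                 confidence = confidence, fitness = fitness),
            class = "ua_rule")
}

#' Number of antecedent features of a rule
#' @param rule a `ua_rule`.
#' @return integer.
#' @export
antecedent_size <- function(rule) length(rule$selections)

#' Encode a rule as a chromosome
#'
#' Lays the per-feature masks out segment by segment in schema order;
#' features absent from the antecedent become all-zero segments.
#'
#' @param rule a `ua_rule`.
#' @param schema a `ua_schema`.
#' @param partitions named list of `ua_partition`.
#' @return A `ua_chromosome`: list with `bits` (integer 0/1 vector) and
#'   `class`.
#' @export
encode_rule <- function(rule, schema, partitions) {
  layout <- chrom_layout(schema, partitions)
  bits <- integer(layout$total)
  for (fname in names(rule$selections)) {
    if (!(fname %in% names(schema))) {
      stop("unknown feature '", fname, "' in rule", call. = FALSE)
    }
    mask <- rule$selections[[fname]]
    if (length(mask) != layout$lengths[[fname]]) {
      stop("mask length mismatch for '", fname, "'", call. = FALSE)
    }
    off <- layout$offsets[[match(fname, names(schema))]]
    bits[off + seq_along(mask)] <- as.integer(mask)
  }
  structure(list(bits = bits, class = rule$class), class = "ua_chromosome")
}

#' Decode a chromosome into a rule
#'
#' Segments that are all-zero or all-one carry no information and are dropped
#' from the antecedent. A chromosome whose every segment is irrelevant is an
#' invalid rule and decodes to `NULL` (callers score it 0).
#'
#' @param chrom a `ua_chromosome`, or a plain integer 0/1 vector together
#'   with `class`.
#' @param schema a `ua_schema`.
#' @param partitions named list of `ua_partition`.
#' @param class consequent, required when `chrom` is a bare bit vector.
#' @return A `ua_rule`, or `NULL` for the invalid all-irrelevant chromosome.
#' @export
decode_chromosome <- function(chrom, schema, partitions, class = NULL) {
  if (inherits(chrom, "ua_chromosome")) {
    bits <- chrom$bits
    class <- chrom$class
  } else {
    bits <- as.integer(chrom)
    if (is.null(class)) stop("class required for a bare bit vector", call. = FALSE)
  }
  layout <- chrom_layout(schema, partitions)
  if (length(bits) != layout$total) {
    stop("bit length ", length(bits), " does not match schema layout (",
         layout$total, ")", call. = FALSE)
  }
  sel <- list()
  for (i in seq_along(schema)) {
    len <- layout$lengths[[i]]
    seg <- bits[layout$offsets[[i]] + seq_len(len)]
    if (all(seg == 0L) || all(seg == 1L)) next
    names(seg) <- layout$terms[[i]]
    sel[[names(schema)[i]]] <- seg
  }
  if (!length(sel)) return(NULL)
  fuzzy_rule(sel, class, schema, partitions)
}

# max membership of one case value among the terms selected for one feature
feature_compat <- function(value, mask, feature, partitions) {
  if (is.na(value)) return(0)
  if (feature$kind == "categorical") {
    return(as.numeric(norm_token(value) %in% names(mask)[mask == 1L]))
  }
  p <- partitions[[feature$name]]
  max(vapply(which(mask == 1L) - 1L, function(j) {
    membership(p, j, as.numeric(value))
  }, numeric(1)))
}

#' Antecedent part compatibility (APC)
#'
#' Mean, over the rule's antecedent features, of the maximal membership of
#' the case value among the selected terms. Categorical memberships are 0/1
#' (token match); a missing value contributes 0 but the feature still counts
#' in the average. A case supports the antecedent iff `apc > 0`.
#'
#' @param sigma a case (see [get_case()]) or a named list of feature values.
#' @param rule a `ua_rule`.
#' @param partitions named list of `ua_partition`.
#' @param schema a `ua_schema`.
#' @return Scalar in `[0, 1]`.
#' @export
apc <- function(sigma, rule, partitions, schema) {
  values <- if (!is.null(sigma$values)) sigma$values else sigma
  compat <- vapply(names(rule$selections), function(fname) {
    feature_compat(values[[fname]], rule$selections[[fname]], schema[[fname]],
                   partitions)
  }, numeric(1))
  mean(compat)
}

#' Support degree of one case for a rule
#'
#' `apc(sigma, rule)` when the case's physician label equals the rule's
#' consequent, else 0.
#'
#' @inheritParams apc
#' @param label the case's risk label; taken from `sigma$label` if omitted.
#' @return Scalar in `[0, 1]`.
#' @export
case_supp <- function(sigma, rule, partitions, schema, label = NULL) {
  if (is.null(label)) label <- sigma$label
  if (is.null(label) || is.na(label)) {
    stop("case ", if (!is.null(sigma$id)) sigma$id else "", " is unlabelled",
         call. = FALSE)
  }
  if (as_risk_label(label) != rule$class) return(0)
  apc(sigma, rule, partitions, schema)
}

# n_cases x n_features(relevant) matrix of per-feature max memberships;
# shared fast path for support/confidence/firing strength
compat_matrix <- function(rule, d, partitions) {
  cm <- vapply(names(rule$selections), function(fname) {
    f <- d$schema[[fname]]
    mask <- rule$selections[[fname]]
    col <- d$data[[fname]]
    if (f$kind == "categorical") {
      out <- as.numeric(col %in% names(mask)[mask == 1L])
      out[is.na(col)] <- 0
      out
    } else {
      mm <- membership_matrix(partitions[[fname]], col)
      do.call(pmax, as.data.frame(mm[, mask == 1L, drop = FALSE]))
    }
  }, numeric(n_cases(d)))
  if (!is.matrix(cm)) cm <- matrix(cm, nrow = n_cases(d))
  cm
}

#' Support of a rule on a dataset
#'
#' Mean over all (labelled) cases of [case_supp()].
#'
#' @param rule a `ua_rule`.
#' @param d a labelled `ua_dataset`.
#' @param partitions named list of `ua_partition`.
#' @return Scalar in `[0, 1]`.
#' @export
rule_support <- function(rule, d, partitions) {
  if (n_cases(d) < 1L) stop("empty dataset", call. = FALSE)
  if (anyNA(d$labels)) stop("dataset contains unlabelled cases", call. = FALSE)
  apcs <- rowMeans(compat_matrix(rule, d, partitions))
  sum(apcs[d$labels == rule$class]) / n_cases(d)
}

#' Confidence of a rule on a dataset
#'
#' Ratio of summed case support to summed APC. Undefined (returns `NA`) when
#' the rule fires on no case; callers score such rules 0.
#'
#' @inheritParams rule_support
#' @return Scalar in `[0, 1]`, or `NA` when the rule fires nowhere.
#' @export
rule_confidence <- function(rule, d, partitions) {
  if (n_cases(d) < 1L) stop("empty dataset", call. = FALSE)
  if (anyNA(d$labels)) stop("dataset contains unlabelled cases", call. = FALSE)
  apcs <- rowMeans(compat_matrix(rule, d, partitions))
  total <- sum(apcs)
  if (total <= 0) return(NA_real_)
  sum(apcs[d$labels == rule$class]) / total
}

#' Composite rule fitness
#'
#' The genetic miner's objective: the mean of support and confidence,
#' balancing generality against accuracy. An undefined confidence (rule
#' firing nowhere) scores 0.
#'
#' @param support,confidence numeric vectors in `[0, 1]` (recycled).
#' @return `(support + confidence) / 2`, with `NA` confidence mapped to 0.
#' @export
combine_fitness <- function(support, confidence) {
  ifelse(is.na(confidence), 0, (support + confidence) / 2)
}

#' Evaluate and cache a rule's statistics
#'
#' @inheritParams rule_support
#' @return The rule with `support`, `confidence`, `fitness` filled in.
#' @export
evaluate_rule <- function(rule, d, partitions) {
  rule$support <- rule_support(rule, d, partitions)
  rule$confidence <- rule_confidence(rule, d, partitions)
  rule$fitness <- combine_fitness(rule$support, rule$confidence)
  rule
}

#' Redundancy between two rules
#'
#' `r1` is redundant with respect to `r2` when both predict the same class,
#' every antecedent selection of `r1` is a (bitwise) subset of `r2`'s
#' selection for that feature (a feature irrelevant in `r2` covers all its
#' terms), and both rules have the same support on `d` (within 1e-9): the
#' narrower rule adds nothing.
#'
#' @param r1,r2 `ua_rule` objects over the same schema.
#' @param d a labelled `ua_dataset`.
#' @param partitions named list of `ua_partition`.
#' @return `TRUE` or `FALSE`.
#' @export
is_redundant <- function(r1, r2, d, partitions) {
  if (r1$class != r2$class) return(FALSE)
  if (!masks_subset(r1, r2)) return(FALSE)
  s1 <- if (!is.na(r1$support %||% NA)) r1$support else rule_support(r1, d, partitions)
  s2 <- if (!is.na(r2$support %||% NA)) r2$support else rule_support(r2, d, partitions)
  isTRUE(abs(s1 - s2) <= 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# antecedent containment: every selection of r1 within r2's (irrelevant in
# r2 = full mask; irrelevant in r1 but constrained in r2 = not contained)
masks_subset <- function(r1, r2) {
  for (fname in union(names(r1$selections), names(r2$selections))) {
    m1 <- r1$selections[[fname]]
    m2 <- r2$selections[[fname]]
    if (is.null(m2)) next                 # r2 unconstrained: anything fits
    if (is.null(m1)) return(FALSE)        # r1 covers all terms, r2 does not
    if (any(m1 == 1L & m2 == 0L)) return(FALSE)
  }
  TRUE
}

#' Human-readable rule statement
#'
#' @param x a `ua_rule`.
#' @param ... unused.
#' @return A string like
#'   `"IF age is (old OR very old) AND smoke is (yes) THEN risk is high-risk"`.
#' @export
format.ua_rule <- function(x, ...) {
  parts <- vapply(names(x$selections), function(fname) {
    mask <- x$selections[[fname]]
    terms <- names(mask)[mask == 1L]
    paste0(fname, " is (", paste(terms, collapse = " OR "), ")")
  }, character(1))
  paste0("IF ", paste(parts, collapse = " AND "), " THEN risk is ", x$class)
}

#' @export
print.ua_rule <- function(x, ...) {
  cat(format(x), "\n")
  if (!is.na(x$support %||% NA)) {
    cat(sprintf("  support %.4f  confidence %s  fitness %.4f\n", x$support,
                if (is.na(x$confidence)) "undefined" else sprintf("%.4f", x$confidence),
                x$fitness))
  }
  invisible(x)
}
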