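#' Firing strength of a rule on a case
#'
#' The sum (not the average) over the rule's antecedent features of the
#' maximal membership of the case value among the selected terms; it may
#' therefore exceed 1 (bounded by the antecedent size). Categorical match
#' contributes 1; mismatch or missing value contributes 0.
#'
#' @param rule a `ua_rule`.
#' @param sigma a case ([get_case()]) or named list of values.
#' @param partitions named list of `ua_partition`.
#' @param schema a `ua_schema`.
#' @return Non-negative scalar.
#' @export
firing_strength <- function(rule, sigma, partitions, schema) {
  values <- if (!is.null(sigma$values)) sigma$values else sigma
  sum(vapply(names(rule$selections), function(fname) {
    feature_compat(values[[fname]], rule$selections[[fname]], schema[[fname]],
                   partitions)
  }, numeric(1)))
}

# n_cases x n_rules matrix of firing strengths
firing_matrix <- function(rules, d, partitions, normalize = FALSE) {
  if (!length(rules)) return(matrix(0, nrow = n_cases(d), ncol = 0L))
  beta <- vapply(rules, function(r) {
    b <- rowSums(compat_matrix(r, d, partitions))
    if (normalize) b / antecedent_size(r) else b
  }, numeric(n_cases(d)))
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = n_cases(d))
  beta
}

#' Per-class scores for a whole dataset
#'
#' For each case and class, sums `confidence(r) * beta(r, sigma)` over the
#' class's rules.
#'
#' @param rb a `ua_rulebase`.
#' @param d a `ua_dataset` (labels not required).
#' @param normalize_beta divide each firing strength by the rule's
#'   antecedent size (off by default; the standard scoring sums raw
#'   strengths).
#' @return `n_cases x 3` numeric matrix, columns [risk_levels()].
#' @export
score_matrix <- function(rb, d, normalize_beta = FALSE) {
  out <- matrix(0, nrow = n_cases(d), ncol = length(risk_levels()),
                dimnames = list(NULL, risk_levels()))
  for (cls in names(rb$rules)) {
    rules <- rb$rules[[cls]]
    if (!length(rules)) next
    beta <- firing_matrix(rules, d, rb$partitions, normalize = normalize_beta)
    conf <- vapply(rules, `[[`, numeric(1), "confidence")
    out[, cls] <- out[, cls] + as.numeric(beta %*% conf)
  }
  out
}

#' Score one case against a rule base
#'
#' @param rb a `ua_rulebase`.
#' @param sigma a case ([get_case()]) or named list of values.
#' @param schema the `ua_schema` (needed for categorical matching).
#' @param normalize_beta see [score_matrix()].
#' @return Named numeric score vector `(v_low, v_medium, v_high)` over
#'   [risk_levels()].
#' @export
score_case <- function(rb, sigma, schema, normalize_beta = FALSE) {
  values <- if (!is.null(sigma$values)) sigma$values else sigma
  scores <- stats::setNames(numeric(length(risk_levels())), risk_levels())
  for (cls in names(rb$rules)) {
    for (r in rb$rules[[cls]]) {
      beta <- firing_strength(r, values, rb$partitions, schema)
      if (normalize_beta) beta <- beta / antecedent_size(r)
      scores[cls] <- scores[cls] + r$confidence * beta
    }
  }
  scores
}

# top-scoring class; ties broken toward the higher risk level
argmax_label <- function(scores) {
  best <- max(scores)
  winners <- which(scores >= best)
  risk_levels()[max(winners)]
}

#' Predict risk levels for a dataset
#'
#' Scores every case ([score_matrix()]) and returns the top-scoring risk
#' level per case. Ties break toward the higher (clinically conservative)
#' risk level. A case firing no rule at all gets the explicit `fallback`
#' label and is flagged.
#'
#' @param object a `ua_rulebase`.
#' @param newdata a `ua_dataset`.
#' @param fallback label assigned when all scores are zero
#'   (default `"medium-risk"`).
#' @param normalize_beta see [score_matrix()].
#' @param ... unused.
#' @return data.frame with columns `id`, `v_low`, `v_medium`, `v_high`,
#'   `label`, `no_rule_fired`; one row per case, in case order.
#' @export
predict.ua_rulebase <- function(object, newdata, fallback = "medium-risk",
                                normalize_beta = FALSE, ...) {
  fallback <- as_risk_label(fallback)
  scores <- score_matrix(object, newdata, normalize_beta = normalize_beta)
  none <- rowSums(scores) <= 0
  labels <- apply(scores, 1L, argmax_label)
  labels[none] <- fallback
  data.frame(id = newdata$ids,
             v_low = scores[, "low-risk"],
             v_medium = scores[, "medium-risk"],
             v_high = scores[, "high-risk"],
             label = labels,
             no_rule_fired = none,
             stringsAsFactors = FALSE)
}

#' Predict a single case
#'
#' @param rb a `ua_rulebase`.
#' @param sigma a case ([get_case()]) or named list of values.
#' @param schema the `ua_schema`.
#' @inheritParams predict.ua_rulebase
#' @return list with `scores` (named vector), `label`, `no_rule_fired`, and
#'   `fired` (data.frame of rules with positive firing strength).
#' @export
classify_case <- function(rb, sigma, schema, fallback = "medium-risk",
                          normalize_beta = FALSE) {
  fallback <- as_risk_label(fallback)
  scores <- score_case(rb, sigma, schema, normalize_beta = normalize_beta)
  values <- if (!is.null(sigma$values)) sigma$values else sigma
  fired <- do.call(rbind, lapply(rulebase_rules(rb), function(r) {
    b <- firing_strength(r, values, rb$partitions, schema)
    if (b <= 0) return(NULL)
    data.frame(rule = format(r), class = r$class, strength = b,
               confidence = r$confidence, stringsAsFactors = FALSE)
  }))
  none <- sum(scores) <= 0
  list(scores = scores,
       label = if (none) fallback else argmax_label(scores),
       no_rule_fired = none,
       fired = fired)
}
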