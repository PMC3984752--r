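#' One-vs-rest confusion counts per risk class
#'
#' @param preds character vector of predicted labels.
#' @param truth character vector of true (physician) labels, same length.
#' @return A `ua_confusion`: 3 x 4 integer matrix (rows = classes, columns
#'   `TP`, `FN`, `TN`, `FP`); each row sums to the number of cases.
#' @export
confusion_counts <- function(preds, truth) {
  preds <- as_risk_label(preds)
  truth <- as_risk_label(truth)
  if (length(preds) != length(truth)) {
    stop("predictions and truth differ in length", call. = FALSE)
  }
  if (!length(preds)) stop("need at least one case", call. = FALSE)
  out <- matrix(0L, nrow = 3L, ncol = 4L,
                dimnames = list(risk_levels(), c("TP", "FN", "TN", "FP")))
  for (cls in risk_levels()) {
    p <- preds == cls
    t <- truth == cls
    out[cls, ] <- c(sum(p & t), sum(!p & t), sum(!p & !t), sum(p & !t))
  }
  structure(out, class = c("ua_confusion", class(out)))
}

#' One-vs-rest sensitivity (true-positive rate)
#'
#' `TP / (TP + FN)` for the given class; `NA` (not applicable) when the
#' class has no positive cases.
#'
#' @param cc a `ua_confusion`.
#' @param class risk level.
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
sensitivity <- function(cc, class) {
  class <- as_risk_label(class)
  denom <- cc[class, "TP"] + cc[class, "FN"]
  if (denom == 0L) return(NA_real_)
  cc[class, "TP"] / denom
}

#' One-vs-rest specificity (true-negative rate)
#'
#' `TN / (TN + FP)` for the given class; `NA` when the class has no
#' negative cases.
#'
#' @inheritParams sensitivity
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
specificity <- function(cc, class) {
  class <- as_risk_label(class)
  denom <- cc[class, "TN"] + cc[class, "FP"]
  if (denom == 0L) return(NA_real_)
  cc[class, "TN"] / denom
}

#' Physician-agreement rate
#'
#' @param preds,truth equal-length label vectors.
#' @return list with `matches` (exact-match count) and `fraction`
#'   (`matches / n`).
#' @export
agreement <- function(preds, truth) {
  preds <- as_risk_label(preds)
  truth <- as_risk_label(truth)
  if (length(preds) != length(truth) || !length(preds)) {
    stop("predictions and truth must be equal-length and non-empty",
         call. = FALSE)
  }
  m <- sum(preds == truth)
  list(matches = m, fraction = m / length(preds))
}

# stratified fold assignment: within each class, cases are shuffled and
# dealt round-robin so every fold sees every class when counts allow
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

metrics_from_confusion <- function(cc) {
  data.frame(class = risk_levels(),
             sensitivity = vapply(risk_levels(), function(c) sensitivity(cc, c),
                                  numeric(1)),
             specificity = vapply(risk_levels(), function(c) specificity(cc, c),
                                  numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the full mining pipeline
#'
#' For each round, cases are shuffled and split into `folds` class-stratified
#' folds; for each fold the fuzzy partitions are re-derived from the training
#' split only (no leakage), a rule base is mined on the training split, and
#' the held-out cases are predicted. Confusion counts are pooled over all
#' rounds and folds. A class absent from some training split yields a warning
#' and the fold proceeds without that class's rules.
#'
#' @param d a fully labelled `ua_dataset` with `n_cases(d) >= folds`.
#' @param cfg a [ga_config()]; per-fold mining seeds are derived from
#'   `seed` deterministically.
#' @param folds number of folds (>= 2).
#' @param rounds number of repeated rounds with different fold assignments.
#' @param seed integer seed for fold shuffling (defaults to `cfg$seed`).
#' @param epsilon passed to [partition_all()].
#' @param max_sets passed to [partition_all()].
#' @param fallback passed to [predict.ua_rulebase()].
#' @return A `ua_eval_report`: list with pooled `confusion`, `metrics`
#'   (per-class sensitivity/specificity), `agreement`, `folds` (per-episode
#'   detail data.frame), `predictions` (per-case detail), `mode = "cv"`, and
#'   `na_excluded` (count of not-applicable per-fold rates).
#' @export
cross_validate <- function(d, cfg = ga_config(), folds = 10L, rounds = 1L,
                           seed = NULL, epsilon = NULL, max_sets = 5L,
                           fallback = "medium-risk") {
  folds <- as.integer(folds)
  rounds <- as.integer(rounds)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n_cases(d) < folds) stop("fewer cases than folds", call. = FALSE)
  if (anyNA(d$labels)) stop("dataset contains unlabelled cases", call. = FALSE)
  if (is.null(seed)) seed <- cfg$seed

  all_pred <- character(0)
  all_truth <- character(0)
  detail <- list()
  pred_rows <- list()
  na_excluded <- 0L
  missing_class_warnings <- 0L
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    assign <- stratified_folds(d$labels, folds)
    for (k in seq_len(folds)) {
      test_idx <- which(assign == k)
      train_idx <- setdiff(seq_len(n_cases(d)), test_idx)
      train <- make_dataset(d$schema, d$data[train_idx, , drop = FALSE],
                            labels = d$labels[train_idx],
                            ids = d$ids[train_idx])
      test <- make_dataset(d$schema, d$data[test_idx, , drop = FALSE],
                           labels = d$labels[test_idx], ids = d$ids[test_idx],
                           update_bounds = FALSE)
      parts <- partition_all(train, epsilon = epsilon, max_sets = max_sets)
      fold_cfg <- cfg
      fold_cfg$seed <- cfg$seed + 1000L * r + 10L * k
      rb <- withCallingHandlers(
        mine_rules(train, parts, fold_cfg),
        warning = function(w) {
          missing_class_warnings <<- missing_class_warnings + 1L
          invokeRestart("muffleWarning")
        })
      pred <- predict(rb, test, fallback = fallback)
      cc <- confusion_counts(pred$label, test$labels)
      fold_metrics <- metrics_from_confusion(cc)
      na_excluded <- na_excluded + sum(is.na(fold_metrics$sensitivity)) +
        sum(is.na(fold_metrics$specificity))
      all_pred <- c(all_pred, pred$label)
      all_truth <- c(all_truth, test$labels)
      detail[[length(detail) + 1L]] <- data.frame(
        round = r, fold = k, n_test = length(test_idx),
        matches = sum(pred$label == test$labels), stringsAsFactors = FALSE)
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        round = r, fold = k, id = test$ids, truth = test$labels,
        predicted = pred$label, no_rule_fired = pred$no_rule_fired,
        stringsAsFactors = FALSE)
    }
  }
  pooled <- confusion_counts(all_pred, all_truth)
  structure(list(mode = "cv",
                 confusion = pooled,
                 metrics = metrics_from_confusion(pooled),
                 agreement = agreement(all_pred, all_truth),
                 folds = do.call(rbind, detail),
                 predictions = do.call(rbind, pred_rows),
                 na_excluded = na_excluded,
                 missing_class_warnings = missing_class_warnings,
                 config = cfg, n_folds = folds, rounds = rounds, seed = seed),
            class = "ua_eval_report")
}

#' Resubstitution evaluation
#'
#' Mines on the full dataset and evaluates on the same cases (the optimistic
#' counterpart of [cross_validate()]; reported with `mode = "resubstitution"`
#' so the two are never conflated).
#'
#' @inheritParams cross_validate
#' @return A `ua_eval_report`.
#' @export
resubstitution <- function(d, cfg = ga_config(), epsilon = NULL,
                           max_sets = 5L, fallback = "medium-risk") {
  if (anyNA(d$labels)) stop("dataset contains unlabelled cases", call. = FALSE)
  parts <- partition_all(d, epsilon = epsilon, max_sets = max_sets)
  rb <- mine_rules(d, parts, cfg)
  pred <- predict(rb, d, fallback = fallback)
  cc <- confusion_counts(pred$label, d$labels)
  structure(list(mode = "resubstitution",
                 confusion = cc,
                 metrics = metrics_from_confusion(cc),
                 agreement = agreement(pred$label, d$labels),
                 folds = NULL,
                 predictions = data.frame(id = d$ids, truth = d$labels,
                                          predicted = pred$label,
                                          no_rule_fired = pred$no_rule_fired,
                                          stringsAsFactors = FALSE),
                 na_excluded = 0L, config = cfg),
            class = "ua_eval_report")
}

#' @export
print.ua_eval_report <- function(x, ...) {
  n_eval <- nrow(x$predictions)
  cat(sprintf("ua_eval_report (%s): agreement %d/%d (%.1f%%)\n", x$mode,
              x$agreement$matches, n_eval, 100 * x$agreement$fraction))
  print(x$metrics)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `ua_eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- list(mode = report$mode,
              confusion = as.data.frame(unclass(report$confusion)),
              metrics = report$metrics,
              agreement = report$agreement,
              folds = report$folds,
              predictions = report$predictions,
              na_excluded = report$na_excluded)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
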