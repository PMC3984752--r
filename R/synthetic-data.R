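#' Default 26-feature clinical schema
#'
#' Nine numerical features (age, blood pressures, cardiac/renal biomarkers)
#' and seventeen categorical features (history flags, ECG findings, sex,
#' smoking, ...) typical of an unstable-angina work-up.
#'
#' @return A `ua_schema` with 26 features.
#' @export
default_schema <- function() {
  num <- function(name, lo, hi) feature_schema(name, "numerical", bounds = c(lo, hi))
  yn <- function(name) feature_schema(name, "categorical", domain = c("yes", "no"))
  validate_schema(list(
    num("age", 30, 90),
    num("sbp", 80, 200),
    num("dbp", 40, 130),
    num("creatinine", 40, 400),
    num("ast", 5, 300),
    num("ldh", 80, 600),
    num("ck", 20, 1000),
    num("ck_mb", 1, 150),
    num("cnt", 0, 2),
    feature_schema("sex", "categorical", domain = c("male", "female")),
    yn("smoke"),
    yn("atrial_premature_beat"),
    yn("st_change"),
    yn("heart_events_recently"),
    yn("chd_history"),
    yn("renal_insufficiency"),
    yn("bleeding_history"),
    feature_schema("diabetes", "categorical",
                   domain = c("none", "type 1", "type 2")),
    yn("hyperlipaemia"),
    feature_schema("hypertension", "categorical",
                   domain = c("none", "level i", "level ii", "level iii")),
    yn("aspirin_recent"),
    yn("pci"),
    yn("lung_blood_expectoration"),
    yn("t_change"),
    yn("drinking_heart_event"),
    yn("irregular_pulse")))
}

# per-feature sampling parameters; spans are clinically plausible
# conventions for an elderly coronary cohort, declared once here
default_numerical_params <- function() {
  list(age = c(mean = 66, sd = 12),
       sbp = c(mean = 135, sd = 22),
       dbp = c(mean = 80, sd = 13),
       creatinine = c(mean = 95, sd = 40),
       ast = c(mean = 35, sd = 25),
       ldh = c(mean = 210, sd = 70),
       ck = c(mean = 140, sd = 90),
       ck_mb = c(mean = 16, sd = 12),
       cnt = c(mean = 0.06, sd = 0.15))
}

default_categorical_params <- function() {
  list(sex = c(male = 0.60, female = 0.40),
       smoke = c(yes = 0.45, no = 0.55),
       atrial_premature_beat = c(yes = 0.15, no = 0.85),
       st_change = c(yes = 0.10, no = 0.90),
       heart_events_recently = c(yes = 0.63, no = 0.37),
       chd_history = c(yes = 0.50, no = 0.50),
       renal_insufficiency = c(yes = 0.10, no = 0.90),
       bleeding_history = c(yes = 0.08, no = 0.92),
       diabetes = c("none" = 0.60, "type 1" = 0.05, "type 2" = 0.35),
       hyperlipaemia = c(yes = 0.40, no = 0.60),
       hypertension = c("none" = 0.35, "level i" = 0.25, "level ii" = 0.25,
                        "level iii" = 0.15),
       aspirin_recent = c(yes = 0.55, no = 0.45),
       pci = c(yes = 0.30, no = 0.70),
       lung_blood_expectoration = c(yes = 0.05, no = 0.95),
       t_change = c(yes = 0.40, no = 0.60),
       drinking_heart_event = c(yes = 0.10, no = 0.90),
       irregular_pulse = c(yes = 0.20, no = 0.80))
}

#' Generator configuration
#'
#' The default class mix (16:33:5 over low/medium/high) mirrors the
#' imbalance of a small single-centre unstable-angina cohort and is enforced
#' exactly (largest-remainder rounding) by stratified rejection.
#'
#' @param n_cases number of cases to generate.
#' @param label_noise probability (< 0.5) that a case's planted label is
#'   flipped to a uniformly chosen different class. Applied after the class
#'   mix is met, so the mix refers to the noise-free planted labels.
#' @param class_mix per-class fractions over [risk_levels()]; need not sum
#'   exactly to 1 (normalised internally).
#' @param seed integer seed; generation is fully determined by it.
#' @param schema the feature schema (default [default_schema()]).
#' @param numerical named list of `c(mean, sd)` per numerical feature
#'   (bounds come from the schema; values are drawn from a truncated
#'   normal).
#' @param categorical named list of per-feature value probabilities.
#' @return A `gen_config` list.
#' @export
generator_config <- function(n_cases = 54L, label_noise = 0,
                             class_mix = c(16, 33, 5) / 54, seed = 1L,
                             schema = default_schema(),
                             numerical = default_numerical_params(),
                             categorical = default_categorical_params()) {
  stopifnot(n_cases >= 1L, label_noise >= 0, label_noise < 0.5,
            length(class_mix) == 3L, all(class_mix >= 0), sum(class_mix) > 0)
  for (nm in names(categorical)) {
    p <- categorical[[nm]]
    if (abs(sum(p) - 1) > 1e-6) {
      stop("categorical weights for '", nm, "' must sum to 1", call. = FALSE)
    }
  }
  structure(list(n_cases = as.integer(n_cases), label_noise = label_noise,
                 class_mix = class_mix / sum(class_mix), seed = as.integer(seed),
                 schema = schema, numerical = numerical,
                 categorical = categorical),
            class = "gen_config")
}

#' Fixed fuzzy partitions of the default generator
#'
#' The generator labels cases against a *known* partition per numerical
#' feature (these are the planted ground truth, not data-derived).
#'
#' @return Named list of `ua_partition`.
#' @export
planted_partitions <- function() {
  list(
    age = fuzzy_partition("age", 30, 90, midpoints = c(55, 72),
                          labels = c("young", "middle-aged", "old", "very old")),
    sbp = fuzzy_partition("sbp", 80, 200, midpoints = 135),
    dbp = fuzzy_partition("dbp", 40, 130, midpoints = c(65, 95)),
    creatinine = fuzzy_partition("creatinine", 40, 400, midpoints = 150),
    ast = fuzzy_partition("ast", 5, 300, midpoints = 80),
    ldh = fuzzy_partition("ldh", 80, 600, midpoints = 300),
    ck = fuzzy_partition("ck", 20, 1000, midpoints = 250),
    ck_mb = fuzzy_partition("ck_mb", 1, 150, midpoints = c(25, 60),
                            labels = c("very low", "low", "medium", "high")),
    cnt = fuzzy_partition("cnt", 0, 2))
}

#' Default planted rule set
#'
#' Ground-truth rules that drive the generator's labels, scored with the
#' classifier's own machinery (confidence-weighted summed firing strengths,
#' argmax with ties toward the higher risk level). A significant ST change
#' on the ECG marks high risk; otherwise recent heart events mark medium
#' risk and quiescent patients are low risk. The three rules tie at equal
#' confidence, so the conservative tie-break resolves ST-change cases to
#' high risk regardless of event history.
#'
#' @param schema the generator schema (default [default_schema()]).
#' @return A `planted_rules` list with `rules` (per-class), `partitions`,
#'   `fallback`.
#' @export
default_planted_rules <- function(schema = default_schema()) {
  parts <- planted_partitions()
  rule <- function(sel, class, conf) {
    r <- fuzzy_rule(sel, class, schema, parts)
    r$confidence <- conf
    r
  }
  rules <- list(
    "low-risk" = list(
      rule(list(heart_events_recently = "no"), "low-risk", 1.0)),
    "medium-risk" = list(
      rule(list(heart_events_recently = "yes"), "medium-risk", 1.0)),
    "high-risk" = list(
      rule(list(st_change = "yes"), "high-risk", 1.0)))
  structure(list(rules = rules, partitions = parts, fallback = "medium-risk"),
            class = "planted_rules")
}

planted_rulebase <- function(planted) {
  new_rulebase(planted$rules, planted$partitions, NULL)
}

#' Noise-free planted labels for a dataset
#'
#' @param planted a `planted_rules` set.
#' @param d a `ua_dataset` over the same schema.
#' @return Character vector of labels.
#' @export
planted_labels <- function(planted, d) {
  missing_feats <- setdiff(
    unique(unlist(lapply(unlist(planted$rules, recursive = FALSE),
                         function(r) names(r$selections)))),
    names(d$schema))
  if (length(missing_feats)) {
    stop("dataset schema lacks planted-rule feature(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  predict(planted_rulebase(planted), d, fallback = planted$fallback)$label
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  out[out < lo] <- lo
  out[out > hi] <- hi
  out
}

draw_batch <- function(cfg, n) {
  cols <- list()
  for (f in cfg$schema) {
    if (f$kind == "numerical") {
      p <- cfg$numerical[[f$name]]
      if (is.null(p)) stop("no distribution for '", f$name, "'", call. = FALSE)
      cols[[f$name]] <- round(rtrunc_norm(n, p[["mean"]], p[["sd"]],
                                          f$bounds[1], f$bounds[2]), 3)
    } else {
      p <- cfg$categorical[[f$name]]
      if (is.null(p)) stop("no probabilities for '", f$name, "'", call. = FALSE)
      cols[[f$name]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
  }
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

largest_remainder <- function(frac, n) {
  raw <- frac * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic labelled cohort
#'
#' Draws feature values from the configured distributions (truncated normal
#' for numerical, weighted draw for categorical), labels each case by
#' scoring it against the planted rules with the classifier's own scoring
#' (so the ground truth exercises the full inference path), enforces the
#' exact per-class mix by stratified rejection, then flips each label to a
#' uniformly different class with probability `label_noise`. Fully
#' determined by `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @param planted a planted rule set (default [default_planted_rules()]).
#' @return A labelled `ua_dataset` of `cfg$n_cases` cases.
#' @export
generate_cohort <- function(cfg, planted = default_planted_rules(cfg$schema)) {
  set.seed(cfg$seed)
  n <- cfg$n_cases
  quota <- largest_remainder(cfg$class_mix, n)
  names(quota) <- risk_levels()
  kept_data <- list()
  kept_labels <- character(0)
  drawn <- 0L
  while (any(quota > 0)) {
    if (drawn >= 10L * n) {
      stop("class mix unsatisfiable after ", drawn, " draws; short of: ",
           paste(names(quota)[quota > 0], collapse = ", "), call. = FALSE)
    }
    batch_n <- min(max(n, 32L), 10L * n - drawn)
    batch <- draw_batch(cfg, batch_n)
    drawn <- drawn + batch_n
    bd <- make_dataset(cfg$schema, batch, update_bounds = FALSE)
    labels <- planted_labels(planted, bd)
    for (i in seq_len(batch_n)) {
      if (quota[[labels[i]]] > 0L) {
        kept_data[[length(kept_data) + 1L]] <- batch[i, , drop = FALSE]
        kept_labels <- c(kept_labels, labels[i])
        quota[[labels[i]]] <- quota[[labels[i]]] - 1L
      }
      if (!any(quota > 0)) break
    }
  }
  data <- do.call(rbind, kept_data)
  rownames(data) <- NULL
  if (cfg$label_noise > 0) {
    flip <- stats::runif(n) < cfg$label_noise
    if (any(flip)) {
      kept_labels[flip] <- vapply(kept_labels[flip], function(l) {
        sample(setdiff(risk_levels(), l), 1L)
      }, character(1))
    }
  }
  make_dataset(cfg$schema, data, labels = kept_labels,
               ids = paste0("case_", seq_len(n)))
}

#' The printed six-case example dataset
#'
#' Loads the packaged six-case toy cohort (age, sex, smoking, recent heart
#' events, physician label) from `inst/extdata`.
#'
#' @return A labelled `ua_dataset` with 6 cases.
#' @export
table1_fixture <- function() {
  schema <- load_schema(system.file("extdata", "table1_schema.json",
                                    package = "gfsrisk", mustWork = TRUE))
  load_dataset(system.file("extdata", "table1.csv", package = "gfsrisk",
                           mustWork = TRUE), schema)
}

#' Planted-rule recovery score
#'
#' Agreement between the labels a mined rule base assigns to held-out cases
#' and the noise-free planted labels: the package's end-to-end benchmark of
#' the miner.
#'
#' @param mined a mined `ua_rulebase`.
#' @param planted a `planted_rules` set.
#' @param test a held-out `ua_dataset` over the same schema.
#' @param fallback fallback label for silent cases.
#' @return Fraction in `[0, 1]`.
#' @export
recovery_score <- function(mined, planted, test, fallback = "medium-risk") {
  truth <- planted_labels(planted, test)
  preds <- predict(mined, test, fallback = fallback)$label
  agreement(preds, truth)$fraction
}
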