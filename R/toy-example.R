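#' Four-term age partition of the worked example
#'
#' The age partition used throughout the package's worked example: domain
#' 30-87 years with midpoints at 56 and 74, giving four fuzzy sets
#' young / middle-aged / old / very old (left semi-trapezoid, two triangles,
#' right semi-trapezoid).
#'
#' @return A `ua_partition` for feature `"age"`.
#' @export
toy_age_partition <- function() {
  fuzzy_partition("age", 30, 87, midpoints = c(56, 74),
                  labels = c("young", "middle-aged", "old", "very old"))
}

#' Six-rule example base over the toy cohort
#'
#' Builds the package's reference rule base for the six-case toy cohort
#' ([table1_fixture()]): two rules per risk level over age, sex, smoking and
#' recent heart events, with support/confidence/fitness computed on the toy
#' data under [toy_age_partition()]. Useful for demonstrating scoring and
#' prediction without running the miner.
#'
#' @param d the toy dataset (default [table1_fixture()]).
#' @return A `ua_rulebase`.
#' @export
toy_rulebase <- function(d = table1_fixture()) {
  parts <- list(age = toy_age_partition())
  S <- d$schema
  mk <- function(sel, cls) {
    evaluate_rule(fuzzy_rule(sel, cls, S, parts), d, parts)
  }
  rules <- list(
    "low-risk" = list(
      mk(list(age = "young", heart_events_recently = "no"), "low-risk"),
      mk(list(age = "young", sex = "female", smoke = "no"), "low-risk")),
    "medium-risk" = list(
      mk(list(age = c("young", "middle-aged"), smoke = "no",
              heart_events_recently = "yes"), "medium-risk"),
      mk(list(age = "old", smoke = "no"), "medium-risk")),
    "high-risk" = list(
      mk(list(age = c("old", "very old"), smoke = "yes"), "high-risk"),
      mk(list(age = c("middle-aged", "old", "very old"), sex = "male",
              heart_events_recently = "yes"), "high-risk")))
  new_rulebase(rules, list(age = toy_age_partition()), NULL)
}
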