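#' Admissible risk levels
#'
#' The classifier is ordinal over exactly three risk levels. The order of the
#' returned vector is the ordinal order (rank 0, 1, 2).
#'
#' @return Character vector `c("low-risk", "medium-risk", "high-risk")`.
#' @export
risk_levels <- function() c("low-risk", "medium-risk", "high-risk")

#' Ordinal rank of a risk level
#'
#' @param level character vector of risk levels.
#' @return Integer vector of ranks: 0 (low), 1 (medium), 2 (high).
#' @export
risk_rank <- function(level) {
  level <- as_risk_label(level)
  match(level, risk_levels()) - 1L
}

#' Normalise a risk label token
#'
#' Trims whitespace, lowercases, and accepts the shorthands "low", "medium",
#' "high" for the hyphenated forms. `NA` passes through (unlabelled case).
#'
#' @param x character vector.
#' @return Character vector of canonical labels.
#' @export
as_risk_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("low", "medium", "high")] <-
    paste0(x[x %in% c("low", "medium", "high")], "-risk")
  bad <- !is.na(x) & !(x %in% risk_levels())
  if (any(bad)) {
    stop("unknown risk label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

norm_token <- function(x) tolower(trimws(as.character(x)))

#' Declare a single feature
#'
#' @param name feature identifier (unique within a schema).
#' @param kind `"numerical"` or `"categorical"`.
#' @param domain for categorical features, the finite set of admissible
#'   tokens (matched case-insensitively after trimming). Ignored for
#'   numerical features.
#' @param bounds optional numeric `c(min, max)` for numerical features;
#'   usually filled in from observed data by [load_dataset()].
#' @return A `ua_feature` list with elements `name`, `kind`, `domain`,
#'   `bounds`.
#' @export
feature_schema <- function(name, kind = c("numerical", "categorical"),
                           domain = NULL, bounds = NULL) {
  kind <- match.arg(kind)
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) {
    stop("feature name must be a single non-empty string", call. = FALSE)
  }
  if (kind == "categorical") {
    if (is.null(domain) || length(domain) == 0L) {
      stop("categorical feature '", name, "' needs a non-empty domain",
           call. = FALSE)
    }
    domain <- norm_token(domain)
    if (anyDuplicated(domain)) {
      stop("categorical feature '", name, "' has duplicate domain values",
           call. = FALSE)
    }
    bounds <- NULL
  } else {
    domain <- NULL
    if (!is.null(bounds)) {
      bounds <- as.numeric(bounds)
      if (length(bounds) != 2L || anyNA(bounds) || bounds[1] > bounds[2]) {
        stop("bounds for '", name, "' must be numeric c(min, max) with min <= max",
             call. = FALSE)
      }
    }
  }
  structure(list(name = name, kind = kind, domain = domain, bounds = bounds),
            class = "ua_feature")
}

validate_schema <- function(schema) {
  if (!length(schema)) stop("schema has no features", call. = FALSE)
  nms <- vapply(schema, function(f) f$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate feature name(s) in schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  structure(schema, names = nms, class = "ua_schema")
}

#' Load a feature schema from JSON
#'
#' The document is a JSON array of objects
#' `{"name": ..., "kind": "numerical"|"categorical", "domain": [...]}` where
#' `domain` is required for (and only used by) categorical features. Declared
#' feature order is preserved.
#'
#' @param path path to the JSON schema file.
#' @return A `ua_schema`: named list of [feature_schema()] entries.
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed schema document '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!is.list(doc) || !length(doc)) {
    stop("schema document '", path, "' must be a non-empty JSON array",
         call. = FALSE)
  }
  schema <- lapply(doc, function(entry) {
    if (is.null(entry$name)) stop("schema entry without a name", call. = FALSE)
    kind <- entry$kind
    if (is.null(kind) || !(kind %in% c("numerical", "categorical"))) {
      stop("feature '", entry$name, "': unknown kind '",
           if (is.null(kind)) "<missing>" else kind, "'", call. = FALSE)
    }
    feature_schema(entry$name, kind,
                   domain = unlist(entry$domain),
                   bounds = unlist(entry$bounds))
  })
  validate_schema(schema)
}

#' Write a feature schema to JSON
#'
#' @param schema a `ua_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  doc <- lapply(schema, function(f) {
    out <- list(name = f$name, kind = f$kind)
    if (f$kind == "categorical") out$domain <- f$domain
    if (!is.null(f$bounds)) out$bounds <- f$bounds
    out
  })
  jsonlite::write_json(unname(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

new_dataset <- function(schema, data, ids, labels) {
  structure(list(schema = schema, data = data, ids = ids, labels = labels),
            class = "ua_dataset")
}

#' Number of cases in a dataset
#' @param d a `ua_dataset`.
#' @return integer case count |D|.
#' @export
n_cases <- function(d) nrow(d$data)

#' Assemble a dataset from in-memory values
#'
#' @param schema a `ua_schema`.
#' @param data data.frame, one column per schema feature (feature order is
#'   taken from the schema). Numerical columns numeric, categorical columns
#'   character; `NA` marks a missing value.
#' @param labels optional character vector of physician risk labels
#'   (`NA` = unlabelled).
#' @param ids optional case identifiers; defaults to `sigma_1 ...`.
#' @param update_bounds update numerical schema bounds to the observed
#'   min/max (default `TRUE`).
#' @return A `ua_dataset` with elements `schema`, `data`, `ids`, `labels`.
#' @export
make_dataset <- function(schema, data, labels = NULL, ids = NULL,
                         update_bounds = TRUE) {
  schema <- validate_schema(unclass(schema))
  missing_cols <- setdiff(names(schema), names(data))
  if (length(missing_cols)) {
    stop("data is missing schema column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < 1L) stop("dataset must contain at least one case", call. = FALSE)
  out <- data[names(schema)]
  for (f in schema) {
    col <- out[[f$name]]
    if (f$kind == "numerical") {
      if (!is.numeric(col)) {
        suppressWarnings(num <- as.numeric(as.character(col)))
        bad <- which(!is.na(as.character(col)) & nzchar(trimws(as.character(col))) & is.na(num))
        if (length(bad)) {
          stop("non-numeric value '", col[bad[1]], "' in numerical column '",
               f$name, "' (row ", bad[1], ")", call. = FALSE)
        }
        col <- num
      }
      obs <- col[!is.na(col)]
      if (update_bounds && length(obs)) {
        f$bounds <- range(obs)
        schema[[f$name]] <- f
      }
    } else {
      col <- norm_token(col)
      col[!nzchar(col) | col == "na"] <- NA_character_
      bad <- which(!is.na(col) & !(col %in% f$domain))
      if (length(bad)) {
        stop("value '", col[bad[1]], "' outside domain of categorical column '",
             f$name, "' (row ", bad[1], ")", call. = FALSE)
      }
    }
    out[[f$name]] <- col
  }
  if (is.null(ids)) ids <- paste0("sigma_", seq_len(nrow(out)))
  if (is.null(labels)) labels <- rep(NA_character_, nrow(out))
  labels <- as_risk_label(labels)
  if (length(ids) != nrow(out) || length(labels) != nrow(out)) {
    stop("ids/labels length must equal the number of rows", call. = FALSE)
  }
  rownames(out) <- NULL
  new_dataset(schema, out, as.character(ids), labels)
}

#' Load a patient dataset from CSV
#'
#' Expects an RFC-4180 CSV with a header row whose columns are the schema
#' feature names, plus an optional id column and an optional label column.
#' Numerical schema bounds are updated to the observed min/max. Rows keep
#' file order. Empty cells are missing values (never imputed; their fuzzy
#' membership downstream is 0).
#'
#' @param path path to the CSV file.
#' @param schema a `ua_schema` (see [load_schema()]).
#' @param label_col name of the physician-label column (default `"risk"`);
#'   absent column means an unlabelled dataset.
#' @param id_col name of the case-id column (default `"id"`), optional.
#' @return A `ua_dataset`.
#' @export
load_dataset <- function(path, schema, label_col = "risk", id_col = "id") {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("NA", ""))
  if (nrow(raw) < 1L) stop("dataset '", path, "' has no data rows", call. = FALSE)
  known <- c(names(schema), label_col, id_col)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown column(s) in '", path, "': ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- if (id_col %in% names(raw)) raw[[id_col]] else NULL
  labels <- if (label_col %in% names(raw)) raw[[label_col]] else NULL
  make_dataset(schema, raw, labels = labels, ids = ids)
}

#' Write a dataset to CSV
#'
#' Inverse of [load_dataset()]: a load/write/load round trip preserves every
#' value, label, and row order.
#'
#' @param d a `ua_dataset`.
#' @param path output path.
#' @param label_col,id_col column names used on output.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, label_col = "risk", id_col = "id") {
  out <- cbind(stats::setNames(data.frame(d$ids, stringsAsFactors = FALSE), id_col),
               d$data)
  if (!all(is.na(d$labels))) out[[label_col]] <- d$labels
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-class case counts
#'
#' @param d a fully labelled `ua_dataset`.
#' @return Named integer vector over [risk_levels()]; sums to `n_cases(d)`.
#' @export
class_counts <- function(d) {
  unl <- which(is.na(d$labels))
  if (length(unl)) {
    stop("unlabelled case(s): ", paste(d$ids[unl], collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(d$labels, levels = risk_levels()))
  stats::setNames(as.integer(counts), risk_levels())
}

#' Extract one case
#'
#' @param d a `ua_dataset`.
#' @param i row index.
#' @return list with `id`, `values` (named list, `NA` = missing), `label`.
#' @export
get_case <- function(d, i) {
  stopifnot(i >= 1L, i <= n_cases(d))
  list(id = d$ids[[i]], values = as.list(d$data[i, , drop = FALSE]),
       label = d$labels[[i]])
}

#' @export
print.ua_dataset <- function(x, ...) {
  kinds <- vapply(x$schema, function(f) f$kind, character(1))
  cat(sprintf("ua_dataset: %d cases, %d features (%d numerical, %d categorical)\n",
              n_cases(x), length(x$schema), sum(kinds == "numerical"),
              sum(kinds == "categorical")))
  if (!all(is.na(x$labels))) {
    cc <- table(factor(x$labels, levels = risk_levels()), useNA = "ifany")
    cat("labels:", paste(names(cc), as.integer(cc), sep = "=", collapse = ", "),
        "\n")
  } else {
    cat("labels: none\n")
  }
  invisible(x)
}

#' @export
print.ua_schema <- function(x, ...) {
  cat(sprintf("ua_schema: %d features\n", length(x)))
  for (f in x) {
    rhs <- if (f$kind == "categorical") {
      paste0("{", paste(f$domain, collapse = ", "), "}")
    } else if (!is.null(f$bounds)) {
      sprintf("[%g, %g]", f$bounds[1], f$bounds[2])
    } else "[unbounded]"
    cat(sprintf("  %s: %s %s\n", f$name, f$kind, rhs))
  }
  invisible(x)
}
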