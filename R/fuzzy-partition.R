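#' Average-linkage distance between two clusters
#'
#' The mean absolute difference over all cross pairs,
#' `(1/(|c1||c2|)) * sum_{x in c1} sum_{y in c2} |x - y|`. Symmetric; zero
#' iff every cross pair is equal.
#'
#' @param c1,c2 non-empty numeric vectors (cluster members).
#' @return Non-negative scalar.
#' @export
cluster_distance <- function(c1, c2) {
  if (!length(c1) || !length(c2)) stop("clusters must be non-empty", call. = FALSE)
  mean(abs(outer(as.numeric(c1), as.numeric(c2), "-")))
}

#' One-dimensional agglomerative clustering
#'
#' Starts from singleton clusters and repeatedly merges the pair with the
#' smallest average-linkage [cluster_distance()], stopping when the smallest
#' inter-cluster distance exceeds `epsilon` (or one cluster remains).
#' Deterministic: distance ties are broken by the lower centroid of the left
#' cluster, then by scan (insertion) order. If `max_clusters` is finite,
#' merging continues past `epsilon` until at most that many clusters remain.
#'
#' @param values non-empty numeric vector (a multiset; duplicates count).
#' @param epsilon non-negative merge threshold, on the scale of the values.
#' @param max_clusters optional upper bound on the number of clusters.
#' @return List of clusters sorted by centroid; each is a list with
#'   `members` (sorted numeric) and `centroid` (arithmetic mean).
#' @export
agglomerate <- function(values, epsilon, max_clusters = Inf) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("values must be non-empty and free of NA", call. = FALSE)
  }
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  maxc <- if (is.finite(max_clusters)) as.integer(max_clusters) else length(values)
  assign_idx <- hac_cpp(values, as.numeric(epsilon), maxc)
  groups <- split(values, assign_idx)
  clusters <- lapply(groups, function(g) {
    list(members = sort(g), centroid = mean(g))
  })
  cents <- vapply(clusters, `[[`, numeric(1), "centroid")
  unname(clusters[order(cents)])
}

#' Cluster centroids
#' @param clusters result of [agglomerate()].
#' @return numeric vector of centroids, in cluster order.
#' @export
centroids <- function(clusters) {
  vapply(clusters, `[[`, numeric(1), "centroid")
}

default_term_vocab <- function(n_sets) {
  switch(as.character(n_sets),
         "2" = c("low", "high"),
         "3" = c("low", "medium", "high"),
         "4" = c("low", "low-medium", "high-medium", "high"),
         "5" = c("very low", "low", "medium", "high", "very high"),
         paste0("set_", seq_len(n_sets) - 1L))
}

new_partition <- function(feature, min, midpoints, max, labels) {
  structure(list(feature = feature, min = min, midpoints = midpoints,
                 max = max, labels = labels),
            class = "ua_partition")
}

#' Number of fuzzy sets in a partition
#' @param p a `ua_partition`.
#' @return integer, `length(p$midpoints) + 2`.
#' @export
n_sets <- function(p) length(p$midpoints) + 2L

#' Build a fuzzy partition manually
#'
#' @param feature feature name.
#' @param min,max domain bounds (v0 and v_{m+1}).
#' @param midpoints strictly increasing midpoints inside `(min, max)`; may be
#'   empty (two semi-trapezoids only).
#' @param labels optional linguistic terms, one per fuzzy set
#'   (`length(midpoints) + 2`); defaults to a size-matched vocabulary
#'   (e.g. low/medium/high for three sets).
#' @return A `ua_partition`.
#' @export
fuzzy_partition <- function(feature, min, max, midpoints = numeric(0),
                            labels = NULL) {
  midpoints <- as.numeric(midpoints)
  if (min >= max) stop("partition needs min < max", call. = FALSE)
  if (length(midpoints) &&
      (any(diff(midpoints) <= 0) || any(midpoints <= min) ||
       any(midpoints >= max))) {
    stop("midpoints must be strictly increasing and inside (min, max)",
         call. = FALSE)
  }
  m <- length(midpoints)
  if (is.null(labels)) labels <- default_term_vocab(m + 2L)
  labels <- as.character(labels)
  if (length(labels) != m + 2L || anyDuplicated(labels)) {
    stop("need ", m + 2L, " unique labels for feature '", feature, "'",
         call. = FALSE)
  }
  new_partition(feature, as.numeric(min), midpoints, as.numeric(max), labels)
}

#' Derive a fuzzy partition from observed values
#'
#' Clusters the values with [agglomerate()]; the cluster centroids become the
#' midpoints of interior triangular fuzzy sets, flanked by two boundary
#' semi-trapezoids at the observed min/max. Centroids within
#' `1e-9 * range` of a domain bound are dropped (they would create
#' zero-width segments). If the resulting set count exceeds `max_sets`,
#' merging continues until it fits.
#'
#' @param feature feature name.
#' @param values observed numeric values (>= 2 distinct; all-identical input
#'   raises a degenerate-partition error suggesting the feature be treated as
#'   categorical).
#' @param epsilon merge threshold; default `0.15 * diff(range(values))`.
#' @param labels optional linguistic terms (see [fuzzy_partition()]).
#' @param max_sets cap on the number of fuzzy sets (default 5).
#' @return A `ua_partition`.
#' @export
build_partition <- function(feature, values, epsilon = NULL, labels = NULL,
                            max_sets = 5L) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("no observed values for '", feature, "'",
                                call. = FALSE)
  v0 <- min(values)
  vmax <- max(values)
  if (vmax - v0 <= 0) {
    stop(structure(class = c("gfs_degenerate_partition", "error", "condition"),
                   list(message = paste0(
                     "feature '", feature, "' has a single distinct value (",
                     v0, "); treat it as categorical"), call = NULL)))
  }
  if (is.null(epsilon)) epsilon <- 0.15 * (vmax - v0)
  tol <- 1e-9 * (vmax - v0)
  maxc <- max(max_sets, 1L)  # clusters may exceed midpoint cap before drops
  repeat {
    cl <- agglomerate(values, epsilon, max_clusters = maxc)
    mids <- centroids(cl)
    mids <- mids[mids > v0 + tol & mids < vmax - tol]
    if (length(mids) + 2L <= max_sets || maxc <= 1L) break
    maxc <- length(cl) - 1L  # over the cap: merge one step further
  }
  fuzzy_partition(feature, v0, vmax, midpoints = mids, labels = labels)
}

#' Fuzzy membership degree
#'
#' Evaluates the `j`-th membership function of a partition. Set 0 is the left
#' semi-trapezoid (1 below the domain minimum, linear fall to the first
#' midpoint); sets `1..m` are triangles peaking at their midpoint; set `m+1`
#' is the right semi-trapezoid (linear rise from the last midpoint, 1 above
#' the domain maximum). The family is a partition of unity on
#' `[min, max]`.
#'
#' @param p a `ua_partition`.
#' @param j set index in `0 .. m+1` (m = number of midpoints).
#' @param x numeric vector of input values.
#' @return Numeric vector of memberships in `[0, 1]`; `NA` input gives 0
#'   (missing evidence never fires a term).
#' @export
membership <- function(p, j, x) {
  m <- length(p$midpoints)
  if (j < 0L || j > m + 1L) {
    stop("set index ", j, " out of range 0..", m + 1L, call. = FALSE)
  }
  knots <- c(p$min, p$midpoints, p$max)  # knots[j+1] is v^j, with v^0 = min
  x <- as.numeric(x)
  out <- numeric(length(x))
  if (j == 0L) {
    v0 <- knots[1]; v1 <- knots[2]
    out[x < v0] <- 1
    sel <- x >= v0 & x <= v1
    out[sel] <- (v1 - x[sel]) / (v1 - v0)
  } else if (j == m + 1L) {
    vm <- knots[m + 1L]; vtop <- knots[m + 2L]
    out[x > vtop] <- 1
    sel <- x > vm & x <= vtop
    out[sel] <- (x[sel] - vm) / (vtop - vm)
  } else {
    lo <- knots[j]; mid <- knots[j + 1L]; hi <- knots[j + 2L]
    rise <- x >= lo & x <= mid
    fall <- x > mid & x <= hi
    out[rise] <- (x[rise] - lo) / (mid - lo)
    out[fall] <- (hi - x[fall]) / (hi - mid)
  }
  out[is.na(x)] <- 0
  out
}

#' Membership matrix of a partition
#'
#' @param p a `ua_partition`.
#' @param x numeric vector.
#' @return `length(x) x n_sets(p)` matrix; columns named by the linguistic
#'   terms.
#' @export
membership_matrix <- function(p, x) {
  cols <- lapply(seq_len(n_sets(p)) - 1L, function(j) membership(p, j, x))
  mat <- do.call(cbind, cols)
  colnames(mat) <- p$labels
  mat
}

#' Partition every numerical feature of a dataset
#'
#' @param d a `ua_dataset`.
#' @param epsilon `NULL` (per-feature default `0.15 * range`), a single
#'   global value, or a named vector/list of per-feature values.
#' @param max_sets cap on fuzzy sets per feature.
#' @return Named list of `ua_partition`, one per numerical feature (empty if
#'   none). Categorical features are untouched.
#' @export
partition_all <- function(d, epsilon = NULL, max_sets = 5L) {
  out <- list()
  for (f in d$schema) {
    if (f$kind != "numerical") next
    eps <- if (is.null(epsilon)) NULL
           else if (length(epsilon) == 1L && is.null(names(epsilon))) as.numeric(epsilon)
           else if (f$name %in% names(epsilon)) as.numeric(epsilon[[f$name]])
           else NULL
    out[[f$name]] <- tryCatch(
      build_partition(f$name, d$data[[f$name]], epsilon = eps,
                      max_sets = max_sets),
      gfs_degenerate_partition = function(e) {
        stop("while partitioning feature '", f$name, "': ",
             conditionMessage(e), call. = FALSE)
      })
  }
  out
}

#' Serialize fuzzy partitions to JSON
#'
#' @param partitions named list of `ua_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  doc <- lapply(unname(partitions), function(p) {
    list(feature = p$feature, min = p$min, midpoints = as.list(p$midpoints),
         max = p$max, labels = as.list(p$labels))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read fuzzy partitions from JSON
#'
#' @param path path written by [write_partitions()].
#' @return Named list of `ua_partition`.
#' @export
read_partitions <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(doc, function(e) {
    fuzzy_partition(e$feature, e$min, e$max, midpoints = unlist(e$midpoints),
                    labels = unlist(e$labels))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "feature"))
}

#' @export
print.ua_partition <- function(x, ...) {
  cat(sprintf("ua_partition '%s': %d fuzzy sets on [%g, %g]\n",
              x$feature, n_sets(x), x$min, x$max))
  knots <- c(x$min, x$midpoints, x$max)
  for (j in seq_len(n_sets(x))) {
    apex <- if (j == 1L) x$min else if (j == n_sets(x)) x$max else knots[j]
    cat(sprintf("  %-12s apex %g\n", x$labels[j], apex))
  }
  invisible(x)
}
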