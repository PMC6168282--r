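#' Summarize an occupancy distribution for box-plot comparison
#'
#' Quartiles use Tukey hinges (median-inclusive halves, linear in the
#' order statistics), the convention under which the lower/upper
#' quartiles of \{0.1, 0.2, 0.3, 0.4\} are 0.15 and 0.35. Whiskers extend
#' to the most extreme values within 1.5 IQR of the hinges.
#'
#' @param values numeric vector of marginal occupancy probabilities
#'   (>= 2 values).
#' @param label distribution label (e.g. `"DC urban"`).
#' @return object of class `occupancy_distribution`: `label`, `values`,
#'   `q1`, `median`, `q3`, `whisker_low`, `whisker_high`, `n`.
#' @export
summarize_distribution <- function(values, label = "") {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values to summarize")
  if (any(values < 0 | values > 1)) stop("occupancy values must lie in [0, 1]")
  fn <- stats::fivenum(values)
  iqr <- fn[4L] - fn[2L]
  structure(list(label = label, values = sort(values),
                 q1 = fn[2L], median = fn[3L], q3 = fn[4L],
                 whisker_low = min(values[values >= fn[2L] - 1.5 * iqr]),
                 whisker_high = max(values[values <= fn[4L] + 1.5 * iqr]),
                 n = length(values)),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("%s (n=%d): q1=%.3f median=%.3f q3=%.3f\n",
              x$label, x$n, x$q1, x$median, x$q3))
  invisible(x)
}

#' Interquartile-range overlap test
#'
#' Two occupancy distributions differ "significantly" under the overlap
#' heuristic iff their interquartile boxes \[q1, q3\] are disjoint.
#' Boxes touching at a single point count as overlapping (closed
#' intervals), hence not significantly different. Symmetric in its
#' arguments.
#'
#' @param a,b `occupancy_distribution` objects.
#' @return list: `overlapping`, `significant_difference`.
#' @export
iqr_overlap_test <- function(a, b) {
  stopifnot(inherits(a, "occupancy_distribution"),
            inherits(b, "occupancy_distribution"))
  overlap <- a$q1 <= b$q3 && b$q1 <= a$q3
  list(overlapping = overlap, significant_difference = !overlap)
}

#' Average occupancy over duplicate studies in an external table
#'
#' For cross-study comparison tables (species, study, occupancy,
#' optionally diet_class): species estimated by several studies are
#' collapsed to their unweighted mean; omnivores can be excluded first
#' via the diet-class column so the table matches a carnivore-only
#' community.
#'
#' @param table data.frame with columns `species`, `occupancy`, and
#'   optionally `study` and `diet_class`.
#' @param exclude_omnivores drop rows whose `diet_class` is
#'   `"omnivore"` before averaging?
#' @return data.frame: `species`, `occupancy` (mean), `n_studies`.
#' @export
average_duplicate_studies <- function(table, exclude_omnivores = FALSE) {
  stopifnot(all(c("species", "occupancy") %in% names(table)))
  if (exclude_omnivores) {
    if (is.null(table$diet_class))
      stop("omnivore exclusion requested but no diet_class column")
    table <- table[tolower(table$diet_class) != "omnivore", , drop = FALSE]
  }
  agg <- stats::aggregate(occupancy ~ species, data = table, FUN = mean)
  cnt <- stats::aggregate(occupancy ~ species, data = table, FUN = length)
  agg$n_studies <- cnt$occupancy[match(agg$species, cnt$species)]
  agg
}

#' Compare stratum occupancy distributions against a reference
#'
#' Runs [iqr_overlap_test()] of every stratum distribution against a
#' reference distribution (e.g. a global protected-areas community) and
#' against each other, returning a tidy comparison table.
#'
#' @param distributions named list of `occupancy_distribution` objects.
#' @return data.frame of pairwise comparisons: `a`, `b`, `overlapping`,
#'   `significant_difference`.
#' @export
compare_distributions <- function(distributions) {
  nm <- names(distributions)
  stopifnot(length(nm) >= 2L)
  pairs <- utils::combn(nm, 2L)
  out <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                    overlapping = NA, significant_difference = NA)
  for (k in seq_len(ncol(pairs))) {
    r <- iqr_overlap_test(distributions[[pairs[1L, k]]],
                          distributions[[pairs[2L, k]]])
    out$overlapping[k] <- r$overlapping
    out$significant_difference[k] <- r$significant_difference
  }
  out
}
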