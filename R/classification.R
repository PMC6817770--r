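## Arteriole/venule classification from morphometry.
##
## The area-ratio rule uses the empirical decision ranges: vessels at or below
## `arteriole_upper` are arterioles, vessels at or above `venule_lower` are
## venules, and the open gap between the two observed ranges maps to an
## explicit `indeterminate` class — the separation claim holds only outside
## the observed ranges, so no boundary is invented inside the gap. The
## diameter-ratio rule is deliberately weak (venule-or-indeterminate): below
## its threshold the two classes cannot be told apart.

#' Published group-2 mean diameter ratio (Results text)
#'
#' The mean lumen-diameter to wall-thickness ratio reported for the
#' arteriole-like group in the source study's results text. The same quantity
#' appears as 4.97 in the subgroup analysis; both values are exposed and
#' neither is resolved as the correct one.
#' @export
DIAMETER_RATIO_GROUP2_MEAN <- 4.348

#' Published group-2 mean diameter ratio used by the subgroup re-test
#'
#' Default threshold of [classify_diameter_ratio()] and
#' [below_threshold_retest()]. See [DIAMETER_RATIO_GROUP2_MEAN] for the
#' alternative published value of the same quantity.
#' @export
DIAMETER_RATIO_SUBGROUP_THRESHOLD <- 4.97

#' Area-ratio decision rule
#'
#' @param arteriole_upper Upper edge of the arteriole area-ratio range
#'   (default 1.57).
#' @param venule_lower Lower edge of the venule area-ratio range
#'   (default 1.89). Must exceed `arteriole_upper`.
#' @return An object of class `decision_rule`.
#' @export
decision_rule <- function(arteriole_upper = 1.57, venule_lower = 1.89) {
  if (!(arteriole_upper < venule_lower)) {
    stop("decision_rule requires arteriole_upper < venule_lower")
  }
  structure(list(arteriole_upper = arteriole_upper, venule_lower = venule_lower),
            class = "decision_rule")
}

.as_record <- function(r) {
  if (is.data.frame(r)) {
    if (nrow(r) != 1L) stop("expected a single morphometry record")
    return(as.list(r))
  }
  as.list(r)
}

.refuse_excluded <- function(rec) {
  if (isTRUE(rec$excluded)) {
    stop("refusing to classify excluded vessel ", rec$vessel_id,
         " (reason: ", rec$exclusion_reason, ")")
  }
}

#' Classify a vessel from its lumen:wall area ratio
#'
#' @param record One morphometry record (one-row data.frame from [measure()],
#'   or a list with at least `vessel_id`, `area_ratio`, `excluded`).
#' @param rule A [decision_rule()].
#' @param binary_cutoff Optional hard threshold for users requiring binary
#'   output: ratios at or below it are arterioles, above it venules, and the
#'   indeterminate class disappears. Default `NULL` keeps the gap explicit.
#'   A conventional choice is the geometric midpoint of the default gap,
#'   `sqrt(1.57 * 1.89)` (about 1.723).
#' @return A one-row data.frame: `vessel_id`, `assigned_class`
#'   (`venule`/`arteriole`/`indeterminate`), `criterion` (`"area_ratio"`),
#'   `score` (the ratio used).
#' @export
classify_area_ratio <- function(record, rule = decision_rule(),
                                binary_cutoff = NULL) {
  stopifnot(inherits(rule, "decision_rule"))
  rec <- .as_record(record)
  .refuse_excluded(rec)
  r <- rec$area_ratio
  if (!is.finite(r)) stop("area_ratio undefined for vessel ", rec$vessel_id)
  cls <- if (!is.null(binary_cutoff)) {
    if (r <= binary_cutoff) "arteriole" else "venule"
  } else if (r <= rule$arteriole_upper) {
    "arteriole"
  } else if (r >= rule$venule_lower) {
    "venule"
  } else {
    "indeterminate"
  }
  data.frame(vessel_id = rec$vessel_id, assigned_class = cls,
             criterion = "area_ratio", score = r, stringsAsFactors = FALSE)
}

#' Classify a vessel from its diameter:thickness ratio
#'
#' Encodes the negative result for the traditional criterion: above the
#' threshold a vessel is called a venule, but below it the two classes
#' overlap and no call is made (`indeterminate`).
#'
#' @param record One morphometry record (see [classify_area_ratio()]).
#' @param threshold Decision threshold; default
#'   [DIAMETER_RATIO_SUBGROUP_THRESHOLD].
#' @return A one-row data.frame as in [classify_area_ratio()], with
#'   `criterion = "diameter_ratio"`.
#' @export
classify_diameter_ratio <- function(record,
                                    threshold = DIAMETER_RATIO_SUBGROUP_THRESHOLD) {
  rec <- .as_record(record)
  .refuse_excluded(rec)
  r <- rec$diameter_ratio
  if (!is.finite(r)) stop("diameter_ratio undefined for vessel ", rec$vessel_id)
  cls <- if (r >= threshold) "venule" else "indeterminate"
  data.frame(vessel_id = rec$vessel_id, assigned_class = cls,
             criterion = "diameter_ratio", score = r, stringsAsFactors = FALSE)
}

#' Classify a batch of morphometry records
#'
#' Excluded records are skipped (they are never classified); the number
#' skipped is attached as attribute `"n_excluded"`.
#'
#' @param records data.frame from [measure_batch()].
#' @param criterion `"area_ratio"` (default) or `"diameter_ratio"`.
#' @param rule A [decision_rule()] (area-ratio criterion).
#' @param threshold Threshold (diameter-ratio criterion).
#' @param binary_cutoff Passed to [classify_area_ratio()].
#' @return data.frame of classification results for the non-excluded records.
#' @export
classify_batch <- function(records, criterion = c("area_ratio", "diameter_ratio"),
                           rule = decision_rule(),
                           threshold = DIAMETER_RATIO_SUBGROUP_THRESHOLD,
                           binary_cutoff = NULL) {
  criterion <- match.arg(criterion)
  keep <- !records$excluded
  rows <- lapply(which(keep), function(i) {
    if (criterion == "area_ratio") {
      classify_area_ratio(records[i, ], rule = rule, binary_cutoff = binary_cutoff)
    } else {
      classify_diameter_ratio(records[i, ], threshold = threshold)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vessel_id = character(), assigned_class = character(),
               criterion = character(), score = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Overlap of two groups' observed ranges
#'
#' Intersects the `[min, max]` envelopes of two samples of a metric. Two
#' groups are separable by a range criterion exactly when their envelopes do
#' not overlap.
#'
#' @param values_g1,values_g2 Non-empty numeric vectors.
#' @return A list: `overlaps` (logical) and `interval` (`c(lo, hi)` when they
#'   overlap, `numeric(0)` otherwise).
#' @export
range_overlap <- function(values_g1, values_g2) {
  if (!length(values_g1) || !length(values_g2)) {
    stop("range_overlap: both groups must be non-empty")
  }
  if (!all(is.finite(values_g1)) || !all(is.finite(values_g2))) {
    stop("range_overlap: values must be finite")
  }
  lo <- max(min(values_g1), min(values_g2))
  hi <- min(max(values_g1), max(values_g2))
  if (lo <= hi) {
    list(overlaps = TRUE, interval = c(lo, hi))
  } else {
    list(overlaps = FALSE, interval = numeric(0))
  }
}
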