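#' Aggregate spot-level results to patients
#'
#' When a patient has several evaluable tissue cores, the highest
#' non-missing extent and the highest non-missing intensity are taken --
#' independently, so a patient's extent and intensity may come from
#' different cores. A variable is missing at the patient level only when it
#' is missing for every core.
#'
#' @param spots Data frame with columns `spot_id`, `extent`, `intensity`
#'   (and optionally `patient_id`).
#' @param manifest Optional data frame with columns `spot_id`, `patient_id`
#'   mapping spots to patients; required if `spots` lacks `patient_id`.
#'   A spot absent from the manifest is an error.
#' @return Data frame with one row per patient: `patient_id`, `n_spots`,
#'   `extent`, `intensity`, ordered by patient id.
#' @examples
#' spots <- data.frame(spot_id = c("a", "b"), patient_id = "p1",
#'                     extent = c(2.0, 5.5), intensity = c(40, NA))
#' aggregate_patients(spots)   # extent 5.5, intensity 40
#' @export
aggregate_patients <- function(spots, manifest = NULL) {
  stopifnot(is.data.frame(spots),
            all(c("spot_id", "extent", "intensity") %in% names(spots)))
  if (!is.null(manifest)) {
    stopifnot(all(c("spot_id", "patient_id") %in% names(manifest)))
    idx <- match(spots$spot_id, manifest$spot_id)
    if (anyNA(idx)) {
      stop("spot(s) with unknown patient: ",
           paste(spots$spot_id[is.na(idx)], collapse = ", "))
    }
    spots$patient_id <- manifest$patient_id[idx]
  } else if (!"patient_id" %in% names(spots)) {
    stop("spots must carry a patient_id column or a manifest must be given")
  }
  max_na <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  ids <- sort(unique(as.character(spots$patient_id)))
  grp <- split(spots, factor(as.character(spots$patient_id), levels = ids))
  data.frame(
    patient_id = ids,
    n_spots = vapply(grp, nrow, integer(1)),
    extent = vapply(grp, function(g) max_na(g$extent), numeric(1)),
    intensity = vapply(grp, function(g) max_na(g$intensity), numeric(1)),
    row.names = NULL
  )
}

#' Split values into ordered groups of stated proportions
#'
#' Computes the two cut points that divide the non-missing values into
#' low / moderate / high groups of the requested proportions. The cut
#' points are empirical quantiles of inverse-CDF type (the smallest data
#' value whose cumulative fraction reaches the target), so they are always
#' actual data values, and ties at a cut point all fall into the lower
#' group. Group sizes therefore match the targets exactly on tie-free data
#' and within the tie-run length otherwise.
#'
#' @param values Numeric vector (NAs are dropped).
#' @param proportions Length-3 non-negative vector summing to 1 (a sum
#'   within 0.01 of 1, as happens with rounded printed percentages, is
#'   renormalized).
#' @return A list of class `"group_split"`: `thresholds` (lower, upper cut
#'   points), `counts` (group sizes over the non-missing values), `n`.
#' @examples
#' proportion_split(1:9, rep(1, 3) / 3)$counts    # 3 3 3
#' @export
proportion_split <- function(values, proportions) {
  proportions <- as.numeric(proportions)
  if (length(proportions) != 3L || any(!is.finite(proportions)) ||
      any(proportions < 0) || abs(sum(proportions) - 1) > 0.01) {
    stop("proportions must be three non-negative values summing to 1")
  }
  # tolerate printed-percentage rounding (e.g. 7.7/55.7/36.7 sums to 100.1)
  proportions <- proportions / sum(proportions)
  x <- values[!is.na(values)]
  if (length(x) < 3L) stop("need at least 3 non-missing values")
  if (length(unique(x)) == 1L) stop("no variation in values")
  q <- stats::quantile(x, cumsum(proportions)[1:2], type = 1, names = FALSE)
  n_low <- sum(x <= q[1])
  n_mod <- sum(x <= q[2]) - n_low
  structure(list(thresholds = q,
                 counts = c(low = n_low, moderate = n_mod,
                            high = length(x) - n_low - n_mod),
                 n = length(x)),
            class = "group_split")
}

#' Split values into tertiles
#'
#' Convenience wrapper for [proportion_split()] with equal proportions:
#' three approximately equally sized ordered groups cut at the 1/3 and 2/3
#' empirical quantiles.
#'
#' @inheritParams proportion_split
#' @return A `"group_split"` (see [proportion_split()]).
#' @export
tertile_split <- function(values) {
  proportion_split(values, rep(1, 3) / 3)
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("split of %d values at thresholds (%.4g, %.4g); sizes %d/%d/%d\n",
              x$n, x$thresholds[1], x$thresholds[2],
              x$counts[1], x$counts[2], x$counts[3]))
  invisible(x)
}

#' Assign ordinal expression groups from two cut points
#'
#' Values are rounded to one decimal before comparison, matching the
#' one-decimal granularity at which cut points are conventionally reported
#' (a boundary pair like 2.3/6.3 means "0 to 2.3" is low, "2.4 to 6.3"
#' moderate, "6.4 up" high). A value is `low` iff it is `<=` the lower cut
#' point, `moderate` iff it is above the lower and `<=` the upper, `high`
#' otherwise. Missing values yield `NA`.
#'
#' @param values Numeric vector of percents.
#' @param thresholds Length-2 numeric, lower then upper cut point
#'   (lower < upper), e.g. `split$thresholds` from [tertile_split()].
#' @param digits Decimals to round values to before comparison (default 1).
#' @return Ordered factor with levels `low < moderate < high`.
#' @examples
#' assign_groups(c(2.3, 2.4, 6.3, 6.4), c(2.3, 6.3))
#' @export
assign_groups <- function(values, thresholds, digits = 1) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 2L || any(!is.finite(thresholds)) ||
      thresholds[1] >= thresholds[2]) {
    stop("thresholds must be two finite values with lower < upper")
  }
  v <- round(as.numeric(values), digits)
  g <- ifelse(is.na(v), NA_character_,
       ifelse(v <= thresholds[1], "low",
       ifelse(v <= thresholds[2], "moderate", "high")))
  factor(g, levels = c("low", "moderate", "high"), ordered = TRUE)
}
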