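# Writes a data frame as CSV preceded by '#'-prefixed header lines echoing
# the run configuration, so every output records how it was produced.
write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

read_result_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

fmt_vec <- function(v) paste(sprintf("%.6f", v), collapse = " ")

#' Batch-analyse a directory of spot images
#'
#' Runs [analyze_spot()] on every PNG/TIFF in a directory and writes one
#' CSV row per image. Unreadable or malformed images never abort the batch:
#' they are logged, counted, and emitted with status `"failed"` and empty
#' statistics. Missing extent/intensity values are written as empty fields,
#' never as 0, so blanks remain distinguishable from true zeros. The CSV is
#' preceded by `#` header lines echoing the stain vectors and thresholds
#' used.
#'
#' @param input_dir Directory of spot images.
#' @param output_csv Path of the spot-result CSV to write.
#' @param m Stain matrix (default [hdab_stain_matrix()]).
#' @param thresholds A [threshold_config()].
#' @param qc_dir If non-`NULL`, pseudocoloured result images (red = DAB,
#'   green = H-only, white = background) are written there, one PNG per
#'   spot -- the overlay to inspect when calibrating thresholds.
#' @param pattern Regular expression selecting image files.
#' @return Invisibly, the spot-result data frame (`spot_id`, pixel counts,
#'   `extent`, `intensity`, `status`).
#' @export
run_analyze <- function(input_dir, output_csv,
                        m = hdab_stain_matrix(),
                        thresholds = threshold_config(),
                        qc_dir = NULL,
                        pattern = "\\.(png|tif|tiff)$") {
  if (!dir.exists(input_dir)) stop("input directory does not exist: ", input_dir)
  files <- sort(list.files(input_dir, pattern = pattern,
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no images found in ", input_dir)
  if (!is.null(qc_dir) && !dir.exists(qc_dir)) dir.create(qc_dir, recursive = TRUE)
  rows <- vector("list", length(files))
  n_failed <- 0L
  for (i in seq_along(files)) {
    sid <- tools::file_path_sans_ext(basename(files[i]))
    res <- tryCatch({
      img <- read_spot_image(files[i])
      r <- analyze_spot(img, m = m, thresholds = thresholds, spot_id = sid,
                        keep_image = !is.null(qc_dir))
      if (!is.null(qc_dir)) {
        write_spot_image(result_to_rgb(r$labels),
                         file.path(qc_dir, paste0(sid, "_result.png")))
      }
      data.frame(spot_id = sid, n_h_only = r$n_h_only, n_dab = r$n_dab,
                 n_union = r$n_union, extent = r$extent,
                 intensity = r$intensity, status = "ok")
    }, error = function(e) {
      warning("spot ", sid, " failed: ", conditionMessage(e), call. = FALSE)
      data.frame(spot_id = sid, n_h_only = NA_integer_, n_dab = NA_integer_,
                 n_union = NA_integer_, extent = NA_real_,
                 intensity = NA_real_, status = "failed")
    })
    if (res$status == "failed") n_failed <- n_failed + 1L
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  header <- c("ihcquant spot analysis",
              paste("stain_h:", fmt_vec(m$M[1, ])),
              paste("stain_dab:", fmt_vec(m$M[2, ])),
              paste("threshold_h:", thresholds$h),
              paste("threshold_dab:", thresholds$dab))
  write_csv_with_header(out, output_csv, header)
  ok <- out$status == "ok"
  message(sprintf(
    "analysed %d spot(s), %d failed; extent mean %.1f%%, median %.1f%%",
    sum(ok), n_failed,
    mean(out$extent[ok], na.rm = TRUE), stats::median(out$extent[ok], na.rm = TRUE)))
  invisible(out)
}

#' Aggregate a spot-result CSV to patients and assign expression groups
#'
#' Joins spot results to patients through a manifest, takes the per-patient
#' maxima (see [aggregate_patients()]), derives low/moderate/high cut
#' points independently for extent and intensity by the chosen grouping
#' mode, and writes a patient-level CSV.
#'
#' @param spot_csv Spot-result CSV from [run_analyze()].
#' @param manifest_csv CSV with columns `spot_id`, `patient_id`.
#' @param output_csv Path of the patient-level CSV to write.
#' @param grouping `"tertile"` (cut at the 1/3 and 2/3 quantiles),
#'   `"proportions"` (cut at the cumulative quantiles of `proportions`),
#'   or `"fixed"` (use the supplied cut points directly).
#' @param proportions Length-3 proportions for `grouping = "proportions"`.
#' @param extent_thresholds,intensity_thresholds Length-2 cut points for
#'   `grouping = "fixed"`; a variable with `NULL` thresholds is left
#'   ungrouped.
#' @return Invisibly, the patient data frame (`patient_id`, `n_spots`,
#'   `extent`, `intensity`, `extent_group`, `intensity_group`).
#' @export
run_aggregate <- function(spot_csv, manifest_csv, output_csv,
                          grouping = c("tertile", "proportions", "fixed"),
                          proportions = NULL,
                          extent_thresholds = NULL,
                          intensity_thresholds = NULL) {
  grouping <- match.arg(grouping)
  spots <- read_result_csv(spot_csv)
  manifest <- read_result_csv(manifest_csv)
  for (col in c("spot_id", "patient_id")) {
    if (!col %in% names(manifest)) stop("manifest is missing column: ", col)
  }
  for (col in c("spot_id", "extent", "intensity")) {
    if (!col %in% names(spots)) stop("spot CSV is missing column: ", col)
  }
  pat <- aggregate_patients(spots, manifest)
  cuts_for <- function(values, fixed) {
    switch(grouping,
      tertile = tertile_split(values)$thresholds,
      proportions = {
        if (is.null(proportions)) stop("grouping 'proportions' needs proportions")
        proportion_split(values, proportions)$thresholds
      },
      fixed = fixed)
  }
  ec <- cuts_for(pat$extent, extent_thresholds)
  ic <- cuts_for(pat$intensity, intensity_thresholds)
  pat$extent_group <- if (is.null(ec)) NA else as.character(assign_groups(pat$extent, ec))
  pat$intensity_group <- if (is.null(ic)) NA else as.character(assign_groups(pat$intensity, ic))
  header <- c("ihcquant patient aggregation",
              paste("grouping:", grouping),
              paste("extent_thresholds:",
                    if (is.null(ec)) "none" else paste(ec, collapse = " ")),
              paste("intensity_thresholds:",
                    if (is.null(ic)) "none" else paste(ic, collapse = " ")))
  write_csv_with_header(pat, output_csv, header)
  invisible(pat)
}

#' Compare automated groups with visual categories
#'
#' Builds the automated-vs-visual contingency table from a patient-level
#' CSV and a visual-score CSV, computes linearly weighted agreement
#' statistics, prints the table, and writes the table (CSV) and statistics
#' (JSON) next to the given output prefix.
#'
#' @param patient_csv Patient CSV from [run_aggregate()].
#' @param visual_csv CSV with columns `patient_id` and a visual category
#'   column.
#' @param output_prefix Path prefix; writes `<prefix>_table.csv` and
#'   `<prefix>_stats.json`.
#' @param auto_col Column of `patient_csv` holding the automated group
#'   (default `"extent_group"`).
#' @param visual_col Column of `visual_csv` holding the visual category.
#' @param auto_levels,visual_levels Ordered category labels of each rater.
#' @return Invisibly, a list with the `"agreement_table"` and the
#'   `"agreement_stats"`.
#' @export
run_agreement <- function(patient_csv, visual_csv, output_prefix,
                          auto_col = "extent_group",
                          visual_col = "visual_category",
                          auto_levels = c("low", "moderate", "high"),
                          visual_levels = c("negative", "moderate", "high")) {
  pat <- read_result_csv(patient_csv)
  vis <- read_result_csv(visual_csv)
  if (!auto_col %in% names(pat)) stop("patient CSV is missing column: ", auto_col)
  if (!visual_col %in% names(vis)) stop("visual CSV is missing column: ", visual_col)
  if (!"patient_id" %in% names(vis)) stop("visual CSV is missing column: patient_id")
  tab <- build_contingency(
    data.frame(patient_id = pat$patient_id, group = pat[[auto_col]]),
    data.frame(patient_id = vis$patient_id, category = vis[[visual_col]]),
    auto_levels = auto_levels, visual_levels = visual_levels)
  stats <- weighted_agreement(tab)
  print(tab)
  print(stats)
  utils::write.csv(as.data.frame(unclass(tab)),
                   paste0(output_prefix, "_table.csv"))
  jsonlite::write_json(
    list(n = stats$n, k = stats$k,
         observed_weighted = stats$observed_weighted,
         expected_weighted = stats$expected_weighted,
         kappa_weighted = stats$kappa_weighted,
         observed_unweighted = stats$observed_unweighted,
         percent_agreement = round(100 * stats$observed_weighted),
         kappa_rounded = round(stats$kappa_weighted, 2),
         n_dropped = attr(tab, "n_dropped")),
    paste0(output_prefix, "_stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(table = tab, stats = stats))
}

#' Generate a synthetic cohort dataset on disk
#'
#' Wraps [generate_cohort()] and additionally writes `visual.csv`, a
#' truth-derived ordinal score per patient (tertiles of the true
#' per-patient maximum extent, labelled negative/moderate/high), usable as
#' a reference rater for end-to-end agreement runs.
#'
#' @param output_dir Directory to create the dataset in.
#' @param n_patients Number of patients.
#' @param seed RNG seed for the whole dataset.
#' @param ... Passed to [generate_cohort()].
#' @return Invisibly, the [generate_cohort()] result.
#' @export
run_simulate <- function(output_dir, n_patients = 60, seed = 1, ...) {
  res <- generate_cohort(output_dir, n_patients = n_patients, seed = seed, ...)
  per_pat <- unique(res$truth[c("patient_id", "patient_max_extent")])
  cuts <- tertile_split(per_pat$patient_max_extent)$thresholds
  grp <- assign_groups(per_pat$patient_max_extent, cuts)
  vis <- data.frame(
    patient_id = per_pat$patient_id,
    visual_category = c(low = "negative", moderate = "moderate",
                        high = "high")[as.character(grp)])
  utils::write.csv(vis, file.path(output_dir, "visual.csv"), row.names = FALSE)
  invisible(res)
}
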