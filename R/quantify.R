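#' Threshold configuration for the two stain channels
#'
#' Thresholds are expressed on the 8-bit pseudo-transmittance channel images
#' produced by [deconvolve()], where 255 = no stain; a pixel counts as
#' stain-positive when its channel value is strictly below the threshold.
#' The defaults (200/200) detect any pixel whose stain amount exceeds
#' roughly 0.1 OD. For real material the thresholds should be calibrated on
#' a few test spots (see [run_analyze()]'s QC overlays) and then kept
#' constant across the whole batch -- constancy, not the particular value,
#' is what makes results comparable across a series.
#'
#' @param h Threshold for the haematoxylin channel, 0..255.
#' @param dab Threshold for the DAB channel, 0..255.
#' @return A list with elements `h` and `dab`, class `"threshold_config"`.
#' @export
threshold_config <- function(h = 200, dab = 200) {
  for (t in c(h, dab)) {
    if (length(t) != 1L || !is.finite(t) || t < 0 || t > 255) {
      stop("thresholds must be single values in [0, 255]")
    }
  }
  structure(list(h = h, dab = dab), class = "threshold_config")
}

#' Threshold a stain channel image into a binary mask
#'
#' @param ch Numeric `h x w` channel matrix (0..255, 255 = no stain).
#' @param t Threshold in 0..255; a pixel is positive iff its value is
#'   strictly less than `t` (darker than the threshold).
#' @return Logical `h x w` matrix, `TRUE` = stain-positive.
#' @examples
#' threshold_channel(matrix(c(199, 200, 201), 1), 200)  # TRUE FALSE FALSE
#' @export
threshold_channel <- function(ch, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0 || t > 255) {
    stop("threshold must be a single value in [0, 255]")
  }
  ch < t
}

#' Merge H and DAB masks into a labelled result image
#'
#' Per-pixel label: `DAB` wherever the DAB mask is positive (regardless of
#' H status), `H_ONLY` where only the H mask is positive, `BACKGROUND`
#' elsewhere. The conventional rendering (see [result_to_rgb()]) is red for
#' DAB, green for H-only, white for background.
#'
#' @param h,dab Logical masks of identical dimensions.
#' @return Integer `h x w` matrix of class `"result_labels"` with codes
#'   0 = BACKGROUND, 1 = H_ONLY, 2 = DAB.
#' @export
merge_masks <- function(h, dab) {
  if (!identical(dim(h), dim(dab))) stop("mask dimension mismatch")
  lab <- matrix(0L, nrow(h), ncol(h))
  lab[h] <- 1L
  lab[dab] <- 2L
  structure(lab, class = "result_labels")
}

#' Render a labelled result image to RGB
#'
#' @param labels A `"result_labels"` matrix from [merge_masks()].
#' @return Numeric `h x w x 3` array (0..255): green (0,255,0) = H-only,
#'   red (255,0,0) = DAB, white = background.
#' @export
result_to_rgb <- function(labels) {
  pal <- rbind(c(255, 255, 255),  # 0 background
               c(0,   255, 0),    # 1 H only
               c(255, 0,   0))    # 2 DAB
  idx <- unclass(labels) + 1L
  array(c(pal[idx, 1], pal[idx, 2], pal[idx, 3]),
        dim = c(nrow(labels), ncol(labels), 3L))
}

#' Extent of staining
#'
#' The fraction of stained tissue that is DAB-positive: the number of
#' DAB-positive pixels divided by the number of pixels in the union of the
#' H-positive and DAB-positive areas, as a percent. This is the primary
#' per-spot statistic; using the union in the denominator makes it a
#' proportion of the stained (roughly, cellular) area rather than of the
#' whole spot.
#'
#' @param h,dab Logical masks of identical dimensions.
#' @return Percent in 0..100, or `NA` if no pixel is stained at all.
#' @export
compute_extent <- function(h, dab) {
  if (!identical(dim(h), dim(dab))) stop("mask dimension mismatch")
  n_union <- sum(h | dab)
  if (n_union == 0L) return(NA_real_)
  100 * sum(dab) / n_union
}

#' Intensity of DAB staining
#'
#' Mean pixel value of the DAB channel image over the DAB-positive area,
#' rescaled so 0% = no stain (channel value 255) and 100% = maximal stain
#' (channel value 0): `100 * (255 - mean) / 255`.
#'
#' @param dab_channel Numeric `h x w` DAB channel matrix (0..255).
#' @param dab Logical DAB mask of identical dimensions.
#' @return Percent in 0..100, or `NA` if the mask is empty.
#' @export
compute_intensity <- function(dab_channel, dab) {
  if (!identical(dim(dab_channel), dim(dab))) stop("mask dimension mismatch")
  if (!any(dab)) return(NA_real_)
  100 * (255 - mean(dab_channel[dab])) / 255
}

#' Analyse one IHC spot image
#'
#' Runs the full per-spot pipeline: RGB to optical density, colour
#' deconvolution into H and DAB channels, fixed thresholding of each
#' channel, and computation of the extent and intensity statistics plus the
#' pseudocoloured QC result image.
#'
#' @param img Numeric `h x w x 3` RGB array (0..255), e.g. from
#'   [read_spot_image()].
#' @param m A `"stain_matrix"` (default [hdab_stain_matrix()]).
#' @param thresholds A [threshold_config()].
#' @param spot_id Identifier carried into the result.
#' @param keep_image If `TRUE`, the labelled result image is kept in the
#'   `labels` field (memory-heavy for large batches; off by default).
#' @return A list of class `"spot_result"` with fields `spot_id`, `width`,
#'   `height`, `n_h_only`, `n_dab`, `n_union`, `n_background`, `extent`,
#'   `intensity` and (optionally) `labels`. `extent` is `NA` iff nothing is
#'   stained; `intensity` is `NA` iff nothing is DAB-positive.
#' @examples
#' white <- array(255, dim = c(16, 16, 3))
#' analyze_spot(white)$n_union    # 0: nothing stained
#' @export
analyze_spot <- function(img, m = hdab_stain_matrix(),
                         thresholds = threshold_config(),
                         spot_id = NA_character_, keep_image = FALSE) {
  stopifnot(inherits(thresholds, "threshold_config"))
  od <- rgb_to_od(img)
  ch <- deconvolve(od, m)
  h_mask <- threshold_channel(ch[[1L]], thresholds$h)
  dab_mask <- threshold_channel(ch[[2L]], thresholds$dab)
  n_dab <- sum(dab_mask)
  n_h_only <- sum(h_mask & !dab_mask)
  n_union <- n_h_only + n_dab
  res <- list(
    spot_id = spot_id,
    width = ncol(h_mask), height = nrow(h_mask),
    n_h_only = n_h_only, n_dab = n_dab, n_union = n_union,
    n_background = length(h_mask) - n_union,
    extent = compute_extent(h_mask, dab_mask),
    intensity = compute_intensity(ch[[2L]], dab_mask)
  )
  if (keep_image) res$labels <- merge_masks(h_mask, dab_mask)
  structure(res, class = "spot_result")
}

#' @export
print.spot_result <- function(x, ...) {
  cat(sprintf("spot %s (%dx%d): DAB %d px, H-only %d px, union %d px\n",
              x$spot_id, x$width, x$height, x$n_dab, x$n_h_only, x$n_union))
  cat(sprintf("  extent: %s  intensity: %s\n",
              if (is.na(x$extent)) "NA" else sprintf("%.2f%%", x$extent),
              if (is.na(x$intensity)) "NA" else sprintf("%.2f%%", x$intensity)))
  invisible(x)
}
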