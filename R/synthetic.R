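# Adds `load` OD units to `acc` over a filled rotated ellipse centred at
# (cx, cy) with semi-axes a >= b and orientation theta. Returns the updated
# accumulator; pixel centres at integer coordinates.
fill_ellipse <- function(acc, cx, cy, a, b, theta, load) {
  r <- ceiling(max(a, b))
  rows <- max(1L, floor(cy - r)):min(nrow(acc), ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(ncol(acc), ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  # rotated coordinates: u along the major axis, v along the minor axis
  u <- outer(dy, dx, function(y, x) x * ct + y * st)
  v <- outer(dy, dx, function(y, x) -x * st + y * ct)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- acc[rows, cols, drop = FALSE]
  sub[inside] <- sub[inside] + load
  acc[rows, cols] <- sub
  acc
}

#' Render a synthetic brightfield H+DAB spot with known ground truth
#'
#' Simulates an IHC-stained tissue spot by forward Beer-Lambert physics:
#' nuclei are drawn as filled ellipses accumulating haematoxylin (all
#' nuclei) and DAB (a chosen fraction of nuclei) optical-density loads --
#' loads add where nuclei overlap -- and each RGB channel is rendered as
#' `round(255 * 10^(-OD_channel))` with optional additive Gaussian sensor
#' noise, clamped to 0..255. Ground-truth masks, extent and intensity are
#' recorded from the noise-free OD fields using the same union formula as
#' [compute_extent()].
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei Number of nuclei to place (overlaps allowed, all fully
#'   inside the image).
#' @param dab_fraction Proportion of nuclei that are DAB-positive (Ki-67
#'   expressing); the count is `round(n_nuclei * dab_fraction)`.
#' @param h_od Mean haematoxylin OD load per nucleus (every nucleus is
#'   counterstained).
#' @param dab_od Mean DAB OD load per DAB-positive nucleus.
#' @param noise_sigma Additive Gaussian noise SD in 8-bit grey levels
#'   (default 0).
#' @param seed Optional RNG seed; a fixed seed makes the image
#'   bit-reproducible.
#' @param m Stain matrix supplying the H and DAB OD vectors.
#' @param axis_range Range of full ellipse axes in pixels (default 8..16,
#'   loosely nucleus-sized at 0.26 um/px).
#' @return A list with `image` (`h x w x 3`, 0..255) and `truth`, itself a
#'   list: `mask_h_only`, `mask_dab` (logical matrices), `true_extent`,
#'   `true_intensity` (percent, `NA` when undefined).
#' @examples
#' sp <- render_spot(64, 64, n_nuclei = 20, dab_fraction = 0.5, seed = 1)
#' sp$truth$true_extent
#' @export
render_spot <- function(width = 256, height = 256, n_nuclei = 150,
                        dab_fraction = 0.3, h_od = 0.6, dab_od = 0.8,
                        noise_sigma = 0, seed = NULL,
                        m = hdab_stain_matrix(), axis_range = c(8, 16)) {
  stopifnot(width >= 1, height >= 1, n_nuclei >= 0,
            dab_fraction >= 0, dab_fraction <= 1,
            h_od >= 0, dab_od >= 0, noise_sigma >= 0,
            length(axis_range) == 2L, axis_range[1] <= axis_range[2])
  if (!is.null(seed)) set.seed(seed)
  semi_max <- axis_range[2] / 2
  if (2 * ceiling(semi_max) + 2 > min(width, height)) {
    stop("nuclei too large for image")
  }
  AH <- matrix(0, height, width)
  AD <- matrix(0, height, width)
  if (n_nuclei > 0) {
    n_dab <- round(n_nuclei * dab_fraction)
    dab_idx <- if (n_dab > 0) sample.int(n_nuclei, n_dab) else integer(0)
    for (i in seq_len(n_nuclei)) {
      a <- stats::runif(1, axis_range[1] / 2, axis_range[2] / 2)
      b <- stats::runif(1, axis_range[1] / 2, a)
      r <- ceiling(a)
      cx <- stats::runif(1, r + 1, width - r)
      cy <- stats::runif(1, r + 1, height - r)
      th <- stats::runif(1, 0, pi)
      jit <- stats::runif(1, 0.85, 1.15)
      if (i %in% dab_idx) {
        AD <- fill_ellipse(AD, cx, cy, a, b, th, dab_od * jit)
        AH <- fill_ellipse(AH, cx, cy, a, b, th,
                           h_od * stats::runif(1, 0.85, 1.15))
      } else {
        AH <- fill_ellipse(AH, cx, cy, a, b, th, h_od * jit)
      }
    }
  }
  vh <- m$M[1, ]
  vd <- m$M[2, ]
  img <- array(0, dim = c(height, width, 3L))
  for (c in 1:3) {
    img[, , c] <- round(255 * 10^(-(AH * vh[c] + AD * vd[c])))
  }
  if (noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sigma)
    img <- round(pmin(pmax(img, 0), 255))
  }
  mask_dab <- AD > 0
  mask_h_only <- AH > 0 & !mask_dab
  union_n <- sum(mask_dab | mask_h_only)
  truth <- list(
    mask_h_only = mask_h_only,
    mask_dab = mask_dab,
    true_extent = if (union_n == 0L) NA_real_
                  else 100 * sum(mask_dab) / union_n,
    true_intensity = if (!any(mask_dab)) NA_real_
                     else 100 * (255 - mean(255 * 10^(-AD[mask_dab]))) / 255
  )
  list(image = img, truth = truth)
}

#' Generate a synthetic TMA cohort with images, manifest and ground truth
#'
#' Emulates a tissue-microarray study: each patient contributes 1-4 cores
#' (spot images) whose DAB-positive nucleus fraction is set from a
#' patient-level target extent with small between-core jitter. Writes one
#' PNG per spot plus `manifest.csv` (spot_id, patient_id, file) and
#' `truth.csv` (per-spot recorded ground truth and the per-patient maxima,
#' mirroring the highest-core aggregation rule).
#'
#' The default cores-per-patient distribution matches a large published TMA
#' series (79% single, 19% duplicate, 1.6% triplicate, 0.5% quadruplicate
#' cores among readable cases).
#'
#' @param dir Output directory (created if needed).
#' @param n_patients Number of patients (>= 1).
#' @param cores_prob Probabilities of 1..4 cores per patient.
#' @param extent_sampler Function of `n` returning per-patient target
#'   extents in percent (default uniform on 0..95, spanning the dynamic
#'   range observed in real Ki-67 material).
#' @param core_jitter_sd SD (percentage points) of the between-core
#'   deviation from the patient target extent (default 2).
#' @param seed RNG seed; all randomness (patients, cores, nuclei, noise)
#'   flows from it.
#' @param width,height,n_nuclei,noise_sigma,m,... Passed to [render_spot()].
#' @return Invisibly, a list with `manifest` and `truth` data frames and
#'   `dir`.
#' @export
generate_cohort <- function(dir, n_patients = 60,
                            cores_prob = c(0.791, 0.188, 0.016, 0.005),
                            extent_sampler = function(n) stats::runif(n, 0, 95),
                            core_jitter_sd = 2, seed = NULL,
                            width = 256, height = 256, n_nuclei = 150,
                            noise_sigma = 0, m = hdab_stain_matrix(), ...) {
  stopifnot(n_patients >= 1, length(cores_prob) == 4L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  targets <- extent_sampler(n_patients)
  n_cores <- sample.int(4L, n_patients, replace = TRUE, prob = cores_prob)
  manifest <- NULL
  truth <- NULL
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (k in seq_len(n_cores[p])) {
      e <- min(max(targets[p] + stats::rnorm(1, 0, core_jitter_sd), 0), 95)
      sid <- sprintf("%s_c%d", pid, k)
      sp <- render_spot(width = width, height = height, n_nuclei = n_nuclei,
                        dab_fraction = e / 100, noise_sigma = noise_sigma,
                        m = m, ...)
      file <- file.path(dir, paste0(sid, ".png"))
      write_spot_image(sp$image, file)
      manifest <- rbind(manifest,
                        data.frame(spot_id = sid, patient_id = pid,
                                   file = basename(file)))
      truth <- rbind(truth,
                     data.frame(spot_id = sid, patient_id = pid,
                                true_extent = sp$truth$true_extent,
                                true_intensity = sp$truth$true_intensity))
    }
  }
  max_na <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  pmax_e <- tapply(truth$true_extent, truth$patient_id, max_na)
  pmax_i <- tapply(truth$true_intensity, truth$patient_id, max_na)
  truth$patient_max_extent <- as.numeric(pmax_e[truth$patient_id])
  truth$patient_max_intensity <- as.numeric(pmax_i[truth$patient_id])
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, truth = truth, dir = dir))
}
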