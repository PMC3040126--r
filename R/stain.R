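#' Build a unit-normalized stain optical-density vector
#'
#' A stain vector gives the relative absorbance of a pure stain in the R, G
#' and B channels, expressed in optical density (OD) units and normalized to
#' unit Euclidean length. Stain contributions are additive in OD space
#' (Beer-Lambert law), which is what makes linear unmixing possible.
#'
#' @param name Stain label, e.g. `"haematoxylin"` or `"dab"`.
#' @param od Numeric length-3 vector of per-channel optical densities.
#' @return A named list with elements `name` and `od` (unit-normalized),
#'   of class `"stain_vector"`.
#' @examples
#' stain_vector("haematoxylin", c(0.650, 0.704, 0.286))
#' @export
stain_vector <- function(name, od) {
  stopifnot(is.character(name), length(name) == 1L)
  od <- as.numeric(od)
  if (length(od) != 3L || any(!is.finite(od))) {
    stop("stain vector must be a finite numeric triple")
  }
  nrm <- sqrt(sum(od^2))
  if (nrm < 1e-12) stop("stain vector has zero length")
  structure(list(name = name, od = od / nrm), class = "stain_vector")
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("stain '%s': OD (R,G,B) = (%.4f, %.4f, %.4f)\n",
              x$name, x$od[1], x$od[2], x$od[3]))
  invisible(x)
}

#' Build a 3x3 stain matrix from haematoxylin and DAB vectors
#'
#' Completes a two-stain system to a full basis of OD space by adding a
#' residual vector (the normalized cross product of the two stain vectors,
#' hence orthogonal to both) and precomputes the unmixing inverse. Rows of
#' the matrix are the unit stain vectors in the order haematoxylin, DAB,
#' residual.
#'
#' @param h Haematoxylin OD triple (numeric length 3) or a
#'   [stain_vector()].
#' @param dab DAB OD triple or a [stain_vector()].
#' @return An object of class `"stain_matrix"`: a list with `M` (3x3 matrix,
#'   rows = unit stain vectors), `Minv` (its inverse, used for unmixing) and
#'   `stains` (labels).
#' @examples
#' m <- build_stain_matrix(c(1, 0, 0), c(0, 1, 0))
#' m$M            # identity: orthonormal toy basis
#' @seealso [hdab_stain_matrix()] for the default H+DAB pair.
#' @export
build_stain_matrix <- function(h, dab) {
  hv <- if (inherits(h, "stain_vector")) h else stain_vector("haematoxylin", h)
  dv <- if (inherits(dab, "stain_vector")) dab else stain_vector("dab", dab)
  a <- hv$od
  b <- dv$od
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  crn <- sqrt(sum(cr^2))
  if (crn < 1e-6) stop("degenerate stain pair")
  r <- cr / crn
  M <- rbind(a, b, r)
  dimnames(M) <- list(c(hv$name, dv$name, "residual"), c("R", "G", "B"))
  if (abs(det(M)) < 1e-9) stop("degenerate stain pair")
  Minv <- solve(M)
  structure(list(M = M, Minv = Minv,
                 stains = c(hv$name, dv$name, "residual")),
            class = "stain_matrix")
}

#' Default haematoxylin + DAB stain matrix
#'
#' The widely published H-DAB pair H = (0.650, 0.704, 0.286),
#' DAB = (0.268, 0.570, 0.776), unit-normalized, with the residual channel
#' completing the basis. Override by building your own matrix from measured
#' vectors with [build_stain_matrix()] or [read_stain_config()].
#'
#' @return A `"stain_matrix"` object.
#' @export
hdab_stain_matrix <- function() {
  build_stain_matrix(c(0.650, 0.704, 0.286), c(0.268, 0.570, 0.776))
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("stain matrix (rows = unit OD vectors):\n")
  print(round(x$M, 4))
  invisible(x)
}

#' Read stain vectors from a plain-text config file
#'
#' The file holds one stain per line: a label followed by three OD
#' components, whitespace-separated. The first line is taken as the
#' haematoxylin-like counterstain, the second as the DAB-like chromogen.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return A `"stain_matrix"` object.
#' @export
read_stain_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) != 2L) {
    stop("stain config must contain exactly two stain lines (counterstain, chromogen)")
  }
  parse1 <- function(s) {
    parts <- strsplit(s, "[[:space:]]+")[[1]]
    if (length(parts) != 4L) stop("malformed stain line: ", s)
    stain_vector(parts[1], as.numeric(parts[2:4]))
  }
  build_stain_matrix(parse1(ln[1]), parse1(ln[2]))
}

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert relation per channel:
#' `od = -log10(max(v, 1) / background)`. Pixel values are clamped to a
#' minimum of 1 before the logarithm so the OD stays finite; with the
#' default background of 255 the maximum representable OD is
#' `log10(255) ~ 2.41`.
#'
#' @param img Numeric array of dimension `h x w x 3` (or `h x w x 4`; an
#'   alpha channel is dropped) with values in 0..255.
#' @param background Incident-light intensity I0 in 1..255 (default 255,
#'   i.e. a pure-white background has zero absorbance).
#' @return Numeric `h x w x 3` array of non-negative optical densities.
#' @examples
#' px <- array(c(25, 255, 255), dim = c(1, 1, 3))
#' rgb_to_od(px)[1, 1, ]   # (1.0086, 0, 0)
#' @export
rgb_to_od <- function(img, background = 255) {
  if (is.null(dim(img)) || length(img) == 0L) stop("empty input image")
  d <- dim(img)
  if (length(d) == 2L) stop("grayscale input not supported; expected an RGB image")
  if (length(d) != 3L || d[3] < 3L) {
    stop("expected an RGB image with 3 channels, got ", d[3], " channel(s)")
  }
  if (d[1] == 0L || d[2] == 0L) stop("empty input image")
  if (d[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (length(background) != 1L || !is.finite(background) ||
      background < 1 || background > 255) {
    stop("background intensity must be a single value in [1, 255]")
  }
  if (any(img < 0 | img > 255)) stop("pixel values must lie in [0, 255]")
  -log10(pmax(img, 1) / background)
}

#' Unmix an optical-density image into per-stain amounts
#'
#' Solves the linear Beer-Lambert mixing model per pixel: the OD triple is
#' decomposed onto the three stain vectors of the matrix; negative amounts
#' (which arise from noise and quantization, not physics) are clamped to 0.
#'
#' @param od Numeric `h x w x 3` OD array from [rgb_to_od()].
#' @param m A `"stain_matrix"`.
#' @return Numeric `h x w x 3` array of stain amounts (OD units), third
#'   dimension ordered as the matrix stains (H, DAB, residual).
#' @export
unmix_amounts <- function(od, m) {
  stopifnot(inherits(m, "stain_matrix"))
  d <- dim(od)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop("od must be an h x w x 3 array")
  }
  A <- matrix(od, ncol = 3L) %*% m$Minv
  A[A < 0] <- 0
  array(A, dim = d)
}

#' Colour-deconvolve an OD image into stain channel images
#'
#' Unmixes the image (see [unmix_amounts()]) and renders each stain amount
#' `a` back to an 8-bit pseudo-transmittance value
#' `v = clamp(round(255 * 10^(-a)), 0, 255)`, so 255 means no stain and
#' darker means more stain -- the same convention in which thresholds are
#' expressed.
#'
#' @inheritParams unmix_amounts
#' @return A named list of three `h x w` numeric matrices (values 0..255),
#'   named after the matrix stains.
#' @examples
#' img <- array(255, dim = c(2, 2, 3))          # pure white field
#' ch <- deconvolve(rgb_to_od(img), hdab_stain_matrix())
#' ch$haematoxylin[1, 1]                        # 255: no stain
#' @export
deconvolve <- function(od, m) {
  a <- unmix_amounts(od, m)
  d <- dim(a)
  v <- pmin(pmax(round(255 * 10^(-a)), 0), 255)
  out <- lapply(seq_len(3L), function(i) matrix(v[, , i], d[1], d[2]))
  names(out) <- m$stains
  out
}
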