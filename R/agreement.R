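#' Linear agreement weights for ordered categories
#'
#' `w(i, j) = 1 - |i - j| / (k - 1)`: full credit on the diagonal, zero at
#' the extreme corners, partial credit for near-miss classifications in
#' between. These are the weights behind linearly weighted kappa.
#'
#' @param k Number of ordered categories (>= 2).
#' @return `k x k` numeric weight matrix.
#' @examples
#' linear_weights(3)    # adjacent weight 0.5, corners 0
#' @export
linear_weights <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k < 2 || k != round(k)) {
    stop("k must be an integer >= 2")
  }
  1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
}

#' Cross-tabulation of two ordinal raters
#'
#' @param counts Square matrix (k >= 2) of non-negative cell counts; rows
#'   are the first rater's categories, columns the second's, in the same
#'   category order on both axes.
#' @param categories Optional character vector of category labels used for
#'   dimnames.
#' @return The counts matrix with class `"agreement_table"`.
#' @export
agreement_table <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2L) {
    stop("counts must be a square matrix with at least 2 categories")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("empty agreement table")
  if (!is.null(categories)) {
    stopifnot(length(categories) == nrow(counts))
    dimnames(counts) <- list(rater_a = categories, rater_b = categories)
  }
  structure(counts, class = c("agreement_table", "matrix"))
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("agreement table, %d categories, n = %d\n", nrow(x), sum(x)))
  print(unclass(x))
  dropped <- attr(x, "n_dropped")
  if (!is.null(dropped) && dropped > 0) {
    cat(sprintf("(%d subject(s) dropped for missing ratings)\n", dropped))
  }
  invisible(x)
}

#' Linearly weighted agreement and kappa
#'
#' Computes the linearly weighted observed agreement
#' `Po_w = sum(w * counts) / n`, the chance-expected weighted agreement
#' `Pe_w = sum(w * row_i * col_j) / n^2` from the marginals, and the
#' weighted kappa `(Po_w - Pe_w) / (1 - Pe_w)`. The unweighted observed
#' agreement (diagonal fraction) is also reported; the weighted observed
#' agreement is the headline "percentage agreement" statistic, since it
#' credits near-miss classifications between adjacent ordered categories.
#'
#' @param x An [agreement_table()] or a square count matrix.
#' @return A list of class `"agreement_stats"`: `observed_weighted`,
#'   `expected_weighted`, `kappa_weighted` (`NA` when the marginals are
#'   degenerate, i.e. expected weighted agreement is 1),
#'   `observed_unweighted`, `n`, `k`. Full precision; see the print method
#'   for conventional rounding.
#' @examples
#' t1 <- agreement_table(rbind(c(46, 53, 0), c(51, 554, 114), c(2, 112, 360)))
#' weighted_agreement(t1)       # 87% weighted agreement, kappa 0.57
#' @export
weighted_agreement <- function(x) {
  t <- if (inherits(x, "agreement_table")) x else agreement_table(x)
  n <- sum(t)
  k <- nrow(t)
  w <- linear_weights(k)
  cnt <- unclass(t)
  po <- sum(w * cnt) / n
  pe <- sum(w * outer(rowSums(cnt), colSums(cnt))) / n^2
  kap <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  structure(list(observed_weighted = po,
                 expected_weighted = pe,
                 kappa_weighted = kap,
                 observed_unweighted = sum(diag(cnt)) / n,
                 n = n, k = k),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("weighted agreement: %d%%  (unweighted: %.1f%%)\n",
              round(100 * x$observed_weighted), 100 * x$observed_unweighted))
  cat(sprintf("linearly weighted kappa: %s  (n = %d, %d categories)\n",
              if (is.na(x$kappa_weighted)) "NA"
              else sprintf("%.2f", x$kappa_weighted), x$n, x$k))
  invisible(x)
}

#' Build the automated-vs-visual contingency table
#'
#' Cross-tabulates two ordinal ratings of the same patients. Only patients
#' rated by both are tabulated; patients missing either rating are dropped
#' and counted in the `n_dropped` attribute of the result.
#'
#' @param auto Data frame with columns `patient_id` and `group` (automated
#'   ordinal category).
#' @param visual Data frame with columns `patient_id` and `category`
#'   (visual ordinal category).
#' @param auto_levels,visual_levels Category labels of each rater in
#'   increasing order; every observed label must be one of these.
#' @return An [agreement_table()] with rows = automated categories and
#'   columns = visual categories, plus attribute `n_dropped`.
#' @export
build_contingency <- function(auto, visual,
                              auto_levels = c("low", "moderate", "high"),
                              visual_levels = c("negative", "moderate", "high")) {
  stopifnot(all(c("patient_id", "group") %in% names(auto)),
            all(c("patient_id", "category") %in% names(visual)))
  if (length(auto_levels) != length(visual_levels)) {
    stop("both raters must use the same number of ordered categories")
  }
  check_levels <- function(obs, levels, who) {
    bad <- setdiff(unique(as.character(obs[!is.na(obs)])), levels)
    if (length(bad)) stop("unknown ", who, " category: ",
                          paste(bad, collapse = ", "))
  }
  check_levels(auto$group, auto_levels, "automated")
  check_levels(visual$category, visual_levels, "visual")
  m <- merge(auto[c("patient_id", "group")],
             visual[c("patient_id", "category")], by = "patient_id")
  keep <- !is.na(m$group) & !is.na(m$category)
  n_all <- length(union(auto$patient_id, visual$patient_id))
  m <- m[keep, ]
  if (nrow(m) == 0L) stop("no overlapping patients")
  tab <- table(factor(m$group, levels = auto_levels),
               factor(m$category, levels = visual_levels))
  out <- agreement_table(matrix(tab, nrow = length(auto_levels),
                                dimnames = list(automated = auto_levels,
                                                visual = visual_levels)))
  attr(out, "n_dropped") <- n_all - nrow(m)
  out
}
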