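# Independent oracles and shared fixtures, deliberately written by a
# different route than the package implementation.

# Forward Beer-Lambert synthesis: stain amounts -> 8-bit RGB pixel array.
render_amounts <- function(a_h, a_dab, m = hdab_stain_matrix()) {
  od <- a_h * m$M[1, ] + a_dab * m$M[2, ]
  array(pmin(pmax(round(255 * 10^(-od)), 0), 255), dim = c(1, 1, 3))
}

# Naive per-pixel double-loop extent oracle.
extent_oracle <- function(h, dab) {
  n_dab <- 0L
  n_union <- 0L
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(ncol(h))) {
      if (dab[i, j]) n_dab <- n_dab + 1L
      if (h[i, j] || dab[i, j]) n_union <- n_union + 1L
    }
  }
  if (n_union == 0L) NA_real_ else 100 * n_dab / n_union
}

# Sort-and-cut grouping oracle: sort the values, cut the sorted list at the
# target cumulative counts, and read the group of each original value off
# its sorted position (ties resolved toward the lower group by comparing
# against the cut values).
sort_cut_oracle <- function(values, proportions) {
  x <- sort(values)
  n <- length(x)
  c1 <- x[ceiling(n * cumsum(proportions)[1])]
  c2 <- x[ceiling(n * cumsum(proportions)[2])]
  g <- ifelse(values <= c1, "low", ifelse(values <= c2, "moderate", "high"))
  list(cuts = c(c1, c2), groups = g,
       counts = c(sum(g == "low"), sum(g == "moderate"), sum(g == "high")))
}

# Weighted-kappa oracle via the complementary disagreement formulation:
# kappa_w = 1 - sum(d_ij * p_ij) / sum(d_ij * e_ij) with d = |i - j|.
kappa_oracle <- function(counts) {
  k <- nrow(counts)
  n <- sum(counts)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  e <- outer(rowSums(counts), colSums(counts)) / n
  1 - sum(d * counts) / sum(d * e)
}

# Printed 3x3 automated-vs-visual cross-tabulation used across the
# agreement tests (rows: automated low/moderate/high; columns: visual
# negative/moderate/high).
table1_counts <- function() {
  rbind(c(46, 53, 0),
        c(51, 554, 114),
        c(2, 112, 360))
}
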