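#' Gini coefficient of a count vector
#'
#' Population (uncorrected) form
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}
#' computed over the supplied counts *including* zero entries, so a one-hot
#' vector of length n yields exactly (n-1)/n. This is the common default of
#' R inequality packages; no small-sample correction is applied.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return Gini coefficient in \[0, (n-1)/n\].
#' @export
#' @examples
#' gini(c(5, 5, 5, 5))   # 0
#' gini(c(0, 0, 0, 10))  # 0.75
gini <- function(counts) {
  counts <- check_counts(counts)
  n <- length(counts)
  mu <- mean(counts)
  x <- sort(counts)
  # sum_i sum_j |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  s <- 2 * sum((2 * seq_len(n) - n - 1) * x)
  s / (2 * n^2 * mu)
}

#' D50 repertoire diversity
#'
#' The smallest number of categories (clonotypes) whose summed counts reach
#' at least 50% of the total.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return integer k >= 1.
#' @export
#' @examples
#' d50(rep(10, 10))              # 5
#' d50(c(50, 10, 10, 10, 10, 10))  # 1
d50 <- function(counts) {
  counts <- check_counts(counts)
  x <- sort(counts, decreasing = TRUE)
  which(cumsum(x) >= sum(x) / 2)[1]
}

#' Fraction of the repertoire occupied by rank ranges
#'
#' For each rank interval (e.g. clonotypes ranked 1-10 by size), the share of
#' total counts those ranks hold. Ranks beyond the number of categories
#' contribute zero.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @param ranges list of integer vectors `c(lo, hi)`, disjoint and ascending.
#' @return named numeric vector of fractions, names `"lo-hi"`.
#' @export
#' @examples
#' topn_fraction(c(60, 20, 10, 5, 5), list(c(1, 1)))  # 0.6
topn_fraction <- function(counts, ranges = list(c(1, 10), c(11, 50), c(51, 500))) {
  counts <- check_counts(counts)
  x <- sort(counts, decreasing = TRUE)
  tot <- sum(x)
  out <- vapply(ranges, function(r) {
    lo <- r[1]; hi <- min(r[2], length(x))
    if (lo > length(x)) 0 else sum(x[lo:hi]) / tot
  }, numeric(1))
  names(out) <- vapply(ranges, function(r) paste(r[1], r[2], sep = "-"),
                       character(1))
  out
}

check_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  if (!is.numeric(counts) || any(counts < 0) || any(is.na(counts))) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  if (sum(counts) <= 0) {
    stop("statistic undefined on an all-zero count vector", call. = FALSE)
  }
  counts
}

#' Diversity summary of a clonotype size distribution
#'
#' @param counts clonotype sizes (or any count vector).
#' @param ranges rank ranges for [topn_fraction()].
#' @return object of class `diversity_summary`.
#' @export
diversity_summary <- function(counts,
                              ranges = list(c(1, 10), c(11, 50), c(51, 500))) {
  counts <- check_counts(counts)
  structure(list(n_categories = length(counts),
                 gini = gini(counts),
                 d50 = d50(counts),
                 topn_fractions = topn_fraction(counts, ranges)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Diversity: %d categories, Gini %.3f, D50 %d\n",
              x$n_categories, x$gini, x$d50))
  fr <- x$topn_fractions
  cat("  occupancy:",
      paste(sprintf("ranks %s = %.1f%%", names(fr), 100 * fr), collapse = "; "),
      "\n")
  invisible(x)
}

#' Down-sample cells uniformly without replacement
#'
#' Used to compare repertoires of unequal depth: the larger repertoire is
#' subsampled to the size of the smaller before clonotype statistics are
#' computed, and clonotypes must be re-assigned on the subsample rather than
#' inherited from the full set.
#'
#' @param cells data frame of cells.
#' @param n number of rows to keep; must not exceed `nrow(cells)`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return the subsampled data frame (original row order preserved).
#' @export
downsample <- function(cells, n, seed) {
  stopifnot(is.data.frame(cells))
  if (n > nrow(cells)) {
    stop("cannot down-sample ", nrow(cells), " cells to ", n, call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(cells), n))
  cells[sort(idx), , drop = FALSE]
}

#' Gene/isotype usage counts
#'
#' Counts records per gene-level label for a chosen annotation field. When a
#' second table is supplied, both count vectors are zero-filled over the
#' union of labels so they share a label space (as needed for usage
#' comparison tests).
#'
#' @param records data frame of rearrangement records or paired cells.
#' @param field one of `"v_call_heavy"`, `"v_call_light"`, `"v_call"`,
#'   `"c_call"`, `"locus"` (the column must exist in `records`).
#' @param other optional second data frame for zero-filled comparison.
#' @return data frame with columns `label`, `count` (and `count_other` when
#'   `other` is given), sorted by decreasing `count`.
#' @export
usage_table <- function(records, field = "v_call_heavy", other = NULL) {
  if (!field %in% names(records)) {
    stop("unknown field '", field, "'", call. = FALSE)
  }
  t1 <- table(records[[field]])
  if (is.null(other)) {
    out <- data.frame(label = names(t1), count = as.integer(t1),
                      stringsAsFactors = FALSE)
    return(out[order(-out$count, out$label), , drop = FALSE])
  }
  t2 <- table(other[[field]])
  labels <- sort(union(names(t1), names(t2)))
  out <- data.frame(label = labels,
                    count = as.integer(t1[labels]),
                    count_other = as.integer(t2[labels]),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  out$count_other[is.na(out$count_other)] <- 0L
  out[order(-out$count, out$label), , drop = FALSE]
}

#' Chi-squared comparison of two usage distributions
#'
#' Pearson chi-squared test on the 2 x K contingency table of two count
#' vectors over a shared label space; labels with zero pooled count are
#' dropped. No continuity correction is applied.
#'
#' @param a,b numeric count vectors over the same labels (zero-filled).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
compare_usage_chisq <- function(a, b) {
  if (length(a) != length(b)) {
    stop("count vectors must share a label space (zero-fill first)",
         call. = FALSE)
  }
  keep <- (a + b) > 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) {
    stop("fewer than 2 informative categories", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(rbind(a, b), correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Wilcoxon rank-sum comparisons with multiplicity adjustment
#'
#' Two-sided Wilcoxon rank-sum tests for one or more pairs of samples, with
#' Benjamini-Hochberg adjustment across the batch.
#'
#' @param pairs a list of `list(x = , y = )` sample pairs, or a single pair
#'   given as `x`/`y` arguments.
#' @param x,y numeric vectors (alternative single-pair interface).
#' @param adjust adjustment method passed to [stats::p.adjust()]; default
#'   `"BH"`.
#' @return data frame with columns `p_value` and `adjusted_p`.
#' @export
compare_groups_wilcoxon <- function(pairs = NULL, x = NULL, y = NULL,
                                    adjust = "BH") {
  if (is.null(pairs)) {
    if (is.null(x) || is.null(y)) stop("supply pairs or x and y", call. = FALSE)
    pairs <- list(list(x = x, y = y))
  }
  p <- vapply(pairs, function(pr) {
    if (length(pr$x) == 0L || length(pr$y) == 0L) {
      stop("empty sample in Wilcoxon comparison", call. = FALSE)
    }
    # ties are handled by the normal approximation wilcox.test falls back to
    suppressWarnings(stats::wilcox.test(pr$x, pr$y, alternative = "two.sided",
                                        exact = NULL)$p.value)
  }, numeric(1))
  data.frame(p_value = p, adjusted_p = stats::p.adjust(p, method = adjust))
}
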