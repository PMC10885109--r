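#' Net fluorescence geomean matrix
#'
#' Converts a long-format bead-competition table into the reference x panel
#' matrix of net geomeans,
#' `net[r, p] = total_geomean[r, p] - reference_alone[r]`,
#' i.e. the binding signal of the panel antibody on a bead already carrying
#' the reference antibody. Negative values (over-subtraction by a noisy
#' control) are retained, not clipped, and reported in a message.
#'
#' @param table data frame with columns `reference_id`, `panel_id`,
#'   `total_geomean`, `reference_alone_geomean` (the control may instead be
#'   supplied via `reference_alone`).
#' @param reference_alone optional named numeric vector of single-bead
#'   control geomeans per reference, overriding the table column.
#' @return numeric matrix (references x panel antibodies) of class
#'   `net_geomean_matrix`.
#' @export
net_geomean <- function(table, reference_alone = NULL) {
  need <- c("reference_id", "panel_id", "total_geomean")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("binning table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  refs <- sort(unique(table$reference_id))
  panel <- sort(unique(table$panel_id))
  if (is.null(reference_alone)) {
    if (!"reference_alone_geomean" %in% names(table)) {
      stop("supply reference_alone or a reference_alone_geomean column",
           call. = FALSE)
    }
    ra <- tapply(table$reference_alone_geomean, table$reference_id,
                 function(v) if (length(unique(v)) == 1L) v[1] else NA_real_)
    if (anyNA(ra)) {
      stop("inconsistent reference_alone_geomean within a reference",
           call. = FALSE)
    }
    reference_alone <- setNames(as.numeric(ra), names(ra))
  }
  missing_ra <- setdiff(refs, names(reference_alone))
  if (length(missing_ra)) {
    stop("no single-bead control for reference(s): ",
         paste(missing_ra, collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_real_, length(refs), length(panel),
              dimnames = list(refs, panel))
  m[cbind(match(table$reference_id, refs), match(table$panel_id, panel))] <-
    table$total_geomean
  if (anyNA(m)) stop("incomplete reference x panel matrix", call. = FALSE)
  net <- m - reference_alone[refs]
  if (any(net < 0)) {
    message(sum(net < 0), " negative net geomean value(s) retained")
  }
  class(net) <- c("net_geomean_matrix", class(net))
  net
}

#' Pairwise correlation of competitive binding profiles
#'
#' Pearson correlation between every pair of panel-antibody columns of a net
#' geomean matrix, taken over the reference antibodies. An antibody whose
#' profile has zero variance has no defined correlation; it is flagged and
#' excluded (its rows/columns are dropped, with a message).
#'
#' @param net reference x panel matrix from [net_geomean()].
#' @return list with `r_matrix` (symmetric, unit diagonal) and
#'   `excluded` (character vector of zero-variance antibodies).
#' @export
correlate_profiles <- function(net) {
  if (nrow(net) < 2) {
    stop("need at least 2 references to correlate profiles", call. = FALSE)
  }
  net <- unclass(net)
  vars <- apply(net, 2, stats::var)
  excluded <- colnames(net)[vars == 0]
  if (length(excluded)) {
    message("zero-variance profile(s) excluded from correlation: ",
            paste(excluded, collapse = ", "))
    net <- net[, vars > 0, drop = FALSE]
  }
  r <- stats::cor(net, method = "pearson")
  list(r_matrix = r, excluded = excluded)
}

#' Group antibodies into epitope bins
#'
#' Single-linkage agglomeration on the profile correlation matrix: two
#' antibodies share a bin iff they are connected by a chain of pairs with
#' `r >= threshold`. Bins are labeled A, B, ... in order of decreasing size,
#' ties broken by the lexicographically first member, so the labeling is
#' deterministic and invariant to input permutation.
#'
#' @param r_matrix symmetric correlation matrix with unit diagonal (e.g.
#'   from [correlate_profiles()]).
#' @param threshold correlation threshold in (0, 1\].
#' @return object of class `bin_assignment`: list with `bins` (named
#'   character vector antibody -> bin label), `threshold`, `r_matrix`.
#' @export
assign_bins <- function(r_matrix, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  if (is.list(r_matrix) && !is.null(r_matrix$r_matrix)) {
    r_matrix <- r_matrix$r_matrix
  }
  n <- ncol(r_matrix)
  ids <- colnames(r_matrix)
  if (is.null(ids)) ids <- paste0("Ab", seq_len(n))
  adj <- r_matrix >= threshold
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  first_member <- vapply(seq_len(max(comp)), function(k) sort(ids[comp == k])[1],
                         character(1))
  ord <- order(-sizes, first_member)
  label_of <- character(max(comp))
  label_of[ord] <- make_bin_labels(length(ord))
  bins <- setNames(label_of[comp], ids)
  structure(list(bins = bins, threshold = threshold, r_matrix = r_matrix),
            class = "bin_assignment")
}

make_bin_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' @export
print.bin_assignment <- function(x, ...) {
  tab <- table(x$bins)
  cat(sprintf("Epitope bins (r >= %.2f): %d bins over %d antibodies\n",
              x$threshold, length(tab), length(x$bins)))
  for (b in names(tab)) {
    cat(sprintf("  bin %s (%d): %s\n", b, tab[b],
                paste(sort(names(x$bins)[x$bins == b]), collapse = ", ")))
  }
  invisible(x)
}

#' Match panel antibodies against benchmark bins
#'
#' For each panel antibody, computes the Pearson correlation of its
#' competition profile with each benchmark antibody's profile (over the
#' shared references); the antibody is assigned the bin of the best
#' benchmark with `r >= threshold`, or flagged `novel` when no benchmark
#' reaches the threshold.
#'
#' @param panel_net reference x panel net geomean matrix.
#' @param benchmark_net reference x benchmark net geomean matrix (same
#'   reference rows).
#' @param benchmark_bins named character vector: benchmark antibody -> bin.
#' @param threshold correlation threshold (default 0.8).
#' @return data frame with `panel_id`, `best_benchmark`, `best_r`,
#'   `matched_bin` (NA when novel), `novel` (logical).
#' @export
benchmark_binning <- function(panel_net, benchmark_net, benchmark_bins,
                              threshold = 0.8) {
  if (length(benchmark_bins) == 0L || ncol(benchmark_net) == 0L) {
    stop("benchmark set is empty", call. = FALSE)
  }
  if (!identical(rownames(panel_net), rownames(benchmark_net))) {
    stop("panel and benchmark matrices must share reference rows",
         call. = FALSE)
  }
  miss <- setdiff(colnames(benchmark_net), names(benchmark_bins))
  if (length(miss)) {
    stop("benchmark(s) without bin label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(unclass(panel_net), unclass(benchmark_net),
                  method = "pearson")
  best <- apply(r, 1, which.max)
  best_r <- r[cbind(seq_len(nrow(r)), best)]
  best_bm <- colnames(r)[best]
  novel <- best_r < threshold
  data.frame(panel_id = rownames(r),
             best_benchmark = best_bm,
             best_r = unname(best_r),
             matched_bin = ifelse(novel, NA_character_,
                                  unname(benchmark_bins[best_bm])),
             novel = unname(novel),
             stringsAsFactors = FALSE)
}
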