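#' Align a light chain to its germline
#'
#' Positional comparison when lengths are equal; otherwise a global
#' (Needleman-Wunsch) amino-acid alignment via
#' [Biostrings::pairwiseAlignment()] with BLOSUM62 scores, gap opening -10
#' and gap extension -0.5. Gap columns are flagged as indels and excluded
#' from substitution counting. Records whose identity over aligned non-gap
#' columns falls below 50% are rejected (the sequence is presumed not to
#' derive from this germline).
#'
#' @param seq_aa query amino-acid sequence.
#' @param germline_aa germline amino-acid sequence.
#' @return list with `germline_index` (germline position of each aligned
#'   column; NA for insertions), `seq_char`, `germ_char`, `indel` (logical
#'   per column), `mismatch` (logical; FALSE at indel columns), `n_indels`,
#'   `identity`.
#' @export
align_to_germline <- function(seq_aa, germline_aa) {
  assert_aa(seq_aa, "query")
  assert_aa(germline_aa, "germline")
  if (nchar(seq_aa) == nchar(germline_aa)) {
    s <- strsplit(seq_aa, "")[[1]]
    g <- strsplit(germline_aa, "")[[1]]
    res <- list(germline_index = seq_along(g), seq_char = s, germ_char = g,
                indel = rep(FALSE, length(g)),
                mismatch = s != g, n_indels = 0L,
                identity = mean(s == g))
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_aa), Biostrings::AAString(germline_aa),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    s <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    g <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    indel <- s == "-" | g == "-"
    gidx <- cumsum(g != "-")
    gidx[g == "-"] <- NA_integer_
    res <- list(germline_index = gidx, seq_char = s, germ_char = g,
                indel = indel,
                mismatch = !indel & s != g,
                n_indels = sum(indel),
                identity = mean(s[!indel] == g[!indel]))
  }
  if (res$identity < 0.5) {
    stop("alignment identity ", sprintf("%.2f", res$identity),
         " below the 0.5 acceptance floor; record rejected", call. = FALSE)
  }
  res
}

#' Count amino-acid substitutions against germline
#'
#' @inheritParams align_to_germline
#' @return number of aligned, non-gap mismatch columns.
#' @export
mutation_count <- function(seq_aa, germline_aa) {
  sum(align_to_germline(seq_aa, germline_aa)$mismatch)
}

#' Somatic hypermutation profile of light chains
#'
#' Aligns each light-chain amino-acid sequence to the prearranged germline
#' and aggregates: a per-sequence mutation-count histogram, per-position
#' mutation frequencies on the germline's numbering labels (mutated records
#' at a label divided by records covering that label; indel columns do not
#' count as covered), and per-CDR summaries — the fraction of sequences with
#' at least one substitution in each CDR region and the fraction with none
#' in any CDR.
#'
#' Records failing the alignment-identity floor are dropped and counted in
#' `n_rejected`.
#'
#' @param light_aa character vector of light-chain amino-acid sequences.
#' @param germlines a [germline_set()] supplying the prearranged germline,
#'   numbering map and region definitions.
#' @return object of class `mutation_profile` with fields `labels`,
#'   `per_position_freq`, `n_covered`, `n_mutated`, `per_sequence_counts`
#'   (named histogram), `mean_mutations`, `region_defs`,
#'   `region_any_mutation_fraction`, `no_cdr_mutation_fraction`,
#'   `n_sequences`, `n_rejected`.
#' @export
shm_profile <- function(light_aa, germlines = default_germlines()) {
  if (length(light_aa) == 0L) stop("no light chains supplied", call. = FALSE)
  germ <- germlines$prearranged_lc
  labels <- germlines$numbering_map
  nlab <- length(labels)
  covered <- mutated <- setNames(rep(0L, nlab), labels)
  counts <- integer(length(light_aa))
  region_hit <- matrix(FALSE, nrow = length(light_aa),
                       ncol = length(germlines$regions),
                       dimnames = list(NULL, names(germlines$regions)))
  keep <- rep(TRUE, length(light_aa))
  for (i in seq_along(light_aa)) {
    al <- tryCatch(align_to_germline(light_aa[i], germ),
                   error = function(e) NULL)
    if (is.null(al)) {
      keep[i] <- FALSE
      next
    }
    gcol <- !is.na(al$germline_index) & al$germ_char != "-" & al$seq_char != "-"
    gi <- al$germline_index[gcol]
    covered[gi] <- covered[gi] + 1L
    mut_gi <- al$germline_index[al$mismatch]
    mutated[mut_gi] <- mutated[mut_gi] + 1L
    counts[i] <- sum(al$mismatch)
    mut_labels <- labels[mut_gi]
    for (rg in names(germlines$regions)) {
      region_hit[i, rg] <- any(mut_labels %in% germlines$regions[[rg]])
    }
  }
  n_rejected <- sum(!keep)
  counts <- counts[keep]
  region_hit <- region_hit[keep, , drop = FALSE]
  if (length(counts) == 0L) stop("all records rejected", call. = FALSE)
  freq <- ifelse(covered > 0, mutated / covered, NA_real_)
  hist_tab <- table(factor(counts, levels = 0:max(counts)))
  structure(list(
    labels = labels,
    per_position_freq = setNames(as.numeric(freq), labels),
    n_covered = covered,
    n_mutated = mutated,
    per_sequence_counts = hist_tab,
    mean_mutations = mean(counts),
    region_defs = germlines$regions,
    region_any_mutation_fraction = colMeans(region_hit),
    no_cdr_mutation_fraction = mean(rowSums(region_hit) == 0),
    n_sequences = length(counts),
    n_rejected = n_rejected
  ), class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("SHM profile: %d light chains (%d rejected)\n",
              x$n_sequences, x$n_rejected))
  cat(sprintf("  mean mutations/chain: %.2f\n", x$mean_mutations))
  fr <- x$region_any_mutation_fraction
  cat("  sequences with >=1 CDR mutation:",
      paste(sprintf("%s %.0f%%", names(fr), 100 * fr), collapse = ", "), "\n")
  cat(sprintf("  no CDR mutation: %.1f%%\n", 100 * x$no_cdr_mutation_fraction))
  top <- utils::head(hotspot_report(x, 5), 5)
  cat("  top positions:",
      paste(sprintf("%s (%.2f, %s)", top$label, top$freq, top$region),
            collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.mutation_profile <- function(x, ...) {
  freq <- x$per_position_freq
  region <- label_region(x$labels, x$region_defs)
  col <- ifelse(region == "FR", "grey60", "firebrick")
  graphics::barplot(freq, names.arg = x$labels, col = col, border = NA,
                    las = 2, cex.names = 0.5,
                    ylab = "mutation frequency",
                    xlab = "Chothia position", ...)
  invisible(x)
}

label_region <- function(labels, region_defs) {
  out <- rep("FR", length(labels))
  for (rg in names(region_defs)) {
    out[labels %in% region_defs[[rg]]] <- rg
  }
  out
}

#' Top mutated positions
#'
#' Ranks numbering labels by per-position mutation frequency (ties broken by
#' label order in the numbering) and annotates each with its region.
#'
#' @param profile a [shm_profile()] result.
#' @param k number of positions to report; truncated with a warning if it
#'   exceeds the number of labels.
#' @return data frame with columns `label`, `freq`, `region`.
#' @export
hotspot_report <- function(profile, k = 7) {
  stopifnot(inherits(profile, "mutation_profile"))
  n <- length(profile$labels)
  if (k > n) {
    warning("k exceeds number of positions; truncated to ", n)
    k <- n
  }
  freq <- profile$per_position_freq
  ord <- order(-freq, seq_along(freq))
  sel <- ord[seq_len(k)]
  data.frame(label = profile$labels[sel],
             freq = unname(freq[sel]),
             region = label_region(profile$labels[sel], profile$region_defs),
             stringsAsFactors = FALSE)
}
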