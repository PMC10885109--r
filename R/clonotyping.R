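#' CDR-H3 amino-acid identity
#'
#' Fraction of positions at which two equal-length amino-acid strings carry
#' the same residue. Clonotype clustering pre-partitions sequences by
#' CDR-H3 length, so unequal lengths are a caller error, not 0 identity.
#'
#' @param a,b amino-acid strings of equal, positive length.
#' @return identity fraction in \[0, 1\].
#' @export
#' @examples
#' cdr3_identity("CARDYW", "CARDYF")  # 5/6
cdr3_identity <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0L) {
    stop("cdr3_identity requires equal, positive lengths; partition by CDR-H3 length first",
         call. = FALSE)
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca == cb) / length(ca)
}

#' Hamming distance between equal-length sequences
#'
#' @param seq,consensus amino-acid strings of equal length.
#' @return count of mismatching positions.
#' @export
hamming_to_consensus <- function(seq, consensus) {
  if (nchar(seq) != nchar(consensus)) {
    stop("hamming distance requires equal lengths", call. = FALSE)
  }
  sum(strsplit(seq, "")[[1]] != strsplit(consensus, "")[[1]])
}

#' Per-position consensus of equal-length sequences
#'
#' Modal residue at each position; ties are broken by the lexicographically
#' smallest residue so the result is deterministic.
#'
#' @param members character vector of equal-length amino-acid strings.
#' @return consensus amino-acid string.
#' @export
consensus_sequence <- function(members) {
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  lens <- nchar(members)
  if (length(unique(lens)) != 1L) {
    stop("consensus requires equal-length sequences; align members upstream",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(members, ""))
  cons <- apply(mat, 2, function(col) {
    tab <- table(col)
    names(tab)[tab == max(tab)][1]  # table() names are sorted, so ties pick smallest
  })
  paste(cons, collapse = "")
}

#' Assign paired cells to clonotypes
#'
#' Implements the clonotype definition used for paired single-cell BCR data:
#' two cells belong to the same clonotype when they share the heavy V gene
#' (gene level, allele-stripped), have the same CDR-H3 length, and their
#' CDR-H3 amino-acid identity is at least `threshold` (default 0.8,
#' the CD-HIT-style reading of ">80% identity").
#'
#' Within each (V gene, CDR-H3 length) block, clustering is greedy and
#' incremental in the CD-HIT manner: unique CDR-H3s are processed in
#' descending multiplicity (ties broken lexicographically); each sequence
#' joins the first existing cluster whose *representative* (the founding
#' sequence) it matches at `>= threshold` identity, otherwise it founds a
#' new cluster. The ordering rule makes the partition deterministic.
#'
#' @param cells data frame of paired cells with columns `cell_id`,
#'   `v_call_heavy`, `cdr3_aa_heavy`, and (optionally, used for consensus)
#'   `sequence_aa_heavy` and `sequence_id_heavy`.
#' @param threshold identity threshold in (0, 1\]; membership uses `>=`.
#' @param min_consensus_size smallest clonotype size for which a consensus
#'   heavy sequence is computed (default 5).
#' @return An object of class `clonotype_set`: list with `clonotypes` (one
#'   row per clonotype: `clonotype_id`, `v_gene`, `cdr3_length`, `size`,
#'   `representative_cdr3`, `consensus_vh_aa`, `consensus_region`) and
#'   `members` (the input cells plus a `clonotype_id` column).
#' @export
assign_clonotypes <- function(cells, threshold = 0.8, min_consensus_size = 5L) {
  if (!is.data.frame(cells) || nrow(cells) == 0L) {
    stop("cells must be a non-empty data frame of paired cells", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  need <- c("v_call_heavy", "cdr3_aa_heavy")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop("cells is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cells$cdr3_length <- nchar(cells$cdr3_aa_heavy)
  block_key <- paste(cells$v_call_heavy, cells$cdr3_length, sep = "|")
  cells$clonotype_id <- NA_character_
  clono_rows <- list()
  cid <- 0L
  for (bk in sort(unique(block_key))) {
    idx <- which(block_key == bk)
    seqs <- cells$cdr3_aa_heavy[idx]
    tab <- table(seqs)
    ord <- order(-as.integer(tab), names(tab))
    uniq <- names(tab)[ord]
    reps <- character(0)
    rep_cid <- integer(0)
    membership <- setNames(integer(length(uniq)), uniq)
    for (s in uniq) {
      joined <- FALSE
      for (k in seq_along(reps)) {
        if (cdr3_identity(s, reps[k]) >= threshold) {
          membership[s] <- rep_cid[k]
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        cid <- cid + 1L
        reps <- c(reps, s)
        rep_cid <- c(rep_cid, cid)
        membership[s] <- cid
        clono_rows[[cid]] <- list(
          v_gene = cells$v_call_heavy[idx][1],
          cdr3_length = cells$cdr3_length[idx][1],
          representative_cdr3 = s
        )
      }
    }
    cells$clonotype_id[idx] <- sprintf("CT%05d", membership[seqs])
  }
  clono <- data.frame(
    clonotype_id = sprintf("CT%05d", seq_along(clono_rows)),
    v_gene = vapply(clono_rows, `[[`, character(1), "v_gene"),
    cdr3_length = vapply(clono_rows, `[[`, integer(1), "cdr3_length"),
    representative_cdr3 = vapply(clono_rows, `[[`, character(1),
                                 "representative_cdr3"),
    stringsAsFactors = FALSE
  )
  sizes <- table(cells$clonotype_id)
  clono$size <- as.integer(sizes[clono$clonotype_id])
  clono$consensus_vh_aa <- NA_character_
  clono$consensus_region <- NA_character_
  if ("sequence_aa_heavy" %in% names(cells)) {
    for (i in which(clono$size >= min_consensus_size)) {
      mem <- cells$sequence_aa_heavy[cells$clonotype_id == clono$clonotype_id[i]]
      if (length(unique(nchar(mem))) == 1L) {
        clono$consensus_vh_aa[i] <- consensus_sequence(mem)
        clono$consensus_region[i] <- "VH"
      } else {
        # indel-bearing clonotype: fall back to CDR-H3 consensus
        mem3 <- cells$cdr3_aa_heavy[cells$clonotype_id == clono$clonotype_id[i]]
        clono$consensus_vh_aa[i] <- consensus_sequence(mem3)
        clono$consensus_region[i] <- "CDR-H3"
        message("clonotype ", clono$clonotype_id[i],
                ": unequal VH lengths, consensus downgraded to CDR-H3")
      }
    }
  }
  structure(list(clonotypes = clono, members = cells,
                 threshold = threshold,
                 min_consensus_size = min_consensus_size),
            class = "clonotype_set")
}

#' @export
print.clonotype_set <- function(x, ...) {
  cat(sprintf("Clonotype set: %d clonotypes over %d cells (threshold %.2f)\n",
              nrow(x$clonotypes), nrow(x$members), x$threshold))
  top <- utils::head(x$clonotypes[order(-x$clonotypes$size), ], 5)
  cat("  largest:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s %s len %d size %d\n", top$clonotype_id[i],
                top$v_gene[i], top$cdr3_length[i], top$size[i]))
  }
  invisible(x)
}

#' @export
summary.clonotype_set <- function(object, ...) {
  sizes <- object$clonotypes$size
  out <- list(n_clonotypes = nrow(object$clonotypes),
              n_cells = nrow(object$members),
              size_quantiles = stats::quantile(sizes, c(0, .5, .9, 1)),
              n_ge5 = sum(sizes >= object$min_consensus_size))
  class(out) <- "summary.clonotype_set"
  out
}

#' @export
print.summary.clonotype_set <- function(x, ...) {
  cat(sprintf("%d clonotypes / %d cells; %d with size >= 5\n",
              x$n_clonotypes, x$n_cells, x$n_ge5))
  print(x$size_quantiles)
  invisible(x)
}

#' Flag antibody sequence liabilities in CDRs
#'
#' Scans CDR amino-acid strings for two developability liabilities:
#' N-glycosylation sequons (`N-X-S/T` with `X != P`) and cysteines, which in
#' a CDR are presumed unpaired. Each CDR may be supplied with its two-residue
#' right flank (e.g. `"...|XY"` is not needed; simply pass `flank3` etc.) so
#' sequons spanning the CDR boundary are caught.
#'
#' @param cdr1,cdr2,cdr3 CDR amino-acid strings (may be empty).
#' @param flank1,flank2,flank3 optional right-flank residues (up to 2) for
#'   each CDR, used only to complete boundary-spanning sequons.
#' @return character vector: subset of `c("nglyc_cdr", "unpaired_cys_cdr")`.
#' @export
#' @examples
#' flag_liabilities(cdr3 = "ARNGSDY")   # sequon
#' flag_liabilities(cdr3 = "ARNPSDY")   # proline blocks the sequon
flag_liabilities <- function(cdr1 = "", cdr2 = "", cdr3 = "",
                             flank1 = "", flank2 = "", flank3 = "") {
  cdrs <- c(cdr1, cdr2, cdr3)
  flanks <- c(flank1, flank2, flank3)
  nonempty <- cdrs[nchar(cdrs) > 0]
  if (length(nonempty)) assert_aa(nonempty, "CDR")
  flags <- character(0)
  has_sequon <- function(x) grepl("N[^P][ST]", x)
  for (i in 1:3) {
    if (nchar(cdrs[i]) == 0L) next
    ext <- paste0(cdrs[i], substr(flanks[i], 1L, 2L))
    # sequon must start inside the CDR proper
    starts <- gregexpr("N(?=[^P][ST])", ext, perl = TRUE)[[1]]
    if (starts[1] != -1 && any(starts <= nchar(cdrs[i]))) {
      flags <- union(flags, "nglyc_cdr")
    }
    if (grepl("C", cdrs[i], fixed = TRUE)) {
      flags <- union(flags, "unpaired_cys_cdr")
    }
  }
  flags
}

#' Rank and select clones for expression
#'
#' Reproduces the clone-selection rule used when picking clones for gene
#' synthesis: candidates are liability-free members of clonotypes with at
#' least `min_size` cells, ranked by larger clonotype size, then minimal
#' hamming distance to the clonotype consensus, then `sequence_id`. One
#' clone is taken per clonotype before any clonotype contributes a second,
#' so the selection favors clonotype coverage.
#'
#' @param cts a [assign_clonotypes()] result (`clonotype_set`).
#' @param k number of clones to select.
#' @param min_size minimum clonotype size for eligibility (default 5).
#' @return data frame of selected clones with columns `sequence_id`,
#'   `cell_id`, `clonotype_id`, `clonotype_size`, `hamming_to_consensus`,
#'   `liabilities`, `pick_round`. May have fewer than `k` rows if candidates
#'   are exhausted (with a warning if empty).
#' @export
select_clones <- function(cts, k, min_size = 5L) {
  stopifnot(inherits(cts, "clonotype_set"), k >= 1)
  mem <- cts$members
  clono <- cts$clonotypes
  need <- c("sequence_aa_heavy", "sequence_id_heavy",
            "cdr1_aa_heavy", "cdr2_aa_heavy", "cdr3_aa_heavy")
  missing_cols <- setdiff(need, names(mem))
  if (length(missing_cols)) {
    stop("members lack column(s) needed for selection: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  eligible_ct <- clono[clono$size >= min_size & !is.na(clono$consensus_vh_aa), ]
  if (nrow(eligible_ct) == 0L) {
    warning("no clonotypes of size >= ", min_size, "; empty selection")
    return(empty_selection())
  }
  cand <- list()
  for (i in seq_len(nrow(eligible_ct))) {
    ct <- eligible_ct[i, ]
    rows <- mem[mem$clonotype_id == ct$clonotype_id, ]
    liab <- vapply(seq_len(nrow(rows)), function(j) {
      paste(flag_liabilities(rows$cdr1_aa_heavy[j], rows$cdr2_aa_heavy[j],
                             rows$cdr3_aa_heavy[j]), collapse = ";")
    }, character(1))
    keep <- liab == ""
    if (!any(keep)) next
    rows <- rows[keep, , drop = FALSE]
    ham <- vapply(seq_len(nrow(rows)), function(j) {
      s <- rows$sequence_aa_heavy[j]
      if (ct$consensus_region == "VH" && nchar(s) == nchar(ct$consensus_vh_aa)) {
        hamming_to_consensus(s, ct$consensus_vh_aa)
      } else {
        hamming_to_consensus(rows$cdr3_aa_heavy[j], ct$representative_cdr3)
      }
    }, numeric(1))
    ord <- order(ham, rows$sequence_id_heavy)
    cand[[ct$clonotype_id]] <- data.frame(
      sequence_id = rows$sequence_id_heavy[ord],
      cell_id = rows$cell_id[ord],
      clonotype_id = ct$clonotype_id,
      clonotype_size = ct$size,
      hamming_to_consensus = ham[ord],
      liabilities = "",
      within_rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
  }
  if (length(cand) == 0L) {
    warning("all eligible members carry CDR liabilities; empty selection")
    return(empty_selection())
  }
  all_cand <- do.call(rbind, cand)
  # round-robin: all first picks (ordered by size desc, clonotype id), then
  # second picks, etc.
  all_cand <- all_cand[order(all_cand$within_rank, -all_cand$clonotype_size,
                             all_cand$clonotype_id,
                             all_cand$hamming_to_consensus,
                             all_cand$sequence_id), ]
  sel <- utils::head(all_cand, k)
  sel$pick_round <- sel$within_rank
  sel$within_rank <- NULL
  rownames(sel) <- NULL
  sel
}

empty_selection <- function() {
  data.frame(sequence_id = character(0), cell_id = character(0),
             clonotype_id = character(0), clonotype_size = integer(0),
             hamming_to_consensus = numeric(0), liabilities = character(0),
             pick_round = integer(0), stringsAsFactors = FALSE)
}
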