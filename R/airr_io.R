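AIRR_COLUMNS <- c("cell_id", "sequence_id", "locus", "v_call", "j_call",
                  "c_call", "productive", "cdr1_aa", "cdr2_aa", "cdr3_aa",
                  "sequence_aa", "sequence")

TENX_REQUIRED <- c("barcode", "contig_id", "chain", "v_gene", "j_gene",
                   "c_gene", "productive", "cdr3")

# Strip an IMGT allele suffix ("IGHV1-64*01" -> "IGHV1-64").
strip_allele <- function(calls) sub("\\*.*$", "", calls)

#' Read an annotated rearrangement table
#'
#' Parses AIRR Rearrangement TSV or 10x-style `filtered_contig_annotations`
#' CSV into a uniform record table. Gene calls are normalized to gene level
#' by stripping allele suffixes (`*01`); the raw calls are retained in
#' `v_call_raw`/`j_call_raw`/`c_call_raw`. Rows whose locus is not one of
#' IGH/IGK/IGL (e.g. TR chains in a mixed 10x run) are dropped and counted
#' in a message.
#'
#' @param path file path.
#' @param dialect `"airr-tsv"` or `"10x-csv"`.
#' @return data frame of rearrangement records with the AIRR-style columns
#'   `cell_id`, `sequence_id`, `locus`, `v_call`, `j_call`, `c_call`,
#'   `productive`, `cdr1_aa`, `cdr2_aa`, `cdr3_aa`, `sequence_aa`,
#'   `sequence`, plus raw-call columns. Attribute `n_skipped_locus` records
#'   dropped rows.
#' @export
read_rearrangements <- function(path, dialect = c("airr-tsv", "10x-csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "airr-tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    required <- c("sequence_id", "locus", "v_call", "j_call", "productive",
                  "cdr3_aa")
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop("AIRR table missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (col in setdiff(AIRR_COLUMNS, names(df))) df[[col]] <- NA_character_
    rec <- df[, AIRR_COLUMNS]
    rec$productive <- toupper(df$productive) %in% c("T", "TRUE", "YES")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    miss <- setdiff(TENX_REQUIRED, names(df))
    if (length(miss)) {
      stop("10x table missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    rec <- data.frame(
      cell_id = df$barcode,
      sequence_id = df$contig_id,
      locus = df$chain,
      v_call = df$v_gene,
      j_call = df$j_gene,
      c_call = df$c_gene,
      productive = toupper(df$productive) %in% c("TRUE", "T", "YES"),
      cdr1_aa = if ("cdr1" %in% names(df)) df$cdr1 else NA_character_,
      cdr2_aa = if ("cdr2" %in% names(df)) df$cdr2 else NA_character_,
      cdr3_aa = df$cdr3,
      sequence_aa = if ("full_length_aa" %in% names(df)) df$full_length_aa
                    else NA_character_,
      sequence = if ("sequence" %in% names(df)) df$sequence else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(rec) == 0L) {
    warning("empty rearrangement table: ", path)
    attr(rec, "n_skipped_locus") <- 0L
    return(rec)
  }
  rec$v_call_raw <- rec$v_call
  rec$j_call_raw <- rec$j_call
  rec$c_call_raw <- rec$c_call
  rec$v_call <- strip_allele(rec$v_call)
  rec$j_call <- strip_allele(rec$j_call)
  rec$c_call <- strip_allele(rec$c_call)
  keep <- rec$locus %in% c("IGH", "IGK", "IGL")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " record(s) with non-IG locus skipped")
  }
  rec <- rec[keep, , drop = FALSE]
  if (anyDuplicated(rec$sequence_id)) {
    stop("sequence_id values are not unique within the table", call. = FALSE)
  }
  rownames(rec) <- NULL
  attr(rec, "n_skipped_locus") <- n_skip
  rec
}

#' Write a rearrangement table as AIRR TSV
#'
#' @param records data frame of rearrangement records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  out <- records[, intersect(c(AIRR_COLUMNS, "v_call_raw", "j_call_raw",
                               "c_call_raw"), names(records)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair heavy and light chains within cells
#'
#' Applies the single-cell pairing filter: a cell is retained iff it has
#' exactly one productive heavy (IGH) and exactly one productive light
#' (IGK or IGL) record. Non-productive records are excluded before counting.
#' Cells with more than one heavy or more than one light chain (including a
#' kappa plus a lambda) are dropped as multiplets; cells missing a chain are
#' dropped as unpaired.
#'
#' @param records rearrangement record data frame with a `cell_id` column.
#' @return list with `cells` (one row per kept cell; heavy and light record
#'   fields suffixed `_heavy`/`_light`) and `report` (a `pairing_report`).
#' @export
pair_cells <- function(records) {
  if (!"cell_id" %in% names(records) || all(is.na(records$cell_id))) {
    stop("records carry no cell_id; use the bulk (unpaired) workflow",
         call. = FALSE)
  }
  prod <- records[records$productive %in% TRUE, , drop = FALSE]
  all_cells <- unique(records$cell_id)
  nh <- table(factor(prod$cell_id[prod$locus == "IGH"], levels = all_cells))
  nl <- table(factor(prod$cell_id[prod$locus %in% c("IGK", "IGL")],
                     levels = all_cells))
  multi <- nh > 1 | nl > 1
  unpaired <- !multi & (nh == 0 | nl == 0)
  kept <- !multi & !unpaired
  kept_ids <- all_cells[kept]
  heavy <- prod[prod$locus == "IGH" & prod$cell_id %in% kept_ids, , drop = FALSE]
  light <- prod[prod$locus %in% c("IGK", "IGL") & prod$cell_id %in% kept_ids, ,
                drop = FALSE]
  heavy <- heavy[match(kept_ids, heavy$cell_id), , drop = FALSE]
  light <- light[match(kept_ids, light$cell_id), , drop = FALSE]
  cell_cols <- setdiff(names(records), "cell_id")
  names(heavy)[names(heavy) != "cell_id"] <-
    paste0(setdiff(names(heavy), "cell_id"), "_heavy")
  names(light)[names(light) != "cell_id"] <-
    paste0(setdiff(names(light), "cell_id"), "_light")
  cells <- cbind(data.frame(cell_id = kept_ids, stringsAsFactors = FALSE),
                 heavy[, names(heavy) != "cell_id", drop = FALSE],
                 light[, names(light) != "cell_id", drop = FALSE])
  rownames(cells) <- NULL
  report <- structure(list(
    n_cells_in = length(all_cells),
    n_heavy = sum(records$locus == "IGH"),
    n_light = sum(records$locus %in% c("IGK", "IGL")),
    n_paired = sum(kept),
    n_dropped_multi = sum(multi),
    n_dropped_unpaired = sum(unpaired)
  ), class = "pairing_report")
  stopifnot(report$n_paired + report$n_dropped_multi +
              report$n_dropped_unpaired == report$n_cells_in)
  list(cells = cells, report = report)
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("Pairing: %d cells in (%d heavy, %d light records)\n",
              x$n_cells_in, x$n_heavy, x$n_light))
  cat(sprintf("  kept 1H+1L : %d\n  multiplets : %d\n  unpaired   : %d\n",
              x$n_paired, x$n_dropped_multi, x$n_dropped_unpaired))
  invisible(x)
}

#' @export
format.pairing_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE)
}
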