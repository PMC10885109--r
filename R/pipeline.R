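#' Pipeline configuration
#'
#' Flat, validated configuration for [run_pipeline()]. Every threshold and
#' seed the analysis depends on is explicit here and echoed into the JSON
#' report, because the headline repertoire numbers are sensitive to them.
#'
#' @param input_path path to an annotated rearrangement table, or `NULL` to
#'   simulate one from `sim` at run time.
#' @param dialect input dialect for [read_rearrangements()].
#' @param sim optional [sim_config()] used when `input_path` is `NULL`.
#' @param clonotype_threshold CDR-H3 identity threshold (default 0.8).
#' @param min_consensus_size minimum clonotype size for consensus/selection
#'   (default 5).
#' @param selection_k number of clones to select (default 48).
#' @param downsample_n optional target size for down-sampling before
#'   diversity statistics; `NULL` disables.
#' @param downsample_seed seed for the down-sampling draw.
#' @param topn_ranges rank ranges for occupancy reporting.
#' @param out_dir output directory (created if missing); `NULL` suppresses
#'   file output.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, dialect = "airr-tsv",
                            sim = sim_config(),
                            clonotype_threshold = 0.8,
                            min_consensus_size = 5L,
                            selection_k = 48L,
                            downsample_n = NULL,
                            downsample_seed = 1L,
                            topn_ranges = list(c(1, 10), c(11, 50), c(51, 500)),
                            out_dir = NULL) {
  if (!is.null(input_path) && !file.exists(input_path)) {
    stop("input_path does not exist: ", input_path, call. = FALSE)
  }
  if (clonotype_threshold <= 0 || clonotype_threshold > 1) {
    stop("clonotype_threshold must lie in (0, 1]", call. = FALSE)
  }
  structure(list(input_path = input_path, dialect = dialect, sim = sim,
                 clonotype_threshold = clonotype_threshold,
                 min_consensus_size = min_consensus_size,
                 selection_k = selection_k,
                 downsample_n = downsample_n,
                 downsample_seed = downsample_seed,
                 topn_ranges = topn_ranges,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Schema checks for the configured input table: distinguishes fatal errors
#' (missing required columns, unreadable file) from warnings (unexpected
#' loci, missing optional columns).
#'
#' @param config a [pipeline_config()].
#' @return list with `errors` and `warnings` (character vectors).
#' @export
validate_inputs <- function(config) {
  errors <- character(0)
  warnings <- character(0)
  if (is.null(config$input_path)) {
    v <- tryCatch({
      validate_sim_config(config$sim)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(v)) errors <- c(errors, v)
    return(list(errors = errors, warnings = warnings))
  }
  header <- tryCatch({
    if (config$dialect == "airr-tsv") {
      names(utils::read.delim(config$input_path, nrows = 1))
    } else {
      names(utils::read.csv(config$input_path, nrows = 1))
    }
  }, error = function(e) {
    errors <<- c(errors, paste("unreadable input:", conditionMessage(e)))
    NULL
  })
  if (!is.null(header)) {
    required <- if (config$dialect == "airr-tsv") {
      c("cell_id", "sequence_id", "locus", "v_call", "productive", "cdr3_aa")
    } else TENX_REQUIRED
    miss <- setdiff(required, header)
    if (length(miss)) {
      errors <- c(errors,
                  paste("missing required column(s):",
                        paste(miss, collapse = ", ")))
    }
    optional <- c("sequence_aa", "cdr1_aa", "cdr2_aa")
    opt_miss <- setdiff(optional, header)
    if (config$dialect == "airr-tsv" && length(opt_miss)) {
      warnings <- c(warnings,
                    paste("optional column(s) absent, some stages degraded:",
                          paste(opt_miss, collapse = ", ")))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run the repertoire characterization pipeline
#'
#' Executes ingest (or simulate) -> pairing filter -> clonotype clustering ->
#' optional down-sampling with re-clonotyping -> diversity statistics -> SHM
#' profile of prearranged-germline light chains -> clone selection, and
#' returns a structured report. When `out_dir` is set, per-stage TSVs, the
#' JSON report and a MANIFEST with content hashes are written; if a stage
#' fails, partial outputs are retained and the MANIFEST records the failed
#' stage.
#'
#' @param config a [pipeline_config()].
#' @param germlines a [germline_set()].
#' @return object of class `pipeline_report` (a nested list; see the
#'   vignette for the section layout).
#' @export
run_pipeline <- function(config, germlines = default_germlines()) {
  stopifnot(inherits(config, "pipeline_config"))
  val <- validate_inputs(config)
  if (length(val$errors)) {
    stop("input validation failed: ", paste(val$errors, collapse = "; "),
         call. = FALSE)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  outputs <- character(0)
  stage <- "ingest"
  report <- list(parameters = list(
    clonotype_threshold = config$clonotype_threshold,
    min_consensus_size = config$min_consensus_size,
    selection_k = config$selection_k,
    downsample_n = config$downsample_n,
    downsample_seed = config$downsample_seed,
    sim_seed = if (is.null(config$input_path)) config$sim$seed else NULL,
    dialect = config$dialect
  ))
  result <- tryCatch({
    if (is.null(config$input_path)) {
      simulated <- generate_repertoire(config$sim, germlines)
      records <- simulated$records
      report$input <- list(source = "simulated", n_records = nrow(records))
    } else {
      records <- read_rearrangements(config$input_path, config$dialect)
      report$input <- list(source = config$input_path,
                           n_records = nrow(records))
    }

    stage <- "pairing"
    paired <- pair_cells(records)
    report$pairing <- unclass(paired$report)
    cells <- paired$cells

    stage <- "clonotyping"
    cts <- assign_clonotypes(cells, threshold = config$clonotype_threshold,
                             min_consensus_size = config$min_consensus_size)
    report$clonotyping <- list(n_clonotypes = nrow(cts$clonotypes),
                               n_cells = nrow(cts$members))

    stage <- "downsample"
    div_cells <- cells
    if (!is.null(config$downsample_n)) {
      div_cells <- downsample(cells, config$downsample_n,
                              config$downsample_seed)
    }
    div_cts <- if (is.null(config$downsample_n)) cts else
      assign_clonotypes(div_cells, threshold = config$clonotype_threshold,
                        min_consensus_size = config$min_consensus_size)

    stage <- "diversity"
    sizes <- div_cts$clonotypes$size
    div <- diversity_summary(sizes, ranges = config$topn_ranges)
    vh_usage <- usage_table(div_cells, "v_call_heavy")
    report$diversity <- list(
      n_cells_used = nrow(div_cells),
      n_clonotypes = div$n_categories,
      gini_clonotype = div$gini,
      d50 = div$d50,
      topn_fractions = as.list(div$topn_fractions),
      gini_vh_usage = gini(vh_usage$count),
      n_vh_genes = nrow(vh_usage)
    )

    stage <- "shm_profile"
    is_target <- cells$v_call_light == germlines$prearranged_v &
      cells$locus_light == "IGK"
    profile <- NULL
    if (any(is_target)) {
      profile <- shm_profile(cells$sequence_aa_light[is_target], germlines)
      hs <- hotspot_report(profile, 7)
      report$shm <- list(
        n_light_chains = profile$n_sequences,
        mean_mutations = profile$mean_mutations,
        region_any_mutation_fraction =
          as.list(profile$region_any_mutation_fraction),
        no_cdr_mutation_fraction = profile$no_cdr_mutation_fraction,
        hotspots = hs$label
      )
    } else {
      report$shm <- list(n_light_chains = 0L)
    }

    stage <- "selection"
    selection <- select_clones(cts, config$selection_k,
                               min_size = config$min_consensus_size)
    report$selection <- list(n_selected = nrow(selection),
                             n_eligible_clonotypes =
                               sum(cts$clonotypes$size >=
                                     config$min_consensus_size))

    stage <- "write"
    if (!is.null(out_dir)) {
      w <- function(df, name) {
        p <- file.path(out_dir, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs <<- c(outputs, p)
      }
      w(records, "records.tsv")
      w(cts$clonotypes, "clonotypes.tsv")
      w(cts$members[, c("cell_id", "clonotype_id")], "membership.tsv")
      w(selection, "selection.tsv")
      w(vh_usage, "vh_usage.tsv")
      if (!is.null(profile)) {
        ptab <- data.frame(label = profile$labels,
                           region = label_region(profile$labels,
                                                 profile$region_defs),
                           n_covered = as.integer(profile$n_covered),
                           n_mutated = as.integer(profile$n_mutated),
                           freq = profile$per_position_freq)
        w(ptab, "shm_profile.tsv")
      }
      rp <- file.path(out_dir, "report.json")
      jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <- c(outputs, rp)
      write_manifest(out_dir, outputs, complete = TRUE)
    }
    structure(list(report = report, cells = cells, clonotypes = cts,
                   diversity = div, shm = profile, selection = selection),
              class = "pipeline_report")
  }, error = function(e) {
    if (!is.null(out_dir)) {
      write_manifest(out_dir, outputs, complete = FALSE, failed_stage = stage,
                     reason = conditionMessage(e))
    }
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

write_manifest <- function(out_dir, outputs, complete, failed_stage = NULL,
                           reason = NULL) {
  mf <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  lines <- c(sprintf("complete: %s", tolower(complete)))
  if (!is.null(failed_stage)) {
    lines <- c(lines, sprintf("failed_stage: %s", failed_stage),
               sprintf("reason: %s", reason))
  }
  lines <- c(lines, sprintf("%s  %s", mf$md5, mf$file))
  writeLines(lines, file.path(out_dir, "MANIFEST"))
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("Repertoire pipeline report\n")
  cat(sprintf("  input    : %s (%d records)\n", r$input$source,
              r$input$n_records))
  cat(sprintf("  pairing  : %d/%d cells kept\n", r$pairing$n_paired,
              r$pairing$n_cells_in))
  cat(sprintf("  clonotypes: %d (threshold %.2f)\n",
              r$clonotyping$n_clonotypes, r$parameters$clonotype_threshold))
  cat(sprintf("  diversity: D50 %d, Gini(sizes) %.3f, top-10 %.1f%%\n",
              r$diversity$d50, r$diversity$gini_clonotype,
              100 * r$diversity$topn_fractions[["1-10"]]))
  if (!is.null(r$shm$mean_mutations)) {
    cat(sprintf("  SHM      : %.2f mean mutations over %d light chains\n",
                r$shm$mean_mutations, r$shm$n_light_chains))
  }
  cat(sprintf("  selection: %d clones\n", r$selection$n_selected))
  invisible(x)
}
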