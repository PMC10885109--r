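#' Default per-position light-chain SHM rates
#'
#' Per-Chothia-label substitution probabilities for the simulated light
#' chain. Hotspots sit at CDR-L1 labels 30-32, CDR-L3 labels 92-94 and
#' framework label 83; the remaining positions carry a uniform background
#' chosen so the rates sum to `total` (default 4.9 expected amino-acid
#' mutations per light chain, the repertoire-mean the generator emulates).
#'
#' @param numbering_map character labels of the light chain positions.
#' @param total target sum of rates (expected mutations per chain).
#' @return named numeric vector of rates over `numbering_map`.
#' @export
default_shm_rates <- function(numbering_map = default_germlines()$numbering_map,
                              total = 4.9) {
  hot <- c("30" = 0.40, "31" = 0.40, "32" = 0.20,
           "92" = 0.50, "93" = 0.50, "94" = 0.22, "83" = 0.30)
  rates <- setNames(rep(0, length(numbering_map)), numbering_map)
  present <- intersect(names(hot), numbering_map)
  rates[present] <- hot[present]
  rest <- setdiff(numbering_map, present)
  leftover <- total - sum(rates)
  if (leftover < 0) stop("total below the summed hotspot rates", call. = FALSE)
  rates[rest] <- leftover / length(rest)
  rates
}

#' Simulation configuration
#'
#' Validated parameter bundle for [generate_repertoire()]. Defaults describe
#' a common-light-chain-like pool: every light chain derives from the
#' prearranged kappa germline, isotypes are IgG-dominated with about 10%
#' IgG1, clone sizes follow a truncated power law, and light-chain SHM
#' follows [default_shm_rates()].
#'
#' @param n_cells number of B cells to emit.
#' @param clone_size_law list with `family = "power"`, `exponent` (Zipf
#'   exponent; default 2.0) and `n_clonotypes` (size of the clonotype pool
#'   cells are drawn from).
#' @param heavy_v_usage named probability vector over heavy V genes; names
#'   must exist in the germline set. Default: geometric-decay usage over the
#'   packaged genes.
#' @param shm_rates named per-label substitution probabilities for the light
#'   chain.
#' @param heavy_shm_rate mean framework substitutions per heavy chain
#'   (Poisson).
#' @param cdrh3_shm_rate mean substitutions per CDR-H3 within a clone
#'   (Poisson; default 0.15, low enough that clonal identity stays high).
#' @param dual_allele_fraction probability that a cell reports the second,
#'   independently mutated light-chain lineage of its clonotype.
#' @param isotype_probs named probability vector over heavy constant genes.
#' @param light_v_usage named probability vector over light V genes
#'   (default: all mass on the prearranged kappa gene).
#' @param lambda_fraction probability of a lambda light chain.
#' @param multiplet_rate probability a cell emits one extra chain and hence
#'   fails the exactly-one-heavy/one-light filter.
#' @param seed integer seed; all downstream generation is deterministic
#'   given the configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 3000,
                       clone_size_law = list(family = "power", exponent = 2.0,
                                             n_clonotypes = 515),
                       heavy_v_usage = NULL,
                       shm_rates = default_shm_rates(),
                       heavy_shm_rate = 2.0,
                       cdrh3_shm_rate = 0.15,
                       dual_allele_fraction = 0.2,
                       isotype_probs = c(IGHG1 = 0.10, IGHG2B = 0.38,
                                         IGHG2C = 0.38, IGHA = 0.05,
                                         IGHD = 0.04, IGHM = 0.05),
                       light_v_usage = c(`IGKV10-96` = 1.0),
                       lambda_fraction = 0.0002,
                       multiplet_rate = 0.25,
                       seed = 1L) {
  if (is.null(heavy_v_usage)) {
    genes <- names(default_germlines()$heavy_v)
    w <- 0.75 ^ seq_along(genes)
    heavy_v_usage <- setNames(w / sum(w), genes)
  }
  cfg <- structure(list(
    n_cells = n_cells, clone_size_law = clone_size_law,
    heavy_v_usage = heavy_v_usage, shm_rates = shm_rates,
    heavy_shm_rate = heavy_shm_rate, cdrh3_shm_rate = cdrh3_shm_rate,
    dual_allele_fraction = dual_allele_fraction,
    isotype_probs = isotype_probs, light_v_usage = light_v_usage,
    lambda_fraction = lambda_fraction, multiplet_rate = multiplet_rate,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells > 0)
  for (v in list(cfg$heavy_v_usage, cfg$isotype_probs, cfg$light_v_usage)) {
    if (abs(sum(v) - 1) > 1e-9) {
      stop("probability vector does not sum to 1", call. = FALSE)
    }
    if (any(v < 0)) stop("negative probability", call. = FALSE)
  }
  rates <- c(cfg$shm_rates, cfg$dual_allele_fraction, cfg$lambda_fraction,
             cfg$multiplet_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(cfg$clone_size_law$family, "power")) {
    stop("unsupported clone_size_law family '", cfg$clone_size_law$family,
         "'", call. = FALSE)
  }
  invisible(cfg)
}

#' Zipf exponent matching a target top-10 clonotype occupancy
#'
#' Solves for the power-law exponent `s` such that, with clonotype rank
#' probabilities proportional to `rank^-s` over `n_clonotypes` clonotypes,
#' the ten largest clonotypes hold `target` of the repertoire. Used by the
#' repertoire presets to plant the occupancy structure being emulated.
#'
#' @param n_clonotypes size of the clonotype pool.
#' @param target top-10 mass in (0, 1).
#' @return exponent `s`.
#' @export
power_exponent_for_top10 <- function(n_clonotypes, target) {
  f <- function(s) {
    w <- seq_len(n_clonotypes) ^ (-s)
    sum(w[1:10]) / sum(w) - target
  }
  stats::uniroot(f, c(1e-6, 5))$root
}

#' Preset: common-light-chain-like repertoire
#'
#' 3915 input cells of which ~2884 survive the exactly-one-pair filter (the
#' pairing loss is expressed through the multiplet rate), drawn from a
#' 515-clonotype pool with a Zipf exponent solved so the planted top-10
#' occupancy is 26%; all kappa light chains derive from the prearranged
#' germline; lambda essentially absent (0.02%).
#'
#' @param seed integer seed.
#' @param n_cells cells to emit (default 3915).
#' @param multiplet_rate chain-multiplet probability (default targets ~2884
#'   surviving pairs).
#' @return `sim_config`.
#' @export
sim_config_clc <- function(seed = 1L, n_cells = 3915,
                           multiplet_rate = 1 - 2884 / 3915) {
  s <- power_exponent_for_top10(515, 0.26)
  sim_config(n_cells = n_cells,
             clone_size_law = list(family = "power", exponent = s,
                                   n_clonotypes = 515),
             multiplet_rate = multiplet_rate,
             seed = seed)
}

#' Preset: wildtype-like repertoire
#'
#' 6173 input cells of which ~2884 survive the pairing filter, over a
#' 704-clonotype pool with top-10 occupancy 14%; light chains drawn from a
#' diverse kappa gene set with 13.4% usage of the dominant gene and 2%
#' lambda; light-chain SHM scaled to a mean of 6.4 substitutions.
#'
#' @param seed integer seed.
#' @param n_cells cells to emit (default 6173).
#' @param multiplet_rate chain-multiplet probability (default targets ~2884
#'   surviving pairs).
#' @return `sim_config`.
#' @export
sim_config_wildtype <- function(seed = 1L, n_cells = 6173,
                                multiplet_rate = 1 - 2884 / 6173) {
  s <- power_exponent_for_top10(704, 0.14)
  germ <- default_germlines()
  kappa <- setdiff(grep("^IGKV", names(germ$light_v), value = TRUE),
                   "IGKV10-96")
  w <- 0.8 ^ seq_along(kappa)
  usage <- c(0.134, (1 - 0.134) * w / sum(w))
  names(usage) <- c("IGKV10-96", kappa)
  heavy_genes <- names(germ$heavy_v)
  hw <- 0.75 ^ seq_along(heavy_genes)
  hw <- hw[c(2L, 1L, seq_along(heavy_genes)[-(1:2)])]  # IGHV5-17 dominant
  sim_config(n_cells = n_cells,
             clone_size_law = list(family = "power", exponent = s,
                                   n_clonotypes = 704),
             heavy_v_usage = setNames(hw / sum(hw), heavy_genes),
             shm_rates = default_shm_rates(total = 6.4),
             light_v_usage = usage,
             lambda_fraction = 0.02,
             multiplet_rate = multiplet_rate,
             seed = seed)
}

#' Generate a synthetic paired-BCR repertoire with ground truth
#'
#' Emits an annotated rearrangement table of the shape produced by
#' single-cell V(D)J annotation (one heavy and one light record per cell,
#' plus occasional extra chains for multiplets) together with a ground-truth
#' table recording each cell's planted clonotype and mutated positions.
#'
#' Cells are assigned to a pool of clonotypes with probabilities following
#' the configured power law. Each clonotype carries a fixed heavy V gene and
#' founder CDR-H3; cells accumulate Poisson framework SHM and (rarely)
#' CDR-H3 substitutions. Light-chain mutation masks are drawn independently
#' per cell from `shm_rates` (clonal correlation of light-chain SHM is not
#' modeled), so empirical per-position frequencies converge to the planted
#' rates with binomial standard errors. With probability
#' `dual_allele_fraction` a cell is annotated as reporting its second,
#' independently mutated light-chain allele, emulating the unresolvable
#' dual-allele mixture of a homozygous prearranged locus; both alleles
#' follow the same mutation law.
#'
#' @param config a [sim_config()].
#' @param germlines a [germline_set()]; default [default_germlines()].
#' @return list with `records` (rearrangement data frame) and `truth`
#'   (per-cell: `cell_id`, `true_clonotype`, `v_gene`, `founder_cdr3`,
#'   `light_lineage`, `n_light_mutations`, `light_mutated_labels`,
#'   `n_heavy_mutations`).
#' @export
generate_repertoire <- function(config, germlines = default_germlines()) {
  validate_sim_config(config)
  unknown <- setdiff(names(config$heavy_v_usage), names(germlines$heavy_v))
  if (length(unknown)) {
    stop("heavy_v_usage names unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_l <- setdiff(names(config$light_v_usage), names(germlines$light_v))
  if (length(unknown_l)) {
    stop("light_v_usage names unknown gene(s): ",
         paste(unknown_l, collapse = ", "), call. = FALSE)
  }
  if (!identical(names(config$shm_rates), germlines$numbering_map)) {
    if (length(config$shm_rates) != nchar(germlines$prearranged_lc)) {
      stop("shm_rates length does not match the prearranged light chain",
           call. = FALSE)
    }
  }
  with_seed(config$seed, generate_repertoire_impl(config, germlines))
}

generate_repertoire_impl <- function(cfg, germ) {
  n <- cfg$n_cells
  n_ct <- cfg$clone_size_law$n_clonotypes
  expo <- cfg$clone_size_law$exponent
  w <- seq_len(n_ct) ^ (-expo)
  ct_of_cell <- sample.int(n_ct, n, replace = TRUE, prob = w / sum(w))

  # clonotype-level draws
  ct_gene <- sample(names(cfg$heavy_v_usage), n_ct, replace = TRUE,
                    prob = cfg$heavy_v_usage)
  ct_cdr3_len <- sample(9:18, n_ct, replace = TRUE)
  # cdr3_aa excludes the conserved junction anchors (AIRR convention), so a
  # liability-free founder carries no obligatory cysteine
  ct_cdr3 <- vapply(ct_cdr3_len, function(L) {
    paste(sample(setdiff(AA_ALPHABET, "C"), L, replace = TRUE), collapse = "")
  }, character(1))
  lc_chars <- strsplit(germ$prearranged_lc, "")[[1]]
  lc_len <- length(lc_chars)
  rates <- unname(cfg$shm_rates)

  # per-cell draws (column-wise; one RNG call per quantity keeps the stream
  # layout stable and the loop fast)
  cell_id <- sprintf("cell%05d", seq_len(n))
  gene <- ct_gene[ct_of_cell]
  n_cdr3_mut <- stats::rpois(n, cfg$cdrh3_shm_rate)
  n_h_mut <- stats::rpois(n, cfg$heavy_shm_rate)
  isotype <- sample(names(cfg$isotype_probs), n, replace = TRUE,
                    prob = cfg$isotype_probs)
  is_lambda <- stats::runif(n) < cfg$lambda_fraction
  light_v_gene <- if (length(cfg$light_v_usage) == 1L) {
    rep(names(cfg$light_v_usage), n)
  } else {
    sample(names(cfg$light_v_usage), n, replace = TRUE,
           prob = cfg$light_v_usage)
  }
  lineage <- ifelse(stats::runif(n) < cfg$dual_allele_fraction, 2L, 1L)
  mask <- matrix(stats::runif(n * lc_len), nrow = n, byrow = TRUE) <
    matrix(rates, nrow = n, ncol = lc_len, byrow = TRUE)
  is_multiplet <- stats::runif(n) < cfg$multiplet_rate
  multiplet_side_heavy <- stats::runif(n) < 0.5

  # cached character vectors
  prefix_chars <- lapply(germ$heavy_v, function(g) strsplit(g$prefix_aa, "")[[1]])
  light_base <- lapply(names(germ$light_v), function(lv) {
    lj <- if (grepl("^IGL", lv)) "IGLJ1" else germ$prearranged_j
    res <- if (lv == germ$prearranged_v) germ$prearranged_lc else
      build_prearranged_lc(germ$light_v[[lv]], germ$light_j[[lj]], "W")$sequence
    strsplit(res, "")[[1]]
  })
  names(light_base) <- names(germ$light_v)
  lambda_gene <- grep("^IGL", names(germ$light_v), value = TRUE)[1]
  lab <- germ$numbering_map
  reg_idx <- lapply(germ$regions, function(r) {
    idx <- match(r, lab)
    idx[!is.na(idx)]
  })

  heavy_cdr3 <- character(n)
  heavy_aa <- character(n)
  light_aa <- character(n)
  light_cdr <- matrix("", n, 3)
  n_light_mut <- integer(n)
  light_labels <- character(n)
  for (i in seq_len(n)) {
    ct <- ct_of_cell[i]
    g <- germ$heavy_v[[gene[i]]]
    cdr3 <- ct_cdr3[ct]
    if (n_cdr3_mut[i] > 0) {
      ch3 <- strsplit(cdr3, "")[[1]]
      for (p in sample.int(length(ch3), min(n_cdr3_mut[i], length(ch3)))) {
        ch3 <- substitute_residue(ch3, p)
      }
      cdr3 <- paste(ch3, collapse = "")
    }
    prefix <- prefix_chars[[gene[i]]]
    if (n_h_mut[i] > 0) {
      for (p in sample.int(length(prefix), min(n_h_mut[i], length(prefix)))) {
        prefix <- substitute_residue(prefix, p)
      }
    }
    heavy_cdr3[i] <- cdr3
    heavy_aa[i] <- paste0(paste(prefix, collapse = ""), cdr3, g$suffix_aa)

    if (is_lambda[i]) {
      light_v_gene[i] <- lambda_gene
      lineage[i] <- NA_integer_
      chars <- light_base[[lambda_gene]]
      m <- rep(FALSE, lc_len)
    } else {
      chars <- light_base[[light_v_gene[i]]]
      m <- mask[i, ]
      for (p in which(m)) chars <- substitute_residue(chars, p)
    }
    light_aa[i] <- paste(chars, collapse = "")
    light_cdr[i, ] <- vapply(reg_idx, function(idx)
      paste(chars[idx], collapse = ""), character(1))
    n_light_mut[i] <- sum(m)
    light_labels[i] <- paste(lab[which(m)], collapse = ",")
  }

  locus_l <- ifelse(is_lambda, "IGL", "IGK")
  heavy <- data.frame(
    cell_id = cell_id, sequence_id = paste0(cell_id, "_H"),
    locus = "IGH", v_call = gene, j_call = "IGHJ2", c_call = isotype,
    productive = TRUE,
    cdr1_aa = vapply(germ$heavy_v[gene], `[[`, character(1), "cdr1_aa"),
    cdr2_aa = vapply(germ$heavy_v[gene], `[[`, character(1), "cdr2_aa"),
    cdr3_aa = heavy_cdr3,
    sequence_aa = heavy_aa, sequence = back_translate(heavy_aa),
    stringsAsFactors = FALSE
  )
  light <- data.frame(
    cell_id = cell_id, sequence_id = paste0(cell_id, "_L"),
    locus = locus_l, v_call = light_v_gene,
    j_call = ifelse(is_lambda, "IGLJ1", germ$prearranged_j),
    c_call = ifelse(is_lambda, "IGLC1", "IGKC"),
    productive = TRUE,
    cdr1_aa = light_cdr[, 1], cdr2_aa = light_cdr[, 2],
    cdr3_aa = light_cdr[, 3],
    sequence_aa = light_aa, sequence = back_translate(light_aa),
    stringsAsFactors = FALSE
  )
  extra_h <- heavy[is_multiplet & multiplet_side_heavy, , drop = FALSE]
  extra_l <- light[is_multiplet & !multiplet_side_heavy, , drop = FALSE]
  extra <- rbind(extra_h, extra_l)
  if (nrow(extra)) extra$sequence_id <- paste0(extra$sequence_id, "x")
  records <- rbind(heavy, light, extra)
  records <- records[order(records$cell_id, records$sequence_id), ]
  rownames(records) <- NULL
  truth <- data.frame(
    cell_id = cell_id,
    true_clonotype = sprintf("TC%05d", ct_of_cell),
    v_gene = gene,
    founder_cdr3 = ct_cdr3[ct_of_cell],
    light_lineage = lineage,
    n_light_mutations = n_light_mut,
    light_mutated_labels = light_labels,
    n_heavy_mutations = n_h_mut + n_cdr3_mut,
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth)
}

#' Binning-panel simulation configuration
#'
#' @param n_references number of immobilized reference antibodies (>= 2).
#' @param n_panel number of test-panel antibodies.
#' @param ref_bins,panel_bins planted bin labels (characters) per reference
#'   and panel antibody; defaults cycle three bins.
#' @param signal_geomean expected fluorescence geomean of un-competed
#'   binding.
#' @param reference_alone_geomean per-reference single-bead control geomean.
#' @param competition_factor multiplicative signal suppression when
#'   reference and panel antibody share a bin (0 = full competition).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   noise on the binding signal.
#' @param seed integer seed.
#' @return object of class `bin_sim_config`.
#' @export
bin_sim_config <- function(n_references = 3, n_panel = 9,
                           ref_bins = NULL, panel_bins = NULL,
                           signal_geomean = 1000,
                           reference_alone_geomean = 400,
                           competition_factor = 0,
                           noise_cv = 0.05, seed = 1L) {
  if (n_references < 2) {
    stop("need at least 2 references (profile correlation undefined)",
         call. = FALSE)
  }
  if (competition_factor < 0 || competition_factor >= 1) {
    stop("competition_factor must lie in [0, 1)", call. = FALSE)
  }
  if (signal_geomean <= 0) stop("signal_geomean must be > 0", call. = FALSE)
  if (is.null(ref_bins)) ref_bins <- LETTERS[(seq_len(n_references) - 1L) %% 3L + 1L]
  if (is.null(panel_bins)) panel_bins <- LETTERS[(seq_len(n_panel) - 1L) %% 3L + 1L]
  stopifnot(length(ref_bins) == n_references, length(panel_bins) == n_panel)
  structure(list(n_references = n_references, n_panel = n_panel,
                 ref_bins = ref_bins, panel_bins = panel_bins,
                 signal_geomean = signal_geomean,
                 reference_alone_geomean = reference_alone_geomean,
                 competition_factor = competition_factor,
                 noise_cv = noise_cv, seed = seed),
            class = "bin_sim_config")
}

#' Generate a synthetic competitive-binning bead table
#'
#' Emulates a bead-based competition experiment: each reference antibody is
#' immobilized on its own bead type, panel antibodies are added, and the
#' total fluorescence geomean of each (reference, panel) pair is recorded
#' together with a per-reference single-bead control. When reference and
#' panel antibody share a planted epitope bin, the panel antibody's binding
#' signal is suppressed by `competition_factor`; multiplicative log-normal
#' noise with the configured CV acts on the signal term only, so the
#' single-bead control is exact.
#'
#' @param config a [bin_sim_config()].
#' @return list with `table` (long-format data frame: `reference_id`,
#'   `panel_id`, `total_geomean`, `reference_alone_geomean`) and `truth`
#'   (planted `ref_bins`, `panel_bins`).
#' @export
generate_binning_panel <- function(config) {
  stopifnot(inherits(config, "bin_sim_config"))
  with_seed(config$seed, {
    refs <- sprintf("REF%02d", seq_len(config$n_references))
    panel <- sprintf("AB%02d", seq_len(config$n_panel))
    grid <- expand.grid(reference_id = refs, panel_id = panel,
                        stringsAsFactors = FALSE)
    same_bin <- config$ref_bins[match(grid$reference_id, refs)] ==
      config$panel_bins[match(grid$panel_id, panel)]
    signal <- config$signal_geomean *
      ifelse(same_bin, config$competition_factor, 1)
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      noise <- stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      signal <- signal * noise
    }
    grid$total_geomean <- config$reference_alone_geomean + signal
    grid$reference_alone_geomean <- config$reference_alone_geomean
    list(table = grid,
         truth = list(ref_bins = setNames(config$ref_bins, refs),
                      panel_bins = setNames(config$panel_bins, panel)))
  })
}
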