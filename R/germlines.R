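#' Germline reference sets
#'
#' A `germline_set` bundles everything downstream stages need to know about
#' the germline context of a repertoire: heavy-chain V genes (amino-acid
#' prefix through the conserved `...YYCAR` motif plus CDR-H1/H2 annotations),
#' light-chain V and J segments, the joined ("prearranged") light chain with
#' the position-96 substitution applied, a Chothia-style numbering map for
#' that light chain, and CDR region definitions on those labels.
#'
#' The sequences shipped by [default_germlines()] are synthetic stand-ins of
#' realistic length and composition, constructed so the package is fully
#' testable without downloading reference databases. Real germline sequences
#' (e.g. from IMGT) are accepted as drop-in replacements through this
#' constructor.
#'
#' @param heavy_v named list; each element a list with `prefix_aa` (amino
#'   acids through the end of framework 3, ending at the CDR-H3 boundary),
#'   `cdr1_aa`, `cdr2_aa`, `suffix_aa` (J-segment tail appended after
#'   CDR-H3).
#' @param light_v named list of light V amino-acid sequences; kappa genes are
#'   recognized by an `IGK` prefix, lambda by `IGL`.
#' @param light_j named list of light J amino-acid sequences.
#' @param position96_residue single residue placed at Chothia label 96 of the
#'   prearranged light chain (default `"L"`, the tryptophan-to-leucine
#'   liability substitution).
#' @param prearranged_v,prearranged_j names of the light V and J genes joined
#'   into the prearranged light chain.
#' @param regions named list mapping region names (`CDR-L1`, `CDR-L2`,
#'   `CDR-L3`) to character vectors of numbering labels; defaults to
#'   [chothia_light_regions()].
#' @return An object of class `germline_set`.
#' @export
germline_set <- function(heavy_v, light_v, light_j,
                         position96_residue = "L",
                         prearranged_v = names(light_v)[1],
                         prearranged_j = names(light_j)[1],
                         regions = chothia_light_regions()) {
  stopifnot(is.list(heavy_v), length(heavy_v) > 0, !is.null(names(heavy_v)))
  stopifnot(is.list(light_v), length(light_v) > 0, !is.null(names(light_v)))
  stopifnot(is.list(light_j), length(light_j) > 0, !is.null(names(light_j)))
  assert_aa(unlist(light_v), "light V")
  assert_aa(unlist(light_j), "light J")
  for (g in heavy_v) {
    assert_aa(c(g$prefix_aa, g$cdr1_aa, g$cdr2_aa, g$suffix_aa), "heavy V part")
  }
  pre <- build_prearranged_lc(light_v[[prearranged_v]],
                              light_j[[prearranged_j]],
                              position96_residue = position96_residue)
  obj <- structure(list(
    heavy_v = heavy_v,
    light_v = light_v,
    light_j = light_j,
    prearranged_v = prearranged_v,
    prearranged_j = prearranged_j,
    prearranged_lc = pre$sequence,
    numbering_map = pre$numbering_map,
    regions = regions
  ), class = "germline_set")
  validate_germline_set(obj)
  obj
}

validate_germline_set <- function(x) {
  nm <- x$numbering_map
  n <- nchar(x$prearranged_lc)
  if (length(nm) != n) {
    stop("numbering_map must cover every index of the prearranged light chain",
         call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("numbering_map labels must be injective", call. = FALSE)
  }
  idx96 <- match("96", nm)
  if (is.na(idx96)) stop("numbering_map must contain label 96", call. = FALSE)
  invisible(x)
}

#' @export
print.germline_set <- function(x, ...) {
  cat("Germline set\n")
  cat(sprintf("  heavy V genes : %d (%s%s)\n", length(x$heavy_v),
              paste(utils::head(names(x$heavy_v), 3), collapse = ", "),
              if (length(x$heavy_v) > 3) ", ..." else ""))
  cat(sprintf("  light V genes : %d; prearranged %s/%s\n",
              length(x$light_v), x$prearranged_v, x$prearranged_j))
  cat(sprintf("  prearranged LC: %d aa, residue at Chothia 96 = %s\n",
              nchar(x$prearranged_lc),
              substr(x$prearranged_lc, match("96", x$numbering_map),
                     match("96", x$numbering_map))))
  invisible(x)
}

#' Join a light V and J segment into a prearranged light chain
#'
#' Concatenates the V and J amino-acid segments and applies the configured
#' residue at Chothia label 96 (the first J-encoded position, a tryptophan in
#' unmodified kappa J1 segments and an oxidation liability inside CDR-L3).
#' The returned numbering map assigns sequential Chothia-style labels
#' (`"1"`, `"2"`, ...) to each index; the fixture light chain carries no
#' insertions, so labels are plain integers with the V segment ending at
#' label 95.
#'
#' @param light_v amino-acid sequence of the V segment (ends at label 95).
#' @param light_j amino-acid sequence of the J segment (starts at label 96).
#' @param position96_residue residue to place at label 96; use `"W"` to keep
#'   the unmodified join.
#' @return list with `sequence` (joined amino acids) and `numbering_map`
#'   (character vector of labels, one per sequence index).
#' @export
build_prearranged_lc <- function(light_v, light_j, position96_residue = "L") {
  assert_aa(light_v, "light V")
  assert_aa(light_j, "light J")
  if (!position96_residue %in% AA_ALPHABET) {
    stop("position96_residue must be one of the 20 amino acids", call. = FALSE)
  }
  joined <- paste0(light_v, light_j)
  chars <- strsplit(joined, "")[[1]]
  pos96 <- nchar(light_v) + 1L
  chars[pos96] <- position96_residue
  seq <- paste(chars, collapse = "")
  labels <- as.character(seq_len(nchar(seq)) + (95L - nchar(light_v)))
  list(sequence = seq, numbering_map = labels)
}

#' Default CDR region definitions for kappa light chains
#'
#' Chothia-style loop boundaries on the packaged numbering: CDR-L1 = 24-34,
#' CDR-L2 = 50-56, CDR-L3 = 89-97. All other labels are framework.
#'
#' @return named list of character label vectors.
#' @export
chothia_light_regions <- function() {
  list(`CDR-L1` = as.character(24:34),
       `CDR-L2` = as.character(50:56),
       `CDR-L3` = as.character(89:97))
}

# Deterministically derive a gene variant from a base sequence by
# substituting fixed positions; used only to give the synthetic fixture
# genes distinguishable sequences.
make_variant <- function(base, gene_index, positions) {
  chars <- strsplit(base, "")[[1]]
  for (k in seq_along(positions)) {
    p <- positions[k]
    repl <- AA_ALPHABET[((gene_index * 7L + k * 3L) %% 20L) + 1L]
    if (repl == chars[p]) repl <- AA_ALPHABET[((gene_index * 7L + k * 3L + 1L) %% 20L) + 1L]
    chars[p] <- repl
  }
  paste(chars, collapse = "")
}

#' Packaged synthetic germline fixtures
#'
#' Returns a [germline_set()] of synthetic stand-in sequences with realistic
#' lengths: 12 heavy V genes named after common mouse IGHV genes, a kappa V
#' fixture standing in for IGKV10-96 (95 aa, ending at Chothia label 95), a
#' J fixture standing in for IGKJ1 (12 aa, labels 96-107), eleven additional
#' kappa V fixtures and one lambda fixture for wildtype-like simulations.
#' The prearranged light chain carries leucine at Chothia 96.
#'
#' These sequences are fixtures, not database entries; substitute real
#' references via [germline_set()] for production analyses.
#'
#' @param position96_residue residue at Chothia 96 of the prearranged light
#'   chain; default `"L"`.
#' @return A `germline_set`.
#' @export
default_germlines <- function(position96_residue = "L") {
  fr1  <- "EVQLQQSGAELVKPGASVKLSCKAS"
  cdr1 <- "GYTFTSYW"
  fr2  <- "INWVKQRPGQGLEWIGR"
  cdr2 <- "IDPNSGGT"
  fr3  <- "KYNEKFKNKATLTVDKPSSTAYMQLSSLTSEDSAVYYCAR"
  base_prefix <- paste0(fr1, cdr1, fr2, cdr2, fr3)
  heavy_names <- c("IGHV1-64", "IGHV5-17", "IGHV1-9", "IGHV1-26",
                   "IGHV2-2", "IGHV3-6", "IGHV5-9", "IGHV6-3",
                   "IGHV8-8", "IGHV9-3", "IGHV10-1", "IGHV14-3")
  heavy_v <- lapply(seq_along(heavy_names), function(i) {
    prefix <- make_variant(base_prefix, i, positions = c(3L, 12L, 40L, 63L, 80L))
    list(prefix_aa = prefix,
         cdr1_aa = substr(prefix, 26L, 33L),
         cdr2_aa = substr(prefix, 51L, 58L),
         suffix_aa = "WGQGTLVTVSS")
  })
  names(heavy_v) <- heavy_names

  kappa_base <- paste0(
    "DIQMTQSPASLSASVGETVTITC",  # FR1, labels 1-23
    "RASENIYSNLA",              # CDR-L1, labels 24-34
    "WYQQKQGKSPQLLVY",          # FR2, labels 35-49
    "AATNLAD",                  # CDR-L2, labels 50-56
    "GVPSRFSGSGSGTQYSLKINSLQSEDFGSYYC",  # FR3, labels 57-88
    "QHFWGTP"                   # CDR-L3 V-encoded part, labels 89-95
  )
  kappa_names <- c("IGKV10-96", "IGKV14-111", "IGKV1-117", "IGKV4-55",
                   "IGKV6-15", "IGKV3-2", "IGKV8-21", "IGKV12-46",
                   "IGKV5-43", "IGKV2-137", "IGKV17-121", "IGKV9-120")
  light_v <- lapply(seq_along(kappa_names), function(i) {
    if (i == 1L) kappa_base else
      make_variant(kappa_base, i, positions = c(5L, 27L, 44L, 66L, 91L))
  })
  names(light_v) <- kappa_names
  light_v[["IGLV1"]] <- make_variant(kappa_base, 99L,
                                     positions = c(2L, 20L, 38L, 59L, 86L))

  light_j <- list(IGKJ1 = "WTFGSGTKLEIK", IGLJ1 = "WVFGGGTKLTVL")

  germline_set(heavy_v = heavy_v, light_v = light_v, light_j = light_j,
               position96_residue = position96_residue,
               prearranged_v = "IGKV10-96", prearranged_j = "IGKJ1")
}
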