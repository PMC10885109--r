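#' @keywords internal
"_PACKAGE"

# The 20 standard amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# One fixed codon per amino acid, used to back-translate amino-acid fixtures
# into nucleotide sequences for simulated records.
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

is_aa_string <- function(x) {
  ok <- nchar(x) > 0L
  ok & vapply(strsplit(x, ""), function(ch) all(ch %in% AA_ALPHABET),
              logical(1))
}

assert_aa <- function(x, what = "sequence") {
  bad <- which(!is_aa_string(x))
  if (length(bad) > 0L) {
    chars <- setdiff(strsplit(x[bad[1]], "")[[1]], AA_ALPHABET)
    stop(sprintf("%s %d is not an uppercase amino-acid string (offending character '%s')",
                 what, bad[1], if (length(chars)) chars[1] else "<empty>"),
         call. = FALSE)
  }
  invisible(x)
}

back_translate <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) paste(AA_CODON[ch], collapse = ""),
         character(1))
}

#' Evaluate an expression under a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Random amino-acid strings (assumes caller controls the RNG).
random_aa <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute position `pos` of `seq` with a residue drawn uniformly from the
# 19 residues other than the current one.
substitute_residue <- function(chars, pos) {
  chars[pos] <- sample(setdiff(AA_ALPHABET, chars[pos]), 1L)
  chars
}
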