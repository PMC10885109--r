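paired_toy <- function(cdr3, v_gene = "IGHV1-1", seq_aa = NULL) {
  n <- length(cdr3)
  if (is.null(seq_aa)) seq_aa <- paste0("EVQ", cdr3)
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    sequence_id_heavy = sprintf("h%03d", seq_len(n)),
    v_call_heavy = rep_len(v_gene, n),
    cdr1_aa_heavy = "GYTFTSYW",
    cdr2_aa_heavy = "IDPNSGGT",
    cdr3_aa_heavy = cdr3,
    sequence_aa_heavy = seq_aa,
    stringsAsFactors = FALSE
  )
}

test_that("cdr3_identity counts matching positions", {
  expect_equal(cdr3_identity("CARDYW", "CARDYW"), 1.0)
  expect_equal(cdr3_identity("CARDYW", "CARDYF"), 5 / 6)
  expect_equal(cdr3_identity("CARDYW", "CARELW"), 4 / 6)
  expect_equal(cdr3_identity("CARDYW", "CARDYF"),
               ref_identity("CARDYW", "CARDYF"))
  expect_error(cdr3_identity("CARD", "CARDY"), "equal")
})

test_that("hamming distance equals a brute-force position loop", {
  expect_equal(hamming_to_consensus("CARDYW", "CARDYW"), 0)
  expect_equal(hamming_to_consensus("CARDYW", "CARDYF"), 1)
  set.seed(99)
  a <- paste(sample(LETTERS[1:20], 100, TRUE), collapse = "")
  b <- paste(sample(LETTERS[1:20], 100, TRUE), collapse = "")
  brute <- sum(vapply(1:100, function(i)
    substr(a, i, i) != substr(b, i, i), logical(1)))
  expect_equal(hamming_to_consensus(a, b), brute)
})

test_that("consensus takes the modal residue with a lexicographic tie rule", {
  expect_equal(consensus_sequence(c("CARDYW", "CARDYW", "CARDYW")), "CARDYW")
  expect_equal(consensus_sequence(c("CARDYW", "CARDYW", "CARDYF")), "CARDYW")
  expect_equal(consensus_sequence(c("CA", "CG")), "CA")
  expect_error(consensus_sequence(c("CA", "CAG")), "equal-length")
})

test_that("clonotype assignment follows the identity threshold and V gene", {
  # identical CDR-H3 and gene: one clonotype of size 2
  cts <- assign_clonotypes(paired_toy(c("CARDYW", "CARDYW")))
  expect_equal(nrow(cts$clonotypes), 1)
  expect_equal(cts$clonotypes$size, 2)

  # identity 5/6 >= 0.8: merged; 4/6 < 0.8: split
  cts2 <- assign_clonotypes(paired_toy(c("CARDYW", "CARDYF")))
  expect_equal(nrow(cts2$clonotypes), 1)
  cts3 <- assign_clonotypes(paired_toy(c("CARDYW", "CARELW")))
  expect_equal(nrow(cts3$clonotypes), 2)

  # same CDR-H3 but different heavy V gene: never merged
  cells <- rbind(paired_toy("CARDYW", "IGHV1-1"),
                 paired_toy("CARDYW", "IGHV2-2"))
  cells$cell_id <- c("x1", "x2")
  cts4 <- assign_clonotypes(cells)
  expect_equal(nrow(cts4$clonotypes), 2)
})

test_that("clonotypes partition the input cells", {
  out <- generate_repertoire(sim_config(n_cells = 300, seed = 21))
  cells <- pair_cells(out$records)$cells
  cts <- assign_clonotypes(cells)
  expect_equal(sum(cts$clonotypes$size), nrow(cells))
  expect_false(anyNA(cts$members$clonotype_id))
  expect_setequal(unique(cts$members$clonotype_id), cts$clonotypes$clonotype_id)
})

test_that("greedy clustering matches the independent reference on random blocks", {
  set.seed(1234)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    len <- sample(6:10, 1)
    # small alphabet so near-threshold identities actually occur
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "D", "E"), len, TRUE), collapse = ""),
      character(1))
    thr <- sample(c(0.7, 0.8, 0.9), 1)
    cts <- assign_clonotypes(paired_toy(seqs), threshold = thr)
    expect_true(same_partition(cts$members$clonotype_id,
                               as.character(ref_greedy(seqs, thr))))
  }
})

test_that("clonotype count is monotone non-increasing as the threshold drops", {
  out <- generate_repertoire(sim_config(n_cells = 400, cdrh3_shm_rate = 0.6,
                                        seed = 31))
  cells <- pair_cells(out$records)$cells
  counts <- vapply(c(0.9, 0.8, 0.7), function(thr)
    nrow(assign_clonotypes(cells, threshold = thr)$clonotypes), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("liability flags match the sequon and cysteine definitions", {
  expect_setequal(flag_liabilities(cdr3 = "ARNGSDY"), "nglyc_cdr")
  expect_equal(flag_liabilities(cdr3 = "ARNPSDY"), character(0))
  expect_setequal(flag_liabilities(cdr1 = "GFCFS"), "unpaired_cys_cdr")
  expect_setequal(flag_liabilities(cdr1 = "GFCFS", cdr3 = "ARNGTDY"),
                  c("nglyc_cdr", "unpaired_cys_cdr"))
  # sequon completed by the right flank still counts
  expect_setequal(flag_liabilities(cdr3 = "ARDN", flank3 = "GS"), "nglyc_cdr")
  # sequon starting outside the CDR does not
  expect_equal(flag_liabilities(cdr3 = "ARD", flank3 = "NG"), character(0))
  expect_error(flag_liabilities(cdr3 = "ARX"), "amino-acid")
})

test_that("clone selection ranks by size, hamming, and covers clonotypes first", {
  mk <- function(prefix, n, cdr3, v_gene, mutate_at = integer(0),
                 liab_at = integer(0)) {
    base <- paste0("EVQAAAAAAA", cdr3)
    seqs <- rep(base, n)
    for (i in mutate_at) substr(seqs[i], 4, 4) <- "M"
    cells <- paired_toy(rep(cdr3, n), v_gene, seqs)
    cells$cell_id <- sprintf("%s%02d", prefix, seq_len(n))
    cells$sequence_id_heavy <- sprintf("%s%02d", prefix, seq_len(n))
    if (length(liab_at)) cells$cdr2_aa_heavy[liab_at] <- "NGSNGSNG"
    cells
  }
  cells <- rbind(mk("a", 10, "ARDYWG", "IGHV1-1"),
                 mk("b", 6, "TREPFA", "IGHV2-2"))
  cts <- assign_clonotypes(cells)
  sel <- select_clones(cts, 4)
  # first two picks: one per clonotype, larger clonotype first
  expect_equal(sel$clonotype_size[1:2], c(10, 6))
  expect_equal(length(unique(sel$clonotype_id[1:2])), 2)
  expect_equal(sel$pick_round[1:2], c(1L, 1L))
  expect_equal(sel$pick_round[3:4], c(2L, 2L))

  # a liability-bearing minimal-hamming member is skipped
  cells2 <- mk("c", 8, "ARDYWG", "IGHV1-1", liab_at = 1)
  cts2 <- assign_clonotypes(cells2)
  sel2 <- select_clones(cts2, 1)
  expect_false(sel2$sequence_id %in% "c01")

  # k beyond the eligible pool returns everything available
  sel3 <- select_clones(cts, 1000)
  expect_lt(nrow(sel3), 1000)
  expect_equal(nrow(sel3), 16)

  # no clonotype of size >= 5: empty selection with a warning
  small <- assign_clonotypes(paired_toy(c("CARDYW", "CARDYW")))
  expect_warning(empty <- select_clones(small, 3), "empty selection")
  expect_equal(nrow(empty), 0)
})
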