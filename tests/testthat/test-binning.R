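long_table <- function(net, ref_alone) {
  grid <- expand.grid(reference_id = rownames(net), panel_id = colnames(net),
                      stringsAsFactors = FALSE)
  grid$total_geomean <- net[cbind(grid$reference_id, grid$panel_id)] +
    ref_alone[grid$reference_id]
  grid$reference_alone_geomean <- unname(ref_alone[grid$reference_id])
  grid
}

test_that("net geomean implements total minus single-bead control", {
  tab <- data.frame(reference_id = "R1", panel_id = "P1",
                    total_geomean = 1500, reference_alone_geomean = 400)
  expect_equal(as.numeric(net_geomean(tab)), 1100)
  tab$total_geomean <- 400
  expect_equal(as.numeric(net_geomean(tab)), 0)
})

test_that("net geomean on a random table equals the loop oracle", {
  set.seed(10)
  refs <- paste0("R", 1:3); panel <- paste0("P", 1:4)
  grid <- expand.grid(reference_id = refs, panel_id = panel,
                      stringsAsFactors = FALSE)
  grid$total_geomean <- runif(nrow(grid), 100, 2000)
  ra <- setNames(runif(3, 200, 600), refs)
  grid$reference_alone_geomean <- ra[grid$reference_id]
  net <- net_geomean(grid)
  for (k in seq_len(nrow(grid))) {
    expect_equal(net[grid$reference_id[k], grid$panel_id[k]],
                 grid$total_geomean[k] - ra[[grid$reference_id[k]]])
  }
  # negative values are retained, with a message rather than clipping
  grid$total_geomean[1] <- 0
  expect_message(net2 <- net_geomean(grid), "negative")
  expect_lt(net2[grid$reference_id[1], grid$panel_id[1]], 0)
})

test_that("net geomean validates completeness and controls", {
  tab <- data.frame(reference_id = c("R1", "R1", "R2"),
                    panel_id = c("P1", "P2", "P1"),
                    total_geomean = c(1, 2, 3),
                    reference_alone_geomean = c(1, 1, 2))
  expect_error(net_geomean(tab), "incomplete")
  tab2 <- data.frame(reference_id = "R1", panel_id = "P1", total_geomean = 5)
  expect_error(net_geomean(tab2), "reference_alone")
})

test_that("profile correlation matches the Pearson formula pairwise", {
  set.seed(11)
  net <- matrix(runif(30, 0, 1000), 5, 6,
                dimnames = list(paste0("R", 1:5), paste0("P", 1:6)))
  r <- correlate_profiles(net)$r_matrix
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  for (i in 1:6) for (j in 1:6) {
    expect_equal(r[i, j], pearson(net[, i], net[, j]))
  }
  expect_equal(diag(r), setNames(rep(1, 6), paste0("P", 1:6)))
  expect_equal(r, t(r))

  # identical columns correlate at 1; sign-flipped profiles at -1
  net2 <- cbind(A = net[, 1], B = net[, 1], C = max(net[, 1]) - net[, 1])
  r2 <- correlate_profiles(net2)$r_matrix
  expect_equal(r2["A", "B"], 1)
  expect_equal(r2["A", "C"], -1)
})

test_that("zero-variance profiles are excluded with a flag", {
  net <- cbind(A = c(1, 2, 3), B = c(5, 5, 5), C = c(3, 2, 1))
  rownames(net) <- paste0("R", 1:3)
  expect_message(res <- correlate_profiles(net), "zero-variance")
  expect_equal(res$excluded, "B")
  expect_equal(colnames(res$r_matrix), c("A", "C"))
  expect_error(correlate_profiles(net[1, , drop = FALSE]), "at least 2")
})

test_that("bin assignment is single-linkage with deterministic labels", {
  ids <- paste0("P", 1:5)
  r <- diag(5); dimnames(r) <- list(ids, ids)
  r[1, 2] <- r[2, 1] <- 0.95
  r[2, 3] <- r[3, 2] <- 0.95   # chain 1-2-3 even though r[1,3] is low
  r[1, 3] <- r[3, 1] <- 0.10
  r[4, 5] <- r[5, 4] <- 0.90
  ba <- assign_bins(r, threshold = 0.8)
  expect_equal(unname(ba$bins[c("P1", "P2", "P3")]), rep("A", 3))
  expect_equal(unname(ba$bins[c("P4", "P5")]), rep("B", 2))

  # nothing above threshold: every antibody is its own bin
  ba2 <- assign_bins(diag(5) * 1.0 + 0, threshold = 0.8)
  expect_equal(length(unique(ba2$bins)), 5)
  expect_error(assign_bins(r, threshold = 0), "\\(0, 1\\]")
})

test_that("bin assignment is invariant to input permutation", {
  set.seed(12)
  cfg <- bin_sim_config(n_references = 4, n_panel = 8,
                        ref_bins = c("A", "B", "C", "A"),
                        panel_bins = rep(c("A", "B", "C", "A"), 2),
                        competition_factor = 0.05, noise_cv = 0.05, seed = 3)
  net <- net_geomean(generate_binning_panel(cfg)$table)
  r <- correlate_profiles(net)$r_matrix
  ba <- assign_bins(r)
  perm <- sample(ncol(r))
  ba_p <- assign_bins(r[perm, perm])
  expect_identical(ba$bins[names(ba_p$bins)], ba_p$bins)
})

test_that("raising the threshold never merges bins", {
  set.seed(13)
  cfg <- bin_sim_config(n_references = 5, n_panel = 10,
                        ref_bins = LETTERS[c(1, 2, 3, 1, 2)],
                        panel_bins = LETTERS[rep(1:3, length.out = 10)],
                        competition_factor = 0.1, noise_cv = 0.15, seed = 9)
  r <- correlate_profiles(net_geomean(generate_binning_panel(cfg)$table))$r_matrix
  lo <- assign_bins(r, 0.6)$bins
  hi <- assign_bins(r, 0.9)$bins
  # refinement: antibodies sharing a bin at the high threshold also share at the low
  for (b in unique(hi)) {
    members <- names(hi)[hi == b]
    expect_equal(length(unique(lo[members])), 1)
  }
})

test_that("planted bins are recovered end-to-end at the default threshold", {
  for (seed in 1:5) {
    cfg <- bin_sim_config(n_references = 6, n_panel = 12,
                          ref_bins = rep(c("A", "B", "C"), 2),
                          panel_bins = rep(c("A", "B", "C"), 4),
                          competition_factor = 0, noise_cv = 0.05,
                          seed = seed)
    out <- generate_binning_panel(cfg)
    r <- correlate_profiles(net_geomean(out$table))$r_matrix
    ba <- assign_bins(r, 0.8)
    expect_true(same_partition(unname(ba$bins),
                               unname(out$truth$panel_bins[names(ba$bins)])))
  }
})

test_that("benchmark matching assigns bins or flags novelty", {
  refs <- paste0("R", 1:4)
  bench_net <- cbind(B1 = c(0, 800, 800, 800), B2 = c(800, 0, 800, 800))
  rownames(bench_net) <- refs
  panel_net <- cbind(P1 = c(10, 790, 805, 810),   # tracks B1
                     P2 = c(400, 420, 390, 410))  # flat: matches nothing
  rownames(panel_net) <- refs
  res <- benchmark_binning(panel_net, bench_net,
                           benchmark_bins = c(B1 = "C", B2 = "D"),
                           threshold = 0.8)
  expect_equal(res$matched_bin[res$panel_id == "P1"], "C")
  expect_true(res$novel[res$panel_id == "P2"])
  expect_error(benchmark_binning(panel_net, bench_net[, 0],
                                 benchmark_bins = character(0)), "empty")
})
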