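test_that("gini matches the pairwise-difference definition", {
  expect_equal(gini(c(5, 5, 5, 5)), 0)
  expect_equal(gini(c(0, 0, 0, 10)), 0.75)
  expect_equal(gini(c(1, 2, 3, 4)), 0.25)  # sum |xi-xj| = 20; 2 n^2 mu = 80
  set.seed(5)
  for (i in 1:10) {
    x <- rpois(sample(3:30, 1), lambda = 4) + ifelse(i %% 2, 0, 1)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini(x), ref_gini(x))
  }
  expect_error(gini(c(0, 0)), "all-zero")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("d50 is the smallest k reaching half the repertoire", {
  expect_equal(d50(100), 1)
  expect_equal(d50(rep(10, 10)), 5)
  expect_equal(d50(c(50, 10, 10, 10, 10, 10)), 1)
  # cumulative-sum oracle on a random vector
  set.seed(6)
  x <- sample(1:40, 25, TRUE)
  cs <- cumsum(sort(x, decreasing = TRUE))
  expect_equal(d50(x), min(which(cs >= sum(x) / 2)))
})

test_that("gini and d50 are permutation- and scale-invariant", {
  set.seed(7)
  x <- c(rpois(40, 3), 0, 0)
  perm <- sample(x)
  expect_equal(gini(x), gini(perm))
  expect_equal(d50(x), d50(perm))
  expect_equal(gini(x), gini(x * 17))
  expect_equal(d50(x), d50(x * 17))
  # one-hot vector attains the (n-1)/n bound
  expect_equal(gini(c(rep(0, 9), 42)), 9 / 10)
  expect_lte(d50(x), length(x))
})

test_that("topn_fraction sums counts at rank ranges", {
  expect_equal(unname(topn_fraction(c(60, 20, 10, 5, 5),
                                    list(c(1, 1)))), 0.6)
  expect_equal(unname(topn_fraction(rep(1, 100), list(c(1, 10)))), 0.10)
  fr <- topn_fraction(c(5, 4, 3), list(c(1, 2), c(3, 500)))
  expect_equal(unname(fr), c(9 / 12, 3 / 12))
  # ranks beyond the table contribute nothing
  expect_equal(unname(topn_fraction(c(5, 4), list(c(51, 500)))), 0)
})

test_that("downsampling is seeded, without replacement, and bounded", {
  out <- generate_repertoire(sim_config(n_cells = 200, seed = 9))
  cells <- pair_cells(out$records)$cells
  expect_error(downsample(cells, nrow(cells) + 1, seed = 1), "cannot")
  full <- downsample(cells, nrow(cells), seed = 1)
  expect_identical(full, cells)
  a <- downsample(cells, 50, seed = 123)
  b <- downsample(cells, 50, seed = 123)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$cell_id), 0)
  # inclusion frequency approaches n/N (hypergeometric marginal)
  N <- nrow(cells); n <- 60; reps <- 300
  hits <- 0
  for (s in seq_len(reps)) {
    hits <- hits + (cells$cell_id[1] %in% downsample(cells, n, seed = s)$cell_id)
  }
  p <- n / N
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(hits / reps - p), 3 * se)
})

test_that("usage tables count gene-level labels and zero-fill comparisons", {
  rec <- data.frame(v_call_heavy = c("A", "A", "A", "B", "C"))
  u <- usage_table(rec, "v_call_heavy")
  expect_equal(u$count[u$label == "A"], 3)
  other <- data.frame(v_call_heavy = c("B", "D"))
  u2 <- usage_table(rec, "v_call_heavy", other = other)
  expect_setequal(u2$label, c("A", "B", "C", "D"))
  expect_equal(u2$count[u2$label == "D"], 0)
  expect_equal(u2$count_other[u2$label == "A"], 0)
  expect_error(usage_table(rec, "nope"), "unknown field")
})

test_that("simulated heavy V usage converges to the configured vector", {
  cfg <- sim_config(n_cells = 4000, seed = 25)
  out <- generate_repertoire(cfg, default_germlines())
  tr <- out$truth
  # the V gene is drawn once per clonotype, so convergence is assessed on
  # the clonotype level where draws are independent
  ct <- unique(tr[, c("true_clonotype", "v_gene")])
  emp <- table(factor(ct$v_gene, levels = names(cfg$heavy_v_usage))) / nrow(ct)
  for (g in names(sort(cfg$heavy_v_usage, decreasing = TRUE))[1:5]) {
    p <- cfg$heavy_v_usage[[g]]
    se <- sqrt(p * (1 - p) / nrow(ct))
    expect_lt(abs(emp[[g]] - p), 3 * se)
  }
})

test_that("a zero-SHM common-light-chain pool uses a single light V gene", {
  germ <- default_germlines()
  zero <- setNames(rep(0, length(germ$numbering_map)), germ$numbering_map)
  out <- generate_repertoire(sim_config(n_cells = 300, shm_rates = zero,
                                        lambda_fraction = 0, seed = 13), germ)
  cells <- pair_cells(out$records)$cells
  u <- usage_table(cells, "v_call_light")
  expect_equal(nrow(u), 1)
  expect_equal(u$label, "IGKV10-96")
  expect_equal(u$count, nrow(cells))
})

test_that("chi-squared usage comparison matches the textbook formula", {
  res0 <- compare_usage_chisq(c(10, 10), c(10, 10))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  a <- c(20, 10); b <- c(10, 20)
  res <- compare_usage_chisq(a, b)
  # hand-computed Pearson statistic on the 2x2 table
  tab <- rbind(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, hand)
  expect_equal(res$df, 1)

  expect_error(compare_usage_chisq(c(5, 0), c(3, 0)), "informative")
  expect_error(compare_usage_chisq(c(5, 1), c(3)), "label space")
})

test_that("chi-squared p-values are null-uniform across seeded simulations", {
  set.seed(77)
  p_usage <- c(0.4, 0.25, 0.2, 0.1, 0.05)
  pvals <- replicate(200, {
    a <- table(factor(sample(1:5, 600, TRUE, p_usage), levels = 1:5))
    b <- table(factor(sample(1:5, 600, TRUE, p_usage), levels = 1:5))
    compare_usage_chisq(as.integer(a), as.integer(b))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-sum p-value equals the permutation-enumeration oracle", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  res <- compare_groups_wilcoxon(x = x, y = y)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, ref_ranksum_p(x, y))
  # identical samples: p = 1 under tie handling
  same <- suppressWarnings(compare_groups_wilcoxon(x = c(1, 2, 3),
                                                   y = c(1, 2, 3)))
  expect_equal(same$p_value, 1, tolerance = 1e-6)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  pairs <- lapply(1:10, function(i) list(x = c(1, 2, 3), y = c(10, 11, 12)))
  res <- compare_groups_wilcoxon(pairs)
  # all m p-values equal p: BH adjusted = p * m / m = p
  expect_equal(res$adjusted_p, res$p_value)
  expect_equal(stats::p.adjust(rep(0.005, 10), "BH"), rep(0.005, 10))
  mixed <- compare_groups_wilcoxon(list(
    list(x = c(1, 2, 3), y = c(10, 11, 12)),
    list(x = c(1, 10, 3), y = c(2, 11, 12))
  ))
  expect_equal(mixed$adjusted_p, p.adjust(mixed$p_value, "BH"))
})
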