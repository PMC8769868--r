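test_that("batches run with consecutive seeds and are reproducible", {
  tab <- tiny_table(seed = 50)
  cfg <- cs_config(n_nests = 5, max_iter = 5)
  b1 <- quiet(run_batch(tab, n_runs = 3, base_seed = 10,
                        config = cfg))
  expect_length(b1$results, 3)
  expect_identical(b1$seeds, 10:12)
  b2 <- quiet(run_batch(tab, n_runs = 3, base_seed = 10, config = cfg))
  expect_identical(lapply(b1$results, `[[`, "best_mask"),
                   lapply(b2$results, `[[`, "best_mask"))
})

test_that("random search respects its budget and traces best-so-far", {
  tab <- tiny_table(seed = 51)
  r1 <- quiet(random_search_baseline(tab, budget = 1, seed = 1))
  expect_identical(r1$n_evaluations, 1L)
  expect_length(r1$trace, 1)
  r <- quiet(random_search_baseline(tab, budget = 40, seed = 2))
  expect_identical(r$n_evaluations, 40L)
  expect_false(is.unsorted(r$trace))
})

test_that("full-budget random search equals the exhaustive oracle", {
  tab <- tiny_table(seed = 52)
  opt <- quiet(exhaustive_best_mask(tab))
  rs <- quiet(random_search_baseline(tab, budget = 63, seed = 3))
  expect_identical(rs$n_evaluations, 63L)
  expect_equal(rs$best_report$fit, opt$report$fit, tolerance = 1e-12)
})

test_that("signed-rank comparison matches its closed forms", {
  expect_error(wilcoxon_compare(1:3, 4:6), "at least 5")
  expect_error(wilcoxon_compare(1:6, 1:5), "equal length")
  a <- c(0.8, 0.81, 0.79, 0.85, 0.9, 0.7)
  same <- wilcoxon_compare(a, a)
  expect_equal(same$p, 1)
  expect_identical(same$verdict, "nonsignificant")
  # all 25 differences positive: W+ = 325, Z = 162.5/sqrt(1381.25) = 4.3724
  set.seed(1)
  b <- runif(25)
  w <- wilcoxon_compare(b + 1, b)
  expect_equal(w$Z, (325 - 162.5) / sqrt(25 * 26 * 51 / 24), tolerance = 1e-9)
  expect_equal(round(w$Z, 4), 4.3724)
  expect_identical(w$verdict, "significant")
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20, 0.3)
    ours <- wilcoxon_compare(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                              correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("rank summation uses competition ranks with shared best rank", {
  vals <- rbind(A = c(acc = 0.9, len = 10),
                B = c(acc = 0.8, len = 20))
  rk <- rank_summation(vals, higher_is_better = c(TRUE, FALSE))
  expect_identical(unname(rk$rank_sums), c(2, 4))
  # exact tie shares rank 1, next method gets rank 2
  vals3 <- rbind(A = c(m = 1), B = c(m = 1), C = c(m = 0.5))
  rk3 <- rank_summation(vals3, TRUE)
  expect_identical(unname(rk3$ranks[, 1]), c(1, 1, 2))
  # single method: all ranks 1
  rk1 <- rank_summation(rbind(A = c(x = 1, y = 2)), TRUE)
  expect_identical(unname(rk1$rank_sums), 2)
  vals_na <- rbind(A = c(m = 1, k = NA), B = c(m = 2, k = 1))
  expect_error(rank_summation(vals_na, TRUE), "method 'A', measure 'k'")
  # ranks without ties are a permutation per measure
  set.seed(2)
  vr <- matrix(runif(15), 5, 3,
               dimnames = list(paste0("M", 1:5), paste0("x", 1:3)))
  rr <- rank_summation(vr, TRUE)
  for (j in 1:3) expect_setequal(rr$ranks[, j], 1:5)
})

test_that("batch comparison is a pure function of its batches", {
  tab <- tiny_table(seed = 53)
  cfg <- cs_config(n_nests = 5, max_iter = 5)
  b1 <- quiet(run_batch(tab, n_runs = 5, base_seed = 1, config = cfg))
  b2 <- quiet(run_batch(tab, optimizer = random_search_optimizer(50),
                        n_runs = 5, base_seed = 1,
                        config = list(budget = 50),
                        method = "random-search"))
  r1 <- compare_batches(list(b1, b2))
  r2 <- compare_batches(list(b1, b2))
  expect_identical(r1$rank_sums, r2$rank_sums)
  expect_identical(r1$wilcoxon$Z, r2$wilcoxon$Z)
  expect_true(all(r1$wilcoxon$p >= 0 & r1$wilcoxon$p <= 1))
  expect_error(compare_batches(list(b1)), "length")
  # comparing a batch against itself: every pair nonsignificant
  same <- compare_batches(list(a = b1, b = b1))
  expect_identical(same$wilcoxon$verdict, "nonsignificant")
})

test_that("dominated comparisons are significant and ranked last", {
  tab <- tiny_table(seed = 54)
  cfg <- cs_config(n_nests = 5, max_iter = 5)
  b <- quiet(run_batch(tab, n_runs = 25, base_seed = 1, config = cfg))
  worse <- b
  worse$method <- "handicapped"
  worse$results <- lapply(b$results, function(r) {
    r$best_report$fit <- r$best_report$fit - 0.1
    r$best_report$acc <- max(0, r$best_report$acc - 0.1)
    r
  })
  rep <- compare_batches(list(b, worse))
  expect_identical(rep$wilcoxon$verdict, "significant")
  expect_lt(rep$rank_sums[["MOBCS-KNN"]], rep$rank_sums[["handicapped"]])
})

test_that("single-run batches refuse statistics with a clear error", {
  tab <- tiny_table(seed = 55)
  b1 <- quiet(run_batch(tab, n_runs = 1, base_seed = 1,
                        config = cs_config(n_nests = 5, max_iter = 3)))
  expect_error(compare_batches(list(b1, b1)), "at least 2 runs")
})

test_that("comparison reports serialize to delimited files", {
  tab <- tiny_table(seed = 56)
  cfg <- cs_config(n_nests = 5, max_iter = 4)
  b1 <- quiet(run_batch(tab, n_runs = 5, base_seed = 1, config = cfg))
  b2 <- quiet(run_batch(tab, optimizer = random_search_optimizer(30),
                        n_runs = 5, base_seed = 1, config = list(budget = 30),
                        method = "random-search"))
  rep <- compare_batches(list(b1, b2))
  prefix <- file.path(withr::local_tempdir(), "cmp")
  write_comparison_report(rep, prefix)
  rk <- read.csv(paste0(prefix, "_ranks.csv"), check.names = FALSE)
  expect_setequal(rk$method, c("MOBCS-KNN", "random-search"))
  expect_true(all(c("EEG_Fit", "EEG_ACC", "EEG_Len", "rank_sum") %in%
                  colnames(rk)))
  summary <- read.csv(paste0(prefix, "_summary.csv"))
  expect_identical(nrow(summary), 12L)  # 2 methods x 6 measures
})
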