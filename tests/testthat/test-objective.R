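test_that("one-vs-rest confusion counts match hand enumeration", {
  cc <- confusion_counts(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  a <- cc[cc$class == "A", ]
  expect_identical(c(a$TA, a$FR, a$FA, a$TR), c(1L, 1L, 0L, 2L))
  b <- cc[cc$class == "B", ]
  expect_identical(c(b$TA, b$FR, b$FA, b$TR), c(2L, 0L, 1L, 1L))
  # perfect prediction: no false acceptances or rejections anywhere
  y <- rep(c("A", "B", "C"), 5)
  pc <- confusion_counts(y, y)
  expect_true(all(pc$FA == 0) && all(pc$FR == 0))
  # collapse onto one class on balanced labels
  y4 <- rep(c("a", "b", "c", "d"), each = 25)
  c4 <- confusion_counts(y4, rep("a", 100))
  expect_identical(c4$TA[c4$class == "a"], 25L)
  expect_identical(c4$FA[c4$class == "a"], 75L)
  expect_error(confusion_counts(c("A", "B"), "A"), "length")
})

test_that("metrics reproduce the acceptance/rejection formulas exactly", {
  cc <- data.frame(class = "x", TA = 50L, FR = 5L, FA = 5L, TR = 40L)
  m <- metrics_from_counts(cc)
  expect_equal(m$acc_macro, 0.90)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$fscore, 50 / 55)
  # perfect prediction scores 1 everywhere
  y <- rep(c("A", "B"), 10)
  mp <- metrics_from_counts(confusion_counts(y, y))
  expect_equal(unlist(mp), c(acc = 1, acc_macro = 1, recall = 1,
                             precision = 1, fscore = 1))
})

test_that("uniform random prediction gives chance-level macro recall", {
  n_class <- 109
  recalls <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rep(seq_len(n_class), each = 10)
    pred <- sample(seq_len(n_class), length(y), replace = TRUE)
    quiet(metrics_from_counts(confusion_counts(y, pred)))$recall
  }, 0)
  se <- sd(recalls) / sqrt(20)
  expect_lt(abs(mean(recalls) - 1 / n_class), 4 * se + 1e-3)
})

test_that("zero-denominator classes warn and contribute zero", {
  cc <- confusion_counts(c("A", "A", "B"), c("A", "A", "A"))
  expect_warning(m <- metrics_from_counts(cc), "zero denominator")
  expect_equal(m$recall, mean(c(1, 0)))
})

test_that("weighted fitness follows the accuracy/reduction trade-off", {
  expect_equal(weighted_fitness(1, 64, 64), 0.8)
  expect_equal(weighted_fitness(0.9386, 24, 64), 0.87588)
  # strictly decreasing in channel count at fixed accuracy
  f24 <- weighted_fitness(0.9, 24, 64)
  f25 <- weighted_fitness(0.9, 25, 64)
  expect_equal(f24 - f25, 0.2 / 64)
  expect_error(weighted_fitness(0.9, 0, 64), "empty")
  expect_error(weighted_fitness(0.9, 2, 64, w1 = 0.7, w2 = 0.2), "sum to 1")
  # bounds over random inputs
  set.seed(1)
  for (i in 1:50) {
    f <- weighted_fitness(runif(1), sample(64, 1), 64)
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("objective config enforces the weight and fold invariants", {
  expect_error(objective_config(w1 = 0.5, w2 = 0.4), "sum to 1")
  expect_error(objective_config(w1 = 1, w2 = 0), "positive")
  expect_error(objective_config(n_folds = 1), "n_folds")
})

test_that("folds partition the rows and stratify by subject", {
  tab <- tiny_table(seed = 2, n_subjects = 6, n_recordings = 12, d = 4,
                    informative = 1)
  folds <- cuckooEEG:::make_folds(tab$subject, 10, 42L, TRUE)
  expect_identical(sort(unique(folds)), 1:10)
  expect_length(folds, 72)
  # every row tested exactly once; per-subject spread over folds
  expect_true(all(table(folds) >= 1))
  for (s in unique(tab$subject)) {
    expect_lte(max(table(folds[tab$subject == s])), 2)
  }
  expect_error(cuckooEEG:::make_folds(rep("a", 5), 10, 1L, TRUE),
               "per_recording")
})

test_that("perfectly separable plants are identified with accuracy 1", {
  tab <- tiny_table(seed = 3, n_subjects = 5, n_recordings = 10, d = 6,
                    informative = c(1, 2), effect_size = 40)
  rep <- knn_cv_evaluate(tab, c(1, 1, 0, 0, 0, 0))
  expect_equal(rep$acc, 1)
  expect_equal(rep$fit, 0.8 + 0.2 * (1 - 2 / 6))
  expect_equal(rep$fscore, 1)
})

test_that("a duplicated training point is its own nearest neighbour", {
  tab <- tiny_table(seed = 4, n_subjects = 5, n_recordings = 10, d = 4,
                    informative = c(1, 2), effect_size = 0.1, noise_sd = 1)
  # duplicate row 1 into another fold position: its duplicate must win
  folds <- cuckooEEG:::make_folds(tab$subject, 10, 42L, TRUE)
  other <- which(tab$subject == tab$subject[1] & folds != folds[1])[1]
  tab$x[other, ] <- tab$x[1, ]
  rep <- quiet(knn_cv_evaluate(tab, rep(1L, 4)))
  # reconstruct the pooled prediction for row `other` via the counts: at
  # minimum, its class must have at least one true acceptance
  cls <- tab$subject[1]
  expect_gte(rep$counts$TA[rep$counts$class == cls], 1L)
})

test_that("fast 1-NN path agrees with class::knn on the same folds", {
  tab <- tiny_table(seed = 6, n_subjects = 6, n_recordings = 10, d = 5,
                    informative = c(1, 3), effect_size = 2)
  mask <- c(1L, 1L, 1L, 0L, 1L)
  cfg <- objective_config()
  fast <- quiet(knn_cv_evaluate(tab, mask, cfg))
  folds <- cuckooEEG:::make_folds(tab$subject, cfg$n_folds, cfg$fold_seed,
                                  TRUE)
  Xm <- mask_columns(tab, mask)
  cl <- factor(tab$subject)
  pred <- character(nrow(Xm))
  for (f in 1:10) {
    te <- folds == f
    pred[te] <- as.character(class::knn(Xm[!te, ], Xm[te, , drop = FALSE],
                                        cl[!te], k = 1))
  }
  expect_equal(fast$acc, mean(pred == as.character(cl)))
})

test_that("masked evaluation ignores noise channels' columns entirely", {
  tab <- tiny_table(seed = 7)
  tab2 <- tab
  tab2$x[, unlist(tab$channel_blocks[3:6])] <- 999  # garbage in dropped blocks
  m <- c(1, 1, 0, 0, 0, 0)
  expect_equal(quiet(knn_cv_evaluate(tab, m))$fit,
               quiet(knn_cv_evaluate(tab2, m))$fit)
})

test_that("metric consistency: stored counts reproduce the report", {
  tab <- tiny_table(seed = 8, effect_size = 1.5)
  rep <- quiet(knn_cv_evaluate(tab, c(1, 1, 1, 0, 0, 0)))
  m <- quiet(metrics_from_counts(rep$counts))
  expect_equal(m$acc, rep$acc)
  expect_equal(m$precision, rep$precision)
  expect_equal(m$recall, rep$recall)
  expect_equal(m$fscore, rep$fscore)
})

test_that("evaluator caching counts only uncached computations", {
  tab <- tiny_table(seed = 9)
  ev <- make_evaluator(tab, objective_config())
  st <- attr(ev, "state")
  m <- c(1, 0, 1, 0, 1, 0)
  r1 <- quiet(ev(m)); r2 <- quiet(ev(m))
  expect_identical(r1, r2)
  expect_identical(st$n_evaluations, 1L)
  expect_identical(st$n_calls, 2L)
  expect_error(ev(rep(0L, 6)), "empty")
  expect_error(ev(c(2, rep(0, 5))), "0/1")
})

test_that("exhaustive oracle evaluates every non-empty mask once", {
  tab <- tiny_table(seed = 10)
  res <- quiet(exhaustive_best_mask(tab))
  expect_identical(res$n_evaluations, 63L)
  expect_true(sum(res$mask) >= 1)
  big <- tiny_table(seed = 1, d = 13, informative = 1)
  expect_error(exhaustive_best_mask(big), "refused")
})

test_that("oracle finds the planted pair among two-channel masks", {
  hits <- vapply(1:20, function(s) {
    tab <- tiny_table(seed = 1000 + s, n_subjects = 5, n_recordings = 10,
                      d = 6, informative = c(1, 2), effect_size = 5)
    ev <- make_evaluator(tab, objective_config())
    two_masks <- Filter(function(m) sum(m) == 2,
                        lapply(1:63, cuckooEEG:::int_to_mask, d = 6))
    fits <- vapply(two_masks, function(m) quiet(ev(m))$fit, 0)
    identical(two_masks[[which.max(fits)]], c(1L, 1L, 0L, 0L, 0L, 0L))
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("fitness report serializes with the canonical measure header", {
  tab <- tiny_table(seed = 12)
  rep <- quiet(knn_cv_evaluate(tab, c(1, 1, 0, 0, 0, 0)))
  lines <- format_report(rep)
  expect_identical(lines[1],
    "EEG_Fit,EEG_ACC,EEG_Len,EEG_Precision,EEG_Recall,EEG_Fscore")
  vals <- as.numeric(strsplit(lines[2], ",")[[1]])
  expect_equal(vals[2], 100 * rep$acc, tolerance = 1e-4)
  expect_equal(vals[3], 2)
})
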