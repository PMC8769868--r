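# Multi-run experiment driver, matched-budget random-search baseline,
# Wilcoxon signed-rank comparison and rank summation across methods.

#' Run a method repeatedly with consecutive seeds
#'
#' Because the search is stochastic, summary results are computed over
#' repeated runs (25 by convention) with seeds `base_seed + 0:(n_runs-1)`.
#'
#' @param features a `feature_table`.
#' @param optimizer a function `(features, obj_config, config)` returning a
#'   `selection_result`; defaults to [run_mobcs()]. Any optimizer honouring
#'   this signature (e.g. a wrapper around [random_search_baseline()]) plugs
#'   in here.
#' @param n_runs number of independent runs (default 25).
#' @param base_seed first seed.
#' @param obj_config an [objective_config()].
#' @param config optimizer configuration; its `seed` field is overwritten
#'   per run.
#' @param method label stored on the batch.
#' @return a `run_batch`: list with `method`, `results`, `seeds`.
#' @export
run_batch <- function(features, optimizer = run_mobcs, n_runs = 25,
                      base_seed = 1L, obj_config = objective_config(),
                      config = cs_config(), method = "MOBCS-KNN") {
  stopifnot(n_runs >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  results <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    r <- tryCatch(optimizer(features, obj_config, cfg), error = function(e) {
      stop("run with seed ", s, " failed: ", conditionMessage(e))
    })
    r
  })
  structure(list(method = method, results = results, seeds = seeds),
            class = "run_batch")
}

#' Matched-budget random-search baseline
#'
#' Evaluates `budget` distinct uniformly random non-empty channel masks and
#' returns the best, with a best-so-far trace. When the budget covers the
#' whole mask space (`budget >= 2^d - 1` and `d` small enough to enumerate),
#' every mask is evaluated, so the result coincides with the exhaustive
#' oracle's optimum fitness.
#'
#' @param features a `feature_table`.
#' @param obj_config an [objective_config()].
#' @param budget number of fitness evaluations (>= 1).
#' @param seed integer seed.
#' @return a `selection_result` with `method = "random-search"`.
#' @export
random_search_baseline <- function(features, obj_config = objective_config(),
                                   budget, seed = 1L) {
  stopifnot(budget >= 1)
  ev <- make_evaluator(features, obj_config, cache = TRUE)
  d <- attr(ev, "d")
  withr::with_seed(seed, {
    best <- NULL
    trace <- numeric(0)
    if (d <= 24 && budget >= 2^d - 1) {
      masks <- lapply(sample(2^d - 1), int_to_mask, d = d)
    } else {
      masks <- NULL
    }
    state <- attr(ev, "state")
    i <- 0L
    while (state$n_evaluations < budget) {
      i <- i + 1L
      mask <- if (!is.null(masks)) {
        if (i > length(masks)) break
        masks[[i]]
      } else {
        m <- rbinom(d, 1, 0.5)
        if (sum(m) == 0) m[sample.int(d, 1)] <- 1L
        m
      }
      before <- state$n_evaluations
      rep <- ev(mask)
      if (state$n_evaluations == before) next  # duplicate mask: free, skip
      if (is.null(best) || rep$fit > best$report$fit) {
        best <- list(mask = mask, report = rep)
      }
      trace <- c(trace, best$report$fit)
    }
    structure(
      list(best_mask = best$mask, best_report = best$report, trace = trace,
           n_evaluations = state$n_evaluations,
           config = list(budget = budget, seed = seed),
           obj_config = obj_config, method = "random-search"),
      class = "selection_result")
  })
}

#' Wrap the random-search baseline as a plug-in optimizer
#'
#' Returns a function with the `(features, obj_config, config)` optimizer
#' signature expected by [run_batch()], drawing its evaluation budget either
#' from `config$budget` or from a fixed value.
#'
#' @param budget fixed evaluation budget; `NULL` reads `config$budget`.
#' @export
random_search_optimizer <- function(budget = NULL) {
  function(features, obj_config, config) {
    b <- budget %||% config$budget
    random_search_baseline(features, obj_config, budget = b,
                           seed = config$seed)
  }
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test with the normal approximation (producing the
#' conventional standardized Z value), pairing runs by seed. Zero differences
#' are dropped; tied absolute differences receive average ranks. The variance
#' uses the untied closed form `n(n+1)(2n+1)/24` without continuity
#' correction, the convention under which 25 same-signed pairs give the
#' maximal `|Z| = 4.3724`.
#'
#' @param a,b equal-length (>= 5) per-run fitness (or accuracy) vectors,
#'   paired elementwise.
#' @param alpha significance level (default 0.05).
#' @return list with `Z`, `p`, `verdict` (`"significant"` or
#'   `"nonsignificant"`), `n_pairs` (nonzero differences).
#' @examples
#' wilcoxon_compare(rnorm(25, 1), rnorm(25))
#' @export
wilcoxon_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 5) stop("need at least 5 pairs, got ", length(a))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(Z = 0, p = 1, verdict = "nonsignificant", n_pairs = 0L))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  z <- (w_plus - mu) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  list(Z = z, p = min(1, p),
       verdict = if (p < alpha) "significant" else "nonsignificant",
       n_pairs = n)
}

#' Dense ranks and rank sums across methods
#'
#' Per measure, methods are ranked 1 (best) upwards; exact ties share the
#' better (smaller) rank and the next method receives the following integer
#' (dense ranking: values 1, 1, 2, ...). Smaller rank sums indicate better
#' overall performance.
#'
#' @param values numeric matrix, rows = methods (rownames required),
#'   columns = measures (colnames required); no missing cells.
#' @param higher_is_better logical vector per measure (recycled if length 1);
#'   e.g. accuracy TRUE, number of selected channels FALSE.
#' @return list with `ranks` (same shape as `values`) and `rank_sums`
#'   (named vector).
#' @export
rank_summation <- function(values, higher_is_better = TRUE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value for method '", rownames(values)[bad[1]],
         "', measure '", colnames(values)[bad[2]], "'")
  }
  hib <- rep_len(higher_is_better, ncol(values))
  ranks <- values
  for (j in seq_len(ncol(values))) {
    v <- if (hib[j]) -values[, j] else values[, j]
    ranks[, j] <- match(v, sort(unique(v)))
  }
  list(ranks = ranks, rank_sums = rowSums(ranks))
}

batch_measure <- function(batch, field) {
  vapply(batch$results, function(r) {
    if (field == "fit") r$best_report$fit
    else if (field == "len") as.numeric(r$best_report$n_selected)
    else r$best_report[[field]]
  }, 0)
}

#' Summarize a run batch
#'
#' Mean, median and interquartile range of fitness, accuracy, channel count,
#' precision, recall and F-score over the batch's runs.
#'
#' @param batch a `run_batch`.
#' @return data frame with one row per measure.
#' @export
summarize_batch <- function(batch) {
  measures <- c(EEG_Fit = "fit", EEG_ACC = "acc", EEG_Len = "len",
                EEG_Precision = "precision", EEG_Recall = "recall",
                EEG_Fscore = "fscore")
  rows <- lapply(names(measures), function(nm) {
    v <- batch_measure(batch, measures[[nm]])
    data.frame(measure = nm, mean = mean(v), median = median(v),
               iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)))
  })
  cbind(method = batch$method, do.call(rbind, rows))
}

#' Compare run batches: summaries, pairwise Wilcoxon tests and rank sums
#'
#' Batches must share the run count (runs are paired by position, i.e. by
#' seed offset). Pairwise Wilcoxon signed-rank tests are computed on per-run
#' fitness; ranks are computed on batch means of each measure, with channel
#' count ranked ascending and all other measures descending.
#'
#' @param batches named list of `run_batch` objects (>= 2), or a list whose
#'   elements carry `$method` labels.
#' @return a `comparison_report`: `summary` (stacked [summarize_batch()]
#'   rows), `wilcoxon` (data frame of pairs, Z, p, verdict), `ranks`,
#'   `rank_sums`.
#' @export
compare_batches <- function(batches) {
  stopifnot(length(batches) >= 2)
  nms <- names(batches) %||% vapply(batches, `[[`, "", "method")
  if (is.null(names(batches))) names(batches) <- nms
  nruns <- vapply(batches, function(b) length(b$results), 0L)
  if (length(unique(nruns)) != 1) stop("batches have different run counts")
  if (nruns[1] < 2) stop("need at least 2 runs per batch for statistics")
  summary <- do.call(rbind, lapply(batches, summarize_batch))
  rownames(summary) <- NULL
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  wil <- do.call(rbind, lapply(pairs, function(pr) {
    w <- wilcoxon_compare(batch_measure(batches[[pr[1]]], "fit"),
                          batch_measure(batches[[pr[2]]], "fit"))
    data.frame(method_a = pr[1], method_b = pr[2], Z = w$Z, p = w$p,
               verdict = w$verdict)
  }))
  measures <- c(EEG_Fit = "fit", EEG_ACC = "acc", EEG_Len = "len",
                EEG_Precision = "precision", EEG_Recall = "recall",
                EEG_Fscore = "fscore")
  vals <- t(vapply(batches, function(b) {
    vapply(measures, function(f) mean(batch_measure(b, f)), 0)
  }, numeric(length(measures))))
  dimnames(vals) <- list(nms, names(measures))
  rk <- rank_summation(vals, higher_is_better = names(measures) != "EEG_Len")
  structure(list(summary = summary, wilcoxon = wil, ranks = rk$ranks,
                 rank_sums = rk$rank_sums),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n\nrank sums (smaller is better):\n")
  print(sort(x$rank_sums))
  cat("\npairwise Wilcoxon signed-rank (on per-run fitness):\n")
  print(x$wilcoxon, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as delimited text files
#'
#' Emits `<prefix>_summary.csv`, `<prefix>_wilcoxon.csv` and
#' `<prefix>_ranks.csv` (rank table with a final `rank_sum` column).
#'
#' @param report a `comparison_report`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_comparison_report <- function(report, prefix) {
  write.csv(report$summary, paste0(prefix, "_summary.csv"), row.names = FALSE)
  write.csv(report$wilcoxon, paste0(prefix, "_wilcoxon.csv"), row.names = FALSE)
  rk <- data.frame(method = rownames(report$ranks), report$ranks,
                   rank_sum = report$rank_sums, check.names = FALSE)
  write.csv(rk, paste0(prefix, "_ranks.csv"), row.names = FALSE)
  invisible(prefix)
}
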