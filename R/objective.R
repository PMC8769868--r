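# Fitness machinery: KNN identification under stratified k-fold CV,
# one-vs-rest confusion counts, macro metrics, and the weighted-sum
# multiobjective fitness combining accuracy with channel reduction.

#' Objective configuration for the channel-selection fitness
#'
#' @param w1,w2 nonnegative weights for the accuracy term and the
#'   channel-reduction term; must sum to 1 and both be positive. Defaults
#'   0.8 / 0.2.
#' @param k_neighbors neighbourhood size of the KNN identifier (default 1,
#'   the usual choice in biometric identification).
#' @param n_folds cross-validation folds (default 10).
#' @param fold_seed seed fixing the fold assignment, so every mask is scored
#'   on identical folds.
#' @param stratified stratify folds by subject (default TRUE).
#' @param standardize z-score feature columns before distances (default
#'   FALSE; AR coefficients are already on comparable scales).
#' @return an `objective_config`.
#' @export
objective_config <- function(w1 = 0.8, w2 = 0.2, k_neighbors = 1, n_folds = 10,
                             fold_seed = 42L, stratified = TRUE,
                             standardize = FALSE) {
  if (w1 <= 0 || w2 <= 0) stop("weights must be strictly positive")
  if (abs(w1 + w2 - 1) > 1e-12) stop("weights must sum to 1, got ", w1 + w2)
  stopifnot(k_neighbors >= 1, n_folds >= 2)
  structure(list(w1 = w1, w2 = w2, k_neighbors = as.integer(k_neighbors),
                 n_folds = as.integer(n_folds), fold_seed = as.integer(fold_seed),
                 stratified = isTRUE(stratified),
                 standardize = isTRUE(standardize)),
            class = "objective_config")
}

#' One-vs-rest confusion counts per class
#'
#' For each class `c`: TA (true acceptance) = samples of `c` predicted `c`;
#' FR (false rejection) = samples of `c` predicted otherwise; FA (false
#' acceptance) = other samples predicted `c`; TR (true rejection) = the rest.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return data frame with one row per class and columns
#'   `class, TA, FR, FA, TR`.
#' @examples
#' confusion_counts(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  ct <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  ta <- diag(ct)
  fr <- rowSums(ct) - ta
  fa <- colSums(ct) - ta
  data.frame(class = classes, TA = as.integer(ta), FR = as.integer(fr),
             FA = as.integer(fa), TR = as.integer(n - ta - fr - fa),
             row.names = NULL)
}

#' Identification metrics from one-vs-rest confusion counts
#'
#' Per class: accuracy `(TA+TR)/(TA+FA+TR+FR)`, recall `TA/(TA+FR)`,
#' precision `TA/(TA+FA)`, F-score `2RP/(R+P)`; macro-averaged over classes.
#' A class with a zero denominator contributes 0 to the average (with a
#' warning). The overall multiclass fraction-correct `sum(TA)/n` is also
#' reported — this is the single accuracy number quoted for an identification
#' system.
#'
#' @param counts output of [confusion_counts()].
#' @return list with `acc` (fraction correct), `acc_macro`, `recall`,
#'   `precision`, `fscore` (macro averages), all fractions in `[0, 1]`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(nrow(counts) >= 1)
  n <- counts$TA[1] + counts$FR[1] + counts$FA[1] + counts$TR[1]
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning("zero denominator in ", what, " for class(es) ",
              paste(counts$class[bad], collapse = ", "),
              "; contributing 0", call. = FALSE)
    }
    ifelse(bad, 0, num / den)
  }
  acc_c <- (counts$TA + counts$TR) / n
  rec_c <- safe_div(counts$TA, counts$TA + counts$FR, "recall")
  pre_c <- safe_div(counts$TA, counts$TA + counts$FA, "precision")
  f_den <- rec_c + pre_c
  f_c <- ifelse(f_den == 0, 0, 2 * rec_c * pre_c / f_den)
  list(acc = sum(counts$TA) / n,
       acc_macro = mean(acc_c),
       recall = mean(rec_c),
       precision = mean(pre_c),
       fscore = mean(f_c))
}

#' Weighted-sum multiobjective fitness
#'
#' `fit = w1 * acc + w2 * (1 - n_selected / d)`: the second objective rewards
#' channel reduction, normalized so the fitness always lies in `[0, 1]` and
#' selecting every channel scores `w1 * acc` exactly. Higher is better.
#'
#' @param acc identification accuracy as a fraction in `[0, 1]`.
#' @param n_selected number of selected channels, `1 <= n_selected <= d`.
#' @param d total number of channels.
#' @param w1,w2 positive weights summing to 1.
#' @return fitness in `[0, 1]`.
#' @examples
#' weighted_fitness(1, 64, 64)        # 0.8: no reduction credit
#' weighted_fitness(0.9386, 24, 64)   # 0.87588
#' @export
weighted_fitness <- function(acc, n_selected, d, w1 = 0.8, w2 = 0.2) {
  if (n_selected < 1) stop("empty channel mask: repair before scoring")
  stopifnot(acc >= 0, acc <= 1, n_selected <= d)
  if (abs(w1 + w2 - 1) > 1e-12 || w1 <= 0 || w2 <= 0) {
    stop("weights must be positive and sum to 1")
  }
  w1 * acc + w2 * (1 - n_selected / d)
}

# Stratified (or plain) fold assignment, fixed by fold_seed so the whole
# search scores masks on identical folds.
make_folds <- function(subject, n_folds, fold_seed, stratified) {
  n <- length(subject)
  n_folds <- as.integer(n_folds)
  withr::with_seed(fold_seed, {
    if (!stratified) return(sample(rep(seq_len(n_folds), length.out = n)))
    folds <- integer(n)
    offset <- 0L
    for (cl in unique(subject)) {
      idx <- which(subject == cl)
      if (length(idx) < n_folds) {
        stop("subject ", cl, " has ", length(idx), " rows but ", n_folds,
             " folds requested; extract features with aggregate = ",
             "'per_recording' or reduce n_folds")
      }
      ord <- sample(idx)
      folds[ord] <- (offset + seq_along(ord) - 1L) %% n_folds + 1L
      offset <- offset + length(ord)
    }
    folds
  })
}

#' Build a memoizing fitness evaluator for a feature table
#'
#' Returns a function `evaluate(mask)` that scores a channel mask by KNN
#' cross-validation and the weighted fitness, caching reports by the mask's
#' bit pattern (metaheuristics revisit masks, and CV dominates the cost).
#' The evaluator carries counters: `attr -> environment` with
#' `n_evaluations` (uncached CV computations) and `n_calls`.
#'
#' @param features a `feature_table`.
#' @param config an [objective_config()].
#' @param cache memoize reports (default TRUE).
#' @return function of `mask` returning a `fitness_report`.
#' @export
make_evaluator <- function(features, config = objective_config(),
                           cache = TRUE) {
  stopifnot(inherits(features, "feature_table"),
            inherits(config, "objective_config"))
  X <- features$x
  if (config$standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
  }
  subject <- features$subject
  folds <- make_folds(subject, config$n_folds, config$fold_seed,
                      config$stratified)
  blocks <- features$channel_blocks
  d <- features$n_channels
  state <- new.env(parent = emptyenv())
  state$n_evaluations <- 0L
  state$n_calls <- 0L
  state$cache <- new.env(parent = emptyenv())
  f <- function(mask) {
    mask <- as.integer(mask)
    if (length(mask) != d || any(mask != 0L & mask != 1L)) {
      stop("mask must be a 0/1 vector of length ", d)
    }
    if (sum(mask) == 0L) stop("empty channel mask: repair before scoring")
    state$n_calls <- state$n_calls + 1L
    key <- paste(mask, collapse = "")
    if (cache && !is.null(rep <- state$cache[[key]])) return(rep)
    state$n_evaluations <- state$n_evaluations + 1L
    keep <- unlist(blocks[mask == 1L], use.names = FALSE)
    Xm <- X[, keep, drop = FALSE]
    y_pred <- character(nrow(Xm))
    cl <- factor(subject)
    if (config$k_neighbors == 1L) {
      # single-neighbour fast path: one squared-distance matrix per mask
      # (first-index tie-break; ties have measure zero on continuous features)
      rs <- rowSums(Xm^2)
      D2 <- outer(rs, rs, "+") - 2 * tcrossprod(Xm)
      for (fd in seq_len(config$n_folds)) {
        te <- which(folds == fd)
        tr <- which(folds != fd)
        nearest <- max.col(-D2[te, tr, drop = FALSE], ties.method = "first")
        y_pred[te] <- as.character(cl[tr][nearest])
      }
    } else {
      for (fd in seq_len(config$n_folds)) {
        te <- folds == fd
        y_pred[te] <- as.character(
          class::knn(Xm[!te, , drop = FALSE], Xm[te, , drop = FALSE],
                     cl[!te], k = config$k_neighbors))
      }
    }
    counts <- confusion_counts(subject, y_pred)
    m <- metrics_from_counts(counts)
    rep <- structure(
      list(fit = weighted_fitness(m$acc, sum(mask), d, config$w1, config$w2),
           acc = m$acc, acc_macro = m$acc_macro, precision = m$precision,
           recall = m$recall, fscore = m$fscore,
           n_selected = sum(mask), counts = counts),
      class = "fitness_report")
    if (cache) state$cache[[key]] <- rep
    rep
  }
  attr(f, "state") <- state
  attr(f, "d") <- d
  f
}

#' Score one channel mask by KNN cross-validation
#'
#' Convenience wrapper around [make_evaluator()] for a single mask: restricts
#' the table to the mask's channel blocks, runs stratified k-fold KNN
#' identification with Euclidean distances, pools the out-of-fold predictions
#' (each row is tested exactly once) and returns the metric/fitness report.
#' Deterministic for a fixed `fold_seed`.
#'
#' @param features a `feature_table`.
#' @param mask 0/1 vector of length `n_channels` with at least one 1.
#' @param config an [objective_config()].
#' @return a `fitness_report`: `fit`, `acc`, `acc_macro`, `precision`,
#'   `recall`, `fscore`, `n_selected`, plus the pooled confusion `counts`.
#' @export
knn_cv_evaluate <- function(features, mask, config = objective_config()) {
  make_evaluator(features, config, cache = FALSE)(mask)
}

#' @export
print.fitness_report <- function(x, ...) {
  cat(sprintf(
    "fitness_report: fit %.4f | acc %.4f | len %d | precision %.4f | recall %.4f | fscore %.4f\n",
    x$fit, x$acc, x$n_selected, x$precision, x$recall, x$fscore))
  invisible(x)
}

#' Serialize a fitness report to a one-line delimited record
#'
#' Header `EEG_Fit,EEG_ACC,EEG_Len,EEG_Precision,EEG_Recall,EEG_Fscore`;
#' accuracy is printed as a percentage, everything else as fractions.
#'
#' @param report a `fitness_report`.
#' @param path optional file; `NULL` returns the two lines as a character
#'   vector.
#' @export
format_report <- function(report, path = NULL) {
  lines <- c("EEG_Fit,EEG_ACC,EEG_Len,EEG_Precision,EEG_Recall,EEG_Fscore",
             sprintf("%.6f,%.4f,%d,%.6f,%.6f,%.6f",
                     report$fit, 100 * report$acc, report$n_selected,
                     report$precision, report$recall, report$fscore))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

int_to_mask <- function(i, d) as.integer(intToBits(i))[seq_len(d)]

#' Exhaustive enumeration of the best channel mask
#'
#' Evaluates all `2^d - 1` non-empty masks and returns the weighted-fitness
#' argmax. Ties are broken towards fewer channels, then towards the
#' lexicographically smallest bit string. Guarded to small `d` — this is the
#' ground-truth oracle the stochastic search is validated against.
#'
#' @param features a `feature_table`.
#' @param config an [objective_config()].
#' @param d_max refuse tables wider than this many channels (default 12).
#' @return list with `mask`, `report`, and `n_evaluations`.
#' @export
exhaustive_best_mask <- function(features, config = objective_config(),
                                 d_max = 12) {
  d <- features$n_channels
  if (d > d_max) stop("exhaustive search refused for d = ", d, " > ", d_max)
  ev <- make_evaluator(features, config, cache = FALSE)
  best <- NULL
  for (i in seq_len(2^d - 1)) {
    mask <- int_to_mask(i, d)
    rep <- ev(mask)
    cand <- list(mask = mask, report = rep)
    if (is.null(best) || rep$fit > best$report$fit + 1e-15 ||
        (abs(rep$fit - best$report$fit) <= 1e-15 &&
         (rep$n_selected < best$report$n_selected ||
          (rep$n_selected == best$report$n_selected &&
           paste(mask, collapse = "") < paste(best$mask, collapse = ""))))) {
      best <- cand
    }
  }
  best$n_evaluations <- attr(ev, "state")$n_evaluations
  best
}
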