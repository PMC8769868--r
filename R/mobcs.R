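# Multiobjective binary cuckoo search: Levy-flight global walk, abandonment
# local walk with per-coordinate Heaviside gating, sigmoid transfer
# binarization, elitist replacement, convergence tracing.

#' Cuckoo search configuration
#'
#' Defaults follow the standard EEG channel-selection setup: 30 nests,
#' 100 iterations, abandonment probability 0.25, Levy exponent 1.5. The step
#' scale defaults to 1: positions live on the order-1 scale the sigmoid
#' transfer discriminates on, and order-1 Levy steps let coordinates commit
#' to (de)selection; much smaller scales leave the walk numerically inert.
#'
#' @param n_nests population size `N >= 2`.
#' @param max_iter iteration budget.
#' @param p_a abandonment probability in `(0, 1)`.
#' @param beta Levy exponent, `1 < beta <= 2`.
#' @param alpha step-size scale `> 0`.
#' @param seed integer seed for the whole run.
#' @param transfer_direction `"standard"`: bit = 1 when a uniform draw falls
#'   below the sigmoid of the coordinate (large coordinates select the
#'   channel). `"printed"` inverts the comparison, for compatibility with the
#'   opposite convention found in parts of the binary-metaheuristic
#'   literature.
#' @return a `cs_config`.
#' @export
cs_config <- function(n_nests = 30, max_iter = 100, p_a = 0.25, beta = 1.5,
                      alpha = 1, seed = 1L,
                      transfer_direction = c("standard", "printed")) {
  transfer_direction <- match.arg(transfer_direction)
  stopifnot(n_nests >= 2, max_iter >= 1)
  if (p_a <= 0 || p_a >= 1) stop("p_a must lie strictly in (0, 1)")
  if (beta <= 1 || beta > 2) stop("beta must lie in (1, 2]")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(n_nests = as.integer(n_nests), max_iter = as.integer(max_iter),
                 p_a = p_a, beta = beta, alpha = alpha, seed = as.integer(seed),
                 transfer_direction = transfer_direction),
            class = "cs_config")
}

#' Heavy-tailed Levy steps by Mantegna's construction
#'
#' Draws symmetric Levy-flight step lengths with tail index `beta` as the
#' ratio `u / |v|^(1/beta)` of scaled normals. Uses the calling RNG state.
#'
#' @param beta tail exponent, `1 < beta <= 2`.
#' @param size number of draws.
#' @return numeric vector of steps, symmetric about 0.
#' @export
levy_step <- function(beta, size) {
  if (beta <= 1 || beta > 2) stop("beta must lie in (1, 2]")
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(size, sd = sigma_u)
  v <- rnorm(size)
  u / abs(v)^(1 / beta)
}

sigmoid <- function(s) 1 / (1 + exp(-s))

#' Binarize a continuous position through the sigmoid transfer function
#'
#' Each coordinate's bit is set with probability `sigma(s) = 1/(1+exp(-s))`:
#' bit = 1 when a fresh uniform draw falls below the sigmoid (the standard
#' direction; `"printed"` inverts it). An all-zero mask is repaired by
#' setting one uniformly chosen bit, since an empty channel set cannot be
#' scored.
#'
#' @param position finite numeric vector.
#' @param direction transfer comparison direction, see [cs_config()].
#' @return integer 0/1 mask of the same length, at least one bit set.
#' @export
binarize <- function(position, direction = "standard") {
  if (any(!is.finite(position))) stop("non-finite coordinate in position")
  prob <- sigmoid(position)
  phi <- runif(length(position))
  bits <- if (direction == "printed") as.integer(phi > prob)
          else as.integer(phi < prob)
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1)] <- 1L
  bits
}

#' Initialize the nest population
#'
#' Positions are drawn uniformly on `[-1, 1]` (the sigmoid transfer absorbs
#' scale, so bit probabilities start near 0.5); masks are binarized and
#' repaired to be non-empty. Uses the calling RNG state.
#'
#' @param n_nests population size.
#' @param d number of channels.
#' @param direction transfer direction for [binarize()].
#' @return list of solutions, each `list(position, mask, report = NULL)`.
#' @export
init_population <- function(n_nests, d, direction = "standard") {
  stopifnot(n_nests >= 2, d >= 1)
  lapply(seq_len(n_nests), function(i) {
    pos <- runif(d, -1, 1)
    list(position = pos, mask = binarize(pos, direction), report = NULL)
  })
}

#' Levy-flight global walk towards the best nest
#'
#' `new = position + alpha * levy * (position - best_position)` elementwise.
#' When the walker is itself the current best (zero difference vector) it
#' takes an unscaled `alpha * levy` perturbation instead, so the best nest
#' still explores.
#'
#' @param position,best_position equal-length numeric vectors.
#' @param alpha step scale.
#' @param beta Levy exponent.
#' @return proposed position vector.
#' @export
global_walk <- function(position, best_position, alpha, beta) {
  stopifnot(length(position) == length(best_position))
  step <- levy_step(beta, length(position))
  diffv <- position - best_position
  if (all(diffv == 0)) position + alpha * step
  else position + alpha * step * diffv
}

#' Abandonment local walk over the whole population
#'
#' Every coordinate of every nest is, with probability `p_a`, displaced along
#' the difference of two other randomly chosen nests:
#' `x_i <- x_i + r * H(p_a - eps) * (x_j - x_k)` with `j != k != i`,
#' per-coordinate uniform `eps` and step scale `r`. Coordinates whose `eps`
#' exceeds `p_a` are untouched.
#'
#' @param positions `N x d` matrix of nest positions, `N >= 3`.
#' @param p_a abandonment probability.
#' @return `N x d` matrix of proposed positions.
#' @export
local_walk <- function(positions, p_a) {
  n <- nrow(positions); d <- ncol(positions)
  if (is.null(n) || n < 3) stop("local walk needs a population of >= 3 nests")
  out <- positions
  for (i in seq_len(n)) {
    jk <- sample((seq_len(n))[-i], 2)
    eps <- runif(d)
    r <- runif(d)
    gate <- as.numeric(eps < p_a)
    out[i, ] <- positions[i, ] +
      r * gate * (positions[jk[1], ] - positions[jk[2], ])
  }
  out
}

#' Run the multiobjective binary cuckoo search
#'
#' Each iteration: (1) every nest takes a Levy-flight global walk towards the
#' best nest, is binarized and scored, and replaces a randomly chosen other
#' nest if strictly fitter; (2) the abandonment local walk perturbs a
#' fraction ~`p_a` of coordinates, with greedy per-nest replacement. The
#' best-ever solution is tracked elitistically, so the convergence trace is
#' non-decreasing. Fitness reports are memoized by bit pattern; the
#' evaluation counter reports uncached cross-validation runs only.
#'
#' @param features a `feature_table`.
#' @param obj_config an [objective_config()].
#' @param config a [cs_config()].
#' @return a `selection_result`: `best_mask`, `best_report`, `trace`
#'   (best-so-far fitness per iteration), `n_evaluations`, `config`,
#'   `obj_config`.
#' @examples
#' tab <- generate_feature_table(plant_spec(5, 10, 6, c(1, 2), seed = 1))
#' res <- run_mobcs(tab, objective_config(), cs_config(n_nests = 8,
#'                  max_iter = 10, seed = 3))
#' which(res$best_mask == 1)
#' @export
run_mobcs <- function(features, obj_config = objective_config(),
                      config = cs_config()) {
  stopifnot(inherits(config, "cs_config"))
  ev <- make_evaluator(features, obj_config, cache = TRUE)
  d <- attr(ev, "d")
  dir <- config$transfer_direction
  withr::with_seed(config$seed, {
    pop <- init_population(config$n_nests, d, dir)
    for (i in seq_along(pop)) pop[[i]]$report <- ev(pop[[i]]$mask)
    bi <- which.max(vapply(pop, function(s) s$report$fit, 0))
    best <- pop[[bi]]
    trace <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      # global Levy-flight walk, compare against a random nest
      for (i in seq_len(config$n_nests)) {
        newpos <- global_walk(pop[[i]]$position, best$position,
                              config$alpha, config$beta)
        newmask <- binarize(newpos, dir)
        newrep <- ev(newmask)
        j <- sample((seq_len(config$n_nests))[-i], 1)
        if (newrep$fit > pop[[j]]$report$fit) {
          pop[[j]] <- list(position = newpos, mask = newmask, report = newrep)
        }
        if (newrep$fit > best$report$fit) {
          best <- list(position = newpos, mask = newmask, report = newrep)
        }
      }
      # abandonment local walk, greedy per-nest replacement
      posmat <- do.call(rbind, lapply(pop, `[[`, "position"))
      newposmat <- local_walk(posmat, config$p_a)
      for (i in seq_len(config$n_nests)) {
        newmask <- binarize(newposmat[i, ], dir)
        newrep <- ev(newmask)
        if (newrep$fit > pop[[i]]$report$fit) {
          pop[[i]] <- list(position = newposmat[i, ], mask = newmask,
                           report = newrep)
        }
        if (newrep$fit > best$report$fit) {
          best <- list(position = newposmat[i, ], mask = newmask,
                       report = newrep)
        }
      }
      trace[t] <- best$report$fit
    }
    structure(
      list(best_mask = best$mask, best_report = best$report, trace = trace,
           n_evaluations = attr(ev, "state")$n_evaluations,
           config = config, obj_config = obj_config, method = "MOBCS-KNN"),
      class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d/%d channels, fit %.4f, acc %.4f, %d evaluations\n",
              x$method %||% "?", x$best_report$n_selected,
              length(x$best_mask), x$best_report$fit, x$best_report$acc,
              x$n_evaluations))
  cat("channels:", paste(which(x$best_mask == 1), collapse = " "), "\n")
  invisible(x)
}

#' Write a selection result as delimited text
#'
#' Emits `<prefix>_mask.csv` (channel, selected — 1-based channel names),
#' `<prefix>_trace.csv` (iteration, best_fit) and `<prefix>_run.json`
#' (configs, seed, evaluation count, final metrics).
#'
#' @param result a `selection_result`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_selection_result <- function(result, prefix) {
  d <- length(result$best_mask)
  write.csv(data.frame(channel = paste0("ch", seq_len(d)),
                       selected = result$best_mask),
            paste0(prefix, "_mask.csv"), row.names = FALSE)
  write.csv(data.frame(iteration = seq_along(result$trace),
                       best_fit = result$trace),
            paste0(prefix, "_trace.csv"), row.names = FALSE)
  meta <- list(method = result$method,
               config = unclass(result$config),
               obj_config = unclass(result$obj_config),
               n_evaluations = result$n_evaluations,
               fit = result$best_report$fit, acc = result$best_report$acc,
               n_selected = result$best_report$n_selected)
  jsonlite::write_json(meta, paste0(prefix, "_run.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(prefix)
}
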