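#' Specify a planted-channel synthetic dataset
#'
#' A plant specification describes an EEG-like population in which only a
#' known subset of channels (the "informative set" `informative_channels`)
#' carries subject-discriminative structure. Everything downstream — feature
#' extraction, KNN identification, channel selection — can then be validated
#' against this ground truth.
#'
#' @param n_subjects number of subjects (identification classes).
#' @param n_recordings recordings per subject. The motor/imagery montage this
#'   emulates has 12 recordings per subject, which is the default.
#' @param n_channels total number of channels `d` (64 on the emulated montage).
#' @param informative_channels integer vector of 1-based channel indices that
#'   carry subject identity; must be a non-empty subset of `1:n_channels`.
#' @param effect_size unitless separation scale between subjects on the
#'   informative channels; `0` removes all identity information.
#' @param noise_sd positive unitless noise scale (observation noise on feature
#'   tables; per-recording AR-coefficient jitter on signals).
#' @param seed integer seed making the generated data reproducible.
#' @return an object of class `plant_spec`.
#' @examples
#' spec <- plant_spec(n_subjects = 4, n_channels = 8,
#'                    informative_channels = c(2, 5), seed = 1)
#' @export
plant_spec <- function(n_subjects, n_recordings = 12, n_channels,
                       informative_channels, effect_size = 3, noise_sd = 1,
                       seed = 1L) {
  stopifnot(n_subjects >= 2, n_recordings >= 1, n_channels >= 2)
  informative_channels <- sort(unique(as.integer(informative_channels)))
  if (length(informative_channels) == 0) {
    stop("informative_channels must be non-empty: a plant with no informative ",
         "channels carries no ground truth (use effect_size = 0 for a null plant)")
  }
  if (any(informative_channels < 1L) || any(informative_channels > n_channels)) {
    stop("informative_channels must lie in 1..n_channels")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_recordings = as.integer(n_recordings),
         n_channels = as.integer(n_channels),
         informative_channels = informative_channels,
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "plant_spec")
}

#' @export
print.plant_spec <- function(x, ...) {
  cat(sprintf(
    "plant_spec: %d subjects x %d recordings x %d channels; %d informative (%s); effect %.2g, noise %.2g, seed %d\n",
    x$n_subjects, x$n_recordings, x$n_channels,
    length(x$informative_channels),
    paste(x$informative_channels, collapse = ","),
    x$effect_size, x$noise_sd, x$seed))
  invisible(x)
}

# Levinson step: reflection coefficients -> AR coefficients in the
# x_t = sum_i a_i x_{t-i} + e_t convention. |k_i| < 1 guarantees stability.
reflection_to_ar <- function(k) {
  a <- numeric(0)
  for (m in seq_along(k)) {
    if (m == 1) a <- k[1]
    else a <- c(a - k[m] * rev(a), k[m])
  }
  a
}

# Shrink the poles of an AR polynomial so all lie within radius rmax,
# preserving conjugate symmetry (magnitude-only shrink).
stabilize_ar <- function(a, rmax = 0.95) {
  p <- length(a)
  roots <- polyroot(c(1, -a))
  poles <- 1 / roots
  mags <- Mod(poles)
  if (all(mags <= rmax)) return(a)
  poles <- poles * pmin(1, rmax / mags)
  coef <- 1
  for (pl in poles) coef <- c(coef, 0) - pl * c(0, coef)
  -Re(coef[2:(p + 1)])
}

ar_is_stable <- function(a) all(Mod(polyroot(c(1, -a))) > 1)

# Subject-specific stable AR coefficients: reflection coefficients squashed
# through tanh so effect_size = 0 collapses every subject to white noise.
# The separation budget is split across the informative channels, mirroring
# the feature-table plant.
draw_subject_ar <- function(order, effect_size, n_informative) {
  k <- tanh(effect_size / sqrt(n_informative) * rnorm(order, sd = 0.5))
  reflection_to_ar(k)
}

#' Generate planted multichannel EEG-like signals
#'
#' Channels in the informative set are realized from subject-specific stable
#' autoregressive processes: each subject draws one set of AR coefficients per
#' informative channel (spread controlled by `effect_size`), which is jittered
#' per recording by Gaussian noise of scale `noise_sd` on the coefficients and
#' re-stabilized by shrinking any pole back inside the unit circle. Channels
#' outside the set share a single AR process common to all subjects, so they
#' carry no identity information. Subject identity therefore lives in the AR
#' coefficients — exactly the quantity the feature pipeline estimates — not in
#' signal amplitude.
#'
#' @param spec a [plant_spec()].
#' @param sampling_rate sampling rate in Hz.
#' @param duration recording duration in seconds; `duration * sampling_rate`
#'   must be at least 256 samples.
#' @param ar_order order of the generating AR processes (default 5).
#' @return an object of class `signal_dataset`: a list with `signals`
#'   (4-d array `[subject, recording, channel, sample]`), `subject_ids`,
#'   `sampling_rate`, `channel_names` and the generating `spec`.
#' @examples
#' spec <- plant_spec(4, 3, 8, c(1, 5), seed = 7)
#' ds <- generate_signals(spec, sampling_rate = 160, duration = 2)
#' dim(ds$signals)
#' @export
generate_signals <- function(spec, sampling_rate = 160, duration = 4,
                             ar_order = 5) {
  stopifnot(inherits(spec, "plant_spec"))
  n_samp <- round(duration * sampling_rate)
  if (n_samp < 256) stop("duration x sampling_rate must give >= 256 samples")
  if (n_samp < 2 * ar_order + 1) stop("too few samples for the AR order")
  d <- spec$n_channels
  withr::with_seed(spec$seed, {
    shared_a <- reflection_to_ar(runif(ar_order, -0.5, 0.5))
    n_info <- length(spec$informative_channels)
    subj_a <- lapply(seq_len(spec$n_subjects), function(s) {
      lapply(spec$informative_channels, function(cc)
        draw_subject_ar(ar_order, spec$effect_size, n_info))
    })
    x <- array(0, dim = c(spec$n_subjects, spec$n_recordings, d, n_samp))
    for (s in seq_len(spec$n_subjects)) {
      for (r in seq_len(spec$n_recordings)) {
        for (ch in seq_len(d)) {
          idx <- match(ch, spec$informative_channels)
          a <- if (is.na(idx)) shared_a else {
            jit <- subj_a[[s]][[idx]] + rnorm(ar_order, sd = 0.05 * spec$noise_sd)
            stabilize_ar(jit)
          }
          ok <- FALSE
          for (try in 1:20) {
            if (ar_is_stable(a)) { ok <- TRUE; break }
            a <- stabilize_ar(a, rmax = 0.9)
          }
          if (!ok) stop("failed to obtain a stable AR polynomial after retries")
          x[s, r, ch, ] <- as.numeric(arima.sim(list(ar = a), n = n_samp))
        }
      }
    }
    structure(
      list(signals = x,
           subject_ids = paste0("S", seq_len(spec$n_subjects)),
           sampling_rate = sampling_rate,
           channel_names = paste0("ch", seq_len(d)),
           spec = spec),
      class = "signal_dataset")
  })
}

#' @export
print.signal_dataset <- function(x, ...) {
  dm <- dim(x$signals)
  cat(sprintf("signal_dataset: %d subjects x %d recordings x %d channels x %d samples @ %g Hz\n",
              dm[1], dm[2], dm[3], dm[4], x$sampling_rate))
  invisible(x)
}

#' Generate a planted channel-blocked feature table directly
#'
#' Bypasses the signal stage: rows are subject-recording feature vectors with
#' `coeffs_per_channel` columns per channel. Columns belonging to informative
#' channels get subject-specific means; all other columns are pure Gaussian
#' noise at scale `noise_sd`. `effect_size` is the *total* multivariate
#' separation budget: per-column subject means are drawn with standard
#' deviation `effect_size / sqrt(n_informative * coeffs_per_channel)`, so
#' identity is distributed across the whole informative set rather than
#' concentrated in any single channel — selecting more of the informative set
#' genuinely improves identification, which is what makes planted-set
#' recovery a meaningful test of the channel selector. This is the fast
#' ground-truth surface used to exercise the objective and the optimizer.
#'
#' @param spec a [plant_spec()].
#' @param coeffs_per_channel number of feature columns per channel (>= 1),
#'   playing the role of the AR order `p`.
#' @return a `feature_table` (see [extract_features()] for the structure).
#' @examples
#' tab <- generate_feature_table(plant_spec(5, 6, 6, c(1, 2), seed = 3),
#'                               coeffs_per_channel = 3)
#' dim(tab$x)
#' @export
generate_feature_table <- function(spec, coeffs_per_channel = 3) {
  stopifnot(inherits(spec, "plant_spec"), coeffs_per_channel >= 1)
  p <- as.integer(coeffs_per_channel)
  d <- spec$n_channels
  n <- spec$n_subjects * spec$n_recordings
  withr::with_seed(spec$seed, {
    mu <- matrix(0, spec$n_subjects, d * p)
    info_cols <- unlist(lapply(spec$informative_channels,
                               function(cc) ((cc - 1) * p + 1):(cc * p)))
    sigma_m <- spec$effect_size / sqrt(length(info_cols))
    mu[, info_cols] <- sigma_m *
      matrix(rnorm(spec$n_subjects * length(info_cols)),
             spec$n_subjects, length(info_cols))
    subject <- rep(seq_len(spec$n_subjects), each = spec$n_recordings)
    recording <- rep(seq_len(spec$n_recordings), times = spec$n_subjects)
    x <- mu[subject, , drop = FALSE] +
      matrix(rnorm(n * d * p, sd = spec$noise_sd), n, d * p)
    colnames(x) <- paste0("ch", rep(seq_len(d), each = p), "_a", rep(seq_len(p), d))
    new_feature_table(x, subject = paste0("S", subject), recording = recording,
                      order = p,
                      meta = list(source = "planted_table", spec = spec))
  })
}

#' Write a signal dataset as delimited text plus a manifest
#'
#' One CSV per subject-recording (columns = channels) and a `manifest.csv`
#' with columns `subject,recording,path,sampling_rate`.
#'
#' @param dataset a `signal_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_signal_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "signal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- dim(dataset$signals)
  rows <- list()
  for (s in seq_len(dm[1])) {
    for (r in seq_len(dm[2])) {
      mat <- t(dataset$signals[s, r, , ])
      colnames(mat) <- dataset$channel_names
      fn <- sprintf("%s_rec%02d.csv", dataset$subject_ids[s], r)
      write.csv(mat, file.path(dir, fn), row.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        subject = dataset$subject_ids[s], recording = r, path = fn,
        sampling_rate = dataset$sampling_rate)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a signal dataset written by [write_signal_dataset()]
#'
#' @param dir directory containing `manifest.csv` and the per-recording files.
#' @return a `signal_dataset`.
#' @export
read_signal_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  subjects <- unique(manifest$subject)
  recs <- sort(unique(manifest$recording))
  first <- read.csv(file.path(dir, manifest$path[1]))
  d <- ncol(first); n_samp <- nrow(first)
  x <- array(0, dim = c(length(subjects), length(recs), d, n_samp))
  for (i in seq_len(nrow(manifest))) {
    s <- match(manifest$subject[i], subjects)
    r <- match(manifest$recording[i], recs)
    mat <- as.matrix(read.csv(file.path(dir, manifest$path[i])))
    x[s, r, , ] <- t(mat)
  }
  structure(
    list(signals = x, subject_ids = subjects,
         sampling_rate = as.numeric(manifest$sampling_rate[1]),
         channel_names = colnames(first), spec = NULL),
    class = "signal_dataset")
}
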