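# Feature pipeline: zero-phase band-pass + notch filtering, optional wavelet
# denoising, and per-channel autoregressive coefficients assembled into a
# channel-blocked feature table.

new_feature_table <- function(x, subject, recording, order, meta = list()) {
  stopifnot(is.matrix(x), nrow(x) == length(subject))
  p <- as.integer(order)
  d <- ncol(x) %/% p
  stopifnot(d * p == ncol(x))
  blocks <- lapply(seq_len(d), function(cc) ((cc - 1L) * p + 1L):(cc * p))
  names(blocks) <- paste0("ch", seq_len(d))
  structure(
    list(x = x, subject = as.character(subject), recording = recording,
         channel_blocks = blocks, n_channels = d, order = p, meta = meta),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d rows (%d subjects) x %d columns = %d channels x AR(%d)\n",
    nrow(x$x), length(unique(x$subject)), ncol(x$x), x$n_channels, x$order))
  invisible(x)
}

#' Zero-phase band-pass plus notch filter
#'
#' Applies a Butterworth band-pass and a narrow Butterworth band-stop (notch)
#' filter, both forward-backward ([signal::filtfilt()]) so the output has no
#' group delay. Defaults suit a 160 Hz motor/imagery montage recorded on a
#' 60 Hz mains supply.
#'
#' @param x numeric signal vector.
#' @param sampling_rate sampling rate in Hz.
#' @param band passband edges `c(lo, hi)` in Hz, `0 < lo < hi < Nyquist`.
#' @param notch mains frequency to remove, in Hz; `NULL` skips the notch.
#' @param notch_width full stop-band width around `notch`, Hz.
#' @param order Butterworth design order for the band-pass.
#' @return filtered vector, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 160)
#' y <- bandpass_notch(sin(2 * pi * 10 * t), 160)
#' @export
bandpass_notch <- function(x, sampling_rate, band = c(0.5, 50), notch = 60,
                           notch_width = 2, order = 4) {
  nyq <- sampling_rate / 2
  if (band[1] <= 0) stop("low passband edge must be > 0, got ", band[1])
  if (band[2] <= band[1]) stop("passband edges must satisfy lo < hi")
  if (band[2] >= nyq) stop("high passband edge ", band[2],
                           " Hz is at or above Nyquist (", nyq, " Hz)")
  mu <- mean(x)
  bp <- signal::butter(order, band / nyq, type = "pass")
  y <- filtfilt_padded(bp, x - mu, sampling_rate, band[1])
  if (!is.null(notch)) {
    if (notch >= nyq) stop("notch frequency ", notch,
                           " Hz is at or above Nyquist (", nyq, " Hz)")
    bs <- signal::butter(2, c(notch - notch_width / 2, notch + notch_width / 2) / nyq,
                         type = "stop")
    y <- filtfilt_padded(bs, y, sampling_rate, band[1])
  }
  y
}

# Forward-backward filtering with odd-reflection end padding (and the mean
# removed by the caller), taming the startup transients of a zero-state
# filter run; pad length tracks the slowest passband period.
filtfilt_padded <- function(filt, x, sampling_rate, lowest_hz) {
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * sampling_rate / lowest_hz))
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Wavelet denoising by detail-coefficient thresholding
#'
#' Decomposes the signal with a periodized orthogonal Daubechies wavelet,
#' thresholds the detail coefficients (universal threshold
#' `sigma * sqrt(2 log n)` with the noise scale estimated by the median
#' absolute deviation of the finest details, unless `threshold` is given),
#' and reconstructs. With `threshold = 0` the round trip is exact to
#' numerical precision.
#'
#' @param x numeric signal vector.
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"`.
#' @param level decomposition depth; must satisfy `2^level <= length(x)`.
#' @param mode `"soft"` (shrink towards zero) or `"hard"` (zero out).
#' @param threshold optional fixed threshold; `NULL` uses the universal rule.
#' @return denoised vector, same length as `x`.
#' @examples
#' y <- wavelet_denoise(rnorm(512), "db4", level = 4)
#' @export
wavelet_denoise <- function(x, wavelet = "db4", level = 4,
                            mode = c("soft", "hard"), threshold = NULL) {
  mode <- match.arg(mode)
  dec <- dwt_periodized(x, wavelet = wavelet, level = level)
  if (is.null(threshold)) {
    sigma <- mad(dec$details[[1]], constant = 1) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  if (threshold > 0) {
    dec$details <- lapply(dec$details, function(d) {
      if (mode == "soft") sign(d) * pmax(abs(d) - threshold, 0)
      else d * (abs(d) > threshold)
    })
  }
  idwt_periodized(dec)
}

#' Fit an autoregressive model to one signal
#'
#' Estimates AR coefficients in the convention
#' `x_t = a_1 x_{t-1} + ... + a_p x_{t-p} + e_t`. Burg's method is the
#' default (well suited to short EEG segments); Yule-Walker is available as
#' an alternative. The presets used for identification features are orders
#' 5, 10 and 20, but any order >= 1 is accepted.
#'
#' @param x numeric signal vector, length > `2 * order`, non-constant.
#' @param order AR order `p`.
#' @param method `"burg"` or `"yule-walker"`.
#' @return an `ar_model`: list with `order`, `coefficients` (length `p`) and
#'   `noise_variance`.
#' @examples
#' m <- fit_ar(as.numeric(arima.sim(list(ar = 0.6), 500)), order = 2)
#' m$coefficients
#' @export
fit_ar <- function(x, order, method = c("burg", "yule-walker")) {
  method <- match.arg(method)
  if (length(x) <= 2 * order) {
    stop("signal of length ", length(x), " too short for AR order ", order,
         " (need > ", 2 * order, " samples)")
  }
  if (var(x) == 0) stop("constant signal: autocovariance is degenerate")
  fit <- if (method == "burg") {
    ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  } else {
    ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  }
  structure(
    list(order = as.integer(order), coefficients = as.numeric(fit$ar),
         noise_variance = max(0, fit$var.pred), method = method),
    class = "ar_model")
}

#' Extract a channel-blocked AR feature table from a signal dataset
#'
#' For every subject, recording and channel the signal is optionally filtered
#' ([bandpass_notch()]) and denoised ([wavelet_denoise()]), an AR model of the
#' requested order is fitted, and the coefficients are laid out contiguously
#' per channel: channel `c` owns columns `((c-1)*p + 1):(c*p)`. Rows are one
#' per subject-recording, or the per-subject mean across recordings.
#'
#' @param dataset a `signal_dataset`.
#' @param order AR order (5, 10 and 20 are the conventional presets).
#' @param preprocessing list of switches: `filter` (logical), `band`, `notch`,
#'   `denoise` (logical), `wavelet`, `level`. `NULL` means raw signals.
#' @param aggregate `"per_recording"` (default; required for 10-fold CV over
#'   recordings) or `"mean_per_subject"`.
#' @param method AR estimator passed to [fit_ar()].
#' @return a `feature_table` with fields `x` (matrix), `subject`, `recording`,
#'   `channel_blocks`, `n_channels`, `order`, `meta`.
#' @examples
#' ds <- generate_signals(plant_spec(3, 2, 4, 1, seed = 1), 160, 2)
#' tab <- extract_features(ds, order = 5)
#' dim(tab$x)
#' @export
extract_features <- function(dataset, order = 5, preprocessing = NULL,
                             aggregate = c("per_recording", "mean_per_subject"),
                             method = "burg") {
  stopifnot(inherits(dataset, "signal_dataset"))
  aggregate <- match.arg(aggregate)
  pp <- preprocessing
  dm <- dim(dataset$signals)
  n_sub <- dm[1]; n_rec <- dm[2]; d <- dm[3]
  p <- as.integer(order)
  x <- matrix(NA_real_, n_sub * n_rec, d * p)
  subject <- character(n_sub * n_rec)
  recording <- integer(n_sub * n_rec)
  row <- 0L
  for (s in seq_len(n_sub)) {
    for (r in seq_len(n_rec)) {
      row <- row + 1L
      subject[row] <- dataset$subject_ids[s]
      recording[row] <- r
      for (cc in seq_len(d)) {
        sig <- dataset$signals[s, r, cc, ]
        if (isTRUE(pp$filter)) {
          sig <- bandpass_notch(sig, dataset$sampling_rate,
                                band = pp$band %||% c(0.5, 50),
                                notch = pp$notch %||% 60)
        }
        if (isTRUE(pp$denoise)) {
          sig <- wavelet_denoise(sig, wavelet = pp$wavelet %||% "db4",
                                 level = pp$level %||% 4)
        }
        fit <- tryCatch(fit_ar(sig, p, method = method), error = function(e) {
          stop("AR fit failed for subject ", dataset$subject_ids[s],
               ", recording ", r, ", channel ", cc, ": ", conditionMessage(e))
        })
        x[row, ((cc - 1L) * p + 1L):(cc * p)] <- fit$coefficients
      }
    }
  }
  colnames(x) <- paste0("ch", rep(seq_len(d), each = p), "_a", rep(seq_len(p), d))
  meta <- list(order = p, preprocessing = pp, aggregate = aggregate,
               method = method, source = "extract_features")
  if (aggregate == "mean_per_subject") {
    xs <- rowsum(x, subject) / as.vector(table(subject)[unique(subject)])
    # rowsum orders groups by sort(unique); realign to first appearance
    xs <- xs[unique(subject), , drop = FALSE]
    x <- xs
    recording <- rep(NA_integer_, nrow(x))
    subject <- rownames(x)
  }
  new_feature_table(x, subject, recording, order = p, meta = meta)
}

#' Restrict a feature table to the channels of a mask
#'
#' Drops the full column block of every deselected channel; the surviving
#' table has `sum(mask) * order` columns.
#'
#' @param features a `feature_table`.
#' @param mask 0/1 vector of length `n_channels`.
#' @return a matrix with only the selected channels' columns.
#' @export
mask_columns <- function(features, mask) {
  stopifnot(length(mask) == features$n_channels)
  keep <- unlist(features$channel_blocks[mask == 1], use.names = FALSE)
  features$x[, keep, drop = FALSE]
}

#' Write a feature table as delimited text
#'
#' Columns `subject,recording,ch{c}_a{j}`; a sidecar JSON file (same path with
#' `.meta.json` appended) records order and preprocessing settings.
#'
#' @param features a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(subject = features$subject,
                   recording = features$recording,
                   features$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- features$meta
  meta$order <- features$order
  meta$n_channels <- features$n_channels
  meta$spec <- NULL
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path; the AR order is recovered from the sidecar metadata
#'   if present, else from the `ch{c}_a{j}` header convention.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  metapath <- paste0(path, ".meta.json")
  if (file.exists(metapath)) {
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    p <- meta$order
  } else {
    meta <- list()
    p <- max(as.integer(sub("^ch\\d+_a", "", colnames(x))))
  }
  new_feature_table(x, df$subject, df$recording, order = p, meta = meta)
}
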