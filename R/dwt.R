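# Periodized orthogonal discrete wavelet transform.
#
# Kept deliberately small: the denoising stage only needs an orthogonal
# perfect-reconstruction transform with a handful of Daubechies filters.
# Signals whose length is not a multiple of 2^level are extended by periodic
# wrap before analysis and truncated after synthesis, which preserves exact
# reconstruction of the original samples.

wavelet_filters <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.482962913144690, 0.836516303737808,
            0.224143868042013, -0.129409522551260),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997),
    stop("unknown wavelet '", name, "'; supported: haar, db2, db4"))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, L = L)
}

dwt_step <- function(x, f) {
  n <- length(x)
  half <- n %/% 2
  idx <- outer(2 * seq_len(half) - 2, seq_len(f$L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], half, f$L)
  list(a = drop(xm %*% f$h), d = drop(xm %*% f$g))
}

idwt_step <- function(a, d, f) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  for (k in seq_len(f$L)) {
    pos <- (2 * seq_len(half) - 2 + (k - 1)) %% n + 1
    contrib <- f$h[k] * a + f$g[k] * d
    # accumulate with possible index collisions when L > n
    acc <- vapply(split(contrib, pos), sum, 0)
    x[as.integer(names(acc))] <- x[as.integer(names(acc))] + acc
  }
  as.numeric(x)
}

max_dwt_level <- function(n) max(0L, floor(log2(n)))

# Multi-level periodized DWT. Returns list(approx, details = list(level 1..J)).
dwt_periodized <- function(x, wavelet = "db4", level = 4) {
  f <- wavelet_filters(wavelet)
  n <- length(x)
  if (level < 1) stop("level must be >= 1")
  if (2^level > n) stop("level ", level, " too deep for signal of length ", n)
  pad <- (2^level - n %% 2^level) %% 2^level
  xp <- if (pad > 0) c(x, x[seq_len(pad)]) else x
  details <- vector("list", level)
  a <- xp
  for (j in seq_len(level)) {
    st <- dwt_step(a, f)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details, wavelet = wavelet, level = level,
       n = n, pad = pad)
}

idwt_periodized <- function(dec) {
  f <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$level))) a <- idwt_step(a, dec$details[[j]], f)
  a[seq_len(dec$n)]
}
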