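# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + 12345 + 97 * as.numeric(k)) %% 2147483647
}

# Trapezoid integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Column standard deviations without apply() overhead.
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1))
}

# Standardize matrix rows to mean 0, SD 1.
standardize_rows <- function(m) {
  m <- m - rowMeans(m)
  s <- sqrt(rowSums(m^2) / (ncol(m) - 1))
  if (any(s == 0)) stop("cannot standardize a zero-variance row")
  m / s
}

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 50% segment overlap and per-segment
#' linear detrending, normalized so the spectrum integrates (trapezoid rule)
#' to unit total power.
#'
#' @param x numeric time series.
#' @param fs sampling frequency (Hz).
#' @param nperseg segment length (default `min(length(x), 128)`).
#' @return list with `freq` (Hz) and `power` (normalized density).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 128L)) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stop("series too short for spectral estimation")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  tt <- seq_len(nperseg)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), seg)
    seg <- fit$residuals * win
    pg <- Mod(stats::fft(seg))^2
    acc <- acc + pg[seq_len(nfreq)]
  }
  freq <- (seq_len(nfreq) - 1L) * fs / nperseg
  power <- acc / length(starts)
  tot <- trapz(freq, power)
  if (tot > 0) power <- power / tot
  list(freq = freq, power = power)
}
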