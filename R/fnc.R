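#' Zero-phase Butterworth band-pass filter
#'
#' Order-5 (per pass) Butterworth applied forward and backward for zero phase,
#' with odd-reflection padding at both ends to suppress edge transients. The
#' default band 0.01-0.1 Hz is where resting-state BOLD power concentrates.
#'
#' @param tc numeric vector, or matrix filtered row-wise.
#' @param tr_s sampling interval (s).
#' @param low_hz,high_hz passband edges (Hz), 0 < low < high < Nyquist.
#' @param order filter order per pass.
#' @return filtered series (same shape as `tc`), mean approximately 0.
#' @export
bandpass_filter <- function(tc, tr_s, low_hz = 0.01, high_hz = 0.10,
                            order = 5L) {
  fs <- 1 / tr_s
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("need 0 < low_hz < high_hz < Nyquist (", round(nyq, 4), " Hz)")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  b <- bf$b; a <- bf$a
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  zi <- lfilter_zi(b, a)
  padlen <- 3L * (nfilt - 1L)
  filt1 <- function(x) {
    n <- length(x)
    if (n <= padlen) {
      stop("series too short for zero-phase filtering; need more than ",
           padlen, " samples, got ", n)
    }
    # odd reflection around the end points suppresses edge transients
    pre <- 2 * x[1] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    ext <- c(pre, x, post)
    y <- lfilter(b, a, ext, zi * ext[1])
    y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
    y[(padlen + 1L):(padlen + n)]
  }
  if (is.matrix(tc)) t(apply(tc, 1, filt1)) else filt1(tc)
}

# Direct-form II transposed IIR filter with explicit initial state.
lfilter <- function(b, a, x, zi) {
  nfilt <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1] * xm + z[1]
    if (nfilt > 2L) {
      for (i in 1:(nfilt - 2L)) {
        z[i] <- b[i + 1L] * xm + z[i + 1L] - a[i + 1L] * ym
      }
    }
    z[nfilt - 1L] <- b[nfilt] * xm - a[nfilt] * ym
    y[m] <- ym
  }
  y
}

# Steady-state initial filter state for a unit step (matched start-up).
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp_t <- matrix(0, n - 1L, n - 1L)
  comp_t[1, ] <- -a[-1] / a[1]
  if (n > 2L) comp_t[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  imin_a <- diag(n - 1L) - t(comp_t)
  bb <- b[-1] - a[-1] * b[1]
  # near-singular for cutoffs extremely close to DC; least-squares fallback
  tryCatch(solve(imin_a, bb),
           error = function(e) as.numeric(MASS::ginv(imin_a) %*% bb))
}

#' Maximal lagged correlation between two time courses
#'
#' Scans candidate lags on a TR/10 grid within ±`lag_max_s`; for each lag the
#' second series is shifted by cubic-spline interpolation and the Pearson
#' correlation with the first series is computed over the overlapping
#' segment. Returns the signed correlation of maximal magnitude and its lag.
#' A positive lag means `tc_b` is delayed relative to `tc_a`. Ties are broken
#' toward the lag nearest 0, then toward the negative lag. At `lag_max_s = 0`
#' this is exactly the plain Pearson correlation.
#'
#' @param tc_a,tc_b equal-length numeric vectors (band-pass filtered).
#' @param tr_s sampling interval (s).
#' @param lag_max_s maximum lag magnitude (s), default 3.
#' @param min_overlap minimum overlapping samples for a lag to be evaluated.
#' @param return_scan also return the full (lag, r) table of the search.
#' @return list with `r` and `lag_s` (and `scan`, a data.frame, when
#'   requested).
#' @export
max_lagged_correlation <- function(tc_a, tc_b, tr_s, lag_max_s = 3.0,
                                   min_overlap = 20L, return_scan = FALSE) {
  n <- length(tc_a)
  stopifnot(length(tc_b) == n, n >= 3L)
  tt <- (seq_len(n) - 1) * tr_s
  step <- tr_s / 10
  k_max <- floor(lag_max_s / step + 1e-9)
  lags <- step * (-k_max):k_max
  lags <- lags[order(abs(lags), lags)]  # preference order for tie-breaking
  fb <- stats::splinefun(tt, tc_b, method = "fmm")
  best_r <- NA_real_; best_lag <- NA_real_
  scan <- if (return_scan) data.frame(lag_s = numeric(0), r = numeric(0))
          else NULL
  for (d in lags) {
    src <- tt + d
    ok <- src >= 0 & src <= tt[n]
    if (sum(ok) < min_overlap) next
    # at whole-sample lags the spline passes through the data exactly
    shifted <- if (abs(d / tr_s - round(d / tr_s)) < 1e-9) {
      tc_b[round(src[ok] / tr_s) + 1L]
    } else {
      fb(src[ok])
    }
    r <- stats::cor(tc_a[ok], shifted)
    if (is.na(r)) next
    if (return_scan) scan <- rbind(scan, data.frame(lag_s = d, r = r))
    if (is.na(best_r) || abs(r) > abs(best_r)) {
      best_r <- r; best_lag <- d
    }
  }
  if (is.na(best_r)) stop("no lag had sufficient overlap")
  out <- list(r = best_r, lag_s = best_lag)
  if (return_scan) out$scan <- scan[order(scan$lag_s), ]
  out
}

#' Fisher z transform of a correlation
#'
#' z = arctanh(r) = 0.5 log((1 + r) / (1 - r)); variance-stabilizing for
#' sample correlations.
#'
#' @param r correlation value(s), |r| < 1.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  0.5 * log((1 + r) / (1 - r))
}

#' Ordered component pair list
#'
#' @param n_comp number of components C.
#' @param names optional component names.
#' @return data.frame with columns `i`, `j` (i < j) and `pair` label;
#'   K = C(C-1)/2 rows.
#' @export
component_pairs <- function(n_comp, names = NULL) {
  if (is.null(names)) names <- paste0("IC", seq_len(n_comp))
  idx <- which(upper.tri(matrix(0, n_comp, n_comp)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             pair = paste(names[idx[, 1]], names[idx[, 2]], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Per-subject functional network connectivity
#'
#' Band-pass filters each selected component time course and computes the
#' maximal lagged correlation for every unordered pair, returning Fisher-z
#' values and lag estimates. Six networks give the canonical 15 pairs.
#'
#' @param subject_tcs list (one per subject) of C x T time-course matrices,
#'   or of `subject_components` (their `tcs` are used).
#' @param tr_s repetition time (s).
#' @param low_hz,high_hz band-pass edges.
#' @param lag_max_s maximal lag (s).
#' @param comp_names optional component names for pair labels.
#' @return list with `z` (subjects x K), `lag_s` (subjects x K), `pairs`
#'   (data.frame from [component_pairs()]).
#' @export
fnc_matrix <- function(subject_tcs, tr_s, low_hz = 0.01, high_hz = 0.10,
                       lag_max_s = 3.0, comp_names = NULL) {
  get_tc <- function(s) if (inherits(s, "subject_components")) s$tcs else s
  first <- get_tc(subject_tcs[[1]])
  n_c <- nrow(first)
  pairs <- component_pairs(n_c, comp_names)
  k <- nrow(pairs)
  n_s <- length(subject_tcs)
  z <- matrix(NA_real_, n_s, k)
  lag <- matrix(NA_real_, n_s, k)
  for (s in seq_len(n_s)) {
    tcs <- bandpass_filter(get_tc(subject_tcs[[s]]), tr_s, low_hz, high_hz)
    for (p in seq_len(k)) {
      ml <- max_lagged_correlation(tcs[pairs$i[p], ], tcs[pairs$j[p], ],
                                   tr_s, lag_max_s)
      z[s, p] <- fisher_z(ml$r)
      lag[s, p] <- ml$lag_s
    }
  }
  rn <- names(subject_tcs)
  if (!is.null(rn)) { rownames(z) <- rn; rownames(lag) <- rn }
  colnames(z) <- colnames(lag) <- pairs$pair
  list(z = z, lag_s = lag, pairs = pairs)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: sort p ascending, find the largest i with
#' p_(i) <= i q / K, reject hypotheses 1..i.
#'
#' @param p vector of p-values in [0, 1].
#' @param q target FDR (default 0.05).
#' @return logical vector of rejections, aligned with `p`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  k <- length(p)
  if (k == 0L) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(k) * q / k)
  rej <- logical(k)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}

#' Group-level functional network connectivity statistics
#'
#' Within each group, every pair's Fisher-z values are tested against zero
#' (one-sample t) with BH-FDR control across the K pairs. Between groups,
#' each pair's z values are modeled by OLS on [intercept, group, demeaned
#' covariates] with a t-test on the group coefficient and BH-FDR across
#' pairs (reducing to the classic pooled two-sample t when no covariates are
#' supplied). Lags are compared between groups with a pooled two-sample t per
#' pair.
#'
#' @param z subjects x K Fisher-z matrix from [fnc_matrix()].
#' @param groups character vector of group labels (2 levels), length =
#'   subjects.
#' @param lag_s subjects x K lag matrix (optional; enables the lag
#'   comparison).
#' @param covariates subjects x k nuisance matrix or `NULL`.
#' @param q FDR level (default 0.05).
#' @param pairs pair data.frame (optional, for labels).
#' @return An `fnc_result`: list with `pairs`, `group_levels`, `group_means`
#'   (2 x K, raw-correlation scale via tanh of mean z), `group_means_z`,
#'   `within_group_p` (2 x K), `within_group_fdr` (2 x K logical),
#'   `between_group_t`, `between_group_p`, `fdr_mask`, `lag_p` (or NULL),
#'   `q`.
#' @export
group_fnc_stats <- function(z, groups, lag_s = NULL, covariates = NULL,
                            q = 0.05, pairs = NULL) {
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (min(table(groups)) < 2L) stop("each group needs >= 2 subjects")
  k <- ncol(z)
  g1 <- groups == lv[1]; g2 <- groups == lv[2]
  within_p <- matrix(NA_real_, 2, k, dimnames = list(lv, colnames(z)))
  means_z <- within_p
  for (gi in 1:2) {
    sel <- if (gi == 1) g1 else g2
    zz <- z[sel, , drop = FALSE]
    mu <- colMeans(zz); s <- col_sds(zz); n <- sum(sel)
    tv <- mu / (s / sqrt(n))
    within_p[gi, ] <- 2 * stats::pt(-abs(tv), n - 1)
    means_z[gi, ] <- mu
  }
  within_fdr <- t(apply(within_p, 1, fdr_bh, q = q))
  x <- cbind(intercept = 1, group = as.numeric(g2))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(z))
    x <- cbind(x, sweep(covariates, 2, colMeans(covariates)))
  }
  xtx <- crossprod(x)
  if (!is.finite(kappa(xtx, exact = TRUE)) ||
      kappa(xtx, exact = TRUE) > 1e12) {
    stop("rank-deficient design in between-group FNC model")
  }
  xtx_inv <- solve(xtx)
  beta <- xtx_inv %*% crossprod(x, z)
  resid <- z - x %*% beta
  df <- nrow(x) - ncol(x)
  se <- sqrt(colSums(resid^2) / df * xtx_inv["group", "group"])
  bt <- stats::setNames(as.numeric(beta["group", ]) / as.numeric(se),
                        colnames(z))
  bp <- 2 * stats::pt(-abs(bt), df)
  mask <- fdr_bh(bp, q = q)
  lag_p <- NULL
  if (!is.null(lag_s)) {
    lag_p <- vapply(seq_len(k), function(p) {
      stats::t.test(lag_s[g1, p], lag_s[g2, p], var.equal = TRUE)$p.value
    }, numeric(1))
  }
  structure(list(pairs = pairs, group_levels = lv,
                 group_means = tanh(means_z), group_means_z = means_z,
                 within_group_p = within_p, within_group_fdr = within_fdr,
                 between_group_t = bt, between_group_p = bp,
                 fdr_mask = mask, lag_p = lag_p, q = q),
            class = "fnc_result")
}
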