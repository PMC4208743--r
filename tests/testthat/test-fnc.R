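test_that("the band-pass filter has the specified gain profile", {
  tr <- 2.7
  # steady-state gain measured away from the padded edges
  mid <- 65:448
  gain <- function(x, tr_s) {
    y <- bandpass_filter(x, tr_s)
    sd(y[mid]) / sd(x[mid])
  }
  t <- seq(0, by = tr, length.out = 512)
  expect_gt(gain(sin(2 * pi * 0.05 * t), tr), 0.95)  # in-band preserved
  expect_lt(gain(sin(2 * pi * 0.17 * t), tr), 0.10)  # out-of-band cut >=90%
  # at 1 Hz sampling a 0.2 Hz tone sits well beyond the 0.1 Hz edge
  t1 <- seq(0, 511)
  expect_lt(gain(sin(2 * pi * 0.2 * t1), 1), 0.10)
  expect_equal(bandpass_filter(rep(0, 200), tr), rep(0, 200))
  expect_lt(abs(mean(bandpass_filter(rnorm(200), tr))), 0.05)
  expect_error(bandpass_filter(rnorm(20), tr), "too short")
  expect_error(bandpass_filter(rnorm(200), tr, low_hz = 0.1, high_hz = 0.3),
               "Nyquist")
})

test_that("maximal lagged correlation finds self-similarity and planted shifts", {
  tr <- 2.7
  set.seed(50)
  x <- bandpass_filter(rnorm(300), tr)
  self <- max_lagged_correlation(x, x, tr)
  expect_equal(self$r, 1.0, tolerance = 1e-12)
  expect_equal(self$lag_s, 0)

  # a copy delayed by one TR is found near +2.7 s with high correlation
  delayed <- c(x[1], x[-length(x)])
  ml <- max_lagged_correlation(x[10:290], delayed[10:290], tr)
  expect_equal(ml$lag_s, 2.7, tolerance = 0.3)
  expect_gt(ml$r, 0.95)
})

test_that("lag 0 search equals plain Pearson and the discrete oracle", {
  tr <- 2.0
  set.seed(51)
  for (i in 1:5) {
    a <- bandpass_filter(rnorm(200), tr)
    b <- bandpass_filter(rnorm(200), tr)
    ml0 <- max_lagged_correlation(a, b, tr, lag_max_s = 0)
    expect_equal(ml0$r, cor(a, b), tolerance = 1e-10)
    expect_equal(ml0$lag_s, 0)
  }
  # at whole-sample lags the search must agree with a brute-force
  # discrete-lag scan to numerical precision
  a <- bandpass_filter(rnorm(400), tr)
  b <- bandpass_filter(rnorm(400), tr)
  n <- length(a)
  scan <- max_lagged_correlation(a, b, tr, lag_max_s = 2 * tr,
                                 return_scan = TRUE)$scan
  for (k in -2:2) {
    # positive lag: b delayed, so a aligns with later samples of b
    r_oracle <- if (k >= 0) cor(a[1:(n - k)], b[(1 + k):n])
                else cor(a[(1 - k):n], b[1:(n + k)])
    r_mine <- scan$r[abs(scan$lag_s - k * tr) < 1e-9]
    expect_equal(r_mine, r_oracle, tolerance = 1e-10)
  }
})

test_that("Fisher z matches the closed form and its inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  rs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-rs), -fisher_z(rs), tolerance = 1e-12)
  zs <- seq(-4.9, 4.9, by = 0.1)
  expect_equal(fisher_z(tanh(zs)), zs, tolerance = 1e-10)
  expect_error(fisher_z(1), "< 1")
})

test_that("pair bookkeeping matches the closed-form count", {
  expect_equal(nrow(component_pairs(6)), 15)
  expect_equal(nrow(component_pairs(2)), 1)
  p <- component_pairs(4, names = c("a", "b", "c", "d"))
  expect_equal(p$pair[1], "a-b")
  expect_true(all(p$i < p$j))
})

test_that("fnc_matrix produces z and lag tables for all pairs", {
  set.seed(52)
  tcs <- lapply(1:3, function(i) matrix(rnorm(6 * 116), 6, 116))
  f <- fnc_matrix(tcs, tr_s = 2.7)
  expect_equal(dim(f$z), c(3, 15))
  expect_equal(dim(f$lag_s), c(3, 15))
  expect_true(all(abs(f$lag_s) <= 3.0 + 1e-9))
  f2 <- fnc_matrix(lapply(tcs, function(m) m[1:2, ]), tr_s = 2.7)
  expect_equal(ncol(f2$z), 1)
})

test_that("FNC is equivariant under a component sign flip", {
  set.seed(53)
  tcs <- matrix(rnorm(3 * 116), 3, 116)
  f <- fnc_matrix(list(tcs), tr_s = 2.7)
  flipped <- tcs; flipped[2, ] <- -flipped[2, ]
  ff <- fnc_matrix(list(flipped), tr_s = 2.7)
  involves2 <- f$pairs$i == 2 | f$pairs$j == 2
  expect_equal(ff$z[1, involves2], -f$z[1, involves2], tolerance = 1e-10)
  expect_equal(ff$z[1, !involves2], f$z[1, !involves2], tolerance = 1e-10)
  expect_equal(abs(ff$z), abs(f$z), tolerance = 1e-10)
})

test_that("Benjamini-Hochberg matches hand calculation and oracle", {
  expect_equal(fdr_bh(c(0.001, 0.2, 0.9), q = 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_equal(fdr_bh(numeric(0)), logical(0))

  bh_oracle <- function(p, q) {
    k <- length(p)
    ord <- order(p)
    ps <- p[ord]
    # exhaustive definition: largest i with p_(i) <= i q / k
    i_star <- 0
    for (i in seq_len(k)) if (ps[i] <= i * q / k) i_star <- i
    rej <- logical(k)
    if (i_star > 0) rej[ord[1:i_star]] <- TRUE
    rej
  }
  set.seed(54)
  for (i in 1:1000) {
    k <- sample(1:25, 1)
    p <- runif(k)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, q), bh_oracle(p, q))
  }
  # agreement with the standard adjusted-p implementation
  set.seed(55)
  for (i in 1:50) {
    p <- runif(15)
    expect_identical(fdr_bh(p, 0.05),
                     unname(p.adjust(p, method = "BH") <= 0.05))
  }
  # monotone in q
  p <- runif(20)
  r1 <- fdr_bh(p, 0.01); r2 <- fdr_bh(p, 0.10)
  expect_true(all(r2[r1]))
})

test_that("group FNC statistics detect planted differences and stay null otherwise", {
  set.seed(56)
  n <- 40; k <- 15
  z0 <- matrix(rnorm(n * k, sd = 0.15), n, k)
  groups <- rep(c("HC", "BD"), each = n / 2)
  st0 <- group_fnc_stats(z0, groups, q = 0.05)
  expect_equal(sum(st0$fdr_mask), 0)

  z1 <- z0
  z1[groups == "BD", 7] <- z1[groups == "BD", 7] + 0.4
  st1 <- group_fnc_stats(z1, groups, q = 0.05)
  expect_true(st1$fdr_mask[7])

  # K = 1 reduces BH to comparing the raw p with q
  z_k1 <- z1[, 7, drop = FALSE]
  st_k1 <- group_fnc_stats(z_k1, groups, q = 0.05)
  expect_equal(st_k1$fdr_mask, st_k1$between_group_p <= 0.05)

  # no covariates equals the classic pooled two-sample t
  tt <- t.test(z1[groups == "BD", 7], z1[groups == "HC", 7],
               var.equal = TRUE)
  expect_equal(abs(st1$between_group_t[7]), abs(unname(tt$statistic)),
               tolerance = 1e-10)

  # lag comparison runs when lags are supplied
  lags <- matrix(sample(seq(-2.7, 2.7, by = 0.27), n * k, TRUE), n, k)
  st2 <- group_fnc_stats(z1, groups, lag_s = lags, q = 0.05)
  expect_equal(length(st2$lag_p), k)
  expect_error(group_fnc_stats(z1, rep("HC", n)), "two groups")
})
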