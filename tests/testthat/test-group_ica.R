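# Sparse, independent source fixtures for ICA checks.
make_sparse_sources <- function(n_src, v, seed = 1) {
  set.seed(seed)
  s <- matrix(0, n_src, v)
  width <- floor(v / n_src)
  for (k in seq_len(n_src)) {
    idx <- ((k - 1) * width + 1):(k * width)
    s[k, idx] <- rnorm(length(idx))^3  # heavy-tailed, super-Gaussian
  }
  s
}

test_that("subject PCA retains the requested variance structure", {
  spec <- small_spec()
  coh <- small_cohort()
  scan <- coh$scans[[1]]

  # rank-2 noiseless data: 2 components explain everything
  v <- 200; t_n <- 30
  set.seed(2)
  low <- matrix(rnorm(v * 2), v, 2) %*% matrix(rnorm(2 * t_n), 2, t_n)
  fake <- subject_scan("r2", low - rowMeans(low) + rowMeans(low),
                       scan$geometry, seq_len(v), 2.7)
  red <- subject_pca_reduce(fake, 2)
  expect_equal(red$explained, 1, tolerance = 1e-10)

  # k1 = T reconstructs exactly
  set.seed(3)
  wn <- subject_scan("wn", matrix(rnorm(v * 12), v, 12), scan$geometry,
                     seq_len(v), 2.7)
  full <- subject_pca_reduce(wn, 12)
  recon <- full$reduced %*% t(full$basis)
  expect_equal(recon, wn$data - rowMeans(wn$data), tolerance = 1e-8)

  expect_error(subject_pca_reduce(wn, 13), "exceeds")

  # planted-source subject: the leading components carry far more variance
  # than the white-noise share (6 of 116 time points ~ 5%)
  red6 <- subject_pca_reduce(scan, 6)
  expect_gt(red6$explained, 2 * 6 / ncol(scan$data))
  expect_true(all(diff(red6$eigenvalues) <= 1e-8))
})

test_that("group PCA output is whitened", {
  coh <- small_cohort()
  red <- lapply(coh$scans[1:4], subject_pca_reduce, k1 = 12)
  gp <- suppressWarnings(group_pca_reduce(lapply(red, `[[`, "reduced"), 8))
  covm <- tcrossprod(gp$whitened) / (ncol(gp$whitened) - 1)
  expect_equal(covm, diag(8), tolerance = 1e-8)
  expect_error(group_pca_reduce(lapply(red, `[[`, "reduced"), 100),
               "exceeds")
  # underfitting warns
  expect_warning(group_pca_reduce(list(matrix(rnorm(2000), 1000, 2)), 1),
                 "underfit")
})

test_that("Infomax recovers sparse sources from a whitened mixture", {
  s <- make_sparse_sources(3, 3000, seed = 4)
  set.seed(5)
  a <- matrix(rnorm(9), 3, 3)
  x <- a %*% s
  # whiten
  x <- x - rowMeans(x)
  eg <- eigen(tcrossprod(x) / (ncol(x) - 1), symmetric = TRUE)
  wh <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% x
  set.seed(6)
  fit <- infomax_ica(wh)
  r <- abs(cor(t(fit$S), t(s)))
  matched <- apply(r, 2, max)
  expect_true(all(matched > 0.95))
  # one-to-one matching
  expect_equal(sort(apply(r, 2, which.max)), 1:3)
  # unit variance and sign convention
  expect_equal(unname(apply(fit$S, 1, sd)), rep(1, 3), tolerance = 1e-8)
  for (k in 1:3) {
    expect_gt(fit$S[k, which.max(abs(fit$S[k, ]))], 0)
  }
})

test_that("Infomax started at the truth stays near a signed permutation", {
  s <- make_sparse_sources(3, 3000, seed = 7)
  s <- standardize_rows_for_test(s)
  set.seed(8)
  fit <- infomax_ica(s, w_init = diag(3), max_steps = 60)
  r <- abs(cor(t(fit$S), t(s)))
  expect_true(all(apply(r, 2, max) > 0.98))
})

test_that("Icasso quality index is exact on constructed pools", {
  # 3 clusters of 4 identical estimates each, mutually orthogonal
  base <- diag(3)
  pool <- base[rep(1:3, each = 4), ]
  pool <- pool + 0  # 12 x 3
  # extend to non-trivial length with orthogonal supports
  long <- matrix(0, 12, 30)
  set.seed(9)
  for (i in 1:12) {
    v <- rnorm(10)
    # zero-mean support blocks make disjoint rows exactly uncorrelated
    long[i, (((i - 1) %/% 4) * 10 + 1):((((i - 1) %/% 4) + 1) * 10)] <-
      v - mean(v)
  }
  # make members of a cluster identical
  for (g in 0:2) for (m in 2:4) long[g * 4 + m, ] <- long[g * 4 + 1, ]
  sim <- abs(cor(t(long)))
  sim[is.na(sim)] <- 0
  membership <- rep(1:3, each = 4)
  qual <- icasso_iq(sim, membership)
  expect_equal(qual$iq, rep(1, 3), tolerance = 1e-12)
  # permutation and sign-flip invariance of the index
  perm <- sample(12)
  qual_p <- icasso_iq(sim[perm, perm], membership[perm])
  expect_equal(sort(qual_p$iq), sort(qual$iq), tolerance = 1e-12)
  flipped <- long * rep(sample(c(-1, 1), 12, replace = TRUE), times = 30)
  sim_f <- abs(cor(t(flipped)))
  expect_equal(icasso_iq(sim_f, membership)$iq, qual$iq, tolerance = 1e-12)
})

test_that("Icasso on the planted cohort is stable and reproducible", {
  coh <- small_cohort()
  ica <- small_ica()
  m <- match_components(ica$components$maps, coh$truth$source_maps)
  expect_true(all(ica$components$iq[m$idx] > 0.8))
  expect_true(all(m$r > 0.9))
  expect_error(icasso(matrix(rnorm(40), 2, 20), 2, n_runs = 1), "at least 2")
  # determinism: same seed, same components
  red <- lapply(coh$scans, subject_pca_reduce, k1 = 12)
  gp <- suppressWarnings(group_pca_reduce(lapply(red, `[[`, "reduced"), 8))
  c1 <- icasso(gp$whitened, 8, n_runs = 4, seed = 99)
  c2 <- icasso(gp$whitened, 8, n_runs = 4, seed = 99)
  expect_identical(c1$maps, c2$maps)
  expect_identical(c1$iq, c2$iq)
})

test_that("dual regression recovers subject structure and is scale invariant", {
  coh <- small_cohort()
  ica <- small_ica()
  m <- match_components(ica$components$maps, coh$truth$source_maps)

  # noiseless analytic case: data built exactly from group maps
  maps <- ica$components$maps
  set.seed(12)
  tcs_true <- matrix(rnorm(nrow(maps) * 50), nrow(maps), 50)
  noiseless <- subject_scan("clean", crossprod(maps, tcs_true),
                            coh$scans[[1]]$geometry, coh$mask_index, 2.7)
  br <- back_reconstruct(ica$components, list(noiseless))[[1]]
  for (k in seq_len(nrow(maps))) {
    expect_gt(abs(cor(br$tcs[k, ], tcs_true[k, ])), 0.99)
  }

  # scaling a subject's data leaves z-scaled maps unchanged
  scaled <- subject_scan("x10", noiseless$data * 10,
                         coh$scans[[1]]$geometry, coh$mask_index, 2.7)
  br10 <- back_reconstruct(ica$components, list(scaled))[[1]]
  expect_equal(br10$maps, br$maps, tolerance = 1e-8)
  # z-scaling contract
  expect_equal(unname(rowMeans(br$maps)), rep(0, nrow(maps)),
               tolerance = 1e-10)
  expect_equal(unname(apply(br$maps, 1, sd)), rep(1, nrow(maps)),
               tolerance = 1e-10)

  # a pure-noise subject yields approximately standard normal map values
  set.seed(13)
  noise <- subject_scan("noise",
                        matrix(rnorm(length(coh$mask_index) * 60),
                               ncol = 60),
                        coh$scans[[1]]$geometry, coh$mask_index, 2.7)
  brn <- back_reconstruct(ica$components, list(noise))[[1]]
  ks <- ks.test(brn$maps[1, ], "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("end-to-end recovery meets the stability contract", {
  coh <- small_cohort()
  ica <- small_ica()
  m <- match_components(ica$components$maps, coh$truth$source_maps)
  expect_gte(mean(m$r), 0.9)
  tr <- vapply(seq_along(ica$subjects), function(i) {
    mean(vapply(1:6, function(k) {
      abs(cor(ica$subjects[[i]]$tcs[m$idx[k], ],
              coh$truth$subject_tcs[[i]][k, ]))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(tr), 0.8)
})
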