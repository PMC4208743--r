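test_that("spatial sources are sparse and well separated", {
  spec <- small_spec()
  maps <- make_spatial_sources(spec)
  cc <- cor(t(maps))
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.2)
  # peak 1, background exactly 0
  expect_equal(unname(apply(maps, 1, max)), rep(1, 6))
  expect_true(all(rowMeans(maps == 0) > 0.5))
})

test_that("two far-apart sources are nearly uncorrelated; degenerate inputs error", {
  spec <- synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 2,
                         source_centers = list(c(5, 6, 5), c(16, 18, 16)))
  maps <- make_spatial_sources(spec)
  expect_lt(abs(cor(maps[1, ], maps[2, ])), 0.05)

  # FWHM -> 0 gives one-voxel indicators
  spec0 <- synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 2,
                          source_fwhm_mm = 0,
                          source_centers = list(c(5, 6, 5), c(16, 18, 16)))
  maps0 <- make_spatial_sources(spec0)
  expect_equal(unname(rowSums(maps0 != 0)), c(1, 1))

  expect_error(make_spatial_sources(
    synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 2,
                   source_centers = list(c(5, 6, 5), c(5, 6, 5)))),
    "distinct")
  expect_error(make_spatial_sources(
    synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 2, source_fwhm_mm = 60,
                   source_centers = list(c(9, 12, 10), c(12, 12, 10)))),
    "overlap")
})

test_that("time courses realize the target correlation structure", {
  # long series: Monte-Carlo check against identity and a strong correlation
  spec_id <- synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 3,
                            t_volumes = 10000L, n_discard = 0L,
                            corr_hc = diag(3), corr_bd = diag(3),
                            source_centers = list(c(5, 6, 5), c(16, 18, 16),
                                                  c(5, 18, 16)))
  set.seed(1)
  x <- make_time_courses(spec_id, "HC")
  cc <- cor(t(x)); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.05)

  target <- diag(3); target[1, 2] <- target[2, 1] <- 0.9
  spec_c <- synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 3,
                           t_volumes = 10000L, n_discard = 0L,
                           corr_hc = target, corr_bd = target,
                           source_centers = list(c(5, 6, 5), c(16, 18, 16),
                                                 c(5, 18, 16)))
  set.seed(2)
  y <- make_time_courses(spec_c, "HC")
  expect_equal(cor(y[1, ], y[2, ]), 0.9, tolerance = 0.05)

  bad <- matrix(0.99, 3, 3); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 3,
                              corr_hc = bad, corr_bd = diag(3),
                              source_centers = list(c(5, 6, 5),
                                                    c(16, 18, 16),
                                                    c(5, 18, 16))),
               "positive semi-definite")
})

test_that("planted lags shift the cross-correlation peak", {
  lag <- matrix(0, 2, 2); lag[1, 2] <- 2.7; lag[2, 1] <- -2.7
  spec <- synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 2,
                         t_volumes = 2000L, n_discard = 0L,
                         corr_hc = diag(2) * 0 + diag(2), corr_bd = diag(2),
                         lag_s = lag,
                         source_centers = list(c(5, 6, 5), c(16, 18, 16)))
  # row 2 is a delayed copy: plant corr 1 so the pair shares one base signal
  spec$corr_hc[1, 2] <- spec$corr_hc[2, 1] <- 1
  set.seed(3)
  x <- make_time_courses(spec, "HC")
  cc <- ccf(x[2, ], x[1, ], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 1)  # +1 sample = 2.7 s = TR
})

test_that("subject assembly follows the linear mixing model", {
  spec <- synthetic_spec(n_hc = 2, n_bd = 2, n_sources = 2, noise_sd = 0,
                         source_centers = list(c(5, 6, 5), c(16, 18, 16)))
  mask_index <- which(make_analysis_mask(spec))
  maps <- make_spatial_sources(spec, mask_index)
  set.seed(4)
  tcs <- make_time_courses(spec, "HC")
  dat <- assemble_subject(maps, tcs, spec, mask_index)
  # noiseless: every in-blob voxel series is proportional to its source tc
  blob1 <- which(maps[1, ] > 0.3 & maps[2, ] == 0)
  rs <- abs(cor(t(dat[blob1, , drop = FALSE]), tcs[1, ]))
  expect_true(all(rs > 0.999))
  # voxels of blob 2 follow tc_2, not tc_1
  blob2 <- which(maps[2, ] > 0.3 & maps[1, ] == 0)
  r2 <- abs(cor(t(dat[blob2, , drop = FALSE]), tcs[2, ]))
  r12 <- abs(cor(t(dat[blob2, , drop = FALSE]), tcs[1, ]))
  expect_true(all(r2 > 0.999))
  expect_true(all(r12 < 0.2))
  # with heavy noise the voxel-tc correlations collapse
  spec$noise_sd <- 50
  set.seed(5)
  noisy <- assemble_subject(maps, tcs, spec, mask_index)
  rn <- abs(cor(t(noisy[blob1, , drop = FALSE]), tcs[1, ]))
  expect_lt(mean(rn), 0.2)
})

test_that("cohorts are reproducible and carry the requested structure", {
  spec <- small_spec(n_qc_fail = 2L)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_cohort(spec, d1)
  c2 <- generate_cohort(spec, d2)
  expect_identical(readBin(file.path(d1, "truth.json"), "raw", 1e6),
                   readBin(file.path(d2, "truth.json"), "raw", 1e6))
  expect_identical(c1$clinical, c2$clinical)
  # QC-failing subjects are exactly the planted ones
  qc <- cohort_qc(c1$traces, c1$clinical$group)
  expect_setequal(qc$summary$subject_id[qc$summary$excluded],
                  c1$truth$qc_fail_ids)
  expect_equal(sum(qc$summary$excluded), 2L)
})

test_that("the full-size cohort matches the study design", {
  spec <- synthetic_spec()  # defaults
  expect_equal(spec$n_hc, 35L)
  expect_equal(spec$n_bd, 30L)
  expect_equal(spec$tr_s, 2.7)
  expect_equal(spec$t_volumes, 120L)
  expect_equal(spec$corr_hc[4, 6], -0.078)
  expect_equal(spec$corr_bd[4, 6], 0.122)
  expect_error(synthetic_spec(n_hc = 2, n_bd = 2, n_qc_fail = 4),
               "n_qc_fail")
})

test_that("subject-level planted correlations are exact after discard", {
  coh <- small_cohort()
  for (id in names(coh$truth$subject_tcs)[c(1, 7)]) {
    tc <- coh$truth$subject_tcs[[id]]
    target <- coh$truth$planted_corrs[[
      coh$truth$group_labels[[id]]]]
    expect_equal(cor(t(tc)), unname(target), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # group means of the designated pair differ in the planted direction
  g <- coh$truth$group_labels
  r46 <- vapply(coh$truth$subject_tcs,
                function(tc) cor(tc[4, ], tc[6, ]), numeric(1))
  expect_lt(mean(r46[g == "HC"]), mean(r46[g == "BD"]))
})
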