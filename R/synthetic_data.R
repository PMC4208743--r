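#' Specification of a synthetic resting-state cohort
#'
#' Defines the study conditions the generator emulates: a two-group cohort
#' (healthy controls and bipolar-disorder patients), 120 volumes at TR 2.7 s
#' of which the first 4 are discarded, six spatially sparse networks with
#' band-limited (0.01-0.1 Hz) time courses, a group-specific inter-network
#' correlation structure with a planted difference on the MPN-rFPN pair
#' (-0.078 in controls, +0.122 in patients), optional inter-network lags,
#' additive Gaussian noise, and realignment traces including QC-failing
#' subjects.
#'
#' @param n_hc,n_bd subjects per group (defaults 35 controls, 30 patients).
#' @param shape volume grid (voxels per axis).
#' @param voxel_mm isotropic voxel size (mm).
#' @param t_volumes acquired volumes (the first `n_discard` are dropped at
#'   load time).
#' @param n_discard leading dummy volumes.
#' @param tr_s repetition time (s).
#' @param n_sources number of planted networks.
#' @param source_centers list of voxel-coordinate triplets (1-based); defaults
#'   place six well-separated blobs in the gray-matter shell.
#' @param source_fwhm_mm blob full width at half maximum (mm).
#' @param band_hz passband (low, high) in Hz for source time courses.
#' @param corr_hc,corr_bd group inter-network correlation matrices (symmetric,
#'   unit diagonal, positive semi-definite).
#' @param lag_s antisymmetric matrix of planted pairwise lags in seconds
#'   (`lag_s[i, j] > 0` means source j lags source i).
#' @param amplitude signal amplitude at blob peak (time-course SD units).
#' @param noise_sd SD of additive voxelwise Gaussian noise.
#' @param smooth_fwhm_mm optional spatial smoothing of assembled volumes
#'   (0 = off).
#' @param subject_map_jitter SD (voxels) of per-subject blob-center jitter.
#' @param motion_rw_sd per-volume SD of the motion random walk (mm / deg).
#' @param n_qc_fail subjects given a motion step exceeding exclusion limits.
#' @param seed master seed; all generator randomness derives from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_hc = 35L, n_bd = 30L,
                           shape = c(20L, 24L, 20L), voxel_mm = 3,
                           t_volumes = 120L, n_discard = 4L, tr_s = 2.7,
                           n_sources = 6L,
                           source_centers = NULL, source_fwhm_mm = 9,
                           band_hz = c(0.01, 0.10),
                           corr_hc = NULL, corr_bd = NULL,
                           lag_s = NULL,
                           amplitude = 1, noise_sd = 0.5,
                           smooth_fwhm_mm = 0,
                           subject_map_jitter = 0,
                           motion_rw_sd = 0.02, n_qc_fail = 0L,
                           seed = 1L) {
  shape <- as.integer(shape)
  n_sources <- as.integer(n_sources)
  stopifnot(n_hc >= 1L, n_bd >= 1L, all(shape >= 4L), t_volumes > n_discard,
            tr_s > 0, n_sources >= 1L)
  nyq <- 1 / (2 * tr_s)
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2] && band_hz[2] < nyq)) {
    stop("band_hz must satisfy 0 < low < high < Nyquist (", round(nyq, 4),
         " Hz)")
  }
  if (is.null(source_centers)) {
    source_centers <- default_source_centers(shape)[seq_len(n_sources)]
  }
  stopifnot(length(source_centers) == n_sources)
  for (ctr in source_centers) {
    if (any(ctr < 1) || any(ctr > shape)) stop("source center outside volume")
  }
  if (is.null(corr_hc)) {
    corr_hc <- diag(n_sources)
    if (n_sources >= 6L) corr_hc[4, 6] <- corr_hc[6, 4] <- -0.078
  }
  if (is.null(corr_bd)) {
    corr_bd <- diag(n_sources)
    if (n_sources >= 6L) corr_bd[4, 6] <- corr_bd[6, 4] <- 0.122
  }
  check_corr <- function(m, lab) {
    stopifnot(all(dim(m) == c(n_sources, n_sources)))
    if (max(abs(m - t(m))) > 1e-12) stop(lab, " not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-12) stop(lab, " diagonal not 1")
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) stop(lab, " not positive semi-definite (smallest ",
                          "eigenvalue ", signif(ev, 4), ")")
  }
  check_corr(corr_hc, "corr_hc"); check_corr(corr_bd, "corr_bd")
  if (is.null(lag_s)) lag_s <- matrix(0, n_sources, n_sources)
  if (max(abs(lag_s + t(lag_s))) > 1e-12) stop("lag_s must be antisymmetric")
  n_qc_fail <- as.integer(n_qc_fail)
  if (n_qc_fail >= n_hc + n_bd) stop("n_qc_fail must be < total subjects")
  structure(list(n_hc = as.integer(n_hc), n_bd = as.integer(n_bd),
                 shape = shape, voxel_mm = voxel_mm,
                 t_volumes = as.integer(t_volumes),
                 n_discard = as.integer(n_discard), tr_s = tr_s,
                 n_sources = as.integer(n_sources),
                 source_centers = source_centers,
                 source_fwhm_mm = source_fwhm_mm, band_hz = band_hz,
                 corr_hc = corr_hc, corr_bd = corr_bd, lag_s = lag_s,
                 amplitude = amplitude, noise_sd = noise_sd,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 subject_map_jitter = subject_map_jitter,
                 motion_rw_sd = motion_rw_sd, n_qc_fail = n_qc_fail,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Canonical network names for the six planted sources.
rsn_names <- function(n) {
  base <- c("aDMN", "pDMN", "lFPN", "rFPN", "SN", "MPN")
  if (n <= 6L) base[seq_len(n)] else c(base, paste0("SRC", 7:n))[seq_len(n)]
}

# Six well-separated centers in the gray-matter shell of an ellipsoidal mask.
default_source_centers <- function(shape) {
  c0 <- (shape + 1) / 2
  r <- shape / 2 - 0.5
  offs <- list(c(-0.55, 0, 0), c(0.55, 0, 0), c(0, -0.62, 0),
               c(0, 0.62, 0), c(0, 0, -0.62), c(0, 0, 0.62))
  lapply(offs, function(o) round(c0 + o * r))
}

#' Ellipsoidal analysis mask for a synthetic volume
#'
#' @param spec a `synthetic_spec`.
#' @return logical 3D array (TRUE = in mask).
#' @export
make_analysis_mask <- function(spec) {
  rho <- normalized_radius(spec$shape)
  rho <= 1
}

# Normalized elliptical radius (0 at center, 1 at mask edge) per voxel.
normalized_radius <- function(shape) {
  c0 <- (shape + 1) / 2
  r <- shape / 2 - 0.5
  gx <- ((seq_len(shape[1]) - c0[1]) / r[1])^2
  gy <- ((seq_len(shape[2]) - c0[2]) / r[2])^2
  gz <- ((seq_len(shape[3]) - c0[3]) / r[3])^2
  sqrt(outer(outer(gx, gy, "+"), gz, "+"))
}

#' Planted spatial source maps
#'
#' Each source is a truncated Gaussian blob (peak 1, background exactly 0) at
#' its center, emulating the sparse, super-Gaussian spatial histograms of
#' resting-state network maps — the regime in which Infomax ICA is
#' identifiable.
#'
#' @param spec a `synthetic_spec`.
#' @param mask_index in-mask linear indices (default: from
#'   [make_analysis_mask()]).
#' @param centers optional list of centers overriding `spec$source_centers`
#'   (used for per-subject jitter).
#' @return n_sources x voxels matrix over the mask.
#' @export
make_spatial_sources <- function(spec, mask_index = NULL, centers = NULL) {
  if (is.null(centers)) centers <- spec$source_centers
  keys <- vapply(centers, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) stop("source centers must be distinct")
  if (is.null(mask_index)) mask_index <- which(make_analysis_mask(spec))
  shape <- spec$shape
  coords <- arrayInd(mask_index, shape)
  sigma_vox <- spec$source_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$voxel_mm
  maps <- matrix(0, length(centers), length(mask_index))
  for (k in seq_along(centers)) {
    d2 <- rowSums((coords - matrix(centers[[k]], nrow(coords), 3,
                                   byrow = TRUE))^2)
    if (sigma_vox <= 1e-8) {
      maps[k, which.min(d2)] <- 1
    } else {
      v <- exp(-d2 / (2 * sigma_vox^2))
      v[v < 0.01] <- 0  # hard truncation keeps the background exactly sparse
      maps[k, ] <- v
    }
  }
  if (nrow(maps) > 1L) {
    cc <- suppressWarnings(stats::cor(t(maps)))
    diag(cc) <- 0
    if (any(is.finite(cc) & abs(cc) > 0.5)) {
      stop("source maps overlap too much (|spatial r| > 0.5); ",
           "increase center separation or reduce FWHM")
    }
  }
  rownames(maps) <- rsn_names(length(centers))
  maps
}

#' Band-limited, correlation-shaped source time courses
#'
#' Draws i.i.d. Gaussian series, band-passes them to the BOLD band, imposes
#' the group's target correlation matrix exactly (empirical whitening followed
#' by the Cholesky factor of the target), applies any planted lags by
#' sub-sample spline shifts of the designated rows, and standardizes rows to
#' mean 0, SD 1. Uses the session RNG (seed it, or call through
#' [generate_cohort()]).
#'
#' @param spec a `synthetic_spec`.
#' @param group `"HC"` or `"BD"` — selects the target correlation matrix.
#' @return n_sources x t_volumes matrix.
#' @export
make_time_courses <- function(spec, group = c("HC", "BD")) {
  group <- match.arg(group)
  target <- if (group == "HC") spec$corr_hc else spec$corr_bd
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("correlation matrix not PSD (smallest eigenvalue ",
         signif(min(ev), 4), ")")
  }
  n <- spec$n_sources; t_n <- spec$t_volumes
  x <- matrix(stats::rnorm(n * t_n), n, t_n)
  x <- bandpass_filter(x, spec$tr_s, spec$band_hz[1], spec$band_hz[2])
  # correlation shaping targets the retained segment (post-discard), the part
  # every downstream stage sees
  keep <- (spec$n_discard + 1L):t_n
  mu <- rowMeans(x[, keep, drop = FALSE])
  sd_k <- sqrt(rowSums((x[, keep, drop = FALSE] - mu)^2) /
                 (length(keep) - 1))
  x <- (x - mu) / sd_k
  if (n > 1L) {
    # exact sample-correlation shaping: whiten empirically, then color
    emp <- stats::cor(t(x[, keep, drop = FALSE]))
    x <- backsolve(chol(emp), x, transpose = TRUE)
    reg <- target + diag(1e-12, n)  # tolerate planted singular targets
    x <- t(chol(reg)) %*% x
  }
  x <- apply_planted_lags(x, spec)
  mu <- rowMeans(x[, keep, drop = FALSE])
  sd_k <- sqrt(rowSums((x[, keep, drop = FALSE] - mu)^2) /
                 (length(keep) - 1))
  (x - mu) / sd_k
}

# Shift designated rows by their planted lag (sub-sample spline shift).
apply_planted_lags <- function(x, spec) {
  lag <- spec$lag_s
  if (all(lag == 0)) return(x)
  t_n <- ncol(x)
  tt <- (seq_len(t_n) - 1) * spec$tr_s
  shifted <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(x) - 1L)) {
    for (j in (i + 1L):nrow(x)) {
      if (lag[i, j] != 0) {
        if (shifted[j]) {
          warning("row ", j, " already shifted; planted lags on multiple ",
                  "pairs sharing a source are only approximately honored")
        }
        f <- stats::splinefun(tt, x[j, ], method = "natural")
        x[j, ] <- f(pmin(pmax(tt - lag[i, j], 0), max(tt)))
        shifted[j] <- TRUE
      }
    }
  }
  x
}

#' Assemble one subject's 4D data from maps and time courses
#'
#' Linear mixing model: voxel series = amplitude * maps' tcs + N(0, noise_sd),
#' optionally followed by 3D Gaussian smoothing of each volume (emulating the
#' spatial smoothing step of standard preprocessing). Uses the session RNG.
#'
#' @param source_maps n_sources x voxels matrix (on the mask).
#' @param tcs n_sources x t_volumes time courses.
#' @param spec a `synthetic_spec`.
#' @param mask_index in-mask linear indices.
#' @return voxels x t_volumes data matrix.
#' @export
assemble_subject <- function(source_maps, tcs, spec, mask_index) {
  stopifnot(nrow(source_maps) == nrow(tcs),
            ncol(source_maps) == length(mask_index))
  dat <- spec$amplitude * crossprod(source_maps, tcs)
  if (spec$noise_sd > 0) {
    dat <- dat + matrix(stats::rnorm(length(dat), sd = spec$noise_sd),
                        nrow(dat), ncol(dat))
  }
  if (spec$smooth_fwhm_mm > 0) {
    dat <- smooth_masked(dat, mask_index, spec$shape,
                         spec$smooth_fwhm_mm / spec$voxel_mm)
  }
  dat
}

# Separable 3D Gaussian smoothing of masked data (FWHM in voxels).
smooth_masked <- function(dat, mask_index, shape, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  full <- array(0, c(shape, ncol(dat)))
  flat <- matrix(0, prod(shape), ncol(dat))
  flat[mask_index, ] <- dat
  full[] <- flat
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (o in seq_along(kern)) {
      sh <- o - half - 1L
      idx_src <- pmin(pmax(seq_len(dim(a)[axis]) + sh, 1L), dim(a)[axis])
      out <- out + kern[o] * switch(axis,
        a[idx_src, , , , drop = FALSE],
        a[, idx_src, , , drop = FALSE],
        a[, , idx_src, , drop = FALSE])
    }
    out
  }
  for (ax in 1:3) full <- conv_axis(full, ax)
  dim(full) <- c(prod(shape), ncol(dat))
  full[mask_index, , drop = FALSE]
}

# Random-walk realignment trace; optionally inject a QC-failing step.
make_motion_trace <- function(spec, subject_id, qc_fail = FALSE) {
  t_n <- spec$t_volumes
  steps <- matrix(stats::rnorm(t_n * 6, sd = spec$motion_rw_sd), t_n, 6)
  steps[1, ] <- 0
  params <- apply(steps, 2, cumsum)
  if (qc_fail) {
    jump_at <- sample(2:t_n, 1)
    params[jump_at:t_n, 1] <- params[jump_at:t_n, 1] + 3.5
  }
  colnames(params) <- c("tx_mm", "ty_mm", "tz_mm",
                        "rx_deg", "ry_deg", "rz_deg")
  structure(list(subject_id = subject_id, params = params),
            class = "motion_trace")
}

# Clinical table row for one subject; BD rows get illness-course variables
# and medication records sampled from the drugs observed in euthymic BD-I
# cohorts.
make_clinical_row <- function(subject_id, group, psychosis = FALSE) {
  age <- round(stats::rnorm(1, 41, 9))
  age <- min(max(age, 18), 65)
  gender <- sample(c("F", "M"), 1)
  if (group == "HC") {
    return(data.frame(subject_id = subject_id, group = group, age = age,
                      gender = gender, ymrs = 0L,
                      bdi = stats::rpois(1, 1), hamd = stats::rpois(1, 0.2),
                      n_depressive = 0L, n_manic = 0L, onset_age = NA,
                      remission_years = NA, psychosis_history = 0L,
                      medication = "none", stringsAsFactors = FALSE))
  }
  onset <- min(max(round(stats::rnorm(1, 25, 6)), 15), age - 1)
  ms <- c("lithium", "valproate", "lamotrigine", "carbamazepine")
  ad <- c("venlafaxine", "citalopram", "sertraline", "duloxetine",
          "clomipramine", "mirtazapine", "opipramol")
  ap <- c("quetiapine", "perazine", "risperidone", "olanzapine",
          "aripiprazole")
  meds <- character(0)
  if (stats::runif(1) < 25 / 30) {
    meds <- c(meds, paste0(sample(ms, 1), ":", sample(1:4, 1)))
  }
  if (stats::runif(1) < 11 / 30) {
    meds <- c(meds, paste0(sample(ad, 1), ":", sample(1:4, 1)))
  }
  if (stats::runif(1) < 11 / 30) {
    meds <- c(meds, paste0(sample(ap, 1), ":cpz", sample(1:2, 1)))
  }
  data.frame(subject_id = subject_id, group = group, age = age,
             gender = gender, ymrs = stats::rpois(1, 1),
             bdi = stats::rpois(1, 4), hamd = stats::rpois(1, 1),
             n_depressive = stats::rpois(1, 4) + 1L,
             n_manic = stats::rpois(1, 2) + 1L,
             onset_age = onset,
             remission_years = round(stats::runif(1, 0.5, 10), 1),
             psychosis_history = as.integer(psychosis),
             medication = if (length(meds)) paste(meds, collapse = ";")
                          else "none",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-subject cohort
#'
#' Produces, for every subject, a 4D scan (linear mixture of the planted
#' sources plus noise), a realignment trace, and a clinical-table row; plus
#' the ground truth needed to validate downstream stages. Fully reproducible
#' from `spec$seed`. When `dir` is given, scans are written as NIfTI, traces
#' as SPM-style `rp_<id>.txt`, the clinical table as CSV, truth maps as a 4D
#' NIfTI, and a JSON manifest.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory (`NULL` = in-memory only).
#' @return list with `scans` (list of `subject_scan`, dummy volumes already
#'   discarded), `traces` (list of `motion_trace`), `clinical` (data.frame),
#'   `mask` (logical array), `mask_index`, `templates` (see
#'   [make_template_library()]), and `truth` (source maps, per-subject time
#'   courses after discard, group labels, planted correlations and lags,
#'   `qc_fail_ids`).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  with_seed(spec$seed, {
    mask <- make_analysis_mask(spec)
    mask_index <- which(mask)
    source_maps <- make_spatial_sources(spec, mask_index)
    templates <- make_template_library(spec, mask_index, source_maps)
    n_tot <- spec$n_hc + spec$n_bd
    groups <- c(rep("HC", spec$n_hc), rep("BD", spec$n_bd))
    ids <- sprintf("sub%03d", seq_len(n_tot))
    qc_fail_ids <- if (spec$n_qc_fail > 0) {
      sample(ids, spec$n_qc_fail)
    } else character(0)
    n_psy <- round(spec$n_bd * 13 / 30)
    psy_flags <- sample(rep(c(TRUE, FALSE),
                            c(n_psy, spec$n_bd - n_psy)))
    keep <- (spec$n_discard + 1L):spec$t_volumes
    geom <- volume_geometry(spec$shape, rep(spec$voxel_mm, 3))
    scans <- vector("list", n_tot); names(scans) <- ids
    traces <- vector("list", n_tot); names(traces) <- ids
    truth_tcs <- vector("list", n_tot); names(truth_tcs) <- ids
    clin <- vector("list", n_tot)
    bd_i <- 0L
    for (i in seq_len(n_tot)) {
      id <- ids[i]
      subj_maps <- source_maps
      if (spec$subject_map_jitter > 0) {
        centers <- lapply(spec$source_centers, function(ctr) {
          pmin(pmax(round(ctr + stats::rnorm(3,
            sd = spec$subject_map_jitter)), 1), spec$shape)
        })
        subj_maps <- make_spatial_sources(spec, mask_index, centers)
      }
      tcs <- make_time_courses(spec, groups[i])
      dat <- assemble_subject(subj_maps, tcs, spec, mask_index)
      scans[[i]] <- subject_scan(id, dat[, keep, drop = FALSE], geom,
                                 mask_index, spec$tr_s, spec$n_discard)
      truth_tcs[[i]] <- tcs[, keep, drop = FALSE]
      traces[[i]] <- make_motion_trace(spec, id, id %in% qc_fail_ids)
      if (groups[i] == "BD") bd_i <- bd_i + 1L
      clin[[i]] <- make_clinical_row(id, groups[i],
        psychosis = groups[i] == "BD" && psy_flags[max(bd_i, 1L)])
    }
    clinical <- do.call(rbind, clin)
    truth <- list(source_maps = source_maps, subject_tcs = truth_tcs,
                  group_labels = stats::setNames(groups, ids),
                  planted_corrs = list(HC = spec$corr_hc, BD = spec$corr_bd),
                  planted_lags = spec$lag_s, qc_fail_ids = qc_fail_ids)
    out <- list(scans = scans, traces = traces, clinical = clinical,
                mask = mask, mask_index = mask_index,
                templates = templates, truth = truth, spec = spec)
    if (!is.null(dir)) write_cohort(out, dir)
    out
  })
}

# Persist a generated cohort in the formats imaging_io reads.
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  mask_arr <- array(0, spec$shape)
  mask_arr[cohort$mask_index] <- 1
  geom <- volume_geometry(spec$shape, rep(spec$voxel_mm, 3))
  write_volume4d(matrix(1, length(cohort$mask_index), 1),
                 cohort$mask_index, geom, file.path(dir, "mask.nii.gz"))
  write_volume4d(t(cohort$templates$maps), cohort$mask_index, geom,
                 file.path(dir, "templates.nii.gz"))
  writeLines(cohort$templates$names, file.path(dir, "template_names.txt"))
  write_volume4d(t(cohort$truth$source_maps), cohort$mask_index, geom,
                 file.path(dir, "truth_source_maps.nii.gz"))
  files <- list()
  for (id in names(cohort$scans)) {
    sc <- cohort$scans[[id]]
    # re-attach discarded volumes as zeros so the on-disk file mimics a raw
    # acquisition (read_volume4d drops them again)
    full <- cbind(matrix(0, nrow(sc$data), spec$n_discard), sc$data)
    fp <- file.path(dir, paste0(id, ".nii.gz"))
    write_volume4d(full, sc$mask_index, geom, fp, tr_s = spec$tr_s)
    mp <- file.path(dir, paste0("rp_", id, ".txt"))
    write_motion_params(cohort$traces[[id]]$params, mp)
    files[[id]] <- list(scan = basename(fp), motion = basename(mp))
  }
  clin <- cohort$clinical
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  truth <- list(
    group_labels = as.list(cohort$truth$group_labels),
    planted_corr_hc = cohort$truth$planted_corrs$HC,
    planted_corr_bd = cohort$truth$planted_corrs$BD,
    planted_lags = cohort$truth$planted_lags,
    qc_fail_ids = cohort$truth$qc_fail_ids,
    seed = spec$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(seed = spec$seed, n_hc = spec$n_hc, n_bd = spec$n_bd,
                   tr_s = spec$tr_s, t_volumes = spec$t_volumes,
                   n_discard = spec$n_discard,
                   subjects = files,
                   mask = "mask.nii.gz", clinical = "clinical.csv",
                   templates = "templates.nii.gz",
                   template_names = "template_names.txt")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Template library for component identification
#'
#' Bundles the planted network maps (serving as RSN templates) with synthetic
#' gray-matter, white-matter and CSF probability maps: concentric shells of an
#' ellipsoidal head model, with the network blobs living in the gray-matter
#' shell.
#'
#' @param spec a `synthetic_spec`.
#' @param mask_index in-mask linear indices.
#' @param source_maps planted maps (rows named by network).
#' @return list with `names`, `maps` (named rows x voxels), `rsn_names`,
#'   `tissue_names`.
#' @export
make_template_library <- function(spec, mask_index, source_maps) {
  rho <- normalized_radius(spec$shape)[mask_index]
  gm <- exp(-((rho - 0.60) / 0.18)^2)
  wm <- exp(-(rho / 0.22)^2)
  csf <- exp(-((rho - 1.0) / 0.10)^2)
  tissue <- rbind(GM = gm, WM = wm, CSF = csf)
  maps <- rbind(source_maps, tissue)
  list(names = rownames(maps), maps = maps,
       rsn_names = rownames(source_maps),
       tissue_names = c("GM", "WM", "CSF"))
}
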