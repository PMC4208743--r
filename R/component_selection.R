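#' Spatial correlation between two maps
#'
#' Pearson correlation over in-mask voxels; the overlap statistic used both
#' for tissue screening and template sorting.
#'
#' @param map_a,map_b numeric vectors on a common mask.
#' @return Pearson r.
#' @export
spatial_correlation <- function(map_a, map_b) {
  stopifnot(length(map_a) == length(map_b))
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("zero-variance map in spatial correlation")
  }
  stats::cor(map_a, map_b)
}

#' Sort components against a template library
#'
#' Computes the full component x template spatial-correlation matrix and
#' assigns templates to components greedily by descending correlation
#' magnitude under a one-to-one constraint (GIFT-style sorting; ranking on
#' |r| makes the assignment invariant to the sign ambiguity of ICA maps);
#' the exhaustive-optimal assignment is available by flag. Signed
#' correlations are recorded alongside.
#'
#' @param components a `component_set` (or C x V matrix of maps).
#' @param templates template library from [make_template_library()], or a
#'   named list/matrix of template maps. Tissue maps (GM/WM/CSF), if present,
#'   are reported separately and not assigned.
#' @param warn_floor warn when an assigned correlation falls below this
#'   (default 0.2; reported template overlaps in the field run ~0.3-0.55).
#' @param optimal use optimal assignment instead of greedy.
#' @return A `sorting_result`: list with `assignments` (named integer vector:
#'   template -> component id), `assigned_r`, `overlap_r` (components x
#'   templates), `tissue_r` (components x tissue classes, if available).
#' @export
sort_by_templates <- function(components, templates, warn_floor = 0.2,
                              optimal = FALSE) {
  maps <- if (inherits(components, "component_set")) components$maps
          else as.matrix(components)
  tmaps <- if (is.list(templates) && !is.null(templates$maps)) templates$maps
           else as.matrix(templates)
  tissue_names <- intersect(c("GM", "WM", "CSF"), rownames(tmaps))
  rsn <- setdiff(rownames(tmaps), tissue_names)
  if (anyDuplicated(rownames(tmaps))) stop("duplicate template names")
  if (length(rsn) > nrow(maps)) {
    stop("fewer components (", nrow(maps), ") than templates (",
         length(rsn), ")")
  }
  r_all <- stats::cor(t(maps), t(tmaps))
  rownames(r_all) <- paste0("IC", seq_len(nrow(maps)))
  overlap <- r_all[, rsn, drop = FALSE]
  tissue <- if (length(tissue_names)) r_all[, tissue_names, drop = FALSE]
            else NULL
  assignments <- stats::setNames(integer(length(rsn)), rsn)
  assigned_r <- stats::setNames(numeric(length(rsn)), rsn)
  if (optimal) {
    perm <- best_assignment(abs(overlap))
    for (j in seq_along(rsn)) {
      assignments[j] <- perm[j]
      assigned_r[j] <- overlap[perm[j], j]
    }
  } else {
    work <- abs(overlap)
    for (step in seq_along(rsn)) {
      pos <- which(work == max(work, na.rm = TRUE), arr.ind = TRUE)[1, ]
      tpl <- colnames(work)[pos[2]]
      assignments[tpl] <- pos[1]
      assigned_r[tpl] <- overlap[pos[1], pos[2]]
      work[pos[1], ] <- NA
      work[, pos[2]] <- NA
    }
  }
  low <- abs(assigned_r) < warn_floor
  if (any(low)) {
    warning("template(s) matched below r = ", warn_floor, ": ",
            paste(sprintf("%s (r=%.2f)", names(assigned_r)[low],
                          assigned_r[low]), collapse = ", "))
  }
  structure(list(assignments = assignments, assigned_r = assigned_r,
                 overlap_r = overlap, tissue_r = tissue),
            class = "sorting_result")
}

# Exhaustive optimal one-to-one assignment maximizing total correlation
# (templates in columns); sized for template libraries, not general matching.
best_assignment <- function(r) {
  n_t <- ncol(r)
  perms <- all_perms(nrow(r), n_t)
  scores <- vapply(perms, function(p) sum(r[cbind(p, seq_len(n_t))]),
                   numeric(1))
  perms[[which.max(scores)]]
}

all_perms <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(n, k - 1L)) {
      if (!(i %in% rest)) out[[length(out) + 1L]] <- c(i, rest)
    }
  }
  out
}

#' Spectral fingerprint of a component time course
#'
#' Two statistics used to screen BOLD-like components: the dynamic range
#' (peak spectral power minus the minimum power at frequencies above the
#' peak) and the low-frequency to high-frequency power ratio (integral of
#' power below 0.10 Hz over the integral between 0.15 and 0.25 Hz), both from
#' a Welch spectrum (Hann window of length min(T, 128), 50% overlap, linear
#' detrend) normalized to unit total power. When the Nyquist frequency falls
#' below 0.25 Hz the upper band is truncated with a warning.
#'
#' @param tc numeric time course (T >= 64 recommended).
#' @param tr_s repetition time (s).
#' @return A `spectral_features` list: `dynamic_range`, `lf_hf_ratio`,
#'   `peak_freq_hz`.
#' @export
spectral_features <- function(tc, tr_s) {
  if (all(tc == 0)) stop("all-zero time course")
  fs <- 1 / tr_s
  ps <- welch_psd(tc, fs)
  spectral_features_from_psd(ps$freq, ps$power)
}

# Shared implementation; also used for subject-averaged spectra.
spectral_features_from_psd <- function(freq, power) {
  nyq <- max(freq)
  peak_i <- which.max(power)
  right <- power[freq > freq[peak_i]]
  dynamic_range <- if (length(right)) power[peak_i] - min(right) else 0
  hf_hi <- 0.25
  if (nyq < 0.25) {
    warning(sprintf(paste0("Nyquist %.3f Hz < 0.25 Hz; high-frequency band ",
                           "truncated to [0.15, %.3f] Hz"), nyq, nyq))
    hf_hi <- nyq
  }
  band_integral <- function(lo, hi) {
    sel <- freq >= lo & freq <= hi
    if (sum(sel) < 2L) return(0)
    trapz(freq[sel], power[sel])
  }
  lf <- band_integral(0, 0.10)
  hf <- band_integral(0.15, hf_hi)
  structure(list(dynamic_range = dynamic_range,
                 lf_hf_ratio = lf / max(hf, .Machine$double.eps),
                 peak_freq_hz = freq[peak_i]),
            class = "spectral_features")
}

#' Identify valid resting-state networks among components
#'
#' Three screening steps: (a) tissue overlap — keep components whose spatial
#' correlation with the gray-matter map exceeds both white-matter and CSF
#' correlations; (b) template sorting — keep components that win a one-to-one
#' template assignment; (c) spectral screen — keep components whose
#' low/high-frequency power ratio (averaged over subjects) exceeds
#' `lf_hf_min`, i.e. whose fluctuations concentrate in the 0.01-0.1 Hz window.
#' The scatter data (lf_hf_ratio vs dynamic range) behind step (c) is
#' returned for plotting.
#'
#' @param components a `component_set`.
#' @param subject_components list from [back_reconstruct()] (their time
#'   courses drive the spectral screen).
#' @param templates template library including GM/WM/CSF maps.
#' @param tr_s repetition time (s).
#' @param lf_hf_min spectral screen threshold (default 2).
#' @param warn_floor passed to [sort_by_templates()].
#' @return list with `selected` (named integer vector: template -> component
#'   id, for components passing all steps), `sorting` (`sorting_result`),
#'   `spectra` (data.frame: component, dynamic_range, lf_hf_ratio,
#'   peak_freq_hz), `survivors` (per-step logical matrix).
#' @export
select_components <- function(components, subject_components, templates,
                              tr_s, lf_hf_min = 2, warn_floor = 0.2) {
  n_c <- nrow(components$maps)
  sorting <- sort_by_templates(components, templates,
                               warn_floor = warn_floor)
  if (is.null(sorting$tissue_r)) {
    stop("template library must include GM/WM/CSF tissue maps")
  }
  gm_ok <- sorting$tissue_r[, "GM"] > sorting$tissue_r[, "WM"] &
           sorting$tissue_r[, "GM"] > sorting$tissue_r[, "CSF"]
  tpl_ok <- seq_len(n_c) %in% sorting$assignments
  fs <- 1 / tr_s
  spec_rows <- lapply(seq_len(n_c), function(k) {
    acc <- NULL
    for (sc in subject_components) {
      ps <- welch_psd(sc$tcs[k, ], fs)
      acc <- if (is.null(acc)) ps$power else acc + ps$power
      freq <- ps$freq
    }
    sf <- spectral_features_from_psd(freq, acc / length(subject_components))
    data.frame(component = k, dynamic_range = sf$dynamic_range,
               lf_hf_ratio = sf$lf_hf_ratio, peak_freq_hz = sf$peak_freq_hz)
  })
  spectra <- do.call(rbind, spec_rows)
  spec_ok <- spectra$lf_hf_ratio > lf_hf_min
  keep <- gm_ok & tpl_ok & spec_ok
  survivors <- cbind(tissue = gm_ok, template = tpl_ok, spectral = spec_ok)
  if (!any(keep)) {
    stop("no component passed selection (survivors per step: tissue=",
         sum(gm_ok), ", template=", sum(tpl_ok), ", spectral=",
         sum(spec_ok), ")")
  }
  sel <- sorting$assignments[sorting$assignments %in% which(keep)]
  list(selected = sel, sorting = sorting, spectra = spectra,
       survivors = survivors)
}
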