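#' Maximum absolute volume-to-volume displacement
#'
#' The motion summary statistic used as a nuisance covariate in group
#' comparisons: the maximum over volumes of the Euclidean norm of the
#' translation difference (dx, dy, dz) between each volume and the previous
#' one.
#'
#' @param trace a `motion_trace` (see [read_motion_params()]).
#' @return displacement in mm (non-negative scalar).
#' @export
max_abs_displacement <- function(trace) {
  p <- trace$params
  if (nrow(p) < 2L) stop("motion trace must have at least 2 volumes")
  d <- diff(p[, 1:3, drop = FALSE])
  max(sqrt(rowSums(d^2)))
}

#' Motion-based subject exclusion rule
#'
#' A subject is excluded if any translation axis spans more than 3 mm
#' (max - min over the run), any rotation axis spans more than 3 degrees, or
#' any volume-to-volume change of any of the six parameters exceeds 2 (mm or
#' degrees).
#'
#' @param trace a `motion_trace`.
#' @param trans_mm,rot_deg,deriv range and first-difference limits.
#' @return list with `excluded` (logical) and `reason` (string naming the
#'   offending parameter and its value; empty if not excluded).
#' @export
exclusion_check <- function(trace, trans_mm = 3, rot_deg = 3, deriv = 2) {
  p <- trace$params
  labels <- c("translation x", "translation y", "translation z",
              "rotation x", "rotation y", "rotation z")
  units <- c(rep("mm", 3), rep("deg", 3))
  ranges <- apply(p, 2, function(v) diff(range(v)))
  limits <- c(rep(trans_mm, 3), rep(rot_deg, 3))
  over <- which(ranges > limits)
  if (length(over)) {
    j <- over[which.max(ranges[over] / limits[over])]
    return(list(excluded = TRUE,
                reason = sprintf("%s %.3g %s (range limit %g)",
                                 labels[j], ranges[j], units[j], limits[j])))
  }
  if (nrow(p) >= 2L) {
    dmax <- apply(abs(diff(p)), 2, max)
    over <- which(dmax > deriv)
    if (length(over)) {
      j <- over[which.max(dmax[over])]
      return(list(excluded = TRUE,
                  reason = sprintf("%s derivative %.3g %s (limit %g)",
                                   labels[j], dmax[j], units[j], deriv)))
    }
  }
  list(excluded = FALSE, reason = "")
}

#' Cohort-level motion quality control
#'
#' Summarizes every subject's motion, applies the exclusion rule, and tests
#' for a group difference in maximum absolute displacement (pooled-variance
#' two-sample t by default; Welch available).
#'
#' @param traces list of `motion_trace`.
#' @param groups character vector of group labels, parallel to `traces`.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return list with `summary` (data.frame: subject_id, max_translation_mm,
#'   max_rotation_deg, max_deriv, max_abs_displacement_mm, excluded, reason)
#'   and `group_test` (list: t, df, p).
#' @export
cohort_qc <- function(traces, groups, welch = FALSE) {
  stopifnot(length(traces) == length(groups))
  rows <- lapply(traces, function(tr) {
    p <- tr$params
    chk <- exclusion_check(tr)
    data.frame(
      subject_id = tr$subject_id,
      max_translation_mm = max(apply(p[, 1:3, drop = FALSE], 2,
                                     function(v) diff(range(v)))),
      max_rotation_deg = max(apply(p[, 4:6, drop = FALSE], 2,
                                   function(v) diff(range(v)))),
      max_deriv = if (nrow(p) >= 2) max(abs(diff(p))) else 0,
      max_abs_displacement_mm = max_abs_displacement(tr),
      excluded = chk$excluded, reason = chk$reason,
      stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$group <- groups
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  x <- summary$max_abs_displacement_mm[groups == lv[1]]
  y <- summary$max_abs_displacement_mm[groups == lv[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 subjects for the motion comparison")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(summary = summary,
       group_test = list(t = unname(tt$statistic), df = unname(tt$parameter),
                         p = tt$p.value))
}
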