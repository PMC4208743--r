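#' Voxelwise one-sample t map
#'
#' Tests each voxel's subject map values against zero (two-sided), with
#' familywise error control by Bonferroni correction over in-mask voxels.
#' Used to delineate the core nodes of each network per group.
#'
#' @param subject_maps subjects x voxels matrix of z-scaled map values.
#' @param alpha familywise significance level (default 0.05).
#' @param correction `"FWE_bonferroni"` or `"none"`.
#' @return A `stat_map`: list with `t_values`, `p_values` (corrected when
#'   requested, capped at 1), `p_uncorrected`, `df`, `threshold_mask`,
#'   `correction`, `n_zero_variance`.
#' @export
one_sample_t_map <- function(subject_maps, alpha = 0.05,
                             correction = c("FWE_bonferroni", "none")) {
  correction <- match.arg(correction)
  n <- nrow(subject_maps)
  if (n < 3L) stop("one-sample t map needs at least 3 subjects")
  v <- ncol(subject_maps)
  mu <- colMeans(subject_maps)
  s <- col_sds(subject_maps)
  zero_var <- s == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance voxel(s); t set to 0")
    s[zero_var] <- 1
  }
  tv <- mu / (s / sqrt(n))
  tv[zero_var & mu == 0] <- 0
  tv[zero_var & mu != 0] <- sign(mu[zero_var & mu != 0]) * .Machine$double.xmax
  df <- n - 1L
  p_unc <- 2 * stats::pt(-abs(tv), df)
  p <- if (correction == "FWE_bonferroni") pmin(1, p_unc * v) else p_unc
  structure(list(t_values = tv, p_values = p, p_uncorrected = p_unc,
                 df = df, threshold_mask = p < alpha,
                 correction = correction,
                 n_zero_variance = sum(zero_var)),
            class = "stat_map")
}

#' Conjunction of two group statistical masks within gray matter
#'
#' The voxels suprathreshold in both groups' one-sample maps, intersected with
#' the gray-matter mask; group comparisons are restricted to this conjunction.
#'
#' @param statmap_g1,statmap_g2 `stat_map` objects for the same component.
#' @param gm_mask logical vector over the same voxels.
#' @return A `conjunction_mask`: list with `mask` (logical) and `n_voxels`.
#' @export
conjunction_mask <- function(statmap_g1, statmap_g2, gm_mask) {
  stopifnot(length(statmap_g1$threshold_mask) ==
              length(statmap_g2$threshold_mask),
            length(gm_mask) == length(statmap_g1$threshold_mask))
  m <- statmap_g1$threshold_mask & statmap_g2$threshold_mask & gm_mask
  if (!any(m)) {
    warning("empty conjunction mask; downstream group comparison will be ",
            "skipped for this component")
  }
  structure(list(mask = m, n_voxels = sum(m)), class = "conjunction_mask")
}

#' Voxelwise two-sample comparison with nuisance covariates
#'
#' Per-voxel OLS of map value on [intercept, group indicator, demeaned
#' covariates], with a t-test on the group coefficient. FWE control is
#' Bonferroni over conjunction voxels; final significance additionally
#' requires the corrected p to survive a Bonferroni correction over the
#' number of networks tested (alpha / n_components).
#'
#' @param maps_g1,maps_g2 subjects x voxels matrices (group 1, group 2).
#' @param covariates subjects x k matrix (rows: group 1 then group 2), or
#'   `NULL`.
#' @param conj a `conjunction_mask` restricting the tested voxels, or `NULL`
#'   for all voxels.
#' @param alpha familywise level (default 0.05).
#' @param n_components number of networks tested (Bonferroni divisor).
#' @return A `stat_map` over the full voxel vector (NA outside the
#'   conjunction) with additional fields `component_corrected_mask`,
#'   `alpha_component` (= alpha / n_components) and `n_tested`.
#' @export
two_sample_glm_map <- function(maps_g1, maps_g2, covariates = NULL,
                               conj = NULL, alpha = 0.05,
                               n_components = 1L) {
  n1 <- nrow(maps_g1); n2 <- nrow(maps_g2)
  v <- ncol(maps_g1)
  stopifnot(ncol(maps_g2) == v)
  y <- rbind(maps_g1, maps_g2)
  grp <- c(rep(0, n1), rep(1, n2))
  x <- cbind(intercept = 1, group = grp)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n1 + n2)
    x <- cbind(x, sweep(covariates, 2, colMeans(covariates)))
  }
  kap <- kappa(crossprod(x), exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    stop("collinear design (condition number ", signif(kap, 3), ")")
  }
  sel <- if (is.null(conj)) rep(TRUE, v) else conj$mask
  n_tested <- sum(sel)
  if (n_tested == 0L) stop("no voxels to test (empty conjunction)")
  ys <- y[, sel, drop = FALSE]
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, ys)
  resid <- ys - x %*% beta
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtx_inv["group", "group"])
  tv_sel <- ifelse(se > 0, beta["group", ] / se, 0)
  p_unc_sel <- 2 * stats::pt(-abs(tv_sel), df)
  p_fwe_sel <- pmin(1, p_unc_sel * n_tested)
  fill <- function(vals) { out <- rep(NA_real_, v); out[sel] <- vals; out }
  tv <- fill(tv_sel); p <- fill(p_fwe_sel)
  mask <- !is.na(p) & p < alpha
  alpha_comp <- alpha / n_components
  structure(list(t_values = tv, p_values = p,
                 p_uncorrected = fill(p_unc_sel), df = df,
                 threshold_mask = mask,
                 component_corrected_mask = !is.na(p) & p < alpha_comp,
                 alpha_component = alpha_comp, n_tested = n_tested,
                 correction = "FWE_bonferroni"),
            class = "stat_map")
}

#' Bonferroni-corrected component-level alpha
#'
#' The familywise level divided by the number of networks tested, rounded as
#' conventionally printed (0.05 over 6 networks gives 0.008).
#'
#' @param alpha familywise level.
#' @param n_components networks tested.
#' @param digits rounding for the printed value (default 3).
#' @return corrected alpha.
#' @export
component_bonferroni_alpha <- function(alpha = 0.05, n_components = 6L,
                                       digits = 3L) {
  round(alpha / n_components, digits)
}
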