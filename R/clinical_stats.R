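#' Composite medication load
#'
#' Each antidepressant or mood-stabilizer entry contributes 1 when its dose
#' level is low (1 or 2) and 2 when high (3 or 4); each antipsychotic entry
#' contributes its chlorpromazine-equivalent code (0, 1 or 2); absent
#' medication contributes 0. The load is the sum over entries.
#'
#' @param record list of medication entries (see [parse_medication()]).
#' @return non-negative integer load.
#' @export
medication_load <- function(record) {
  if (length(record) == 0L) return(0)
  sum(vapply(record, function(e) {
    if (e$class == "antipsychotic") {
      code <- e$cpz_code
      if (is.null(code) || code < 0L || code > 2L) {
        stop("antipsychotic cpz_code must be 0-2")
      }
      as.numeric(code)
    } else {
      lvl <- e$dose_level
      if (is.null(lvl) || lvl < 1L || lvl > 4L) {
        stop("dose_level must be 1-4 for ", e$class)
      }
      if (lvl <= 2L) 1 else 2
    }
  }, numeric(1)))
}

# Illness-course variables examined against aberrant connectivity.
.clinical_course_vars <- c("n_depressive", "n_manic", "onset_age",
                           "remission_years", "med_load")

#' Correlations of connectivity with illness-course variables
#'
#' Bivariate Pearson correlations, within the patient group, between a
#' per-patient connectivity value (e.g. the aberrant pair's Fisher z) and the
#' illness-course variables: number of depressive and manic episodes, onset
#' age, years in remission, and medication load. No multiplicity correction
#' is applied by default (reported alongside raw p-values).
#'
#' @param fnc_values numeric vector, one value per patient.
#' @param table clinical data.frame restricted to (or containing only) the
#'   patients, row-aligned with `fnc_values`; must carry the illness-course
#'   columns and `med_load`.
#' @param variables columns to correlate (default: the standard five).
#' @return data.frame with `variable`, `r`, `p`, `n`.
#' @export
clinical_correlations <- function(fnc_values, table,
                                  variables = .clinical_course_vars) {
  stopifnot(length(fnc_values) == nrow(table))
  if (length(fnc_values) < 3L) stop("need at least 3 patients")
  rows <- lapply(variables, function(v) {
    if (!v %in% names(table)) stop("missing clinical variable: ", v)
    x <- as.numeric(table[[v]])
    ok <- is.finite(x) & is.finite(fnc_values)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 ||
        stats::sd(fnc_values[ok]) == 0) {
      warning("correlation undefined for ", v,
              " (constant input or too few observations)")
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    ct <- stats::cor.test(fnc_values[ok], x[ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Psychotic-history subgroup comparison
#'
#' Pooled-variance two-sample t-test of a connectivity value between patients
#' with and without a history of psychotic symptoms.
#'
#' @param fnc_values numeric vector, one value per patient.
#' @param psychosis_flags logical vector, same length.
#' @return list with `t`, `df` (n1 + n2 - 2), `p`, `n_with`, `n_without`.
#' @export
subgroup_ttest <- function(fnc_values, psychosis_flags) {
  stopifnot(length(fnc_values) == length(psychosis_flags))
  x <- fnc_values[psychosis_flags]
  y <- fnc_values[!psychosis_flags]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each psychosis-history subgroup needs at least 2 patients")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n_with = length(x), n_without = length(y))
}
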