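# Shared fixtures, memoized so expensive stages run once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Reduced cohort used for ICA-stage checks: 12 subjects, 6 planted sources.
small_spec <- function(seed = 42, ...) {
  synthetic_spec(n_hc = 6L, n_bd = 6L, seed = seed, ...)
}

small_cohort <- function() {
  memo("small_cohort", generate_cohort(small_spec()))
}

small_ica <- function() {
  memo("small_ica", {
    coh <- small_cohort()
    suppressWarnings(run_group_ica(coh$scans, n_comp = 8L, n_runs = 20L,
                                   seed = 7L))
  })
}

# Match each planted source to the component of maximal |spatial r|.
match_components <- function(comp_maps, truth_maps) {
  r <- abs(stats::cor(t(comp_maps), t(truth_maps)))
  list(idx = apply(r, 2, which.max),
       r = apply(r, 2, max))
}

standardize_rows_for_test <- function(m) {
  m <- m - rowMeans(m)
  m / sqrt(rowSums(m^2) / (ncol(m) - 1))
}

# Per-subject planted time courses drawn without assembling 4D volumes
# (used for FNC-stage statistics where only time courses matter).
draw_cohort_tcs <- function(spec) {
  set.seed(spec$seed)
  groups <- c(rep("HC", spec$n_hc), rep("BD", spec$n_bd))
  tcs <- lapply(groups, function(g) {
    full <- make_time_courses(spec, g)
    full[, (spec$n_discard + 1L):spec$t_volumes, drop = FALSE]
  })
  list(tcs = tcs, groups = groups)
}
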