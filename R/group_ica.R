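#' Subject-level temporal PCA reduction
#'
#' First reduction stage of group spatial ICA: each voxel's series is demeaned
#' over time and the top `k1` temporal principal components are retained,
#' giving a voxels x k1 reduced data set per subject.
#'
#' @param scan a `subject_scan`.
#' @param k1 number of components to retain (GIFT convention: ~1.5x the group
#'   model order).
#' @return list with `reduced` (voxels x k1), `basis` (time x k1, orthonormal
#'   columns), `eigenvalues` (all, non-increasing), `explained` (fraction of
#'   variance retained).
#' @export
subject_pca_reduce <- function(scan, k1) {
  d <- scan$data
  t_n <- ncol(d)
  if (k1 > t_n) stop("k1 (", k1, ") exceeds number of time points (", t_n, ")")
  d <- d - rowMeans(d)
  ct <- crossprod(d) / (nrow(d) - 1)
  eg <- eigen(ct, symmetric = TRUE)
  basis <- eg$vectors[, seq_len(k1), drop = FALSE]
  ev <- pmax(eg$values, 0)
  list(reduced = d %*% basis, basis = basis, eigenvalues = ev,
       explained = sum(ev[seq_len(k1)]) / max(sum(ev), .Machine$double.eps))
}

#' Group-level PCA reduction and whitening
#'
#' Second reduction stage: the subject-reduced data sets are concatenated
#' along the reduced-time dimension, reduced to `n_comp` principal components,
#' and whitened so the output rows have identity covariance over voxels.
#'
#' @param reduced_list list of voxels x k1 matrices from
#'   [subject_pca_reduce()].
#' @param n_comp group model order C.
#' @param underfit_warn_frac warn when the retained variance fraction falls
#'   below this (a sign the model order underfits).
#' @return list with `whitened` (C x voxels, row covariance = I),
#'   `dewhitening` ((n k1) x C), `eigenvalues`, `explained`.
#' @export
group_pca_reduce <- function(reduced_list, n_comp,
                             underfit_warn_frac = 0.6) {
  g <- do.call(cbind, reduced_list)
  if (n_comp > ncol(g)) {
    stop("model order ", n_comp, " exceeds stacked dimension ", ncol(g))
  }
  g <- sweep(g, 2, colMeans(g))
  v <- nrow(g)
  m <- crossprod(g) / (v - 1)
  eg <- eigen(m, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  frac <- sum(ev[seq_len(n_comp)]) / max(sum(ev), .Machine$double.eps)
  if (frac < underfit_warn_frac) {
    warning(sprintf(paste0("top %d components retain only %.1f%% of stacked ",
                           "variance; model order may underfit"),
                    n_comp, 100 * frac))
  }
  e_c <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  lam <- ev[seq_len(n_comp)]
  if (any(lam <= 0)) stop("rank-deficient group data at requested order")
  whitened <- t(g %*% e_c) / sqrt(lam)
  list(whitened = whitened,
       dewhitening = e_c * rep(sqrt(lam), each = nrow(e_c)),
       eigenvalues = ev, explained = frac)
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with the logistic nonlinearity
#' g(u) = 1 / (1 + exp(-u)): update step dW = lrate (I + (1 - 2 g(U)) U' / V) W
#' on whitened data, with learning-rate annealing (x 0.9 whenever the weight
#' change rises) and convergence when the relative weight change drops below
#' `tol`. Suited to super-Gaussian (sparse) sources such as resting-state
#' network maps. Output sources have unit variance and the sign of each is
#' fixed so its largest-magnitude voxel is positive.
#'
#' @param whitened C x V matrix with identity row covariance.
#' @param w_init initial C x C unmixing matrix (default: random orthogonal
#'   from the session RNG).
#' @param max_steps iteration cap.
#' @param lrate initial learning rate (default 0.015 / ln(C)).
#' @param tol convergence tolerance on the relative weight change.
#' @param anneal learning-rate decay applied when the weight change rises.
#' @return list with `W` (unmixing), `S` (C x V sources, unit variance,
#'   sign-fixed), `steps`, `converged`.
#' @export
infomax_ica <- function(whitened, w_init = NULL, max_steps = 512L,
                        lrate = NULL, tol = 1e-6, anneal = 0.9) {
  n_c <- nrow(whitened); v <- ncol(whitened)
  if (is.null(lrate)) lrate <- 0.015 / max(log(n_c), 1)
  rand_orth <- function() {
    qr.Q(qr(matrix(stats::rnorm(n_c * n_c), n_c)))
  }
  if (is.null(w_init)) w_init <- rand_orth()
  w <- w_init
  eye <- diag(n_c)
  # stochastic block updates: many weight updates per pass over the voxels
  block <- as.integer(ceiling(min(5 * log(v), 0.3 * v)))
  restarts <- 0L
  prev_change <- Inf
  converged <- FALSE
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    w_old <- w
    perm <- sample.int(v)
    blew_up <- FALSE
    for (s0 in seq(1L, v - block + 1L, by = block)) {
      u <- w %*% whitened[, perm[s0:(s0 + block - 1L)], drop = FALSE]
      gu <- 1 / (1 + exp(-u))
      w <- w + lrate * (block * eye + (1 - 2 * gu) %*% t(u)) %*% w
      if (max(abs(w)) > 1e8) { blew_up <- TRUE; break }
    }
    change <- sum((w - w_old)^2) / sum(w_old^2)
    if (blew_up || !is.finite(change)) {
      restarts <- restarts + 1L
      if (restarts > 10L) {
        stop("Infomax diverged repeatedly; try a lower learning rate")
      }
      lrate <- lrate * 0.5
      w <- rand_orth()
      prev_change <- Inf
      step <- 0L
      next
    }
    if (change > prev_change) lrate <- lrate * anneal
    prev_change <- change
    if (change < tol) { converged <- TRUE; break }
  }
  s <- w %*% whitened
  sds <- sqrt(rowSums((s - rowMeans(s))^2) / (v - 1))
  sds[sds == 0] <- 1
  s <- s / sds
  w <- w / sds
  flip <- vapply(seq_len(n_c),
                 function(k) sign(s[k, which.max(abs(s[k, ]))]), numeric(1))
  flip[flip == 0] <- 1
  list(W = w * flip, S = s * flip, steps = step, converged = converged)
}

#' Icasso stability analysis of repeated Infomax runs
#'
#' Runs Infomax `n_runs` times from different random initial conditions, pools
#' all estimates, clusters them by average-linkage agglomerative clustering on
#' the dissimilarity 1 - |spatial correlation|, and scores each cluster with
#' the quality index Iq = (average intra-cluster similarity) - (average
#' similarity between the cluster's members and all non-members); Iq is in
#' [0, 1] for compact, well-separated clusters and near 1 when the
#' decomposition is stable. The representative map of each cluster is its
#' centrotype — the member maximizing summed intra-cluster similarity.
#'
#' @param whitened C x V whitened group data.
#' @param n_comp model order C (clusters requested).
#' @param n_runs Infomax repetitions (default 20).
#' @param seed seed for the run initializations.
#' @param ... passed to [infomax_ica()].
#' @return A `component_set`: list with `maps` (C x V, unit variance,
#'   sign-fixed), `iq` (C), `centrotype_runs`, `run_cluster_members`
#'   (data.frame: run, component, cluster), `order`, `n_runs`, `seed`.
#' @export
icasso <- function(whitened, n_comp, n_runs = 20L, seed = 1L, ...) {
  if (n_runs < 2L) stop("Icasso needs at least 2 runs")
  n_c <- nrow(whitened)
  stopifnot(n_comp == n_c)
  runs <- lapply(seq_len(n_runs), function(r) {
    with_seed(derive_seed(seed, r), infomax_ica(whitened, ...))
  })
  pool <- do.call(rbind, lapply(runs, `[[`, "S"))
  run_of <- rep(seq_len(n_runs), each = n_c)
  comp_of <- rep(seq_len(n_c), times = n_runs)
  sim <- abs(stats::cor(t(pool)))
  cl <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  membership <- stats::cutree(cl, k = n_comp)
  qual <- icasso_iq(sim, membership)
  iq <- qual$iq
  centro <- qual$centrotype
  ord <- order(iq, decreasing = TRUE)
  iq <- iq[ord]; centro <- centro[ord]
  maps <- pool[centro, , drop = FALSE]
  flip <- vapply(seq_len(n_comp),
                 function(k) sign(maps[k, which.max(abs(maps[k, ]))]),
                 numeric(1))
  flip[flip == 0] <- 1
  maps <- maps * flip
  relabel <- match(membership, membership[centro])
  structure(list(maps = maps, iq = iq,
                 centrotype_runs = run_of[centro],
                 run_cluster_members = data.frame(run = run_of,
                                                  component = comp_of,
                                                  cluster = relabel),
                 order = n_comp, n_runs = n_runs, seed = seed),
            class = "component_set")
}

#' Cluster quality index and centrotypes for an estimate pool
#'
#' Iq for cluster k is the average pairwise similarity among its members
#' (including self-similarity) minus the average similarity between its
#' members and all non-members; the centrotype is the member with maximal
#' summed intra-cluster similarity.
#'
#' @param sim symmetric similarity matrix over pooled estimates (typically
#'   absolute spatial correlations).
#' @param membership integer cluster labels, one per estimate.
#' @return list with `iq` (one value per cluster, ordered by cluster label)
#'   and `centrotype` (estimate index per cluster).
#' @export
icasso_iq <- function(sim, membership) {
  labels <- sort(unique(membership))
  iq <- numeric(length(labels))
  centro <- integer(length(labels))
  for (li in seq_along(labels)) {
    inside <- which(membership == labels[li])
    outside <- which(membership != labels[li])
    intra <- mean(sim[inside, inside])
    extra <- if (length(outside)) mean(sim[inside, outside, drop = FALSE])
             else 0
    iq[li] <- intra - extra
    within <- sim[inside, inside, drop = FALSE]
    centro[li] <- inside[which.max(rowSums(within))]
  }
  list(iq = iq, centrotype = centro)
}

#' Back-reconstruct subject-specific maps and time courses
#'
#' Dual (spatial-temporal) regression against the group maps: (1) each
#' subject's volumes are regressed on the group spatial maps to give subject
#' time courses; (2) each voxel's series is regressed on those time courses to
#' give subject spatial maps, which are then z-scaled (mean 0, SD 1 over
#' in-mask voxels) so map intensities are comparable across subjects.
#'
#' @param components a `component_set`.
#' @param scans list of `subject_scan` (same mask and ordering as the group
#'   decomposition).
#' @return list of `subject_components`: each a list with `subject_id`, `maps`
#'   (C x V, z-scaled), `tcs` (C x T).
#' @export
back_reconstruct <- function(components, scans) {
  gm <- components$maps
  x1 <- cbind(1, t(gm))  # V x (C+1) design for the spatial regression
  lapply(scans, function(scan) {
    y <- scan$data
    fit1 <- stats::lm.fit(x1, y)  # coefficients: (C+1) x T
    tcs <- fit1$coefficients[-1, , drop = FALSE]
    kappa_tc <- kappa(tcs %*% t(tcs), exact = FALSE)
    if (!is.finite(kappa_tc) || kappa_tc > 1e10) {
      stop("rank-deficient subject time courses (condition number ",
           signif(kappa_tc, 3), ") for ", scan$subject_id)
    }
    x2 <- cbind(1, t(tcs))  # T x (C+1)
    fit2 <- stats::lm.fit(x2, t(y))
    maps <- fit2$coefficients[-1, , drop = FALSE]
    maps <- standardize_rows(maps)
    structure(list(subject_id = scan$subject_id, maps = maps, tcs = tcs),
              class = "subject_components")
  })
}

#' Run the full group ICA stage
#'
#' Convenience wrapper: subject PCA (order `k1`, default round(1.5 C)), group
#' PCA/whitening, Icasso-stabilized Infomax, and dual-regression
#' back-reconstruction.
#'
#' @param scans list of `subject_scan`.
#' @param n_comp group model order C.
#' @param n_runs Icasso repetitions.
#' @param k1 subject PCA order.
#' @param seed seed for ICA initializations.
#' @param ... passed to [infomax_ica()].
#' @return list with `components` (`component_set`), `subjects` (list of
#'   `subject_components`), `pca` (group reduction), `k1`.
#' @export
run_group_ica <- function(scans, n_comp, n_runs = 20L, k1 = NULL,
                          seed = 1L, ...) {
  if (is.null(k1)) k1 <- round(1.5 * n_comp)
  k1 <- min(k1, min(vapply(scans, function(s) ncol(s$data), numeric(1))))
  red <- lapply(scans, subject_pca_reduce, k1 = k1)
  gp <- group_pca_reduce(lapply(red, `[[`, "reduced"), n_comp)
  comps <- icasso(gp$whitened, n_comp, n_runs = n_runs, seed = seed, ...)
  subj <- back_reconstruct(comps, scans)
  list(components = comps, subjects = subj, pca = gp, k1 = k1)
}
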