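#' Population PCA trajectories
#'
#' Treats each 50 ms bin's population vector (one column of the
#' concatenated response matrix) as an observation, computes the covariance
#' across neurons over all concatenated bins (mean-centered), and projects
#' every bin onto the top-`k` eigenvectors. Within each condition the
#' first-bin value (pre-stimulus baseline) is subtracted and a three-point
#' moving average applied, with shrinking windows at the ends so the point
#' count is preserved. Eigenvector signs are fixed by making each vector's
#' largest-magnitude component positive.
#'
#' @param concatenated a [concatenate_conditions()] response matrix (its
#'   column provenance defines the conditions); at least 2 bins.
#' @param k number of components (default 3).
#' @param smooth apply the three-point moving average (default TRUE).
#' @param baseline_subtract subtract each condition's first-bin projection
#'   (default TRUE).
#' @return list of class `pca_trajectories`: `trajectories` (named list of
#'   bins x k coordinate matrices per condition), `rotation` (neurons x k
#'   eigenvectors), `sdev` (all singular sdevs), `center`.
#' @export
pca_trajectories <- function(concatenated, k = 3, smooth = TRUE,
                             baseline_subtract = TRUE) {
  stopifnot(inherits(concatenated, "response_matrix"))
  X <- t(unclass(concatenated))              # bins x neurons
  if (nrow(X) < 2) stop("at least 2 bins are required")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  k <- min(k, ncol(sv$v))
  V <- sv$v[, seq_len(k), drop = FALSE]
  # reproducible eigenvector sign: largest-|component| made positive
  for (j in seq_len(k)) {
    p <- which.max(abs(V[, j]))
    if (V[p, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(concatenated)
  proj <- Xc %*% V
  prov <- attr(concatenated, "provenance")
  conds <- if (is.data.frame(prov)) unique(prov$condition) else "cond1"
  traj <- lapply(conds, function(cd) {
    sel <- if (is.data.frame(prov)) prov$condition == cd else TRUE
    p <- proj[sel, , drop = FALSE]
    if (baseline_subtract) p <- sweep(p, 2, p[1, ])
    if (smooth) apply(p, 2, moving_average3) else p
  })
  names(traj) <- conds
  structure(list(trajectories = traj, rotation = V,
                 sdev = sv$d / sqrt(max(1, nrow(X) - 1)), center = ctr),
            class = "pca_trajectories")
}

#' Three-point moving average with shrinking end windows
#'
#' Linear smoother used on trajectories: interior points average their two
#' neighbours and themselves; the first and last points average the two
#' available points, so the point count never changes.
#'
#' @param x numeric vector.
#' @return smoothed vector of the same length.
#' @export
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  y[1] <- mean(x[1:2]); y[n] <- mean(x[(n - 1):n])
  as.numeric(y)
}

#' Fisher linear discriminant projection
#'
#' Finds the directions maximizing between-class scatter relative to
#' within-class scatter of labeled population bin vectors, and projects
#' every bin onto the top-`k` directions. When the within-class scatter is
#' singular (common with 85 neurons and few bins per class) its diagonal is
#' regularized by `1e-6 * trace / n`.
#'
#' @param bins numeric matrix, observations (bins) in rows.
#' @param labels class label per row; at least 2 classes with at least 2
#'   observations each.
#' @param k number of discriminant directions (default 3; capped at
#'   `n_classes - 1`).
#' @return list of class `lda_projection`: `projections` (rows match
#'   `bins`), `labels`, `directions` (features x k), `degenerate` (TRUE
#'   when no direction carries positive between-class variance).
#' @export
lda_project <- function(bins, labels, k = 3) {
  bins <- as.matrix(bins)
  labels <- as.character(labels)
  stopifnot(nrow(bins) == length(labels))
  cls <- unique(labels)
  if (length(cls) < 2) stop("at least 2 classes are required")
  if (any(table(labels) < 2)) stop("every class needs at least 2 bins")
  d <- ncol(bins)
  mu <- colMeans(bins)
  W <- matrix(0, d, d); B <- matrix(0, d, d)
  for (cl in cls) {
    Xc <- bins[labels == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    Xd <- sweep(Xc, 2, mc)
    W <- W + crossprod(Xd)
    B <- B + nrow(Xc) * tcrossprod(mc - mu)
  }
  if (rcond_sym(W) < 1e-12)
    W <- W + diag(1e-6 * sum(diag(W)) / d + 1e-12, d)
  M <- solve(W, B)
  ei <- eigen(M)
  ev <- Re(ei$values)
  k <- min(k, length(cls) - 1, d)
  keep <- order(ev, decreasing = TRUE)[seq_len(k)]
  V <- Re(ei$vectors[, keep, drop = FALSE])
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  for (j in seq_len(ncol(V))) {
    p <- which.max(abs(V[, j]))
    if (V[p, j] < 0) V[, j] <- -V[, j]
  }
  degenerate <- all(ev[keep] <= 1e-10 * max(1, sum(diag(B))))
  if (degenerate)
    warning("no direction with positive between-class variance; ",
            "classes appear identical")
  structure(list(projections = bins %*% V, labels = labels,
                 directions = V, eigenvalues = ev[keep],
                 degenerate = degenerate),
            class = "lda_projection")
}

rcond_sym <- function(A) {
  ev <- tryCatch(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 0))
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Correlation between two conditions' ensemble responses
#'
#' For each trial, averages spike counts per neuron over the bins of the
#' comparison window (by default the first 1 s after onset) in both
#' conditions and correlates the two population vectors (Pearson), pairing
#' trials by index. The trial-averaged vectors give the summary bar value.
#'
#' @param tensor_a,tensor_b [bin_spikes()] tensors for the two conditions,
#'   each aligned to its own stimulus onset, with matching neuron order and
#'   trial counts.
#' @param window interval (relative to each condition's alignment) averaged
#'   over; default `c(0, 1)`.
#' @return list of class `ensemble_correlation`: `per_trial` (numeric, NA
#'   where a trial vector has zero variance), `mean`, `sd`, and `bar`
#'   (correlation of trial-averaged vectors).
#' @export
ensemble_correlation <- function(tensor_a, tensor_b, window = c(0, 1)) {
  stopifnot(inherits(tensor_a, "binned_tensor"),
            inherits(tensor_b, "binned_tensor"))
  if (!identical(dimnames(tensor_a)[[1]], dimnames(tensor_b)[[1]]))
    stop("neuron order must match")
  if (dim(tensor_a)[2] != dim(tensor_b)[2])
    stop("trial counts must match (trials are paired by index)")
  va <- window_means(tensor_a, window)   # neurons x trials
  vb <- window_means(tensor_b, window)
  n_tr <- ncol(va)
  per_trial <- vapply(seq_len(n_tr), function(tr) {
    if (stats::sd(va[, tr]) == 0 || stats::sd(vb[, tr]) == 0)
      return(NA_real_)
    stats::cor(va[, tr], vb[, tr])
  }, 0)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  bar <- if (stats::sd(ma) == 0 || stats::sd(mb) == 0) NA_real_ else
    stats::cor(ma, mb)
  structure(list(per_trial = per_trial,
                 mean = mean(per_trial, na.rm = TRUE),
                 sd = stats::sd(per_trial[!is.na(per_trial)]),
                 bar = bar, window = window),
            class = "ensemble_correlation")
}

window_means <- function(tensor, window) {
  bs <- attr(tensor, "bin_starts")
  sel <- bs >= window[1] & bs < window[2]
  if (!any(sel)) stop("window contains no bins")
  apply(unclass(tensor)[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Paired t-test on per-trial correlation values
#'
#' Two-sided paired t-test comparing, trial by trial, the
#' distractor-vs-solitary-target correlations with the
#' distractor-vs-sequential-target correlations (the contrast-enhancement
#' test). Degenerate inputs are handled explicitly: identical samples give
#' `p = 1`; a constant non-zero difference gives the smallest representable
#' p-value.
#'
#' @param solitary_rs,sequential_rs per-trial correlations, paired by trial
#'   index; at least 2 complete pairs.
#' @return list: `p_value`, `t`, `df`, `mean_diff`.
#' @export
contrast_test <- function(solitary_rs, sequential_rs) {
  if (length(solitary_rs) != length(sequential_rs))
    stop("samples must be paired (equal lengths)")
  ok <- !is.na(solitary_rs) & !is.na(sequential_rs)
  d <- solitary_rs[ok] - sequential_rs[ok]
  n <- length(d)
  if (n < 2) stop("at least 2 complete pairs are required")
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    if (all(d == 0))
      return(list(p_value = 1, t = 0, df = n - 1, mean_diff = 0))
    return(list(p_value = .Machine$double.xmin,
                t = sign(mean(d)) * Inf, df = n - 1, mean_diff = mean(d)))
  }
  tt <- stats::t.test(solitary_rs[ok], sequential_rs[ok], paired = TRUE)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Linear approximation of the history-induced response shift
#'
#' Predicts the sequential target response as the solitary target response
#' plus a scaled "uniqueness" term:
#' `prediction = target + alpha * (target - distractor)`, clipped at zero.
#' When `alpha` is `NULL` and an observed sequential matrix is supplied,
#' `alpha` is fit by least squares on the unclipped model.
#'
#' @param target,distractor `response_matrix` objects of matching shape.
#' @param alpha scale factor, or `NULL` to fit.
#' @param observed observed sequential `response_matrix` (required to fit).
#' @return predicted `response_matrix` with attribute `alpha`.
#' @export
linear_shift_prediction <- function(target, distractor, alpha = NULL,
                                    observed = NULL) {
  stopifnot(inherits(target, "response_matrix"),
            inherits(distractor, "response_matrix"),
            all(dim(target) == dim(distractor)))
  u <- unclass(target) - unclass(distractor)
  if (is.null(alpha)) {
    if (is.null(observed))
      stop("either alpha or an observed sequential matrix is required")
    stopifnot(all(dim(observed) == dim(target)))
    denom <- sum(u^2)
    alpha <- if (denom == 0) 0 else
      sum((unclass(observed) - unclass(target)) * u) / denom
  }
  pred <- pmax(unclass(target) + alpha * u, 0)  # pmax keeps dim of arg 1
  structure(pred, class = c("response_matrix", "matrix"),
            provenance = list(kind = "linear_shift_prediction"),
            bin_starts = attr(target, "bin_starts"),
            bin_width = attr(target, "bin_width"),
            alpha = alpha)
}

#' Per-neuron temporal-pattern correlations
#'
#' Correlates, neuron by neuron, the 80-bin trial-averaged spike-count
#' vector of the solitary presentation with that of a sequential
#' presentation. Zero-variance neurons are excluded and counted.
#'
#' @param solitary,sequential `response_matrix` objects with matched
#'   neurons and equal bin counts (the 4 s target window).
#' @return list of class `temporal_correlation`: `values` (named numeric),
#'   `n_excluded`, `excluded_ids`.
#' @export
temporal_pattern_correlation <- function(solitary, sequential) {
  stopifnot(inherits(solitary, "response_matrix"),
            inherits(sequential, "response_matrix"),
            all(dim(solitary) == dim(sequential)),
            identical(rownames(solitary), rownames(sequential)))
  ids <- rownames(solitary)
  sd_a <- apply(solitary, 1, stats::sd)
  sd_b <- apply(sequential, 1, stats::sd)
  ok <- sd_a > 0 & sd_b > 0
  vals <- rep(NA_real_, length(ids))
  vals[ok] <- vapply(which(ok), function(i)
    stats::cor(unclass(solitary)[i, ], unclass(sequential)[i, ]), 0)
  structure(list(values = stats::setNames(vals[ok], ids[ok]),
                 n_excluded = sum(!ok), excluded_ids = ids[!ok]),
            class = "temporal_correlation")
}
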