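test_that("pca_trajectories matches a dense eigendecomposition oracle", {
  set.seed(10)
  X <- matrix(rnorm(10 * 20), 10, 20)   # 10 neurons x 20 bins
  m <- make_rm(X)
  pc <- pca_trajectories(concatenate_conditions(list(a = m)), k = 3,
                         smooth = FALSE, baseline_subtract = FALSE)
  # oracle: eigendecomposition of the bin-vector covariance
  Y <- t(X)
  S <- stats::cov(Y)
  ei <- eigen(S, symmetric = TRUE)
  proj_oracle <- sweep(Y, 2, colMeans(Y)) %*% ei$vectors[, 1:3]
  got <- pc$trajectories$a
  for (j in 1:3) {
    s <- sign(sum(got[, j] * proj_oracle[, j]))
    expect_lt(max(abs(got[, j] - s * proj_oracle[, j])), 1e-8)
  }
  # PCA energy: projected variances sum to the covariance trace
  expect_equal(sum(pc$sdev^2), sum(diag(S)), tolerance = 1e-10)
})

test_that("planar data have zero third-component variance", {
  set.seed(3)
  basis <- matrix(rnorm(10), 5, 2)
  coefs <- matrix(rnorm(40), 2, 20)
  m <- make_rm(basis %*% coefs)          # rank-2, 5 neurons
  pc <- pca_trajectories(concatenate_conditions(list(a = m)), k = 3,
                         smooth = FALSE, baseline_subtract = FALSE)
  expect_lt(pc$sdev[3]^2, 1e-9)
  # duplicated condition gives identical trajectories
  pc2 <- pca_trajectories(concatenate_conditions(list(a = m, b = m)))
  expect_equal(pc2$trajectories$a, pc2$trajectories$b)
})

test_that("three-point smoothing is linear and preserves length", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30)
  expect_length(moving_average3(x), 30)
  expect_equal(moving_average3(x + y),
               moving_average3(x) + moving_average3(y), tolerance = 1e-12)
  expect_equal(moving_average3(c(1, 2, 3, 4)),
               c(1.5, 2, 3, 3.5))
})

test_that("lda_project recovers the two-class Fisher direction", {
  set.seed(5)
  mu <- c(4, -3, 2, 0, 1)
  A <- matrix(rnorm(200 * 5), 200, 5)
  B <- sweep(matrix(rnorm(200 * 5), 200, 5), 2, mu, `+`)
  fit <- lda_project(rbind(A, B), rep(c("a", "b"), each = 200), k = 1)
  # closed form: w ~ Sw^{-1} (mu_b - mu_a); isotropic classes -> ~ mu
  d <- fit$directions[, 1]
  cosine <- abs(sum(d * mu)) / sqrt(sum(d^2) * sum(mu^2))
  expect_gte(cosine, 0.99)
  expect_false(fit$degenerate)
  # identical classes: degenerate, flagged
  expect_warning(fit0 <- lda_project(rbind(A, A),
                                     rep(c("a", "b"), each = 200), k = 1),
                 "identical")
  expect_true(fit0$degenerate)
  expect_error(lda_project(A, rep("a", 200)), "2 classes")
})

test_that("distinct ON-set conditions cluster by class after LDA", {
  set.seed(6)
  n_cls <- 6; d <- 30; per <- 40
  protos <- matrix(0, n_cls, d)
  for (k in seq_len(n_cls)) protos[k, ((k - 1) * 5 + 1):(k * 5)] <- 3
  X <- do.call(rbind, lapply(seq_len(n_cls), function(k)
    sweep(matrix(rnorm(per * d, sd = 0.8), per, d), 2, protos[k, ], `+`)))
  lab <- rep(sprintf("c%d", seq_len(n_cls)), each = per)
  fit <- lda_project(X, lab, k = 3)
  cent <- do.call(rbind, lapply(unique(lab), function(cl)
    colMeans(fit$projections[lab == cl, , drop = FALSE])))
  rownames(cent) <- unique(lab)
  nearest <- apply(fit$projections, 1, function(p)
    rownames(cent)[which.min(colSums((t(cent) - p)^2))])
  expect_gte(mean(nearest == lab), 0.95)
})

test_that("ensemble_correlation matches hand-computed values", {
  # identical conditions -> r = 1 in every trial
  counts <- array(rpois(4 * 3 * 20, 3), c(4, 3, 20))
  tens <- make_tensor(counts, window_start = 0)
  r_same <- ensemble_correlation(tens, tens, window = c(0, 1))
  expect_true(all(abs(r_same$per_trial - 1) < 1e-12))
  # 4-neuron hand computation with disjoint active sets
  a <- c(2, 0, 1, 0); b <- c(0, 3, 0, 1)
  ca <- array(rep(a, 2 * 1), c(4, 2, 1)); cb <- array(rep(b, 2), c(4, 2, 1))
  ra <- make_tensor(ca, bin_width = 1, window_start = 0)
  rb <- make_tensor(cb, bin_width = 1, window_start = 0)
  r <- ensemble_correlation(ra, rb, window = c(0, 1))
  # by hand: r = sum((a-mean a)(b-mean b)) / ((n-1) sd_a sd_b)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    (3 * stats::sd(a) * stats::sd(b))
  expect_equal(unname(r$per_trial[1]), hand, tolerance = 1e-12)
  expect_lt(hand, 0)
  # zero-variance trial is reported as NA
  cz <- array(0L, c(4, 2, 1))
  rz <- make_tensor(cz, bin_width = 1, window_start = 0)
  expect_true(all(is.na(ensemble_correlation(rz, rb,
                                             window = c(0, 1))$per_trial)))
})

test_that("history suppression lowers the distractor-target correlation", {
  for (s in 1:5) {
    cfg <- generator_config(seed = s)
    gt <- sample_tuning(cfg, c("d", "t"), seed = s)
    tensors <- simulate_pair(cfg, gt, "d", "t", seed = 100 + s * 3)
    r_sol <- ensemble_correlation(tensors$D, tensors$T)
    r_seq <- ensemble_correlation(tensors$D, tensors$S)
    expect_lt(mean(r_seq$per_trial), mean(r_sol$per_trial))
  }
})

test_that("contrast_test handles degenerate inputs and is calibrated", {
  x <- c(0.2, 0.5, 0.3, 0.8)
  same <- contrast_test(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)
  shifted <- contrast_test(x + 0.1, x)
  expect_equal(shifted$p_value, .Machine$double.xmin)
  expect_error(contrast_test(1, 2), "2 complete pairs")
  # power at effect d = 1 s.d., n = 10 vs the noncentral-t closed form
  set.seed(7)
  n <- 10; reps <- 10000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    sol <- rnorm(n)
    rej[i] <- contrast_test(sol, sol - rnorm(n, 1, 1))$p_value < 0.05
  }
  tcrit <- qt(0.975, n - 1)
  ncp <- sqrt(n)
  power <- 1 - pt(tcrit, n - 1, ncp) + pt(-tcrit, n - 1, ncp)
  expect_lt(abs(mean(rej) - power), 0.02)
})

test_that("linear_shift_prediction reduces to the documented limits", {
  set.seed(8)
  tgt <- make_rm(matrix(runif(50, 1, 3), 5))
  dis <- make_rm(matrix(runif(50, 1, 3), 5))
  expect_equal(unclass(linear_shift_prediction(tgt, dis, alpha = 0))[, ],
               unclass(tgt)[, ])
  expect_equal(unclass(linear_shift_prediction(tgt, tgt, alpha = 7))[, ],
               unclass(tgt)[, ])
  # fitting recovers the generating alpha and beats alpha = 0
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    t0 <- matrix(runif(200, 1, 3), 10)
    d0 <- matrix(runif(200, 1, 3), 10)
    obs <- t0 + 0.7 * (t0 - d0) + matrix(rnorm(200, sd = 0.1), 10)
    fit <- linear_shift_prediction(make_rm(t0), make_rm(d0),
                                   observed = make_rm(obs))
    expect_lt(abs(attr(fit, "alpha") - 0.7), 0.15)
    res_fit <- sum((unclass(fit) - obs)^2)
    res_0 <- sum((t0 - obs)^2)
    if (res_fit < res_0) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("temporal_pattern_correlation behaves at its limits", {
  set.seed(9)
  m <- make_rm(matrix(runif(400), 5, 80))
  same <- temporal_pattern_correlation(m, m)
  expect_true(all(abs(same$values - 1) < 1e-12))
  ramp <- matrix(rep(seq_len(80), each = 5), 5, 80)
  rev <- ramp[, 80:1]
  r <- temporal_pattern_correlation(make_rm(ramp), make_rm(rev))
  expect_true(all(abs(r$values + 1) < 1e-12))
  # history modulation pushes per-neuron correlations toward zero
  lower <- 0L
  for (s in 1:5) {
    cfg_mod <- generator_config(rho_sup = 0.2, rho_enh = 2, seed = s)
    cfg_ctl <- generator_config(rho_sup = 1, rho_enh = 1, seed = s)
    for (nm in c("mod", "ctl")) {
      cfg <- if (nm == "mod") cfg_mod else cfg_ctl
      gt <- sample_tuning(cfg, c("d", "t"), seed = s)
      tensors <- simulate_pair(cfg, gt, "d", "t", seed = 400 + s * 3)
      sel <- function(tens) {
        bs <- attr(tens, "bin_starts")
        m <- trial_average(tens)
        structure(unclass(m)[, bs >= 0 & bs < 4],
                  class = c("response_matrix", "matrix"),
                  bin_starts = bs[bs >= 0 & bs < 4], provenance = list())
      }
      tc <- temporal_pattern_correlation(sel(tensors$T), sel(tensors$S))
      on_ids <- intersect(names(tc$values), gt$on$t)
      assign(paste0("r_", nm), mean(abs(tc$values[on_ids])))
    }
    if (r_mod < r_ctl) lower <- lower + 1L
  }
  expect_gte(lower, 4L)
})
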