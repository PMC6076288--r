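test_that("train_svm reproduces the closed-form maximum-margin separator", {
  # two support points (2,2) and (0,0): w* = d/ (||d||^2/2) = (0.5, 0.5),
  # b* = -1, margins exactly 1 at both supports
  pos <- rbind(c(2, 2), c(3, 2.5))
  neg <- rbind(c(0, 0), c(-1, 0.5))
  m <- train_svm(pos, neg, C = 1e4, tol = 1e-10)
  expect_lt(max(abs(m$weights - c(0.5, 0.5))), 1e-6)
  expect_lt(abs(m$bias + 1), 1e-6)
  expect_lt(abs(m$margin[1] - 1), 1e-6)
  expect_true(all(m$slack < 1e-6))
  # label swap negates the solution
  m2 <- train_svm(neg, pos, C = 1e4, tol = 1e-10)
  expect_lt(max(abs(m$weights + m2$weights)), 1e-6)
  expect_lt(abs(m$bias + m2$bias), 1e-6)
  expect_error(train_svm(pos[1, , drop = FALSE], neg), "2 examples")
})

test_that("svm_classify is the sign of the affine score, ties to absent", {
  m <- structure(list(weights = c(a = 1, b = -2), bias = 0.5, C = 0.01),
                 class = "svm_model")
  expect_false(svm_classify(structure(list(weights = c(1, -2), bias = -1,
                                           C = 0.01),
                                      class = "svm_model"), c(0, 0)))
  # point exactly on the hyperplane: score 0 -> absent
  expect_false(svm_classify(m, c(0.5, 0.5)))
  set.seed(1)
  X <- matrix(rnorm(100), 50, 2)
  expect_identical(as.logical(svm_classify(m, X)),
                   as.numeric(X %*% c(1, -2)) + 0.5 > 0)
  expect_error(svm_classify(m, c(1, 2, 3)), "length")
})

test_that("SVM solution beats random feasible perturbations", {
  set.seed(2)
  pos <- matrix(rnorm(60, 1), 30, 2)
  neg <- matrix(rnorm(60, -1), 30, 2)
  m <- train_svm(pos, neg, C = 0.01, tol = 1e-10)
  X <- rbind(pos, neg); y <- rep(c(1, -1), each = 30)
  primal <- function(w, b)
    0.5 * sum(w^2) + 0.01 * sum(pmax(0, 1 - y * (X %*% w + b)))
  ours <- primal(m$weights, m$bias)
  for (i in 1:1000) {
    w2 <- m$weights + rnorm(2, sd = 0.05)
    b2 <- m$bias + rnorm(1, sd = 0.05)
    expect_gte(primal(w2, b2), ours - 1e-9)
  }
})

test_that("SVM separates synthetic target from distractor bins held out", {
  cfg <- generator_config(seed = 12)
  gt <- sample_tuning(cfg, c("d", "t"), seed = 12)
  simT <- simulate_trials(cfg, solitary_protocol("t"), gt = gt, seed = 31)
  simD <- simulate_trials(cfg, solitary_protocol("d"), gt = gt, seed = 32)
  bins_of <- function(sim, trials) {
    tens <- bin_spikes(sim$raster, 0.05, c(-2.5, 9))
    bs <- attr(tens, "bin_starts")
    sel <- bs >= 0 & bs < 4
    do.call(rbind, lapply(trials, function(tr)
      t(unclass(tens)[, tr, sel])))
  }
  m <- train_svm(bins_of(simT, 1:8), bins_of(simD, 1:8))
  held <- rbind(bins_of(simT, 9:10), bins_of(simD, 9:10))
  truth <- rep(c(TRUE, FALSE), each = 160)
  expect_gte(mean(svm_classify(m, held) == truth), 0.95)
})

test_that("flex decoder construction enforces its contracts", {
  bc <- barcode(stats::setNames(c(TRUE, FALSE, TRUE, TRUE),
                                c("a", "b", "c", "d")))
  dec <- build_flex_weights(bc, m = 2)
  expect_identical(unname(as.integer(dec$v)), c(1L, 0L, 1L, 1L))
  expect_identical(dec$n, 3L)
  expect_error(build_flex_weights(bc, m = 3), "m < n")
  empty <- barcode(stats::setNames(c(FALSE, FALSE), c("a", "b")))
  expect_error(build_flex_weights(empty), "empty|responsive")
})

test_that("digital flex decisions match the OR-of-ANDs truth table", {
  # n = 4 template neurons among 6, m = 2: exhaustive over all 2^6 inputs
  v <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                       sprintf("n%d", 1:6))
  dec <- flex_decoder(v, m = 2)
  tmpl <- which(v)
  ands <- utils::combn(tmpl, 2, simplify = FALSE)
  for (code in 0:63) {
    x <- as.integer(intToBits(code))[1:6]
    oracle <- any(vapply(ands, function(a) all(x[a] == 1), TRUE))
    expect_identical(unname(flex_classify(dec, x, mode = "digital")),
                     oracle)
  }
  # 2-of-3 example: neurons {1,3} active -> present; only weight-0
  # neuron active -> absent
  v2 <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE), sprintf("n%d", 1:4))
  d2 <- flex_decoder(v2, m = 2)
  expect_true(flex_classify(d2, c(1, 0, 1, 0), mode = "digital"))
  expect_false(flex_classify(d2, c(0, 0, 0, 1), mode = "digital"))
})

test_that("analog flex decisions threshold the template spike count", {
  v <- stats::setNames(c(TRUE, TRUE, FALSE), c("a", "b", "c"))
  dec <- flex_decoder(v, m = 1, tau = 3)
  expect_true(flex_classify(dec, c(2, 1, 9), mode = "analog"))
  expect_false(flex_classify(dec, c(2, 0.5, 9), mode = "analog"))
  cal <- calibrate_tau(dec, rbind(c(4, 4, 0), c(2, 2, 0)))
  expect_equal(cal$tau, 1 / 2 * mean(c(8, 4)))
})

test_that("digital decisions are monotone and permutation-equivariant", {
  set.seed(3)
  for (rep in 1:50) {
    n_feat <- 8
    v <- stats::setNames(sample(c(TRUE, FALSE), n_feat, TRUE,
                                prob = c(.6, .4)),
                         sprintf("n%d", seq_len(n_feat)))
    if (sum(v) < 2) next
    dec <- flex_decoder(v, m = sample(sum(v) - 1, 1))
    x <- sample(c(0, 1), n_feat, TRUE)
    base <- flex_classify(dec, x, mode = "digital")
    off <- which(x == 0)
    if (length(off)) {
      x2 <- x; x2[sample(off, 1)] <- 1
      more <- flex_classify(dec, x2, mode = "digital")
      expect_true(!base || more)        # never present -> absent
    }
    perm <- sample(n_feat)
    dec_p <- flex_decoder(stats::setNames(v[perm], names(v)), m = dec$m)
    expect_identical(flex_classify(dec_p, x[perm], mode = "digital"),
                     base)
  }
})

test_that("classification_probability averages decisions across trials", {
  dec <- matrix(TRUE, 4, 3)
  expect_equal(as.numeric(classification_probability(dec)), c(1, 1, 1))
  dec2 <- matrix(c(rep(TRUE, 7), rep(FALSE, 3)), 10, 1)
  expect_equal(as.numeric(classification_probability(dec2)), 0.7)
  set.seed(4)
  d <- matrix(sample(c(TRUE, FALSE), 200, TRUE), 10, 20)
  expect_equal(as.numeric(classification_probability(d)),
               apply(d, 2, function(col) sum(col) / length(col)))
  expect_error(classification_probability(matrix(TRUE, 0, 3)), "trial")
})

test_that("nearest_centroid_confusion matches brute-force leave-one-out", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, 10), 10), matrix(rnorm(40, -10), 10))
  lab <- rep(c("a", "b"), each = 10)
  cm <- nearest_centroid_confusion(X, lab)
  expect_equal(unname(cm), diag(2))
  expect_equal(unname(rowSums(cm)), c(1, 1))
  # brute-force oracle on overlapping classes, <= 20 trials
  X2 <- matrix(rnorm(20 * 3), 20, 3)
  lab2 <- rep(c("a", "b"), each = 10)
  cm2 <- nearest_centroid_confusion(X2, lab2)
  oracle <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (i in 1:20) {
    cents <- sapply(c("a", "b"), function(cl) {
      keep <- lab2 == cl & seq_len(20) != i
      colMeans(X2[keep, , drop = FALSE])
    })
    pred <- c("a", "b")[which.min(colSums((cents - X2[i, ])^2))]
    oracle[lab2[i], pred] <- oracle[lab2[i], pred] + 1
  }
  expect_equal(cm2, sweep(oracle, 1, rowSums(oracle), `/`))
  expect_error(nearest_centroid_confusion(X2[c(1, 11:20), ],
                                          lab2[c(1, 11:20)]), "2 trials")
})

test_that("identical class distributions confuse symmetrically", {
  set.seed(6)
  off_diag <- numeric(100)
  for (s in 1:100) {
    X <- matrix(rnorm(10 * 2), 10, 2)
    cm <- nearest_centroid_confusion(X, rep(c("a", "b"), each = 5))
    off_diag[s] <- (cm["a", "b"] + cm["b", "a"]) / 2
  }
  # binomial error around 1/2 over 100 seeds x 10 assignments
  expect_lt(abs(mean(off_diag) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("digital decoding survives histories that silence responders", {
  # noise-free check of the robustness narrative: each history silences
  # at most n - m template neurons, so every target bin stays "present"
  # even though no neuron responds in all histories
  n <- 12; m <- 8
  ids <- sprintf("n%02d", 1:n)
  v <- barcode(stats::setNames(rep(TRUE, n), ids))
  dec <- build_flex_weights(v, m = m)
  hist_bcs <- list()
  for (h in 1:3) {
    silenced <- ((h - 1) * 4 + 1):(h * 4)       # n - m = 4 per history
    x <- rep(1, n); x[silenced] <- 0
    expect_true(flex_classify(dec, x, mode = "digital"))
    hist_bcs[[h]] <- barcode(stats::setNames(x == 1, ids))
  }
  cons <- consistent_set(hist_bcs)
  expect_identical(sum(cons), 0L)
})
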