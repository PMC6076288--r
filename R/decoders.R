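#' Train the soft-margin linear SVM decoder
#'
#' Solves the standard hinge-loss problem
#' `min 1/2 ||v||^2 + C sum mu_i` subject to
#' `y_i (v' x_i + b) >= 1 - mu_i`, `mu_i >= 0`, at box constraint
#' `C = 0.01`, via sequential minimal optimization on the dual (compiled;
#' maximal-violating-pair selection, deterministic for a fixed row order).
#' Positive examples are the per-trial per-bin population vectors during
#' solitary target presentations; negatives are the solitary distractor
#' and baseline bins.
#'
#' @param positive,negative numeric matrices, one population bin vector per
#'   row (columns = neurons, with column names); both classes need at least
#'   2 rows.
#' @param C box constraint (default 0.01).
#' @param tol dual optimality tolerance (default 1e-8).
#' @param max_iter safety cap on SMO iterations.
#' @return object of class `svm_model`: `weights` (named per-neuron vector
#'   `v_svm`), `bias` (b), `C`, and diagnostics (`alpha`, per-example
#'   `margin` gamma_i, `slack` mu_i, `objective`, `iterations`,
#'   `converged`).
#' @export
train_svm <- function(positive, negative, C = 0.01, tol = 1e-8,
                      max_iter = 1000000L) {
  positive <- as.matrix(positive); negative <- as.matrix(negative)
  if (nrow(positive) < 2 || nrow(negative) < 2)
    stop("both classes need at least 2 examples")
  if (ncol(positive) != ncol(negative))
    stop("classes must share the feature dimension")
  X <- rbind(positive, negative)
  y <- c(rep(1, nrow(positive)), rep(-1, nrow(negative)))
  fit <- smo_linear_svm(X, y, C, tol, as.integer(max_iter))
  if (!fit$converged)
    warning(sprintf("SMO stopped at gap %.3g after %d iterations",
                    fit$gap, fit$iterations))
  w <- as.numeric(fit$w)
  names(w) <- colnames(positive)
  margin <- y * (as.numeric(X %*% w) + fit$b)
  slack <- pmax(0, 1 - margin)
  structure(list(weights = w, bias = fit$b, C = C,
                 alpha = as.numeric(fit$alpha), margin = margin,
                 slack = slack,
                 objective = 0.5 * sum(w^2) + C * sum(slack),
                 iterations = fit$iterations, converged = fit$converged),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d weights, b = %.4g, C = %g, %d SVs\n",
              length(x$weights), x$bias, x$C, sum(x$alpha > 1e-12)))
  invisible(x)
}

#' Classify population bin vectors with a trained SVM
#'
#' Decision `h(x) = sign(v_svm' x + b)`: "present" iff the score is
#' strictly positive (a score of exactly zero is "absent" — presence
#' requires positive evidence).
#'
#' @param model an [train_svm()] model.
#' @param x numeric vector (one bin) or matrix (bins in rows) matching the
#'   weight length.
#' @return logical: `TRUE` = present, one element per bin.
#' @export
svm_classify <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$weights))
    stop("bin vector length does not match the model")
  as.numeric(x %*% model$weights) + model$bias > 0
}

#' Flexible m-of-n (OR-of-ANDs) decoder
#'
#' The template decoder with binary weights: `v` marks the neurons
#' responsive to solitary introductions of the target, `n = sum(v)`, and
#' the classification threshold is either an analog cutoff `tau` on the
#' summed spike count `v' x(t)` or a digital count `m < n` of co-active
#' template neurons. Any `m` of the `n` template neurons suffice, so the
#' digital rule is an OR over `choose(n, m)` AND-terms.
#'
#' @param v named binary (0/1 or logical) weight vector.
#' @param m digital threshold (neuron count); must satisfy `m < n`.
#' @param tau analog threshold in summed spike-count units.
#' @return object of class `flex_decoder`.
#' @export
flex_decoder <- function(v, m = NULL, tau = NULL) {
  stopifnot(!is.null(names(v)))
  v <- as.logical(v)
  if (anyNA(v)) stop("weights must be binary")
  n <- sum(v)
  if (n == 0) stop("no responsive neurons: the template is empty")
  if (!is.null(m)) {
    m <- as.integer(m)
    if (m < 1 || m >= n)
      stop("the digital threshold m must satisfy 1 <= m < n (n = ", n, ")")
  }
  structure(list(v = v, n = n, m = m, tau = tau), class = "flex_decoder")
}

#' @export
print.flex_decoder <- function(x, ...) {
  cat(sprintf("<flex_decoder> n = %d template neurons, m = %s, tau = %s\n",
              x$n, ifelse(is.null(x$m), "unset", x$m),
              ifelse(is.null(x$tau), "unset", format(x$tau))))
  invisible(x)
}

#' Build flexible-decoder weights from a responder barcode
#'
#' Copies the solitary-target responder barcode into the binary weight
#' vector (`1` for responsive neurons, `0` otherwise).
#'
#' @param solitary_target_barcode a [barcode()] from [classify_responders()]
#'   on the solitary target condition.
#' @param m,tau thresholds, validated as in [flex_decoder()].
#' @return a [flex_decoder()].
#' @export
build_flex_weights <- function(solitary_target_barcode, m = NULL,
                               tau = NULL) {
  stopifnot(inherits(solitary_target_barcode, "barcode"))
  flex_decoder(stats::setNames(as.logical(solitary_target_barcode),
                               names(solitary_target_barcode)),
               m = m, tau = tau)
}

#' Classify bin vectors with the flexible decoder
#'
#' Analog mode thresholds the summed raw count of template neurons:
#' present iff `v' x >= tau`. Digital mode expects a binarized bin vector
#' (see [binarize_counts()]) and declares presence iff at least `m` of the
#' `n` template neurons are active; which `m` neurons they are does not
#' matter.
#'
#' @param decoder a [flex_decoder()] (with `tau` set for analog mode, `m`
#'   for digital mode).
#' @param x numeric (analog) or logical/0-1 (digital) vector, or a matrix
#'   with one bin per row, matching the weight length.
#' @param mode `"analog"` or `"digital"`.
#' @return logical, `TRUE` = present, one element per bin.
#' @export
flex_classify <- function(decoder, x, mode = c("analog", "digital")) {
  mode <- match.arg(mode)
  stopifnot(inherits(decoder, "flex_decoder"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(decoder$v))
    stop("bin vector length does not match the decoder")
  if (mode == "analog") {
    if (is.null(decoder$tau)) stop("analog mode requires tau")
    as.numeric(x %*% decoder$v) >= decoder$tau
  } else {
    if (is.null(decoder$m)) stop("digital mode requires m")
    xb <- x != 0
    as.numeric(xb %*% decoder$v) >= decoder$m
  }
}

#' Binarize bin counts against per-neuron response thresholds
#'
#' Digital front-end of the flexible decoder: a neuron is "active" in a bin
#' iff its count strictly exceeds its own pre-stimulus response threshold
#' (the same mean + 6.5 s.d. rule as [classify_responders()]).
#'
#' @param x numeric vector or matrix (bins in rows; columns = neurons).
#' @param thresholds named per-neuron thresholds from
#'   [response_threshold()], in the same units as `x`.
#' @return logical vector/matrix of active flags.
#' @export
binarize_counts <- function(x, thresholds) {
  if (is.null(dim(x))) return(as.numeric(x) > thresholds)
  sweep(x, 2, thresholds, `>`)
}

#' Default analog threshold for the flexible decoder
#'
#' Sets `tau` to the fraction `m/n` of the mean training score `v' x` over
#' solitary-target stimulus bins, the decoder's single tunable.
#'
#' @param decoder a [flex_decoder()] with `m` set.
#' @param training_bins matrix of solitary-target stimulus bin vectors
#'   (rows).
#' @return the decoder with `tau` filled in.
#' @export
calibrate_tau <- function(decoder, training_bins) {
  stopifnot(inherits(decoder, "flex_decoder"), !is.null(decoder$m))
  scores <- as.numeric(as.matrix(training_bins) %*% decoder$v)
  decoder$tau <- decoder$m / decoder$n * mean(scores)
  decoder
}

#' Per-bin classification probability across trials
#'
#' Fraction of trials classified "present" in each bin.
#'
#' @param decisions logical/0-1 matrix, trials in rows, bins in columns.
#' @param bin_starts optional bin start times carried along.
#' @param condition optional label.
#' @return object of class `classification_probability`: numeric per-bin
#'   probabilities in `[0, 1]` with attributes `n_trials`, `bin_starts`,
#'   `condition`.
#' @export
classification_probability <- function(decisions, bin_starts = NULL,
                                       condition = NULL) {
  decisions <- as.matrix(decisions)
  if (nrow(decisions) < 1) stop("at least one trial is required")
  p <- colMeans(decisions != 0)
  structure(p, class = "classification_probability",
            n_trials = nrow(decisions), bin_starts = bin_starts,
            condition = condition)
}

#' Leave-one-trial-out nearest-centroid confusion matrix
#'
#' For every held-out trial the class centroids are recomputed from the
#' remaining trials and the trial is assigned the label of the nearest
#' centroid (Euclidean distance; ties broken toward the first class in
#' sorted label order). Rows are true classes, normalized to
#' classification fractions.
#'
#' @param features numeric matrix, one per-trial feature vector per row.
#' @param labels class label per row; every class needs at least 2 trials.
#' @return numeric matrix (classes x classes) of row-normalized fractions.
#' @export
nearest_centroid_confusion <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("at least 2 classes are required")
  if (any(table(labels) < 2))
    stop("every class needs at least 2 trials for leave-one-out")
  cm <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
  for (i in seq_len(nrow(features))) {
    cent <- vapply(cls, function(cl) {
      sel <- labels == cl
      sel[i] <- FALSE
      colMeans(features[sel, , drop = FALSE])
    }, numeric(ncol(features)))
    d2 <- colSums((cent - features[i, ])^2)
    pred <- cls[which.min(d2)]     # which.min keeps the first tie
    cm[labels[i], pred] <- cm[labels[i], pred] + 1
  }
  sweep(cm, 1, rowSums(cm), `/`)
}

#' Serialize a decoder model as JSON
#'
#' @param model an `svm_model` or `flex_decoder`.
#' @param path output path.
#' @export
write_decoder <- function(model, path) {
  if (inherits(model, "svm_model")) {
    obj <- list(type = "svm", weights = as.list(model$weights),
                bias = model$bias, C = model$C,
                iterations = model$iterations, converged = model$converged)
  } else if (inherits(model, "flex_decoder")) {
    obj <- list(type = "flex", v = as.list(as.integer(model$v)),
                n = model$n, m = model$m, tau = model$tau)
  } else stop("unknown model type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
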