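# Classifier: quadratic-kernel SVM on the 4-D feature vectors, stratified
# cross-validation, metrics, and Bayesian hyperparameter search.

FEATURE_NAMES <- c("max_rolled_diversity", "max_rolled_entropy",
                   "max_rolled_substitution", "mean_uncertainty")
CLASS_LEVELS <- c("monomorphic", "fold_switching")

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- intersect(FEATURE_NAMES, names(features))
    if (length(cols) == 4L) features <- features[, cols]
    else features <- features[, vapply(features, is.numeric, TRUE)]
  }
  x <- as.matrix(features)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("feature values must be finite")
  colnames(x) <- NULL
  x
}

as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad) > 0L) {
    stop("labels must be 'fold_switching' or 'monomorphic'; got: ",
         paste(bad, collapse = ", "))
  }
  factor(labels, levels = CLASS_LEVELS)
}

#' Fit the quadratic-kernel SVM fold-switching classifier
#'
#' Features are standardized (zero mean, unit variance, parameters taken
#' from the training data supplied here) and fed to a degree-2 polynomial
#' kernel SVM. Decision values are reported with positive sign meaning
#' fold-switching.
#'
#' @param features numeric matrix or data.frame of the four features, one
#'   row per protein.
#' @param labels vector over `fold_switching` / `monomorphic`.
#' @param cost regularization weight (default 1).
#' @param gamma polynomial-kernel coefficient (default 0.25, i.e. 1/4
#'   features).
#' @param coef0 polynomial-kernel independent term (default 1, the
#'   inhomogeneous quadratic kernel; a homogeneous quadratic kernel,
#'   `coef0 = 0`, is an even function of the standardized features and
#'   cannot represent affine decision boundaries).
#' @return an object of class `foldswitch_model`.
#' @export
fit_foldswitch_svm <- function(features, labels, cost = 1, gamma = 0.25,
                               coef0 = 1) {
  x <- as_feature_matrix(features)
  y <- as_label_factor(labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training data must contain both classes; try a different seed ",
         "or stratified folds")
  }
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  fit <- e1071::svm(xs, y, kernel = "polynomial", degree = 2,
                    cost = cost, gamma = gamma, coef0 = coef0,
                    scale = FALSE)
  # e1071 decision values are positive for the class named first in the
  # column label "A/B"; flip so positive always means fold_switching.
  dv <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  first_class <- strsplit(colnames(dv), "/", fixed = TRUE)[[1L]][1L]
  structure(
    list(svm = fit, center = center, scale = scl,
         sign = if (first_class == "fold_switching") 1 else -1,
         hyperparameters = list(cost = cost, gamma = gamma, coef0 = coef0)),
    class = "foldswitch_model"
  )
}

#' @export
print.foldswitch_model <- function(x, ...) {
  h <- x$hyperparameters
  cat("<foldswitch_model> quadratic-kernel SVM |",
      x$svm$tot.nSV, "support vectors | cost =", signif(h$cost, 3),
      "gamma =", signif(h$gamma, 3), "coef0 =", signif(h$coef0, 3), "\n")
  invisible(x)
}

#' Predict fold-switching behaviour from feature vectors
#'
#' @param object a fitted `foldswitch_model`.
#' @param features matrix/data.frame of feature vectors (or a single named
#'   vector).
#' @param ... unused.
#' @return data.frame with columns `label` and `confidence` (signed distance
#'   to the decision boundary; positive = fold-switching).
#' @export
predict.foldswitch_model <- function(object, features, ...) {
  if (is.null(object$svm)) stop("model is not fitted")
  if (is.numeric(features) && is.null(dim(features)) &&
      length(features) == 4L) {
    features <- matrix(features, nrow = 1L)
  }
  x <- as_feature_matrix(features)
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  pr <- stats::predict(object$svm, xs, decision.values = TRUE)
  conf <- object$sign * as.numeric(attr(pr, "decision.values"))
  data.frame(label = as.character(pr), confidence = conf,
             stringsAsFactors = FALSE)
}

#' Save / load a fitted classifier
#'
#' @param model a `foldswitch_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "foldswitch_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "foldswitch_model"))
  model
}

#' Classification metrics from a binary confusion matrix
#'
#' Standard definitions: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' precision TP/(TP+FP), accuracy 100*(TP+TN)/total (a percentage), F1 the
#' harmonic mean of precision and sensitivity, and the Matthews correlation
#' coefficient. Ratios with a zero denominator are reported as `NaN` with a
#' warning.
#'
#' @param tp,fn,tn,fp non-negative confusion-matrix counts (fold-switching
#'   is the positive class).
#' @return named numeric vector of the six metrics.
#' @export
compute_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("confusion matrix is empty")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  prec <- ratio(tp, tp + fp, "precision")
  acc <- 100 * (tp + tn) / total
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
    warning("F1 undefined; reported as NaN", call. = FALSE)
    NaN
  } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as NaN",
            call. = FALSE)
    NaN
  } else (tp * tn - fp * fn) / mcc_den
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, f1 = f1, mcc = mcc)
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed controlling the random partition.
#' @return integer vector of fold ids (1..n_folds), one per example.
#' @export
make_folds <- function(labels, n_folds = 6L, seed = 1L) {
  y <- as_label_factor(labels)
  counts <- table(y)
  if (any(counts < n_folds)) {
    stop("each class needs at least ", n_folds, " examples for ", n_folds,
         "-fold stratified cross-validation (counts: ",
         paste(counts, collapse = "/"), ")")
  }
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of the fold-switching classifier
#'
#' The data are partitioned into stratified random folds (controlled by
#' `seed`), the SVM is refit on each training split — feature
#' standardization parameters are recomputed from the training split alone —
#' and metrics are computed on the held-out folds only.
#'
#' @param features feature matrix/data.frame (4 columns).
#' @param labels class labels.
#' @param n_folds number of folds (default 6).
#' @param seed RNG seed for the partition.
#' @param cost,gamma,coef0 SVM hyperparameters passed to
#'   [fit_foldswitch_svm()].
#' @param folds optional precomputed fold assignment (overrides `seed`).
#' @return a `ValidationReport`: list with `folds` (per-fold metrics plus
#'   confusion counts and the fold's standardization centers), `summary`
#'   (mean and sd of each metric across folds) and the hyperparameters.
#' @export
cross_validate <- function(features, labels, n_folds = 6L, seed = 1L,
                           cost = 1, gamma = 0.25, coef0 = 1, folds = NULL) {
  x <- as_feature_matrix(features)
  y <- as_label_factor(labels)
  stopifnot(nrow(x) == length(y))
  if (is.null(folds)) folds <- make_folds(y, n_folds = n_folds, seed = seed)
  n_folds <- max(folds)
  rows <- vector("list", n_folds)
  centers <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    if (nlevels(droplevels(y[!test])) < 2L) {
      stop("fold ", f, " has a single-class training split; use a ",
           "different seed or stratified folds")
    }
    model <- fit_foldswitch_svm(x[!test, , drop = FALSE], y[!test],
                                cost = cost, gamma = gamma, coef0 = coef0)
    pred <- predict(model, x[test, , drop = FALSE])$label
    truth <- as.character(y[test])
    tp <- sum(pred == "fold_switching" & truth == "fold_switching")
    fn <- sum(pred == "monomorphic" & truth == "fold_switching")
    tn <- sum(pred == "monomorphic" & truth == "monomorphic")
    fp <- sum(pred == "fold_switching" & truth == "monomorphic")
    metrics <- suppressWarnings(compute_metrics(tp, fn, tn, fp))
    rows[[f]] <- data.frame(fold = f, tp = tp, fn = fn, tn = tn, fp = fp,
                            t(metrics))
    centers[[f]] <- model$center
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "precision", "accuracy",
                   "f1", "mcc")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]]), 0),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]]), 0),
    row.names = NULL
  )
  structure(
    list(folds = per_fold, summary = summ, fold_assignment = folds,
         standardization_centers = centers,
         hyperparameters = list(cost = cost, gamma = gamma, coef0 = coef0)),
    class = "ValidationReport"
  )
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("<ValidationReport>", max(x$folds$fold), "folds\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %7.3f (sd %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Mean cross-validated metric from a ValidationReport
#' @param report a `ValidationReport`.
#' @param metric metric name (default `"accuracy"`).
#' @return numeric mean across folds.
#' @export
cv_metric <- function(report, metric = "accuracy") {
  report$summary$mean[report$summary$metric == metric]
}

# --- Bayesian hyperparameter search ---------------------------------------
# Gaussian-process surrogate (squared-exponential kernel on unit-cube
# coordinates) with expected-improvement acquisition over a random candidate
# pool. Search space: cost log-uniform 1e-2..1e3, gamma log-uniform
# 1e-3..10, coef0 uniform 0..5.

hp_bounds <- function() {
  list(log10_cost = c(-2, 3), log10_gamma = c(-3, 1), coef0 = c(0, 5))
}

hp_default <- function() c(log10_cost = 0, log10_gamma = log10(0.25), coef0 = 1)

hp_to_unit <- function(theta) {
  b <- hp_bounds()
  vapply(seq_along(b), function(i)
    (theta[i] - b[[i]][1]) / diff(b[[i]]), 0)
}

hp_decode <- function(theta) {
  theta <- unname(theta)
  list(cost = 10^theta[1], gamma = 10^theta[2], coef0 = theta[3])
}

gp_expected_improvement <- function(X, y, Xcand, lengthscale = 0.3,
                                    noise = 1e-6) {
  # X, Xcand on the unit cube; y standardized internally
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  sqdist <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  }
  K <- exp(-sqdist(X, X) / (2 * lengthscale^2)) + diag(noise, nrow(X))
  Ks <- exp(-sqdist(Xcand, X) / (2 * lengthscale^2))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  mu <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- max(ys)
  z <- (mu - best) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  ei
}

#' Bayesian hyperparameter search for the fold-switching SVM
#'
#' Sequential model-based optimization of the mean cross-validated accuracy:
#' an initial seeded random design over (cost, gamma, coef0) — always
#' including the default point — is refined by a Gaussian-process surrogate
#' with the expected-improvement acquisition. Folds are fixed across all
#' evaluations so comparisons are paired. Ties in CV accuracy are broken
#' toward the smaller regularization weight (lower model complexity). With
#' `search_budget = 1` only the default point is evaluated.
#'
#' @param features feature matrix/data.frame.
#' @param labels class labels.
#' @param search_budget total number of hyperparameter points to evaluate.
#' @param seed RNG seed (folds, design and candidate pools).
#' @param n_folds folds for the inner cross-validation (default 6).
#' @return a `foldswitch_model` fitted on all data at the best
#'   hyperparameters, with attributes `cv_accuracy` (its mean CV accuracy)
#'   and `search_history` (all evaluated points).
#' @export
tune_hyperparameters <- function(features, labels, search_budget = 20L,
                                 seed = 1L, n_folds = 6L) {
  stopifnot(search_budget >= 1L)
  x <- as_feature_matrix(features)
  y <- as_label_factor(labels)
  folds <- make_folds(y, n_folds = n_folds, seed = seed)
  b <- hp_bounds()
  evaluate <- function(theta) {
    hp <- hp_decode(theta)
    rep <- cross_validate(x, y, folds = folds, cost = hp$cost,
                          gamma = hp$gamma, coef0 = hp$coef0)
    cv_metric(rep, "accuracy")
  }
  set.seed(seed + 1L)
  n_init <- min(search_budget, 8L)
  design <- matrix(NA_real_, nrow = search_budget, ncol = 3L,
                   dimnames = list(NULL, names(hp_default())))
  design[1L, ] <- hp_default()
  if (n_init > 1L) {
    for (i in 2:n_init) {
      design[i, ] <- vapply(b, function(r) stats::runif(1, r[1], r[2]), 0)
    }
  }
  acc <- rep(NA_real_, search_budget)
  for (i in seq_len(n_init)) acc[i] <- evaluate(design[i, ])
  if (search_budget > n_init) {
    for (i in (n_init + 1L):search_budget) {
      X <- t(apply(design[seq_len(i - 1L), , drop = FALSE], 1L, hp_to_unit))
      cand <- matrix(stats::runif(500 * 3), ncol = 3L)
      ei <- gp_expected_improvement(X, acc[seq_len(i - 1L)], cand)
      u <- cand[which.max(ei), ]
      design[i, ] <- vapply(seq_along(b), function(j)
        b[[j]][1] + u[j] * diff(b[[j]]), 0)
      acc[i] <- evaluate(design[i, ])
    }
  }
  # best accuracy; ties toward smaller cost
  ord <- order(-acc, design[, "log10_cost"])
  best <- ord[1L]
  hp <- hp_decode(design[best, ])
  model <- fit_foldswitch_svm(x, y, cost = hp$cost, gamma = hp$gamma,
                              coef0 = hp$coef0)
  attr(model, "cv_accuracy") <- acc[best]
  attr(model, "search_history") <- data.frame(design, cv_accuracy = acc)
  model
}
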