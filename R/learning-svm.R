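## Multiclass support vector machine with a radial basis kernel.
## Binary C-SVC subproblems are solved by sequential minimal optimization
## (maximal-violating-pair working-set selection, as in standard SMO
## implementations); the multiclass decision follows the one-vs-one voting
## contract.  Everything is deterministic.

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

## SMO for one binary problem; y in {-1, +1}.
smo_binary <- function(K, y, C, tol = 1e-6, max_iter = 20000) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)     # gradient of the dual objective wrt alpha
  for (it in seq_len(max_iter)) {
    ## maximal violating pair over  y_i alpha_i  box constraints
    Iup <- which((y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12))
    Ilow <- which((y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12))
    gy <- -y * grad
    i <- Iup[which.max(gy[Iup])]
    j <- Ilow[which.min(gy[Ilow])]
    if (length(i) == 0 || length(j) == 0 || gy[i] - gy[j] < tol) break
    ## analytic two-variable update
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    quad <- max(quad, 1e-12)
    delta <- (gy[i] - gy[j]) / quad
    ## step in terms of t where alpha_i += y_i t, alpha_j -= y_j t
    t_max_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_step <- min(delta, t_max_i, t_max_j)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * y * (K[, i] - K[, j])
  }
  ## bias from margin support vectors (fallback: midpoint of bounds)
  on_margin <- alpha > 1e-8 & alpha < C - 1e-8
  fx <- as.numeric(K %*% (alpha * y))
  b <- if (any(on_margin)) mean(y[on_margin] - fx[on_margin]) else {
    up <- min((y - fx)[(y > 0 & alpha < C - 1e-8) | (y < 0 & alpha > 1e-8)])
    lo <- max((y - fx)[(y > 0 & alpha > 1e-8) | (y < 0 & alpha < C - 1e-8)])
    (up + lo) / 2
  }
  list(alpha = alpha, b = b)
}

#' Fit a multiclass RBF support vector machine
#'
#' One-vs-one C-SVC with an RBF kernel; ties in the vote resolve to the
#' smallest class label.
#'
#' @param X feature matrix (samples x features).
#' @param y class labels (integer or factor); every class needs >= 1 sample
#'   and at least two classes must be present.
#' @param C soft-margin cost (default 1).
#' @param gamma kernel width; default `1 / (ncol(X) * var(X))` (the "scale"
#'   convention).
#' @return object of class `svm_model`.
#' @export
fit_svm <- function(X, y, C = 1, gamma = NULL) {
  X <- as.matrix(X)
  y <- as.integer(factor(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) bspim_error("single-class input", "bspim_training_error")
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(X))
    gamma <- 1 / (ncol(X) * ifelse(v > 0, v, 1))
  }
  pairs <- utils::combn(classes, 2)
  machines <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    c1 <- pairs[1, p]; c2 <- pairs[2, p]
    idx <- which(y %in% c(c1, c2))
    yy <- ifelse(y[idx] == c1, 1, -1)
    K <- rbf_kernel(X[idx, , drop = FALSE], X[idx, , drop = FALSE], gamma)
    sol <- smo_binary(K, yy, C)
    machines[[p]] <- list(idx = idx, coef = sol$alpha * yy, b = sol$b,
                          c1 = c1, c2 = c2)
  }
  structure(list(X = X, y = y, classes = classes, gamma = gamma, C = C,
                 machines = machines, levels = levels(factor(y))),
            class = "svm_model")
}

#' Predict classes with a fitted SVM
#' @param object an `svm_model`; @param newdata matrix of samples; @param ... unused.
#' @return integer class labels.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0L, nrow(newdata), length(object$classes))
  for (m in object$machines) {
    Kx <- rbf_kernel(newdata, object$X[m$idx, , drop = FALSE], object$gamma)
    f <- as.numeric(Kx %*% m$coef) + m$b
    win <- ifelse(f >= 0, m$c1, m$c2)
    votes[cbind(seq_len(nrow(newdata)), win)] <-
      votes[cbind(seq_len(nrow(newdata)), win)] + 1L
  }
  ## ties resolve to the smallest class label
  apply(votes, 1, which.max)
}

## Deterministic stratified fold assignment: per class (seeded shuffle),
## each sample goes to the fold currently lightest in that class, ties by
## total fold size then fold index.
stratified_folds <- function(y, n_folds, seed) {
  n <- length(y)
  folds <- integer(n)
  class_counts <- matrix(0L, n_folds, length(unique(y)))
  colnames(class_counts) <- as.character(sort(unique(y)))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        cc <- class_counts[, as.character(cl)]
        tot <- rowSums(class_counts)
        f <- order(cc, tot, seq_len(n_folds))[1]
        folds[i] <- f
        class_counts[f, as.character(cl)] <- class_counts[f, as.character(cl)] + 1L
      }
    }
  })
  folds
}

#' Stratified N-fold cross-validation of the SVM classifier
#'
#' Folds preserve per-class proportions to within one sample; every sample is
#' tested exactly once; the final score is the mean of the fold accuracies.
#'
#' @param features `feature_matrix` or plain matrix.
#' @param labels cluster labels (one per sample).
#' @param n_folds number of folds (default 4: 75%/25% train/test splits).
#' @param seed fold-assignment seed.
#' @param C,gamma SVM hyperparameters (see [fit_svm()]).
#' @return object of class `classifier_report`: `k`, `fold_accuracy`,
#'   `mean_accuracy`, `confusion`, `misclassified` (ids or indices),
#'   `predicted`, `folds`, `seed`.
#' @export
stratified_cv <- function(features, labels, n_folds = 4, seed = 0,
                          C = 1, gamma = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$X else as.matrix(features)
  ids <- if (inherits(features, "feature_matrix")) features$ids else
    as.character(seq_len(nrow(X)))
  y <- as.integer(factor(labels))
  n <- nrow(X)
  if (n_folds > n) parameter_error("more folds than samples")
  if (n_folds < 2) parameter_error("need at least 2 folds")
  if (min(table(y)) < n_folds)
    warning("some class has fewer samples than folds; stratification degrades")
  folds <- stratified_folds(y, n_folds, seed)
  pred <- integer(n)
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- which(folds == f)
    tr <- setdiff(seq_len(n), te)
    if (length(unique(y[tr])) < 2) {
      pred[te] <- unique(y[tr])[1]
    } else {
      mdl <- fit_svm(X[tr, , drop = FALSE], y[tr], C = C, gamma = gamma)
      ## map internal class indices back to y levels present in training
      map <- sort(unique(y[tr]))
      pred[te] <- map[predict(mdl, X[te, , drop = FALSE])]
    }
    fold_acc[f] <- mean(pred[te] == y[te])
  }
  conf <- table(truth = y, predicted = factor(pred, levels = sort(unique(y))))
  structure(list(
    k = length(unique(y)),
    fold_accuracy = fold_acc,
    mean_accuracy = mean(fold_acc),
    confusion = conf,
    misclassified = ids[pred != y],
    predicted = pred,
    truth = y,
    folds = folds,
    seed = seed
  ), class = "classifier_report")
}

#' Sweep the number of ectopic clusters
#'
#' For each k: cluster, check spatial coherence, run the stratified CV, and
#' summarize.
#'
#' @param features a `feature_matrix`.
#' @param k_range integer vector of cluster counts (within 2..10).
#' @param algorithm clustering algorithm (see [cluster_bspims()]).
#' @param cluster_seed,cv_seed seeds for the two stages.
#' @param n_folds CV folds.
#' @param m_neighbors coherence neighborhood.
#' @return data.frame (class `sweep_summary`) with one row per k: `k`,
#'   `coherent`, `cv_accuracy`, `misclassified` (comma-separated ids); the
#'   full reports are in attribute `reports`.
#' @export
sweep_k <- function(features, k_range = 2:6, algorithm = "kmeans",
                    cluster_seed = 0, cv_seed = 0, n_folds = 4,
                    m_neighbors = 5) {
  if (any(k_range < 2 | k_range > 10))
    parameter_error("k_range must lie within [2, 10]")
  rows <- list(); reports <- list()
  for (k in k_range) {
    cm <- cluster_bspims(features, k, algorithm = algorithm, seed = cluster_seed)
    coh <- spatial_coherence(cm, features, m_neighbors)
    rep_k <- stratified_cv(features, cm$labels, n_folds = n_folds, seed = cv_seed)
    rows[[length(rows) + 1]] <- data.frame(
      k = k, coherent = coh$verdict, cv_accuracy = rep_k$mean_accuracy,
      misclassified = paste(rep_k$misclassified, collapse = ","))
    reports[[as.character(k)]] <- list(cluster = cm, coherence = coh, cv = rep_k)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  class(out) <- c("sweep_summary", "data.frame")
  out
}
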