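## Clustering of BSPiM feature vectors into ectopic clusters (ECs) and
## validation of their spatial coherence on the atria.

#' Assemble the feature matrix from a set of integral maps
#'
#' @param maps list of `bspim_map` (normalized via [normalize_set()] unless
#'   `use_normalized = FALSE`).
#' @param catalog the `foci_catalog` (row order).
#' @param mesh the mesh (for focus centers).
#' @param use_normalized use normalized values (default) or raw integrals.
#' @return object of class `feature_matrix`: `X` (foci x leads), `ids`,
#'   `centers` (foci x 3, mm), `atrium`.
#' @export
feature_matrix <- function(maps, catalog, mesh, use_normalized = TRUE) {
  ids <- unname(vapply(maps, function(m) m$focus, character(1)))
  if (!identical(ids, catalog$id))
    schema_error("map set is not aligned with the catalog")
  X <- t(vapply(maps, function(m) {
    v <- if (use_normalized) m$normalized else m$values
    if (anyNA(v)) schema_error("normalize the map set first (or use raw values)")
    v
  }, numeric(length(maps[[1]]$values))))
  structure(list(X = X, ids = ids, centers = foci_centers(mesh, catalog),
                 atrium = catalog$atrium),
            class = "feature_matrix")
}

## k-means++ seeding (deterministic given the RNG state).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- d2 / sum(d2)
    centers[j] <- sample.int(n, 1, prob = prob)
    d2j <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  X[centers, , drop = FALSE]
}

## Diagonal-covariance Gaussian-mixture EM in a PCA-reduced space.
gmm_em <- function(X, k, seed, n_dim = 8, max_iter = 200, tol = 1e-8) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  d <- min(n_dim, ncol(pc$x), nrow(X) - 1)
  Z <- pc$x[, seq_len(d), drop = FALSE]
  n <- nrow(Z)
  km <- with_seed(seed, kmeans_restarts(Z, k, n_init = 5))
  lab <- km$cluster
  mu <- t(vapply(seq_len(k), function(j) colMeans(Z[lab == j, , drop = FALSE]),
                 numeric(d)))
  sg <- t(vapply(seq_len(k), function(j) {
    v <- apply(Z[lab == j, , drop = FALSE], 2, stats::var)
    v[!is.finite(v)] <- 1
    pmax(v, 1e-6)
  }, numeric(d)))
  pi_k <- tabulate(lab, k) / n
  ll_old <- -Inf
  warned <- FALSE
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j) {
      -0.5 * rowSums(sweep(Z, 2, mu[j, ])^2 / matrix(sg[j, ], n, d, byrow = TRUE)) -
        0.5 * sum(log(2 * pi * sg[j, ])) + log(pmax(pi_k[j], 1e-12))
    }, numeric(n))
    m <- apply(logp, 1, max)
    post <- exp(logp - m)
    tot <- rowSums(post)
    post <- post / tot
    ll <- sum(m + log(tot))
    nk <- colSums(post)
    if (any(nk < 1e-8)) { warned <- TRUE; nk <- pmax(nk, 1e-8) }
    pi_k <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(post[, j] * Z) / nk[j]
      v <- colSums(post[, j] * sweep(Z, 2, mu[j, ])^2) / nk[j]
      if (any(v < 1e-8)) warned <- TRUE
      sg[j, ] <- pmax(v, 1e-8)
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  if (warned) warning("EM covariance regularization applied")
  list(labels = apply(post, 1, which.max), means = mu, vars = sg,
       weights = pi_k, loglik = ll, projection = pc, n_dim = d)
}

## Lloyd k-means from k-means++ seeds, best of n_init restarts by inertia.
kmeans_restarts <- function(X, k, n_init = 10) {
  best <- NULL
  for (r in seq_len(n_init)) {
    cen <- kmeanspp_centers(X, k)
    km <- suppressWarnings(stats::kmeans(X, centers = cen,
                                         iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Cluster BSPiM feature vectors into ectopic clusters
#'
#' @param features a `feature_matrix` (or plain matrix).
#' @param k number of clusters (1 allowed for testing; 2..10 typical).
#' @param algorithm `"kmeans"` (k-means++ seeding, Lloyd iterations, best of
#'   `n_init` restarts by inertia) or `"em"` (diagonal Gaussian mixture in a
#'   PCA-reduced space, maximum-posterior labels).
#' @param seed RNG seed (results are reproducible given the seed).
#' @param n_init restarts for k-means.
#' @return object of class `cluster_model`: `k`, `algorithm`, `labels`
#'   (1-based), `centroids` or `means`/`vars`, `inertia` or `loglik`, `seed`.
#' @export
cluster_bspims <- function(features, k, algorithm = c("kmeans", "em"),
                           seed = 0, n_init = 10) {
  algorithm <- match.arg(algorithm)
  X <- if (inherits(features, "feature_matrix")) features$X else features
  if (k > nrow(X)) parameter_error("k exceeds the number of samples")
  if (k < 1) parameter_error("k must be >= 1")
  if (any(!is.finite(X))) validation_error("non-finite feature values")
  if (algorithm == "kmeans") {
    if (k == 1) {
      cen <- colMeans(X)
      inertia <- sum(sweep(X, 2, cen)^2)
      out <- list(k = k, algorithm = algorithm, labels = rep(1L, nrow(X)),
                  centroids = matrix(cen, 1), inertia = inertia, seed = seed)
    } else {
      km <- with_seed(seed, kmeans_restarts(X, k, n_init))
      out <- list(k = k, algorithm = algorithm, labels = km$cluster,
                  centroids = km$centers, inertia = km$tot.withinss, seed = seed)
    }
  } else {
    if (k == 1) {
      out <- list(k = k, algorithm = algorithm, labels = rep(1L, nrow(X)),
                  loglik = NA_real_, seed = seed)
    } else {
      em <- gmm_em(X, k, seed)
      out <- list(k = k, algorithm = algorithm, labels = em$labels,
                  means = em$means, vars = em$vars, loglik = em$loglik,
                  seed = seed)
    }
  }
  if (length(unique(out$labels)) < k)
    warning("clustering produced an empty cluster")
  class(out) <- "cluster_model"
  out
}

#' Adjusted Rand index between two labelings
#' @param a,b integer label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Spatial coherence of ectopic clusters on the atria
#'
#' For each focus, the fraction of its `m` nearest foci (3-D Euclidean)
#' sharing its cluster label; per-cluster purity is the mean over members.
#' A focus whose neighborhood is majority-foreign raises an overlap flag for
#' the pair of clusters involved; the global verdict is `TRUE` iff no flag is
#' set.
#'
#' @param model a `cluster_model`.
#' @param features the `feature_matrix` (for focus centers).
#' @param m_neighbors neighborhood size (default 5).
#' @return object of class `coherence_report`: `purity` (per cluster),
#'   `focus_purity`, `overlap_pairs`, `verdict`.
#' @export
spatial_coherence <- function(model, features, m_neighbors = 5) {
  centers <- features$centers
  n <- nrow(centers)
  if (m_neighbors >= n) parameter_error("m_neighbors must be < n_samples")
  lab <- model$labels
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  focus_purity <- numeric(n)
  overlap <- list()
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(m_neighbors)]
    focus_purity[i] <- mean(lab[nb] == lab[i])
    tb <- table(lab[nb])
    top <- as.integer(names(which.max(tb)))
    if (top != lab[i] && max(tb) > m_neighbors / 2) {
      overlap[[length(overlap) + 1]] <- sort(c(lab[i], top))
    }
  }
  purity <- vapply(sort(unique(lab)), function(j) mean(focus_purity[lab == j]),
                   numeric(1))
  overlap_pairs <- unique(do.call(rbind, overlap))
  structure(list(purity = purity, focus_purity = focus_purity,
                 overlap_pairs = overlap_pairs,
                 verdict = is.null(overlap_pairs) || nrow(overlap_pairs) == 0),
            class = "coherence_report")
}
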