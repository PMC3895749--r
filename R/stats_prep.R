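#' Min-max standardization to \[0, 1\]
#'
#' Rescales every column of a numeric table to the unit interval,
#' x' = (x - min) / (max - min), recording the per-variable bounds so the
#' transform can be inverted. Constant columns map to 0 everywhere (keeping
#' output in range and making the degeneracy visible).
#'
#' @param x Numeric matrix or data frame with at least 2 rows.
#' @return A list of class `"minmax_scaled"`: `values` (data frame of scaled
#'   values), `min`, `max` (named numeric vectors).
#' @seealso [minmax_invert()]
#' @export
minmax_standardize <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  mins <- vapply(x, min, numeric(1))
  maxs <- vapply(x, max, numeric(1))
  values <- as.data.frame(Map(function(col, lo, hi) {
    if (hi > lo) (col - lo) / (hi - lo) else rep(0, length(col))
  }, x, mins, maxs))
  names(values) <- names(x)
  rownames(values) <- rownames(x)
  structure(list(values = values, min = mins, max = maxs),
            class = "minmax_scaled")
}

#' Invert a min-max standardization
#'
#' @param scaler A `"minmax_scaled"` object holding the fitted bounds.
#' @param values Scaled values: a data frame/matrix with columns named as in
#'   the scaler, or a numeric vector together with `variable`.
#' @param variable Column name, required when `values` is a bare vector.
#' @return Values on the original scale. Constant columns invert to their
#'   stored minimum.
#' @export
minmax_invert <- function(scaler, values, variable = NULL) {
  stopifnot(inherits(scaler, "minmax_scaled"))
  inv1 <- function(v, name) {
    if (!name %in% names(scaler$min)) {
      stop("unknown variable: ", name, call. = FALSE)
    }
    lo <- scaler$min[[name]]
    hi <- scaler$max[[name]]
    if (hi > lo) lo + v * (hi - lo) else rep(lo, length(v))
  }
  if (is.null(variable)) {
    values <- as.data.frame(values)
    out <- as.data.frame(Map(inv1, values, names(values)))
    names(out) <- names(values)
    out
  } else {
    inv1(values, variable)
  }
}

#' Pearson correlation matrix with constant-column guard
#'
#' @param x Numeric matrix or data frame, at least 3 rows, no constant column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(x) {
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) stop("correlation input must be numeric", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 rows for correlations", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("correlation undefined for constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cor(x)
}

#' Drop collinear variables by priority
#'
#' For every variable pair with |r| at or above `threshold`, removes the
#' lower-priority member, so the returned set has no remaining pair at or
#' above the threshold. Used to discard TDS in favour of EC when the two are
#' perfectly correlated.
#'
#' @param corr Correlation matrix with dimnames.
#' @param threshold Absolute-correlation cutoff in (0, 1\] (default 0.95).
#' @param keep_priority Character vector; earlier names win conflicts.
#'   Variables absent from it rank below all listed ones. Defaults to the
#'   column order of `corr`.
#' @return Character vector of retained variable names, in original order.
#' @export
drop_collinear <- function(corr, threshold = 0.95,
                           keep_priority = colnames(corr)) {
  vars <- colnames(corr)
  if (is.null(vars)) stop("correlation matrix must have dimnames", call. = FALSE)
  check_scalar_number(threshold, "threshold", min = 1e-12, max = 1)
  rank <- match(vars, keep_priority)
  rank[is.na(rank)] <- length(keep_priority) + seq_len(sum(is.na(rank)))
  kept <- character(0)
  for (v in vars[order(rank)]) {
    if (!length(kept) || all(abs(corr[v, kept]) < threshold)) {
      kept <- c(kept, v)
    }
  }
  vars[vars %in% kept]
}

# Squared Euclidean distances from each row of X to each center (rows of C).
.sqdist <- function(X, C) {
  d <- matrix(0, nrow(X), nrow(C))
  for (j in seq_len(nrow(C))) {
    d[, j] <- colSums((t(X) - C[j, ])^2)
  }
  d
}

kmeanspp_init <- function(X, k) {
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(nrow(X), 1L), ]
  if (k > 1L) {
    for (j in 2L:k) {
      d2 <- apply(.sqdist(X, centers[seq_len(j - 1L), , drop = FALSE]), 1L, min)
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / nrow(X), nrow(X))
      centers[j, ] <- X[sample.int(nrow(X), 1L, prob = p), ]
    }
  }
  centers
}

#' K-means clustering (Lloyd iterations, k-means++ initialization)
#'
#' Runs Lloyd's algorithm to convergence (no assignment changes) from a
#' k-means++ start, keeping the best of `n_restarts` restarts by total
#' within-cluster squared error. The per-iteration SSE trajectory of the
#' winning restart is retained (it is non-increasing).
#'
#' @param features Numeric matrix or data frame (typically a standardized
#'   feature table); rownames, if any, become sample keys.
#' @param k Number of clusters, `1 <= k <= nrow(features)`.
#' @param seed Integer seed.
#' @param n_restarts Number of independent restarts (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @return A list of class `"kmeans_assignment"`: `cluster` (labels 1..k,
#'   named by sample key), `centers`, `tot_withinss`, `sse_trajectory`, `k`.
#' @export
kmeans_cluster <- function(features, k, seed = 1L, n_restarts = 10L,
                           max_iter = 100L) {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  check_scalar_number(k, "k", min = 1)
  if (k > nrow(X)) {
    stop(sprintf("invalid k: %d clusters requested for %d samples",
                 k, nrow(X)), call. = FALSE)
  }
  k <- as.integer(k)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_init(X, k)
      assign_prev <- rep(0L, nrow(X))
      traj <- numeric(0)
      for (it in seq_len(max_iter)) {
        d2 <- .sqdist(X, centers)
        assign_now <- max.col(-d2, ties.method = "first")
        # re-seed any emptied cluster with the point farthest from its center
        for (j in seq_len(k)) {
          if (!any(assign_now == j)) {
            far <- which.max(d2[cbind(seq_len(nrow(X)), assign_now)])
            assign_now[far] <- j
          }
        }
        traj <- c(traj, sum(d2[cbind(seq_len(nrow(X)), assign_now)]))
        for (j in seq_len(k)) {
          centers[j, ] <- colMeans(X[assign_now == j, , drop = FALSE])
        }
        if (identical(assign_now, assign_prev)) break
        assign_prev <- assign_now
      }
      sse <- sum(.sqdist(X, centers)[cbind(seq_len(nrow(X)), assign_prev)])
      if (is.null(best) || sse < best$tot_withinss) {
        best <- list(cluster = assign_prev, centers = centers,
                     tot_withinss = sse, sse_trajectory = traj)
      }
    }
    names(best$cluster) <- rownames(X)
    structure(c(best, list(k = k)), class = "kmeans_assignment")
  })
}

#' Drop the winter cluster from a 2-means seasonal stratification
#'
#' Identifies the cluster containing the majority of winter samples
#' (December-February by default) and returns the keys of the other cluster —
#' the spring/summer/autumn data carried forward into the regression stage.
#'
#' @param assignment A k = 2 [kmeans_cluster()] result.
#' @param months Integer month (1-12) for each sample, aligned with the
#'   assignment.
#' @param winter_months Months defining winter (default `c(12, 1, 2)`).
#' @return Indices (or sample keys, when the assignment is named) of the
#'   retained, non-winter cluster.
#' @export
exclude_winter_cluster <- function(assignment, months,
                                   winter_months = c(12L, 1L, 2L)) {
  stopifnot(inherits(assignment, "kmeans_assignment"))
  if (assignment$k != 2L) {
    stop("winter exclusion requires a k = 2 assignment, got k = ",
         assignment$k, call. = FALSE)
  }
  if (length(months) != length(assignment$cluster)) {
    stop("'months' must align with the cluster assignment", call. = FALSE)
  }
  winter <- months %in% winter_months
  n1 <- sum(assignment$cluster == 1L & winter)
  n2 <- sum(assignment$cluster == 2L & winter)
  if (n1 == n2) {
    stop("ambiguous season: winter samples split evenly between clusters",
         call. = FALSE)
  }
  keep <- assignment$cluster == (if (n1 > n2) 2L else 1L)
  if (!is.null(names(assignment$cluster))) names(assignment$cluster)[keep]
  else which(keep)
}

#' PCA of the correlation matrix with varimax-rotated loadings
#'
#' Eigen-decomposes the correlation matrix of the feature table (so the
#' analysis is scale-free), reports the explained-variance fraction of every
#' component, and varimax-rotates the loadings of the leading
#' `n_components` components (Kaiser-normalized, the SPSS-style "rotated
#' component matrix"). Rotation preserves per-variable communalities.
#'
#' @param features Numeric matrix or data frame, at least 3 rows.
#' @param n_components Number of components to retain and rotate (default 4).
#' @return A list of class `"pca_varimax"`: `loadings` (all unrotated
#'   loadings, variables x components), `rotated` (variables x
#'   `n_components`), `explained_variance`, `cumulative_variance`.
#' @export
pca_varimax <- function(features, n_components = 4L) {
  X <- as.data.frame(features)
  if (nrow(X) < 3L) stop("insufficient data: PCA needs >= 3 rows", call. = FALSE)
  if (n_components > ncol(X)) {
    stop("n_components exceeds the number of variables", call. = FALSE)
  }
  R <- pearson_correlation_matrix(X)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-magnitude element of each eigenvector positive
  for (j in seq_len(ncol(vecs))) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  loadings <- vecs %*% diag(sqrt(vals), nrow = length(vals))
  dimnames(loadings) <- list(colnames(R), sprintf("PC%d", seq_along(vals)))
  rot <- varimax(loadings[, seq_len(n_components), drop = FALSE],
                 normalize = TRUE)
  rotated <- unclass(rot$loadings)
  dimnames(rotated) <- list(colnames(R), sprintf("PC%d", seq_len(n_components)))
  structure(list(
    loadings = loadings,
    rotated = rotated,
    explained_variance = vals / sum(vals),
    cumulative_variance = cumsum(vals / sum(vals))
  ), class = "pca_varimax")
}

#' Seeded train/validation split of sample keys
#'
#' @param keys Vector of sample keys (length >= 2).
#' @param fraction Training fraction in (0, 1); the paper's protocol uses 0.8.
#' @param seed Integer seed.
#' @return A list with `train` and `validation` keys: disjoint, exhaustive,
#'   with `length(train) == round(fraction * n)`.
#' @export
train_validation_split <- function(keys, fraction = 0.8, seed = 1L) {
  n <- length(keys)
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  check_scalar_number(fraction, "fraction", min = 1e-12, max = 1 - 1e-12)
  n_train <- round(fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop(sprintf("invalid split: %d train / %d validation", n_train,
                 n - n_train), call. = FALSE)
  }
  with_seed(seed, {
    idx <- sample.int(n, n_train)
    list(train = keys[sort(idx)], validation = keys[-sort(idx)])
  })
}
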