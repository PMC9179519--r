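#' k-nearest-neighbour Gaussian affinity matrix
#'
#' Features are z-scored per column before Euclidean distances are taken.
#' `W[i,j] = exp(-d_ij^2 / width^2)` when j is among i's k nearest
#' neighbours or vice versa, else 0; the diagonal is zero and the matrix
#' is exactly symmetric.
#'
#' @param X cases x features numeric matrix.
#' @param k_neighbors neighbourhood size (must be < number of cases).
#' @param kernel_width positive bandwidth, or `"auto"` for the median
#'   pairwise distance over the retained k-NN edges.
#' @param standardize z-score columns first (constant columns drop to 0).
#' @return symmetric nonnegative affinity matrix.
#' @export
build_affinity <- function(X, k_neighbors = 10L, kernel_width = "auto",
                           standardize = TRUE) {
  n <- nrow(X)
  if (k_neighbors >= n)
    stop("build_affinity: k_neighbors must be smaller than the number of cases")
  if (standardize) X <- zscore_cols(X)$X
  d <- as.matrix(stats::dist(X))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])        # indices into the vector without i
    nb <- seq_len(n)[-i][nb[seq_len(k_neighbors)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  if (identical(kernel_width, "auto")) {
    ed <- d[adj]
    kernel_width <- stats::median(ed)
    if (!is.finite(kernel_width) || kernel_width <= 0) kernel_width <- 1
  }
  W <- matrix(0, n, n)
  W[adj] <- exp(-d[adj]^2 / kernel_width^2)
  diag(W) <- 0
  attr(W, "kernel_width") <- kernel_width
  attr(W, "k_neighbors") <- k_neighbors
  W
}

zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
}

graph_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(W[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Laplacian eigenmaps embedding from an affinity matrix
#'
#' Solves the generalized eigenproblem `L v = lambda D v` with
#' `L = D - W` and returns the eigenvectors of the smallest nontrivial
#' eigenvalues (the constant eigenvector at lambda ~ 0 is excluded).  If
#' the graph is disconnected a small ridge (1e-8) is added to all
#' off-diagonal affinities, with a warning, so the problem stays
#' well-posed.  Sign convention: each eigenvector's largest-magnitude
#' entry is positive.
#'
#' @param W symmetric nonnegative affinity matrix.
#' @param n_components embedding width (default 12); must be smaller than
#'   `nrow(W) - 1`.
#' @return object of class `spectral_embedding`: list with `embedding`
#'   (cases x n_components), `eigenvalues` (ascending, including the
#'   trivial one), `n_components`.
#' @export
laplacian_eigenmaps <- function(W, n_components = 12L) {
  n <- nrow(W)
  if (n_components >= n - 1L)
    stop("laplacian_eigenmaps: n_components must be < n_cases - 1")
  if (!graph_connected(W)) {
    warning("laplacian_eigenmaps: affinity graph is disconnected; ",
            "adding a 1e-8 ridge to all affinities")
    W <- W + 1e-8
    diag(W) <- 0
  }
  deg <- rowSums(W)
  L <- diag(deg) - W
  ds <- 1 / sqrt(deg)
  S <- L * outer(ds, ds)          # D^{-1/2} L D^{-1/2}
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values)          # ascending
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE] * ds  # back-transform to L v = l D v
  emb <- vecs[, 2:(n_components + 1L), drop = FALSE]
  for (j in seq_len(ncol(emb))) {
    m <- which.max(abs(emb[, j]))
    if (emb[m, j] < 0) emb[, j] <- -emb[, j]
  }
  structure(list(embedding = emb, eigenvalues = vals,
                 n_components = as.integer(n_components)),
            class = "spectral_embedding")
}

#' Fit a spectral embedding of a radiomic matrix
#'
#' Convenience wrapper: z-scores the feature matrix, builds the k-NN
#' Gaussian affinity, and runs Laplacian eigenmaps.  The returned object
#' supports out-of-sample embedding of new cases via [predict()] using the
#' Nystrom-style weighted average of training embeddings (the standard
#' remedy — note that a left-out case embedded this way never influences
#' the training embedding).
#'
#' @param X cases x features matrix (e.g. the 354-wide radiomic panel).
#' @param n_components embedding width; default 12.
#' @param k_neighbors,kernel_width see [build_affinity()].
#' @return a `spectral_embedding` with the training matrix statistics
#'   attached for out-of-sample use.
#' @export
spectral_embed <- function(X, n_components = 12L, k_neighbors = 10L,
                           kernel_width = "auto") {
  z <- zscore_cols(X)
  W <- build_affinity(z$X, k_neighbors, kernel_width, standardize = FALSE)
  fit <- laplacian_eigenmaps(W, n_components)
  fit$mu <- z$mu; fit$sd <- z$sd; fit$Xs <- z$X
  fit$kernel_width <- attr(W, "kernel_width")
  fit$k_neighbors <- k_neighbors
  fit
}

#' Embed new cases into a fitted spectral embedding (Nystrom extension)
#'
#' @param object a `spectral_embedding` fitted by [spectral_embed()].
#' @param newdata matrix of new cases on the original feature scale.
#' @param ... unused.
#' @return matrix new-cases x n_components.
#' @export
predict.spectral_embedding <- function(object, newdata, ...) {
  if (is.null(object$Xs))
    stop("predict.spectral_embedding: object was not fitted by spectral_embed()")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  Z <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  out <- matrix(0, nrow(Z), object$n_components)
  for (r in seq_len(nrow(Z))) {
    d2 <- colSums((t(object$Xs) - Z[r, ])^2)
    nb <- order(d2)[seq_len(object$k_neighbors)]
    w <- exp(-d2[nb] / object$kernel_width^2)
    if (sum(w) == 0) w <- rep(1, length(w))
    out[r, ] <- colSums(object$embedding[nb, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' Elbow selection of the embedding dimension
#'
#' Returns the index maximising the perpendicular distance from the
#' eigenvalue curve to the chord joining its endpoints (kneedle-style).
#' Ties within 1e-12 resolve to the smaller count, so a perfectly linear
#' spectrum yields 1.
#'
#' @param eigenvalues nontrivial eigenvalues in ascending order (>= 3).
#' @return integer component count.
#' @export
elbow_select <- function(eigenvalues) {
  m <- length(eigenvalues)
  if (m < 3L) stop("elbow_select: need at least 3 eigenvalues")
  x <- seq_len(m); y <- eigenvalues
  x1 <- x[1]; y1 <- y[1]; x2 <- x[m]; y2 <- y[m]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / len
  best <- which(dist > max(dist) - 1e-12)[1]
  as.integer(best)
}
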