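test_that("affinity matrix follows the k-NN Gaussian kernel contract", {
  X <- matrix(1, 3, 4)          # three identical points
  W <- build_affinity(X, k_neighbors = 2L)
  expect_equal(unname(W[upper.tri(W)]), rep(1, 3))
  expect_equal(unname(diag(W)), rep(0, 3))

  set.seed(2)
  X2 <- matrix(rnorm(15 * 5), 15, 5)
  W2 <- build_affinity(X2, k_neighbors = 4L)
  expect_identical(W2, t(W2))

  # 10 points on a line: nonzero pattern equals the brute-force k-NN union
  xline <- matrix(c(1, 2, 4, 7, 11, 16, 22, 29, 37, 46), ncol = 1)
  W3 <- build_affinity(xline, k_neighbors = 2L, standardize = FALSE)
  d <- as.matrix(dist(scale(xline)))
  adj <- matrix(FALSE, 10, 10)
  for (i in 1:10) {
    nb <- setdiff(order(d[i, ]), i)[1:2]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  expect_identical(unname(W3 > 0), adj)
  expect_error(build_affinity(X2, k_neighbors = 15L), "smaller")
})

test_that("eigenmaps solve the generalized problem (dense oracle, 1e-8)", {
  for (n in c(20L, 50L)) {
    set.seed(n)
    X <- matrix(rnorm(n * 8), n, 8)
    W <- build_affinity(X, k_neighbors = 5L)
    fit <- laplacian_eigenmaps(W, n_components = 5L)
    deg <- rowSums(W)
    L <- diag(deg) - W
    ev <- eigen(solve(diag(deg)) %*% L)   # dense non-symmetric oracle
    ord <- order(Re(ev$values))
    expect_lt(fit$eigenvalues[1], 1e-8)   # trivial eigenvalue ~ 0
    expect_false(is.unsorted(fit$eigenvalues))
    for (j in 1:5) {
      v <- Re(ev$vectors[, ord[j + 1]])
      m <- which.max(abs(v)); if (v[m] < 0) v <- -v
      v <- v / sqrt(sum(v^2))
      u <- fit$embedding[, j] / sqrt(sum(fit$embedding[, j]^2))
      expect_lt(max(abs(u - v)), 1e-8)
    }
  }
})

test_that("zero-eigenvalue multiplicity counts connected components", {
  blocks <- function(sizes) {
    n <- sum(sizes)
    W <- matrix(0, n, n)
    at <- 0
    for (s in sizes) { W[at + 1:s, at + 1:s] <- 1; at <- at + s }
    diag(W) <- 0
    W
  }
  graph_comps <- function(A) { # BFS component oracle on the adjacency
    n <- nrow(A); seen <- logical(n); k <- 0L
    for (i in seq_len(n)) {
      if (seen[i]) next
      k <- k + 1L; q <- i; seen[i] <- TRUE
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        nb <- which(A[v, ] > 0 & !seen)
        seen[nb] <- TRUE; q <- c(q, nb)
      }
    }
    k
  }
  for (sizes in list(c(5, 5), c(4, 4, 4))) {
    W <- blocks(sizes)
    fit <- suppressWarnings(laplacian_eigenmaps(W, 1L))
    expect_equal(sum(fit$eigenvalues < 1e-6), graph_comps(W))
  }
  # first nontrivial eigenvector separates two cliques by sign
  W <- blocks(c(5, 5))
  fit <- suppressWarnings(laplacian_eigenmaps(W, 1L))
  s1 <- sign(fit$embedding[1:5, 1]); s2 <- sign(fit$embedding[6:10, 1])
  expect_true(all(s1 == s1[1]) && all(s2 == s2[1]) && s1[1] != s2[1])
  expect_error(laplacian_eigenmaps(W, 9L), "n_components")
})

test_that("embedding rows permute with the cases", {
  set.seed(9)
  X <- matrix(rnorm(25 * 6), 25, 6)
  f1 <- spectral_embed(X, n_components = 3L, k_neighbors = 5L)
  perm <- sample(25)
  f2 <- spectral_embed(X[perm, ], n_components = 3L, k_neighbors = 5L)
  expect_equal(f2$embedding, f1$embedding[perm, ], tolerance = 1e-8)
})

test_that("default reduction yields a 12-wide embedding from 354 features", {
  set.seed(3)
  X <- matrix(rnorm(40 * 354), 40, 354)
  fit <- spectral_embed(X)
  expect_identical(dim(fit$embedding), c(40L, 12L))
  # Nystrom re-embedding of a training case stays near its own row
  back <- predict(fit, X[7, , drop = FALSE])
  ref <- sqrt(mean(fit$embedding^2))
  expect_lt(sqrt(mean((back - fit$embedding[7, ])^2)), ref)
})

test_that("elbow picks the maximum chord distance, ties to smaller counts", {
  expect_identical(elbow_select(c(0.01, 0.02, 0.03, 1.0, 1.01, 1.02)), 3L)
  expect_identical(elbow_select(seq(0.2, 1.6, by = 0.2)), 1L)
  spectrum <- c(seq(0.01, 0.12, by = 0.01), seq(1, 1.8, by = 0.1))
  expect_identical(elbow_select(spectrum), 12L)
  # chord oracle recomputed explicitly
  x <- seq_along(spectrum); y <- spectrum
  d <- abs((y[length(y)] - y[1]) * x - (x[length(x)] - x[1]) * y +
             x[length(x)] * y[1] - y[length(y)] * x[1])
  expect_identical(which.max(d), 12L)
  expect_error(elbow_select(c(1, 2)), "at least 3")
})
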