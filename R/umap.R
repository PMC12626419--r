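#' @name umap_embed
#' @title UMAP embedding (package implementation)
#'
#' @description
#' A compact implementation of Uniform Manifold Approximation and
#' Projection for moderate sample sizes (hundreds to a few thousand
#' points), written for the syllable-labeling stage: exact k-nearest
#' neighbours from the Gram matrix, the standard fuzzy simplicial set
#' construction (per-point connectivity radius `rho` and bandwidth `sigma`
#' calibrated to `log2(k)`), PCA initialization scaled to the usual 10-unit
#' extent, and batch gradient optimization of the cross-entropy layout with
#' negative sampling. All randomness flows from `seed`, so embeddings are
#' reproducible.
#'
#' @param X Numeric matrix, one row per observation.
#' @param n_components Output dimensionality (default 2).
#' @param n_neighbors Neighbourhood size (default 30, suited to clustering).
#' @param min_dist Minimum inter-point distance in the layout (default 0.0,
#'   suited to density-based clustering downstream).
#' @param spread Layout scale parameter (default 1).
#' @param n_epochs Optimization epochs (default 200).
#' @param learning_rate Initial SGD step size.
#' @param negative_rate Negative samples per positive edge per epoch.
#' @param seed Integer seed controlling all randomness.
#' @return Matrix `nrow(X) x n_components` of embedding coordinates.
#' @export
umap_embed <- function(X, n_components = 2L, n_neighbors = 30L,
                       min_dist = 0.0, spread = 1.0, n_epochs = 200L,
                       learning_rate = 1.0, negative_rate = 5L, seed = 42L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 points to embed", call. = FALSE)
  k <- min(n_neighbors, n - 1L)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  D <- .gram_dist(X)
  # --- fuzzy simplicial set -------------------------------------------------
  target <- log2(k)
  rows <- integer(0); cols <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])
    nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
    d <- D[i, nb]
    rho <- min(d[d > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    sigma <- .calibrate_sigma(d, rho, target)
    wi <- exp(-pmax(d - rho, 0) / sigma)
    rows <- c(rows, rep.int(i, k)); cols <- c(cols, nb); w <- c(w, wi)
  }
  W <- matrix(0, n, n)
  W[cbind(rows, cols)] <- w
  W <- W + t(W) - W * t(W)          # probabilistic t-conorm symmetrization
  edge <- which(upper.tri(W) & W > 1e-8, arr.ind = TRUE)
  ew <- W[edge]
  if (nrow(edge) == 0L) stop("degenerate neighbourhood graph", call. = FALSE)

  ab <- .fit_ab(spread, min_dist)
  a <- ab[1]; b <- ab[2]

  # --- initialization: PCA scaled to a 10-unit extent ----------------------
  Y <- .pca_scores(X, n_components)
  ext <- max(apply(Y, 2, function(c) diff(range(c))), 1e-9)
  Y <- Y / ext * 10
  Y <- Y + matrix(stats::rnorm(n * n_components, sd = 1e-4), n)

  # --- layout optimization --------------------------------------------------
  i1 <- edge[, 1]; i2 <- edge[, 2]
  p_keep <- ew / max(ew)
  for (epoch in seq_len(n_epochs)) {
    alpha <- learning_rate * (1 - (epoch - 1) / n_epochs)
    live <- which(stats::runif(length(ew)) < p_keep)
    if (length(live) == 0L) next
    ia <- i1[live]; ib <- i2[live]
    diffs <- Y[ia, , drop = FALSE] - Y[ib, , drop = FALSE]
    d2 <- rowSums(diffs^2)
    coeff <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
    coeff[d2 <= 0] <- 0
    g <- pmax(pmin(coeff * diffs, 4), -4)
    upd <- rowsum(rbind(g, -g), c(ia, ib))
    idx <- as.integer(rownames(upd))
    Y[idx, ] <- Y[idx, ] + alpha * upd
    # negative sampling: repulsion from random points
    nneg <- negative_rate
    ian <- rep(ia, nneg)
    ibn <- sample.int(n, length(ian), replace = TRUE)
    diffs <- Y[ian, , drop = FALSE] - Y[ibn, , drop = FALSE]
    d2 <- rowSums(diffs^2)
    coeff <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
    g <- pmax(pmin(coeff * diffs, 4), -4)
    g[d2 <= 0, ] <- 0
    upd <- rowsum(g, ian)
    idx <- as.integer(rownames(upd))
    Y[idx, ] <- Y[idx, ] + alpha * upd
  }
  unname(Y)
}

# pairwise Euclidean distances via the Gram matrix (fast for wide X)
.gram_dist <- function(X) {
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, `+`) - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}

# binary search for the smooth-kNN bandwidth
.calibrate_sigma <- function(d, rho, target, n_iter = 64) {
  lo <- 1e-12; hi <- max(d) + 1
  mid <- 1
  for (it in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    s <- sum(exp(-pmax(d - rho, 0) / mid))
    if (abs(s - target) < 1e-5) break
    if (s > target) hi <- mid else lo <- mid
  }
  mid
}

# least-squares fit of 1/(1 + a d^(2b)) to the min_dist/spread target curve
.fit_ab <- function(spread, min_dist) {
  xv <- seq(0, spread * 3, length.out = 300)[-1]
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * xv^(2 * b)) - yv)^2)
  }
  fit <- stats::optim(c(log(1.6), log(0.9)), obj, method = "Nelder-Mead")
  exp(fit$par)
}

# top-k principal component scores via the Gram matrix (no d x d work)
.pca_scores <- function(X, k) {
  Xc <- sweep(X, 2, colMeans(X))
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  k <- min(k, sum(eg$values > 1e-9))
  if (k < 1L) return(matrix(stats::rnorm(nrow(X) * 2, sd = 1e-3), nrow(X)))
  sc <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)
  sc
}
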