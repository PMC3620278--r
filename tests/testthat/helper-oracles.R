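# Independent oracles and fixture builders used across the test files.

# Patristic distances by a route independent of cophenetic(): root-to-tip
# depths and most recent common ancestors,
# d(i, j) = depth(i) + depth(j) - 2 * depth(mrca(i, j)).
patristic_oracle <- function(tree) {
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  anc <- ape::mrca(tree)
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d[i, j] <- d[j, i] <- depth[i] + depth[j] - 2 * depth[anc[i, j]]
    }
  }
  d
}

# Brute-force 2-D Procrustes oracle: minimize ||X - c Y R||^2 over a fine
# grid of rotation angles, both reflection states, with the closed-form
# optimal non-negative scale for each candidate rotation.
grid_oracle_m2 <- function(X, Y, n_theta = 400000) {
  stopifnot(ncol(X) == 2, ncol(Y) == 2)
  theta <- seq(0, 2 * pi, length.out = n_theta)
  trX2 <- sum(X^2)
  best <- Inf
  for (flip in c(FALSE, TRUE)) {
    Yf <- if (flip) Y %*% diag(c(1, -1)) else Y
    trY2 <- sum(Yf^2)
    M <- crossprod(Yf, X)                      # tr(R'M) = A cos + B sin
    tr <- (M[1, 1] + M[2, 2]) * cos(theta) + (M[2, 1] - M[1, 2]) * sin(theta)
    best <- min(best, trX2 - pmax(tr, 0)^2 / trY2)
  }
  best
}

# Smallest additive constant making a dissimilarity matrix Euclidean,
# found by bisection on the Euclidean-embeddability predicate.
bisect_cailliez <- function(d, tol = 1e-10) {
  is_euclidean <- function(cc) {
    dc <- d + cc
    diag(dc) <- 0
    g <- gower_center(dc)
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    min(ev) >= -1e-9 * max(abs(ev), 1)
  }
  if (is_euclidean(0)) return(0)
  lo <- 0
  hi <- 2 * max(d)
  while (!is_euclidean(hi)) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_euclidean(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Distance matrix of random points in Euclidean space (always embeddable).
euclidean_fixture <- function(n, k = 3) {
  pts <- matrix(stats::rnorm(n * k), n, k)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

# A 4x4 non-Euclidean dissimilarity: unit distances except one long pair.
non_euclidean_fixture <- function() {
  d <- matrix(1, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 2.5
  dimnames(d) <- list(letters[1:4], letters[1:4])
  d
}

random_rotation_2d <- function(theta, flip = FALSE) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (flip) r <- r %*% diag(c(1, -1))
  r
}
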