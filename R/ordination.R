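# Principal-coordinate decomposition of a distance matrix, with the
# additive (Cailliez), Lingoes and square-root corrections for
# non-Euclidean dissimilarities.

#' Gower-centred matrix of a distance matrix
#'
#' Computes `G = -1/2 * J %*% (D*D) %*% J` with `J = I - 11'/m`, the
#' double-centred matrix of squared dissimilarities whose eigenvectors give
#' the principal coordinates.
#'
#' @param d A validated labelled distance matrix.
#' @return A symmetric matrix with zero row/column sums.
#' @export
gower_center <- function(d) {
  d <- validate_distance_matrix(d)
  g <- dbl_center(-0.5 * d * d)
  dimnames(g) <- dimnames(d)
  g
}

dbl_center <- function(x) {
  rm <- rowMeans(x)
  cm <- colMeans(x)
  x - outer(rm, rep(1, ncol(x))) - outer(rep(1, nrow(x)), cm) + mean(x)
}

#' Cailliez additive constant and correction
#'
#' `cailliez_constant()` returns the smallest constant `c >= 0` such that
#' adding `c` to every off-diagonal dissimilarity makes the matrix
#' Euclidean-embeddable (Gower matrix positive semi-definite). It is the
#' largest real eigenvalue of the standard `2m x 2m` companion problem;
#' already-Euclidean input gives `c = 0` (any 2x2 matrix is Euclidean).
#' `cailliez_correct()` applies the constant and returns both.
#'
#' @param d A validated labelled distance matrix.
#' @return For `cailliez_constant()`, a single number `>= 0`. For
#'   `cailliez_correct()`, a list with elements `d` (corrected matrix) and
#'   `constant`.
#' @export
cailliez_constant <- function(d) {
  d <- validate_distance_matrix(d)
  m <- nrow(d)
  if (m <= 2L) return(0)
  ev0 <- eigen(gower_center(d), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) >= -1e-8 * max(abs(ev0), 1)) return(0)  # already Euclidean
  g1 <- dbl_center(-0.5 * d * d)
  g2 <- dbl_center(-0.5 * d)
  companion <- rbind(cbind(matrix(0, m, m), 2 * g1),
                     cbind(-diag(m), -4 * g2))
  ev <- eigen(companion, only.values = TRUE)$values
  cc <- max(Re(ev))
  if (cc < sqrt(.Machine$double.eps) * max(d, 1)) cc <- 0
  cc
}

#' @rdname cailliez_constant
#' @export
cailliez_correct <- function(d) {
  d <- validate_distance_matrix(d)
  cc <- cailliez_constant(d)
  if (cc > 0) {
    d <- d + cc
    diag(d) <- 0
  }
  list(d = d, constant = cc)
}

#' Principal-coordinate ordination of a distance matrix
#'
#' Eigendecomposes the (optionally corrected) Gower matrix and scales each
#' retained eigenvector by the square root of its eigenvalue. Axes with
#' eigenvalues at or below the tolerance `m * max_eigenvalue * 1e-12` are
#' dropped; with `correction = "none"` any substantially negative
#' eigenvalues are dropped with a warning. The coordinate matrix is always
#' right-padded with zero columns to exactly `m - 1` columns, the full
#' documented width of the configuration, so host and parasite ordinations
#' can be expanded side by side.
#'
#' @param d A validated labelled distance matrix (`m >= 2` taxa).
#' @param correction One of `"cailliez"` (default; additive constant on the
#'   off-diagonal dissimilarities), `"none"`, `"lingoes"` (additive
#'   constant on the squared dissimilarities) or `"sqrt"` (element-wise
#'   square root of the dissimilarities).
#' @return An object of class `"pco_ordination"`: a list with `labels`,
#'   `vectors` (an `m x (m-1)` coordinate matrix), `eigenvalues`
#'   (non-increasing, full spectrum of the corrected Gower matrix),
#'   `n_axes` (retained axes), `correction` and `cailliez_constant`.
#' @examples
#' d <- patristic_distances(read_newick("((A:1,B:1):1,(C:1,D:2):1);"))
#' ord <- pco_ordination(d)
#' ord$eigenvalues
#' @export
pco_ordination <- function(d, correction = c("cailliez", "none", "lingoes", "sqrt")) {
  correction <- match.arg(correction)
  d <- validate_distance_matrix(d)
  m <- nrow(d)
  cc <- 0
  d_use <- d
  if (correction == "cailliez") {
    corr <- cailliez_correct(d)
    d_use <- corr$d
    cc <- corr$constant
  } else if (correction == "sqrt") {
    d_use <- sqrt(d)
  }
  g <- gower_center(d_use)
  if (correction == "lingoes") {
    ev_min <- min(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -sqrt(.Machine$double.eps) * max(abs(g), 1)) {
      cc <- -ev_min
      d2 <- d * d
      d2[row(d2) != col(d2)] <- d2[row(d2) != col(d2)] + 2 * cc
      g <- dbl_center(-0.5 * d2)
    }
  }
  eig <- eigen(g, symmetric = TRUE)
  vals <- eig$values
  thr <- m * max(vals, 0) * 1e-12
  keep <- vals > thr
  if (correction == "none" && any(vals < -max(thr, sqrt(.Machine$double.eps))))
    warning("negative eigenvalues dropped (non-Euclidean distances; ",
            "consider a correction)", call. = FALSE)
  k <- sum(keep)
  vec <- eig$vectors[, keep, drop = FALSE]
  # reproducible sign: largest-magnitude loading of each axis positive
  for (j in seq_len(k)) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- vec %*% diag(sqrt(vals[keep]), k, k)
  if (k < m - 1L) coords <- cbind(coords, matrix(0, m, m - 1L - k))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(labels = rownames(d), vectors = coords,
                 eigenvalues = vals, n_axes = k,
                 correction = correction, cailliez_constant = cc),
            class = "pco_ordination")
}

#' @export
print.pco_ordination <- function(x, ...) {
  cat("Principal-coordinate ordination: ", length(x$labels), " taxa, ",
      x$n_axes, " retained axes (padded to ", ncol(x$vectors), ")\n",
      "correction: ", x$correction, sep = "")
  if (x$correction == "cailliez")
    cat(" (constant ", format(x$cailliez_constant, digits = 6), ")", sep = "")
  cat("\nfirst eigenvalues:", format(utils::head(x$eigenvalues, 5), digits = 6), "\n")
  invisible(x)
}
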