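# Core of the method: expansion of the host and parasite ordinations over
# the observed links, least-squares Procrustes superimposition and the
# goodness-of-fit statistic m2 with its per-link squared residuals.

#' Expand host and parasite ordinations over the association links
#'
#' For each link (host i, parasite j), taken in row-major order, the host
#' coordinate row i is appended to `X` and the parasite coordinate row j to
#' `Y`, so both configurations have one row per link (hosts and parasites
#' with several links have their rows duplicated). Columns of `X` and `Y`
#' are then centred on their means; if the two matrices still differ in
#' width the narrower one is right-padded with zero columns.
#'
#' @param host_pco,par_pco [pco_ordination()] objects whose labels match
#'   the rows/columns of `A`.
#' @param A An [association_matrix()].
#' @return A list of class `"expanded_config"` with centred matrices `X`
#'   and `Y` (each `n x k`) and the link tibble `links`.
#' @export
expand_pco <- function(host_pco, par_pco, A) {
  stopifnot(inherits(host_pco, "pco_ordination"), inherits(par_pco, "pco_ordination"))
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  if (!identical(host_pco$labels, rownames(A)))
    stop("host ordination labels do not match association rows ",
         "(run align_labels first)", call. = FALSE)
  if (!identical(par_pco$labels, colnames(A)))
    stop("parasite ordination labels do not match association columns ",
         "(run align_labels first)", call. = FALSE)
  links <- association_links(A)
  n <- nrow(links)
  if (n < 2L) stop("need at least 2 links for a Procrustes fit", call. = FALSE)
  X <- host_pco$vectors[links$host_idx, , drop = FALSE]
  Y <- par_pco$vectors[links$par_idx, , drop = FALSE]
  k <- max(ncol(X), ncol(Y))
  if (ncol(X) < k) X <- cbind(X, matrix(0, n, k - ncol(X)))
  if (ncol(Y) < k) Y <- cbind(Y, matrix(0, n, k - ncol(Y)))
  X <- center_cols(X)
  Y <- center_cols(Y)
  rownames(X) <- rownames(Y) <- paste(links$host, links$parasite, sep = "::")
  structure(list(X = X, Y = Y, links = links), class = "expanded_config")
}

center_cols <- function(x) {
  x - rep(colMeans(x), each = nrow(x))
}

#' Least-squares Procrustes superimposition of Y onto X
#'
#' Fits the parasite configuration `Y` onto the host configuration `X` by
#' rotation (reflection permitted) and a single positive scale, both
#' configurations already centred: with the singular value decomposition
#' `X'Y = V W U'`, the rotation is `R = U V'`, the scale
#' `c = sum(W) / tr(Y'Y)`, and the residual sum of squares
#' `m2 = tr(X'X) - sum(W)^2 / tr(Y'Y)`. The statistic is asymmetric in its
#' arguments: fitting X onto Y generally gives a different value.
#'
#' @param X,Y Column-centred numeric matrices with equal dimensions
#'   (`n >= 2` rows).
#' @return An object of class `"procrustes_fit"`: list with `m2`,
#'   `residuals_sq` (length-n, summing to `m2`), `rotation`, `scale`,
#'   `fitted_Y` (`c * Y %*% R`), and the inputs `X`, `Y`.
#' @examples
#' X <- scale(matrix(stats::rnorm(12), 6, 2), scale = FALSE)
#' theta <- pi / 5
#' R0 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
#' fit <- procrustes_m2(X, 3 * X %*% R0)
#' fit$m2   # 0 up to rounding: rotation and scale are removed by the fit
#' @export
procrustes_m2 <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != ncol(Y))
    stop("X and Y must have identical dimensions", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (max(abs(colMeans(X))) > 1e-8 * max(abs(X), 1) ||
      max(abs(colMeans(Y))) > 1e-8 * max(abs(Y), 1))
    stop("X and Y must be column-centred", call. = FALSE)
  trY <- sum(Y * Y)
  if (trY == 0)
    stop("degenerate configuration: all rows of Y are identical", call. = FALSE)
  s <- svd(crossprod(X, Y))
  rotation <- s$v %*% t(s$u)
  scale <- sum(s$d) / trY
  fitted_Y <- scale * Y %*% rotation
  resid_sq <- rowSums((X - fitted_Y)^2)
  m2 <- sum(X * X) - sum(s$d)^2 / trY
  structure(list(m2 = m2, residuals_sq = resid_sq, rotation = rotation,
                 scale = scale, fitted_Y = fitted_Y, X = X, Y = Y),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("Procrustes fit of Y onto X: n = ", nrow(x$X), ", k = ", ncol(x$X),
      "\n  m2 = ", format(x$m2, digits = 6),
      ", scale = ", format(x$scale, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Procrustean fit of a parasite phylogeny onto a host phylogeny
#'
#' Full pipeline for the global congruence statistic: principal-coordinate
#' ordination of both distance matrices (with the chosen negative-
#' eigenvalue correction), expansion of the two configurations over the
#' host-parasite links, and least-squares Procrustes superimposition of the
#' parasite configuration onto the host configuration. The resulting
#' residual sum of squares `m2` (squared units of the host dissimilarity)
#' is inversely proportional to cophylogenetic congruence, and its per-link
#' decomposition measures each link's contribution to the lack of fit.
#'
#' @param host_d,par_d Labelled distance matrices, or `"phylo"` trees from
#'   which patristic distances are computed.
#' @param A An [association_matrix()] (hosts as rows).
#' @param correction Negative-eigenvalue correction passed to
#'   [pco_ordination()].
#' @return An object of class `c("paco_fit", "procrustes_fit")`, with the
#'   [procrustes_m2()] fields plus `links` (tibble with per-link `r2`),
#'   `host_pco`, `par_pco` and `correction`.
#' @examples
#' sys <- null_system(6, 6, 8)
#' fit <- paco_fit(sys$host_d, sys$par_d, sys$A)
#' glance(fit)
#' @export
paco_fit <- function(host_d, par_d, A, correction = "cailliez") {
  aligned <- align_labels(host_d, par_d, A)
  host_pco <- pco_ordination(aligned$host_d, correction)
  par_pco <- pco_ordination(aligned$par_d, correction)
  conf <- expand_pco(host_pco, par_pco, aligned$A)
  fit <- procrustes_m2(conf$X, conf$Y)
  fit$links <- conf$links
  fit$links$r2 <- unname(fit$residuals_sq)
  fit$host_pco <- host_pco
  fit$par_pco <- par_pco
  fit$correction <- correction
  class(fit) <- c("paco_fit", class(fit))
  fit
}

#' @export
print.paco_fit <- function(x, ...) {
  cat("PACo fit: ", length(x$host_pco$labels), " hosts, ",
      length(x$par_pco$labels), " parasites, ", nrow(x$links), " links\n",
      "  correction: ", x$correction,
      "\n  m2 = ", format(x$m2, digits = 6), "\n", sep = "")
  invisible(x)
}
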