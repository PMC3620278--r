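# Global permutation test of the Procrustes statistic and jackknife
# estimation of per-link squared residuals.

#' Randomize an association matrix by independent row permutation
#'
#' Each host row's cells are permuted independently and uniformly across
#' the parasite columns, so per-host link counts and the total number of
#' links are preserved. Parasite columns may become empty in the permuted
#' matrix; that is permitted (such parasites simply contribute no rows to
#' the expanded configurations). This is the null-generating move of the
#' global test: hosts are randomly allocated to parasites.
#'
#' @param A An [association_matrix()].
#' @return A permuted `association_matrix` (empty parasites allowed).
#' @export
permute_links <- function(A) {
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  p <- ncol(A)
  Z <- matrix(0L, nrow(A), p, dimnames = dimnames(A))
  counts <- rowSums(unclass(A))
  for (i in which(counts > 0L)) {
    Z[i, sample.int(p, counts[i])] <- 1L
  }
  association_matrix(Z, allow_empty_parasites = TRUE, empty_hosts = "ok")
}

# Draw the parasite indices (host-major order) of one row-permuted matrix.
permuted_par_idx <- function(counts, p) {
  n <- sum(counts)
  pars <- integer(n)
  pos <- 1L
  for (i in which(counts > 0L)) {
    k <- counts[i]
    pars[pos:(pos + k - 1L)] <- sample.int(p, k)
    pos <- pos + k
  }
  pars
}

# m2 for a fixed centred host configuration and a parasite row selection.
# A permuted matrix can put every link on one parasite; the centred Y is
# then 0 and no fit is possible, so the residual is the whole tr(X'X).
m2_stat <- function(Xc, tX2, P, pars) {
  Y <- P[pars, , drop = FALSE]
  Yc <- Y - rep(colMeans(Y), each = nrow(Y))
  trY <- sum(Yc * Yc)
  if (trY <= .Machine$double.eps * max(tX2, 1)) return(tX2)
  d <- svd(crossprod(Xc, Yc), nu = 0, nv = 0)$d
  tX2 - sum(d)^2 / trY
}

# Null distribution of m2 under independent row permutation, reusing the
# principal-coordinate matrices (only the link expansion changes).
paco_null_m2 <- function(H, P, counts, n_perm) {
  hosts <- rep.int(seq_len(nrow(H)), counts)
  Xc <- center_cols(H[hosts, , drop = FALSE])
  tX2 <- sum(Xc * Xc)
  p <- nrow(P)
  vapply(seq_len(n_perm), function(b) {
    m2_stat(Xc, tX2, P, permuted_par_idx(counts, p))
  }, numeric(1))
}

pad_to <- function(x, k) {
  if (ncol(x) < k) cbind(x, matrix(0, nrow(x), k - ncol(x))) else x
}

new_cophylo_test <- function(method, statistic, statistic_name, p_value,
                             n_perm, null, seed, tail) {
  structure(list(method = method, statistic = statistic,
                 statistic_name = statistic_name, p_value = p_value,
                 n_perm = n_perm, null = null, seed = seed, tail = tail),
            class = "cophylo_test")
}

#' @export
print.cophylo_test <- function(x, ...) {
  cat(x$method, " permutation test\n  ", x$statistic_name, " = ",
      format(x$statistic, digits = 6), "\n  P = ",
      format(x$p_value, digits = 4), "  (", x$n_perm, " permutations, ",
      x$tail, " tail)\n", sep = "")
  invisible(x)
}

#' Global permutation test of the Procrustean cophylogenetic fit
#'
#' Tests the null hypothesis that the host ordination does not predict the
#' parasite ordination: the observed `m2` is compared with its distribution
#' over association matrices whose rows are independently permuted
#' ([permute_links()]). Small `m2` means congruence, so the one-tailed
#' P value is `(count(m2_null <= m2_obs) + 1) / (n_perm + 1)`, the observed
#' statistic counted as one realization of its own null; P can never fall
#' below `1 / (n_perm + 1)`. The principal-coordinate decompositions are
#' computed once and reused across permutations (only the link expansion
#' and the Procrustes fit change).
#'
#' @inheritParams paco_fit
#' @param n_perm Number of permutations (at least 99).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `c("paco_test", "cophylo_test")`, with the
#'   observed statistic, `p_value`, `null` (vector of permuted statistics),
#'   and the underlying [paco_fit()] in `$fit`.
#' @examples
#' sys <- coevolution_system(8)
#' paco_test(sys$host_d, sys$par_d, sys$A, n_perm = 99, seed = 1)
#' @export
paco_test <- function(host_d, par_d, A, n_perm = 999,
                      correction = "cailliez", seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- paco_fit(host_d, par_d, A, correction)
  k <- max(ncol(fit$host_pco$vectors), ncol(fit$par_pco$vectors))
  H <- pad_to(fit$host_pco$vectors, k)
  P <- pad_to(fit$par_pco$vectors, k)
  counts <- tabulate(fit$links$host_idx, nbins = nrow(H))
  null <- paco_null_m2(H, P, counts, n_perm)
  if (max(null) - min(null) <= 1e-12 * max(abs(null), 1))
    warning("all permuted statistics are identical; the null distribution ",
            "is degenerate", call. = FALSE)
  p <- (sum(null <= fit$m2) + 1) / (n_perm + 1)
  out <- new_cophylo_test("PACo", fit$m2, "m2", p, n_perm, null, seed, "lower")
  out$fit <- fit
  out$correction <- correction
  class(out) <- c("paco_test", class(out))
  out
}

#' Jackknife estimation of per-link squared residuals
#'
#' Each link's squared residual measures its contribution to the global
#' lack of fit `m2 = sum(r2)`. To attach uncertainty to these
#' contributions, each link `i` is deleted in turn (its 1 in `A` set to 0)
#' and the remaining `n - 1` residuals are recomputed on the reduced
#' system; the pseudovalue of link `j` under deletion `i` is
#' `phi[i, j] = n * r2[j] - (n - 1) * r2_minus_i[j]`. The jackknife
#' estimate of each link's residual is the mean of its `n - 1`
#' pseudovalues, its standard error the pseudovalue standard deviation
#' divided by `sqrt(n - 1)`, and the one-sided upper confidence bound
#' `estimate + t(conf, df) * se` with `df = n - 2` by default.
#'
#' @inheritParams paco_fit
#' @param conf One-sided confidence level for the upper bound.
#' @param df Degrees of freedom for the Student t quantile: `"n-2"`
#'   (default) or `"n-1"`.
#' @return An object of class `"paco_jackknife"`: list with `$table`
#'   (tibble: `host`, `parasite`, `r2`, `estimate`, `se`, `upper`),
#'   `$pseudovalues` (the `n x n` matrix, `NA` on the diagonal), `$m2`,
#'   `$conf` and `$df`.
#' @export
paco_jackknife <- function(host_d, par_d, A, correction = "cailliez",
                           conf = 0.95, df = c("n-2", "n-1")) {
  df <- match.arg(df)
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  if (nrow(association_links(A)) < 3L)
    stop("jackknife needs at least 3 links", call. = FALSE)
  fit <- paco_fit(host_d, par_d, A, correction)
  links <- fit$links
  n <- nrow(links)
  r2 <- links$r2
  k <- max(ncol(fit$host_pco$vectors), ncol(fit$par_pco$vectors))
  H <- pad_to(fit$host_pco$vectors, k)
  P <- pad_to(fit$par_pco$vectors, k)
  phi <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    Xc <- center_cols(H[links$host_idx[keep], , drop = FALSE])
    Yc <- center_cols(P[links$par_idx[keep], , drop = FALSE])
    trY <- sum(Yc * Yc)
    if (trY == 0) {
      r2m <- rowSums(Xc * Xc)      # degenerate reduced Y: nothing to fit
    } else {
      s <- svd(crossprod(Xc, Yc))
      fitted <- (sum(s$d) / trY) * Yc %*% (s$v %*% t(s$u))
      r2m <- rowSums((Xc - fitted)^2)
    }
    phi[i, keep] <- n * r2[keep] - (n - 1) * r2m
  }
  est <- colMeans(phi, na.rm = TRUE)
  se <- apply(phi, 2, sd, na.rm = TRUE) / sqrt(n - 1)
  dfval <- if (df == "n-2") n - 2 else n - 1
  upper <- est + qt(conf, dfval) * se
  structure(list(
    table = tibble(host = links$host, parasite = links$parasite,
                   r2 = r2, estimate = est, se = se, upper = upper),
    pseudovalues = phi, m2 = fit$m2, conf = conf, df = dfval,
    correction = correction),
    class = "paco_jackknife")
}

#' @export
print.paco_jackknife <- function(x, ...) {
  cat("Jackknifed squared residuals (", nrow(x$table), " links, m2 = ",
      format(x$m2, digits = 6), ")\n", sep = "")
  cat("one-sided ", format(100 * x$conf), "% upper bounds, t on ", x$df,
      " df\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Write a per-link residual report to TSV
#'
#' @param x A [paco_jackknife()] result.
#' @param path Output path.
#' @export
write_residual_report <- function(x, path) {
  stopifnot(inherits(x, "paco_jackknife"))
  utils::write.table(format(as.data.frame(x$table), digits = 10), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
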