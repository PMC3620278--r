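test_that("expansion duplicates rows by link and centres columns", {
  set.seed(31)
  hd <- euclidean_fixture(2)
  pd <- euclidean_fixture(2)
  rownames(pd) <- colnames(pd) <- c("q1", "q2")
  hp <- pco_ordination(hd); pp <- pco_ordination(pd)
  m <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(rownames(hd), rownames(pd)))
  conf <- expand_pco(hp, pp, association_matrix(m))
  expect_equal(nrow(conf$X), 3)
  expect_equal(conf$links$host_idx, c(1L, 1L, 2L))
  expect_equal(conf$links$par_idx, c(1L, 2L, 2L))
  # X is the host PCo rows in link order, centred on their column means
  xsel <- hp$vectors[c(1, 1, 2), , drop = FALSE]
  ysel <- pp$vectors[c(1, 2, 2), , drop = FALSE]
  expect_equal(unname(conf$X), unname(xsel - rep(colMeans(xsel), each = 3)))
  expect_equal(unname(conf$Y), unname(ysel - rep(colMeans(ysel), each = 3)))
  expect_lt(max(abs(colMeans(conf$X))), 1e-12)
  expect_lt(max(abs(colMeans(conf$Y))), 1e-12)
})

test_that("one-to-one matched links leave the centred ordinations unchanged", {
  set.seed(32)
  hd <- euclidean_fixture(5)
  pd <- euclidean_fixture(5)
  rownames(pd) <- colnames(pd) <- paste0("q", 1:5)
  hp <- pco_ordination(hd); pp <- pco_ordination(pd)
  m <- diag(1L, 5)
  dimnames(m) <- list(rownames(hd), rownames(pd))
  conf <- expand_pco(hp, pp, association_matrix(m))
  expect_equal(unname(conf$X), unname(scale(hp$vectors, scale = FALSE)),
               ignore_attr = TRUE)
  expect_equal(unname(conf$Y), unname(scale(pp$vectors, scale = FALSE)),
               ignore_attr = TRUE)
})

test_that("widths are equalized by zero-padding the narrower configuration", {
  set.seed(33)
  hd <- euclidean_fixture(4)
  pd <- euclidean_fixture(7)
  rownames(pd) <- colnames(pd) <- paste0("q", 1:7)
  m <- matrix(0L, 4, 7, dimnames = list(rownames(hd), rownames(pd)))
  m[cbind(1:4, 1:4)] <- 1L
  m[1, 5] <- m[2, 6] <- m[3, 7] <- 1L
  conf <- expand_pco(pco_ordination(hd), pco_ordination(pd),
                     association_matrix(m))
  expect_equal(ncol(conf$X), 6)
  expect_equal(ncol(conf$Y), 6)
  expect_true(all(conf$X[, 4:6] == conf$X[, 4:6][1]))  # padded columns constant
})

test_that("procrustes_m2 is zero for exact similarity transforms of X", {
  set.seed(34)
  X <- scale(matrix(rnorm(16), 8, 2), scale = FALSE)
  expect_equal(procrustes_m2(X, X)$m2, 0, tolerance = 1e-12)
  for (flip in c(FALSE, TRUE)) {
    R0 <- random_rotation_2d(runif(1, 0, 2 * pi), flip)
    fit <- procrustes_m2(X, 3 * X %*% R0)
    expect_equal(fit$m2, 0, tolerance = 1e-10)
    expect_equal(max(abs(fit$fitted_Y - X)), 0, tolerance = 1e-7)
  }
})

test_that("procrustes_m2 matches the rotation-grid oracle on random 2-D data", {
  set.seed(35)
  for (rep in 1:20) {
    X <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
    Y <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
    fit <- procrustes_m2(X, Y)
    expect_equal(fit$m2, grid_oracle_m2(X, Y), tolerance = 1e-6)
  }
})

test_that("procrustes_m2 agrees with the vegan reference and decomposes into residuals", {
  skip_if_not_installed("vegan")
  set.seed(36)
  sys <- null_system(8, 9, 12)
  fit <- paco_fit(sys$host_d, sys$par_d, sys$A)
  ref <- vegan::procrustes(fit$X, fit$Y, symmetric = FALSE, scale = TRUE)
  expect_equal(fit$m2, ref$ss, tolerance = 1e-10)
  expect_equal(unname(fit$residuals_sq),
               unname(as.numeric(stats::residuals(ref))^2), tolerance = 1e-10)
  expect_equal(sum(fit$residuals_sq), fit$m2, tolerance = 1e-10)
  # rotation is orthogonal
  expect_equal(crossprod(fit$rotation), diag(ncol(fit$X)), tolerance = 1e-8)
})

test_that("the statistic has the documented invariances and asymmetry", {
  set.seed(37)
  X <- scale(matrix(rnorm(20), 10, 2), scale = FALSE)
  Y <- scale(matrix(rnorm(20), 10, 2), scale = FALSE)
  m2 <- procrustes_m2(X, Y)$m2
  # orthogonal transform or positive rescaling of Y changes nothing
  R0 <- random_rotation_2d(1.1, flip = TRUE)
  expect_equal(procrustes_m2(X, 2.7 * Y %*% R0)$m2, m2, tolerance = 1e-9)
  # orthogonal transform of X changes nothing; scaling X scales m2 by s^2
  R1 <- random_rotation_2d(0.6)
  expect_equal(procrustes_m2(X %*% R1, Y)$m2, m2, tolerance = 1e-9)
  expect_equal(procrustes_m2(2 * X, Y)$m2, 4 * m2, tolerance = 1e-9)
  # asymmetric in its arguments
  expect_gt(abs(procrustes_m2(Y, X)$m2 - m2), 1e-8)
  # degenerate Y is rejected
  expect_error(procrustes_m2(X, matrix(0, 10, 2)), "degenerate")
})

test_that("paco_fit is exact for perfectly congruent systems", {
  set.seed(38)
  sys <- coevolution_system(10)
  fit <- paco_fit(sys$host_d, sys$par_d, sys$A)
  expect_equal(fit$m2, 0, tolerance = 1e-9)
  expect_lt(max(fit$residuals_sq), 1e-9)
})

test_that("paco_fit on a gopher-louse-sized random system is finite and self-consistent", {
  set.seed(39)
  sys <- null_system(15, 17, 17)
  fit <- paco_fit(sys$host_d, sys$par_d, sys$A)
  expect_gt(fit$m2, 0)
  expect_true(is.finite(fit$m2))
  expect_equal(sum(fit$residuals_sq), fit$m2, tolerance = 1e-10)
  expect_equal(nrow(fit$links), 17)
  # swapping host and parasite roles changes the statistic
  swapped <- paco_fit(sys$par_d, sys$host_d,
                      association_matrix(t(unclass(sys$A)),
                                         allow_empty_parasites = TRUE,
                                         empty_hosts = "ok"))
  expect_gt(abs(swapped$m2 - fit$m2), 1e-8)
})
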