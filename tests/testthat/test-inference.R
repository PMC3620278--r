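test_that("permute_links preserves per-host counts and total links", {
  set.seed(41)
  sys <- null_system(6, 7, 12)
  for (rep in 1:20) {
    z <- permute_links(sys$A)
    expect_equal(rowSums(unclass(z)), rowSums(unclass(sys$A)))
    expect_equal(sum(z), sum(sys$A))
  }
})

test_that("single-link rows land uniformly across columns", {
  set.seed(42)
  m <- matrix(c(1L, 0L, 0L), 1, 3,
              dimnames = list("h", paste0("p", 1:3)))
  A <- association_matrix(m, allow_empty_parasites = TRUE, empty_hosts = "ok")
  draws <- replicate(3000, which(unclass(permute_links(A)) == 1L))
  counts <- tabulate(draws, 3)
  # chi-square goodness of fit against uniform over the 3 positions
  chi <- sum((counts - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("full rows and single-column matrices are permutation-invariant", {
  m <- matrix(1L, 2, 3, dimnames = list(c("h1", "h2"), paste0("p", 1:3)))
  A <- association_matrix(m)
  expect_equal(unclass(permute_links(A)), unclass(A))
  m1 <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("h1", "h2"), "p1"))
  A1 <- association_matrix(m1)
  expect_equal(unclass(permute_links(A1)), unclass(A1))
})

test_that("the fast permutation engine matches a full refit on permuted matrices", {
  set.seed(43)
  sys <- null_system(7, 8, 11)
  fit <- paco_fit(sys$host_d, sys$par_d, sys$A)
  k <- max(ncol(fit$host_pco$vectors), ncol(fit$par_pco$vectors))
  H <- cophylofit:::pad_to(fit$host_pco$vectors, k)
  P <- cophylofit:::pad_to(fit$par_pco$vectors, k)
  hosts <- fit$links$host_idx
  Xc <- cophylofit:::center_cols(H[hosts, , drop = FALSE])
  tX2 <- sum(Xc^2)
  for (rep in 1:5) {
    z <- permute_links(sys$A)
    full <- paco_fit(sys$host_d, sys$par_d, z)$m2
    zl <- association_links(z)
    engine <- cophylofit:::m2_stat(Xc, tX2, P, zl$par_idx)
    expect_equal(engine, full, tolerance = 1e-9)
  }
})

test_that("the global test is reproducible, bounded below, and uses the +1 rule", {
  set.seed(44)
  sys <- null_system(8, 8, 10)
  t1 <- paco_test(sys$host_d, sys$par_d, sys$A, n_perm = 99, seed = 5)
  t2 <- paco_test(sys$host_d, sys$par_d, sys$A, n_perm = 99, seed = 5)
  expect_equal(t1$p_value, t2$p_value)
  expect_equal(t1$null, t2$null)
  expect_gte(t1$p_value, 1 / 100)
  expect_lte(t1$p_value, 1)
  expect_equal(t1$p_value, (sum(t1$null <= t1$statistic) + 1) / 100)
})

test_that("congruent systems are detected with small P values", {
  set.seed(45)
  for (rep in 1:10) {
    sys <- coevolution_system(10)
    tt <- paco_test(sys$host_d, sys$par_d, sys$A, n_perm = 199)
    expect_lte(tt$p_value, 0.05)
  }
})

test_that("jackknife of a perfectly congruent system has zero estimates and SEs", {
  set.seed(46)
  sys <- coevolution_system(8)
  jk <- paco_jackknife(sys$host_d, sys$par_d, sys$A)
  expect_lt(max(abs(jk$table$estimate)), 1e-8)
  expect_lt(max(jk$table$se), 1e-8)
  expect_true(all(jk$table$upper >= jk$table$estimate - 1e-12))
})

test_that("jackknife pseudovalue algebra matches a hand-unrolled 3-link system", {
  set.seed(47)
  sys <- null_system(4, 4, 3)
  # distinct hosts and parasites so every 2-link deletion refit is non-degenerate
  while (anyDuplicated(association_links(sys$A)$host_idx) ||
         anyDuplicated(association_links(sys$A)$par_idx)) {
    sys <- null_system(4, 4, 3)
  }
  n <- 3
  jk <- paco_jackknife(sys$host_d, sys$par_d, sys$A)
  # independent unroll: full residuals and each deletion refit via paco_fit
  r2 <- paco_fit(sys$host_d, sys$par_d, sys$A)$links$r2
  lk <- association_links(sys$A)
  phi <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    Ai <- unclass(sys$A)
    Ai[lk$host_idx[i], lk$par_idx[i]] <- 0L
    sub <- paco_fit(sys$host_d, sys$par_d,
                    association_matrix(Ai, allow_empty_parasites = TRUE,
                                       empty_hosts = "ok"))
    keep <- setdiff(seq_len(n), i)
    phi[i, keep] <- n * r2[keep] - (n - 1) * sub$links$r2
  }
  est <- colMeans(phi, na.rm = TRUE)
  se <- apply(phi, 2, sd, na.rm = TRUE) / sqrt(n - 1)
  upper <- est + qt(0.95, n - 2) * se
  expect_equal(jk$table$estimate, est, tolerance = 1e-10)
  expect_equal(jk$table$se, se, tolerance = 1e-10)
  expect_equal(jk$table$upper, upper, tolerance = 1e-10)
  expect_equal(unname(jk$pseudovalues), unname(phi), tolerance = 1e-10)
})

test_that("jackknife refuses systems with fewer than 3 links", {
  set.seed(48)
  sys <- null_system(4, 4, 2)
  expect_error(paco_jackknife(sys$host_d, sys$par_d, sys$A), "at least 3")
})
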