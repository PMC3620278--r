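# Monte-Carlo experiments: Type I error calibration on null systems and
# statistical power under progressively degraded coevolutionary signal.
# All requested tests see the identical system in each replicate, which
# makes the per-test results directly comparable.

# P values of the requested tests on one system, sharing the PCo
# decompositions between the Procrustes and ParaFit statistics.
system_pvalues <- function(sys, tests, n_perm, correction) {
  links <- association_links(sys$A)
  hosts <- links$host_idx
  pars <- links$par_idx
  counts <- tabulate(hosts, nbins = nrow(sys$host_d))
  p_n <- nrow(sys$par_d)
  out <- stats::setNames(rep(NA_real_, length(tests)), tests)
  if (any(tests %in% c("paco", "parafit"))) {
    Hv <- pco_ordination(sys$host_d, correction)$vectors
    Pv <- pco_ordination(sys$par_d, correction)$vectors
  }
  if ("paco" %in% tests) {
    k <- max(ncol(Hv), ncol(Pv))
    H <- pad_to(Hv, k); P <- pad_to(Pv, k)
    Xc <- center_cols(H[hosts, , drop = FALSE])
    tX2 <- sum(Xc * Xc)
    obs <- m2_stat(Xc, tX2, P, pars)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (m2_stat(Xc, tX2, P, permuted_par_idx(counts, p_n)) <= obs)
        cnt <- cnt + 1L
    }
    out["paco"] <- (cnt + 1) / (n_perm + 1)
  }
  if ("parafit" %in% tests) {
    obs <- sum(crossprod(Pv[pars, , drop = FALSE], Hv[hosts, , drop = FALSE])^2)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      z <- permuted_par_idx(counts, p_n)
      s <- sum(crossprod(Pv[z, , drop = FALSE], Hv[hosts, , drop = FALSE])^2)
      if (s >= obs) cnt <- cnt + 1L
    }
    out["parafit"] <- (cnt + 1) / (n_perm + 1)
  }
  if ("hct" %in% tests) {
    n <- length(hosts)
    pair <- utils::combn(n, 2L)
    ha <- hosts[pair[1L, ]]; hb <- hosts[pair[2L, ]]
    pa <- pars[pair[1L, ]];  pb <- pars[pair[2L, ]]
    hD <- sys$host_d; pD <- sys$par_d
    hvec <- hD[cbind(ha, hb)]; pvec <- pD[cbind(pa, pb)]
    obs <- suppressWarnings(cor(hvec, pvec))
    h_n <- nrow(hD)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      sh <- sample.int(h_n); sp <- sample.int(p_n)
      r <- suppressWarnings(cor(hD[cbind(sh[ha], sh[hb])], pD[cbind(sp[pa], sp[pb])]))
      if (is.na(r) || r >= obs) cnt <- cnt + 1L
    }
    out["hct"] <- (cnt + 1) / (n_perm + 1)
  }
  out
}

run_experiment <- function(make_system, n_sim, n_perm, tests, alpha,
                           correction, n_boot, seed, config,
                           checkpoint_path = NULL) {
  tests <- match.arg(tests, c("paco", "parafit", "hct"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  pmat <- matrix(NA_real_, n_sim, length(tests),
                 dimnames = list(NULL, tests))
  for (s in seq_len(n_sim)) {
    pmat[s, ] <- system_pvalues(make_system(), tests, n_perm, correction)
    if (!is.null(checkpoint_path) && s %% 100L == 0L)
      utils::write.table(pmat[seq_len(s), , drop = FALSE], checkpoint_path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  p_values <- tibble(
    sim = rep(seq_len(n_sim), times = length(tests)),
    test = rep(tests, each = n_sim),
    p_value = as.vector(pmat))
  rates <- rejection_rates(pmat, alpha, n_boot)
  structure(list(p_values = p_values, rates = rates,
                 config = c(config, list(n_sim = n_sim, n_perm = n_perm,
                                         tests = tests, alpha = alpha,
                                         correction = correction, seed = seed))),
            class = "cophylo_experiment")
}

# Rejection rate per test and alpha, with a percentile bootstrap CI over
# the simulation replicates.
rejection_rates <- function(pmat, alpha, n_boot = 1000) {
  grid <- expand.grid(test = colnames(pmat), alpha = alpha,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rej <- pmat[, grid$test[i]] <= grid$alpha[i]
    rate <- mean(rej)
    boot <- vapply(seq_len(n_boot), function(b) {
      mean(rej[sample.int(length(rej), replace = TRUE)])
    }, numeric(1))
    ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
    tibble(test = grid$test[i], alpha = grid$alpha[i], rate = rate,
           ci_lower = ci[1], ci_upper = ci[2], n_sim = length(rej))
  })
  do.call(rbind, res)
}

#' Type I error experiment on null cophylogenetic systems
#'
#' Repeatedly generates null systems ([null_system()]: independent random
#' trees, random links) and computes the permutation P value of each
#' requested test on the identical data. Under this design the null
#' hypothesis of every test is true, so rejection rates estimate Type I
#' error and P values should be uniform.
#'
#' @inheritParams null_system
#' @param n_sim Number of simulated systems.
#' @param n_perm Permutations per test per system.
#' @param tests Subset of `c("paco", "parafit", "hct")`.
#' @param alpha Significance levels at which rejection rates are reported.
#' @param correction Negative-eigenvalue correction for the ordinations.
#' @param n_boot Bootstrap resamples for the rate confidence intervals.
#' @param seed Optional integer seed.
#' @param checkpoint_path Optional TSV path; accumulated P values are
#'   written there every 100 simulations.
#' @return A `"cophylo_experiment"` object: `$p_values` (tibble: sim,
#'   test, p_value), `$rates` (tibble with bootstrap 95% CIs), `$config`.
#' @examples
#' \donttest{
#' ex <- run_type1_experiment(n_sim = 50, n_perm = 99, tests = "paco", seed = 1)
#' ex$rates
#' }
#' @export
run_type1_experiment <- function(n_host = 10, n_par = 10, n_links = 10,
                                 n_sim = 1000, n_perm = 199,
                                 tests = c("paco", "parafit", "hct"),
                                 alpha = c(0.01, 0.05),
                                 correction = "cailliez", n_boot = 1000,
                                 seed = NULL, checkpoint_path = NULL) {
  run_experiment(
    function() null_system(n_host, n_par, n_links),
    n_sim, n_perm, tests, alpha, correction, n_boot, seed,
    config = list(scenario = "null", n_host = n_host, n_par = n_par,
                  n_links = n_links),
    checkpoint_path = checkpoint_path)
}

#' Statistical power experiment under degraded coevolutionary signal
#'
#' Starts from an ideal coevolutionary system (one tree for both
#' phylogenies, identity links) and degrades it according to `scenario`:
#' `"links_added"` adds `round(fraction * n)` random links on top of the
#' coevolutionary ones, `"links_replaced"` replaces that many
#' coevolutionary links with randomly located ones, and
#' `"partly_congruent"` rebuilds the parasite tree so that only
#' `round((1 - fraction) * n)` taxa keep the host subtree
#' ([partly_congruent_system()]). `fraction = 0` is the ideal scenario in
#' every case; `fraction = 1` under `"links_replaced"` or
#' `"partly_congruent"` makes the null hypothesis true again.
#'
#' @inheritParams run_type1_experiment
#' @param scenario One of `"links_added"`, `"links_replaced"`,
#'   `"partly_congruent"`.
#' @param n_taxa Number of host (= parasite) taxa.
#' @param fraction Randomization fraction in `[0, 1]`.
#' @return A `"cophylo_experiment"` object (rejection rates here estimate
#'   power).
#' @export
run_power_experiment <- function(scenario = c("links_added", "links_replaced",
                                              "partly_congruent"),
                                 n_taxa = 10, fraction = 0,
                                 n_sim = 1000, n_perm = 199,
                                 tests = c("paco", "parafit", "hct"),
                                 alpha = c(0.01, 0.05),
                                 correction = "cailliez", n_boot = 1000,
                                 seed = NULL, checkpoint_path = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(fraction >= 0, fraction <= 1)
  make_system <- switch(scenario,
    links_added = function() {
      sys <- coevolution_system(n_taxa)
      sys$A <- add_random_links(sys$A, round(fraction * n_taxa))
      sys
    },
    links_replaced = function() {
      sys <- coevolution_system(n_taxa)
      sys$A <- replace_links(sys$A, round(fraction * n_taxa))
      sys
    },
    partly_congruent = function() {
      partly_congruent_system(n_taxa, n_taxa - round(fraction * n_taxa))
    })
  run_experiment(
    make_system, n_sim, n_perm, tests, alpha, correction, n_boot, seed,
    config = list(scenario = scenario, n_taxa = n_taxa, fraction = fraction),
    checkpoint_path = checkpoint_path)
}

#' @export
print.cophylo_experiment <- function(x, ...) {
  cfg <- x$config
  cat("Cophylogenetic simulation experiment (", cfg$scenario, ")\n",
      cfg$n_sim, " simulations x ", cfg$n_perm, " permutations; tests: ",
      paste(cfg$tests, collapse = ", "), "\n", sep = "")
  print(x$rates, ...)
  invisible(x)
}

#' Kolmogorov-Smirnov uniformity check of simulated P values
#'
#' Under a true null hypothesis, correctly formed P values are uniform on
#' (0, 1]; this compares each test's empirical P value distribution with
#' Uniform(0, 1).
#'
#' @param experiment A `"cophylo_experiment"` object.
#' @return A tibble with `test`, `ks_statistic`, `ks_p_value`.
#' @export
p_uniformity <- function(experiment) {
  stopifnot(inherits(experiment, "cophylo_experiment"))
  tests <- unique(experiment$p_values$test)
  do.call(rbind, lapply(tests, function(tn) {
    p <- experiment$p_values$p_value[experiment$p_values$test == tn]
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    tibble(test = tn, ks_statistic = unname(ks$statistic),
           ks_p_value = ks$p.value)
  }))
}
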