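# Reimplementations of the two comparison tests used in the benchmarking
# harness: the ParaFit global trace test and the Hommola et al.
# cospeciation test (HCT). Both consume exactly the same inputs as the
# Procrustes test so the three tests can be run on byte-identical data.

#' ParaFit global test of host-parasite association
#'
#' Fourth-corner style trace statistic: with `H` the host
#' principal-coordinate matrix (`h x (h-1)`), `Pm` the parasite one
#' (`p x (p-1)`) and `A` the binary association matrix, the statistic is
#' `ParaFitGlobal = sum(D^2)` with `D = t(Pm) %*% t(A) %*% H`
#' (the trace of `D'D`). Large values indicate congruence, so the test is
#' upper-tailed. Significance is established by randomizing the
#' association matrix: by default each host row is permuted independently
#' (the same scheme as [permute_links()]); `permutation = "shuffle-rows"`
#' instead shuffles whole rows of `A` across hosts.
#'
#' @inheritParams paco_test
#' @param permutation Randomization unit, `"within-rows"` (default) or
#'   `"shuffle-rows"`.
#' @return A `"cophylo_test"` object (statistic, `p_value`, `null`, ...).
#' @export
parafit_test <- function(host_d, par_d, A, n_perm = 999,
                         correction = "cailliez", seed = NULL,
                         permutation = c("within-rows", "shuffle-rows")) {
  permutation <- match.arg(permutation)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  aligned <- align_labels(host_d, par_d, A)
  H <- pco_ordination(aligned$host_d, correction)$vectors
  P <- pco_ordination(aligned$par_d, correction)$vectors
  links <- association_links(aligned$A)
  hosts <- links$host_idx
  pars <- links$par_idx
  counts <- tabulate(hosts, nbins = nrow(H))
  # sum over links of outer(P[j, ], H[i, ]) is exactly t(Pm) A' H
  stat_for <- function(hidx, pidx) {
    sum(crossprod(P[pidx, , drop = FALSE], H[hidx, , drop = FALSE])^2)
  }
  obs <- stat_for(hosts, pars)
  p_n <- nrow(P)
  h_n <- nrow(H)
  null <- vapply(seq_len(n_perm), function(b) {
    if (permutation == "within-rows") {
      stat_for(hosts, permuted_par_idx(counts, p_n))
    } else {
      stat_for(sample.int(h_n)[hosts], pars)
    }
  }, numeric(1))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  out <- new_cophylo_test("ParaFit", obs, "ParaFitGlobal", p, n_perm, null,
                          seed, "upper")
  out$permutation <- permutation
  out
}

#' Hommola et al. cospeciation test (HCT)
#'
#' Mantel-style generalization built on links rather than taxa, so
#' many-to-many associations are accommodated: for every unordered pair of
#' links `(a, b)`, the host vector holds the host-host distance
#' `d_host(host(a), host(b))` and the parasite vector the corresponding
#' parasite-parasite distance; the statistic is the Pearson correlation of
#' the two vectors over all `choose(n, 2)` pairs. The null hypothesis of
#' unrelated phylogenies is simulated by randomly and separately permuting
#' the host and parasite tip labels while topologies and the association
#' matrix stay fixed; the test is upper-tailed.
#'
#' @inheritParams paco_test
#' @return A `"cophylo_test"` object.
#' @export
hct_test <- function(host_d, par_d, A, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  aligned <- align_labels(host_d, par_d, A)
  hD <- aligned$host_d
  pD <- aligned$par_d
  links <- association_links(aligned$A)
  n <- nrow(links)
  if (n < 3L) stop("HCT needs at least 3 links (>= 3 link pairs)", call. = FALSE)
  pair <- utils::combn(n, 2L)
  ha <- links$host_idx[pair[1L, ]]; hb <- links$host_idx[pair[2L, ]]
  pa <- links$par_idx[pair[1L, ]];  pb <- links$par_idx[pair[2L, ]]
  hvec <- hD[cbind(ha, hb)]
  pvec <- pD[cbind(pa, pb)]
  if (sd(hvec) == 0 || sd(pvec) == 0)
    stop("undefined correlation: all link pairs share one host or one parasite",
         call. = FALSE)
  obs <- cor(hvec, pvec)
  h_n <- nrow(hD); p_n <- nrow(pD)
  null <- vapply(seq_len(n_perm), function(b) {
    sh <- sample.int(h_n); sp <- sample.int(p_n)
    r <- suppressWarnings(cor(hD[cbind(sh[ha], sh[hb])], pD[cbind(sp[pa], sp[pb])]))
    if (is.na(r)) Inf else r       # degenerate permutation: count against H1
  }, numeric(1))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  new_cophylo_test("HCT", obs, "r", p, n_perm, null, seed, "upper")
}
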