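# Synthetic cophylogenetic systems and the Type I / power experiments.
# These generators define the study conditions under which the three
# tests are calibrated and compared.

#' Random additive phylogenetic tree
#'
#' Random binary topology by recursive uniform splitting of the taxon set
#' (the scheme of [ape::rtree()]), with every branch length drawn from
#' Uniform(0, 1). Tips are labelled `t1..tn`.
#'
#' @param n_taxa Number of tips (at least 2).
#' @return A `"phylo"` object.
#' @export
random_tree <- function(n_taxa) {
  if (n_taxa < 2L) stop("need at least 2 taxa", call. = FALSE)
  ape::rtree(n_taxa, br = runif)
}

#' Null cophylogenetic system: independent trees, random links
#'
#' Independent random host and parasite trees plus an association matrix
#' with `n_links` cells sampled uniformly without replacement from the
#' `n_host x n_par` grid. Used for Type I error estimation: the null
#' hypothesis of no dependence is true by construction.
#'
#' @param n_host,n_par Numbers of host and parasite taxa.
#' @param n_links Number of links (at most `n_host * n_par`).
#' @return A list with `host_tree`, `par_tree`, `host_d`, `par_d`, `A`.
#' @export
null_system <- function(n_host = 10, n_par = 10, n_links = 10) {
  if (n_links < 1L || n_links > n_host * n_par)
    stop("n_links must be between 1 and n_host * n_par", call. = FALSE)
  host_tree <- random_tree(n_host)
  par_tree <- random_tree(n_par)
  host_d <- patristic_distances(host_tree)
  par_d <- patristic_distances(par_tree)
  A <- matrix(0L, n_host, n_par,
              dimnames = list(rownames(host_d), paste0("p", seq_len(n_par))))
  A[sample.int(n_host * n_par, n_links)] <- 1L
  colnames(par_d) <- rownames(par_d) <- colnames(A)
  list(host_tree = host_tree, par_tree = par_tree,
       host_d = host_d, par_d = par_d,
       A = association_matrix(A, allow_empty_parasites = TRUE, empty_hosts = "ok"))
}

#' Ideal coevolutionary system: one tree, one-to-one links
#'
#' A single random tree serves as both the host and the parasite
#' phylogeny, and each host is associated to the parasite at the
#' corresponding position, so the association matrix is the identity. The
#' Procrustes fit of such a system is perfect (`m2 = 0`).
#'
#' @param n_taxa Number of host (= parasite) taxa.
#' @return A list with `tree`, `host_d`, `par_d`, `A`.
#' @export
coevolution_system <- function(n_taxa = 10) {
  tree <- random_tree(n_taxa)
  d <- patristic_distances(tree)
  host_d <- d
  par_d <- d
  rownames(par_d) <- colnames(par_d) <- paste0("p", seq_len(n_taxa))
  A <- diag(1L, n_taxa)
  dimnames(A) <- list(rownames(host_d), rownames(par_d))
  list(tree = tree, host_d = host_d, par_d = par_d,
       A = association_matrix(A))
}

#' Degrade a coevolutionary association matrix
#'
#' `add_random_links()` adds `k` new links at cells sampled uniformly from
#' the current 0-cells (existing links are never replaced).
#' `replace_links()` removes `k` uniformly chosen existing links and
#' places `k` new ones uniformly among cells that were 0 before the draw;
#' by default a removed cell may not be recreated within the same draw.
#'
#' @param A An [association_matrix()].
#' @param k Number of links to add / replace.
#' @param allow_restore For `replace_links()`: permit a new link to land
#'   on a cell that was just cleared.
#' @return A new `association_matrix` (total links `n + k` after adding,
#'   `n` after replacement).
#' @export
add_random_links <- function(A, k) {
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  if (k == 0L) return(A)
  zeros <- which(unclass(A) == 0L)
  if (k > length(zeros)) stop("not enough empty cells to add ", k, " links",
                              call. = FALSE)
  A[zeros[sample.int(length(zeros), k)]] <- 1L
  association_matrix(unclass(A), allow_empty_parasites = TRUE, empty_hosts = "ok")
}

#' @rdname add_random_links
#' @export
replace_links <- function(A, k, allow_restore = FALSE) {
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  if (k == 0L) return(A)
  ones <- which(unclass(A) == 1L)
  if (k > length(ones)) stop("cannot replace more links than exist", call. = FALSE)
  zeros_before <- which(unclass(A) == 0L)
  removed <- ones[sample.int(length(ones), k)]
  A[removed] <- 0L
  candidates <- if (allow_restore) c(zeros_before, removed) else zeros_before
  if (k > length(candidates))
    stop("not enough empty cells to place ", k, " replacement links", call. = FALSE)
  A[candidates[sample.int(length(candidates), k)]] <- 1L
  association_matrix(unclass(A), allow_empty_parasites = TRUE, empty_hosts = "ok")
}

#' Partly congruent cophylogenetic system
#'
#' A host tree on `n_taxa` taxa is generated; the parasite tree copies the
#' host subtree induced by a random set of `n_congruent` taxa (same
#' topology and branch lengths) and, when taxa remain, attaches an
#' independently generated random subtree of the other `n_taxa -
#' n_congruent` parasite taxa as its sister at the root (connecting
#' branches Uniform(0, 1)). Links are one-to-one: matched on the congruent
#' set, and a uniform random perfect matching between the remaining hosts
#' and remaining parasites. Boundaries: `n_congruent = n_taxa` gives
#' identical trees with identity links; `n_congruent = 0` gives a fully
#' random pair.
#'
#' @param n_taxa Total number of host (= parasite) taxa.
#' @param n_congruent Number of taxa in the shared, identical part.
#' @return A list with `host_tree`, `par_tree`, `host_d`, `par_d`, `A`.
#' @export
partly_congruent_system <- function(n_taxa = 10, n_congruent = n_taxa) {
  if (n_congruent < 0L || n_congruent > n_taxa)
    stop("n_congruent must be in [0, n_taxa]", call. = FALSE)
  host_tree <- random_tree(n_taxa)
  if (n_congruent == n_taxa) {
    par_tree <- host_tree
    congruent <- host_tree$tip.label
  } else if (n_congruent >= 2L) {
    congruent <- sample(host_tree$tip.label, n_congruent)
    common <- ape::keep.tip(host_tree, congruent)
    free <- n_taxa - n_congruent
    if (free == 1L) {
      sister <- sprintf("x1:%.10f", runif(1))
    } else {
      rand_part <- random_tree(free)
      rand_part$tip.label <- paste0("x", seq_len(free))
      sister <- sprintf("%s:%.10f", sub(";$", "", ape::write.tree(rand_part)),
                        runif(1))
    }
    nwk <- sprintf("(%s:%.10f,%s);", sub(";$", "", ape::write.tree(common)),
                   runif(1), sister)
    par_tree <- ape::read.tree(text = nwk)
  } else {
    # 0 or 1 congruent taxa pin no shared structure: fully random pair
    congruent <- character(0)
    par_tree <- random_tree(n_taxa)
    par_tree$tip.label <- paste0("x", seq_len(n_taxa))
  }
  host_d <- patristic_distances(host_tree)
  par_d <- patristic_distances(par_tree)
  # one-to-one links: matched on the congruent part, random matching elsewhere
  hosts <- rownames(host_d)
  pars <- rownames(par_d)
  A <- matrix(0L, n_taxa, n_taxa, dimnames = list(hosts, pars))
  matched <- intersect(hosts, congruent)
  for (tip in matched) A[tip, tip] <- 1L
  free_h <- setdiff(hosts, matched)
  free_p <- setdiff(pars, matched)
  if (length(free_h)) {
    A[cbind(free_h, sample(free_p))] <- 1L
  }
  list(host_tree = host_tree, par_tree = par_tree,
       host_d = host_d, par_d = par_d,
       A = association_matrix(A))
}
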