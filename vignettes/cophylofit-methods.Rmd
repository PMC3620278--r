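---
title: "Procrustean analysis of cophylogenetic congruence: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Procrustean analysis of cophylogenetic congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophylofit)
```

## The model

`cophylofit` tests whether a parasite phylogeny depends on its host
phylogeny. The data are two dissimilarity matrices — typically patristic
distances from additive trees, but any dissimilarity is accepted — and a
binary association matrix $A$ ($h \times p$, hosts as rows, so a 1 in cell
$(i, j)$ records parasite $j$ occurring on host $i$). Multiple hosts per
parasite and multiple parasites per host are allowed, and the phylogenies
need not be fully resolved, since only distances enter the analysis.

Each distance matrix is embedded in Euclidean space by principal
coordinates: the Gower matrix $G = -\tfrac12 J D^{(2)} J$ (with $J$ the
centring projector and $D^{(2)}$ the element-wise squared distances) is
eigendecomposed and each retained eigenvector scaled by the square root of
its eigenvalue. Phylogenetic distances are usually non-Euclidean, which
produces negative eigenvalues; by default we apply the Cailliez
correction — the smallest additive constant on the off-diagonal distances
that makes the matrix embeddable, obtained as the largest real eigenvalue
of the standard $2m \times 2m$ companion problem. Lingoes (additive on
squared distances) and element-wise square-root corrections are available
as options; the square root of an additive tree metric is itself
Euclidean, which makes that option attractive for patristic input, but
Cailliez remains the default used in all calibration runs. Coordinate
matrices are always zero-padded on the right to their full documented
width ($m - 1$ columns), so host and parasite configurations can be
combined regardless of rank loss.

The two ordinations are then *expanded over the links*: one row per link,
in row-major order of $A$, duplicating the coordinate rows of taxa with
several partners. Duplicated rows are deliberately treated as independent
observations at identical positions; the Type I calibration below shows
this produces correct error rates for the Procrustes test. After column
centring, the parasite configuration $Y$ is fitted to the host
configuration $X$ by least-squares Procrustes superimposition with
reflection allowed and a single non-negative scale applied to $Y$ only.
With the SVD $X'Y = VWU'$, the rotation is $UV'$, the scale
$c = \sum_i w_i / \mathrm{tr}(Y'Y)$, and the goodness-of-fit statistic is

$$ m^2_{XY} \;=\; \mathrm{tr}(X'X) - \frac{\left(\sum_i w_i\right)^2}{\mathrm{tr}(Y'Y)}, $$

the residual sum of squares of the superimposition, in squared units of
the host dissimilarity. We verify this closed form against a brute-force
rotation-grid oracle and against an independent Procrustes implementation
in the test suite rather than trusting the algebra alone. The statistic is
asymmetric: fitting hosts onto parasites tests the reverse dependence and
generally gives a different value. A symmetric, variance-normalized
variant exists but is not offered: with duplicated rows the per-column
variance normalization distorts the statistic's calibration, and the
asymmetric form keeps interpretable units.

## Inference

**Global test.** The null hypothesis — the host ordination does not
predict the parasite ordination — is simulated by permuting each row of
$A$ independently and uniformly (hosts randomly allocated to parasites).
Per-host link counts are preserved; parasite columns may become empty in a
permuted matrix, which is harmless because only realized links enter the
expansion. The PCoA decompositions depend on the distance matrices only,
so they are computed once and reused across permutations; each permutation
re-does only the expansion and the Procrustes fit, which makes 999
permutations cheap. The one-tailed P value uses the add-one rule
$P = (\#\{m^2_* \le m^2_{XY}\} + 1)/(N + 1)$: the observed statistic
counts as one realization of its own null, guaranteeing validity and a
non-zero minimum of $1/(N+1)$. A permuted configuration can degenerate
(every link on one parasite, so the centred $Y$ is zero); the fit then
explains nothing and the permuted statistic is taken as
$\mathrm{tr}(X'X)$, its natural limit.

**Per-link residuals.** Because $m^2_{XY} = \sum_i r^2_i$, the squared
residual of each link measures its contribution to the global lack of
fit. Rather than a per-link permutation test — which would require
multiple-testing control and sacrifice power — uncertainty is attached by
the jackknife: deleting link $i$ and refitting yields pseudovalues
$\varphi_{ij} = n\,r^2_j - (n-1)\,r^2_j(-i)$ for each surviving link $j$;
each link's estimate is the mean of its $n - 1$ pseudovalues, its standard
error the pseudovalue standard deviation over $\sqrt{n-1}$. The reference
graphics plot *upper* confidence limits only, so we report a one-sided
upper bound $\hat\varphi_j + t_{0.95,\,n-2}\,S_e$. The confidence level,
and the choice of $n-2$ versus $n-1$ degrees of freedom, are conventions
rather than derivations — both are exposed as arguments, and the defaults
are stated in every output log.

**Rival tests.** Two published global-fit tests are re-implemented for
benchmarking on byte-identical inputs. The ParaFit global statistic is the
sum of squared entries of the fourth-corner matrix $P'A'H$ built from the
two PCoA configurations and the association matrix; its published
description leaves the randomization unit open, so we default to the same
independent within-row permutation as the Procrustes test and expose a
whole-row shuffle as an alternative, validating the choice by Type I
calibration rather than bug-compatibility with any particular
implementation. The Hommola et al. cospeciation test (HCT) correlates,
over all $\binom{n}{2}$ link pairs, host distances with parasite
distances, and permutes host and parasite tip labels separately; it is
upper-tailed on the Pearson correlation. Our ParaFit statistic matches the
`ape` reference implementation to full precision on shared fixtures; the
statistic of HCT on perfectly congruent data is exactly 1.

## The synthetic-data generator

The simulation harness generates the study conditions under which the
tests are compared:

* **Null systems** (`null_system()`): independent random additive trees
  (recursive uniform splitting, the scheme of `ape::rtree`, with branch
  lengths Uniform(0, 1)) and a fixed number of links sampled without
  replacement from the host × parasite grid. Reference sizes are 10–20
  taxa per side with 10–35 links.
* **Ideal coevolution** (`coevolution_system()`): one tree for both
  phylogenies and identity links; the Procrustes fit is exact
  ($m^2 = 0$).
* **Degradation** (`add_random_links()`, `replace_links()`,
  `partly_congruent_system()`): random links added on top of the
  coevolutionary ones, coevolutionary links replaced by random ones
  (replacement may not recreate a removed or existing cell; an
  `allow_restore` flag relaxes this), or a parasite tree that shares only
  an induced subtree with the host tree. For the partly congruent
  scenario the parasite tree is the host subtree induced by a random
  congruent set joined, at a new root with Uniform(0, 1) connecting
  branches, to an independent random subtree; fewer than two congruent
  taxa pin no shared structure and fall back to a fully random pair.

These generators emulate tree shape and random association, not explicit
coevolutionary event histories (host switches, duplications, sorting
events), rate heterogeneity, or phylogenetic uncertainty. Calibration and
power results therefore speak to the statistical behaviour of the tests
under random additive trees, not to any particular biological system.

## Numerical choices

* Eigenvalue retention threshold $m \cdot \lambda_{max} \cdot 10^{-12}$,
  a machine-scale relative cut that keeps rank decisions stable across
  platforms; eigenvector signs are fixed by making each axis's
  largest-magnitude loading positive (Procrustes results are invariant to
  both choices).
* The Cailliez constant is declared zero when the uncorrected Gower
  matrix is already positive semi-definite within $10^{-8}$ relative
  tolerance, making the correction exactly idempotent.
* Distance matrices must be symmetric within $10^{-10}$ relative
  tolerance; smaller asymmetries (text-format rounding) are averaged
  away. Numeric output is written with 10 significant digits so
  read/write round-trips are lossless at text precision.
* Zero-padding to equal width happens before expansion for the ordinations
  and after expansion for any residual width mismatch; the order is
  mathematically irrelevant to $m^2$ and fixed for determinism.
* Permutation streams are implementation-defined but reproducible for a
  given seed and package version; every user-facing function takes a
  `seed` argument.

## Calibration summary

The test suite runs the full pipeline at reduced but adequate Monte-Carlo
sizes — 1,000 null simulations with 199 permutations per test for the
Type I checks (both 10- and 20-taxon designs), 200 simulations at the
ideal coevolutionary boundary, 1,000 simulations with all links replaced,
and a Kolmogorov–Smirnov uniformity check of the P values of every test
under each null design; `scripts/acceptance.R` repeats these runs (plus a
2,000 × 499 run to resolve the 0.01 tail) and writes the observed
rejection proportions. The package reports only what these runs compute:
rejection rates statistically indistinguishable from the nominal levels
under true nulls, uniform P values, and rejection of every ideal
coevolutionary system.

## Known limitations

PCoA configurations are a noisy representation of tree topology — pairs of
Euclidean distances cannot capture all of tree space — so these are tests
of congruence between *distance structures*, not strict topological
congruence. The Cailliez correction can inflate the total sum of squares.
Least-squares Procrustes is sensitive to outlying links (a resistant-fit
variant is out of scope). The jackknife bounds are approximate and their
level nominal; they are meant for ranking links and flagging uncertainty,
not for formal per-link hypothesis tests.
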