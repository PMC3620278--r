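# broom-style tidiers: tidy() returns the per-unit table of a result,
# glance() a one-row model summary.

#' Tidy a Procrustean cophylogenetic fit
#'
#' @param x A [paco_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per host-parasite link and its squared
#'   residual `r2`.
#' @export
tidy.paco_fit <- function(x, ...) {
  x$links
}

#' @rdname tidy.paco_fit
#' @export
glance.paco_fit <- function(x, ...) {
  tibble(m2 = x$m2, scale = x$scale,
         n_links = nrow(x$links),
         n_hosts = length(x$host_pco$labels),
         n_parasites = length(x$par_pco$labels),
         correction = x$correction)
}

#' Tidy a permutation test result
#'
#' @param x A `"cophylo_test"` (or `"paco_test"`) object.
#' @param ... Unused.
#' @return For `tidy()`, the null distribution as a tibble; for
#'   `glance()`, a one-row summary with the statistic and P value.
#' @export
tidy.cophylo_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null), statistic = x$null)
}

#' @rdname tidy.cophylo_test
#' @export
glance.cophylo_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         statistic_name = x$statistic_name, p_value = x$p_value,
         n_perm = x$n_perm, tail = x$tail)
}

#' Tidy a jackknife residual report
#'
#' @param x A [paco_jackknife()] object.
#' @param ... Unused.
#' @return The per-link table (tibble: `host`, `parasite`, `r2`,
#'   `estimate`, `se`, `upper`).
#' @export
tidy.paco_jackknife <- function(x, ...) {
  x$table
}

#' @rdname tidy.paco_jackknife
#' @export
glance.paco_jackknife <- function(x, ...) {
  tibble(m2 = x$m2, n_links = nrow(x$table), conf = x$conf, df = x$df,
         correction = x$correction)
}

#' Tidy a simulation experiment
#'
#' @param x A `"cophylo_experiment"` object.
#' @param ... Unused.
#' @return For `tidy()`, the rejection-rate table with bootstrap CIs; for
#'   `glance()`, a one-row configuration summary.
#' @export
tidy.cophylo_experiment <- function(x, ...) {
  x$rates
}

#' @rdname tidy.cophylo_experiment
#' @export
glance.cophylo_experiment <- function(x, ...) {
  cfg <- x$config
  tibble(scenario = cfg$scenario, n_sim = cfg$n_sim, n_perm = cfg$n_perm,
         tests = paste(cfg$tests, collapse = ","),
         correction = cfg$correction)
}
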