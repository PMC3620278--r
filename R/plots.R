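# Graphics: the Procrustes superimposition plot and the jackknifed
# residual bar plot, plus an ECDF plot for simulation experiments.

#' Procrustes superimposition plot
#'
#' Projects the superimposed configurations onto two ordination axes: host
#' positions are drawn as arrow tips, fitted parasite positions as dots,
#' and each host-parasite link as an arrow from the parasite to its host.
#' Arrow lengths are the projection of the residuals onto the chosen
#' axes and therefore underestimate the actual residuals in the
#' full-dimensional space.
#'
#' @param fit A [paco_fit()] (or [procrustes_m2()]) object.
#' @param axes Integer vector of length 2: which axes to draw.
#' @return A ggplot object.
#' @export
plot_superimposition <- function(fit, axes = c(1, 2)) {
  stopifnot(inherits(fit, "procrustes_fit"), length(axes) == 2)
  if (max(axes) > ncol(fit$X))
    stop("requested axes exceed the configuration width", call. = FALSE)
  labs <- if (!is.null(fit$links))
    paste(fit$links$host, fit$links$parasite, sep = "::")
  else as.character(seq_len(nrow(fit$X)))
  df <- tibble(link = labs,
               host_x = fit$X[, axes[1]], host_y = fit$X[, axes[2]],
               par_x = fit$fitted_Y[, axes[1]], par_y = fit$fitted_Y[, axes[2]])
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$par_x, y = .data$par_y,
                   xend = .data$host_x, yend = .data$host_y),
      arrow = grid::arrow(length = grid::unit(2, "mm")), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$par_x, y = .data$par_y),
                        size = 1.8) +
    ggplot2::labs(
      x = paste("Axis", axes[1]), y = paste("Axis", axes[2]),
      title = "Procrustes superimposition",
      subtitle = "dots: fitted parasite ordination; arrow tips: host ordination") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.paco_fit <- function(object, axes = c(1, 2), ...) {
  plot_superimposition(object, axes = axes)
}

#' Jackknifed residual bar plot
#'
#' One bar per host-parasite link at its jackknife estimate, an error bar
#' up to the one-sided upper confidence bound, and a dashed horizontal
#' line at the median of the plotted estimates for reference.
#'
#' @param report A [paco_jackknife()] object.
#' @return A ggplot object.
#' @export
plot_residual_bars <- function(report) {
  stopifnot(inherits(report, "paco_jackknife"))
  tab <- report$table
  if (nrow(tab) == 0L) stop("empty residual report", call. = FALSE)
  tab$link <- factor(paste(tab$host, tab$parasite, sep = "::"),
                     levels = paste(tab$host, tab$parasite, sep = "::"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$link, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate,
                                        ymax = .data$upper), width = 0.3) +
    ggplot2::geom_hline(yintercept = stats::median(tab$estimate),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "jackknifed squared residual",
                  title = "Contribution of individual host-parasite links") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @export
autoplot.paco_jackknife <- function(object, ...) {
  plot_residual_bars(object)
}

#' P value ECDF plot for a simulation experiment
#'
#' Empirical cumulative distribution of each test's P values against the
#' diagonal expected under a true null hypothesis.
#'
#' @param object A `"cophylo_experiment"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cophylo_experiment <- function(object, ...) {
  ggplot2::ggplot(object$p_values,
                  ggplot2::aes(x = .data$p_value, colour = .data$test)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "P value", y = "empirical CDF") +
    ggplot2::theme_minimal()
}
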