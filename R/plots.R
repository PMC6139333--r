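# ggplot2 visualisations for the main result types.

#' Plot posterior parameter densities
#'
#' Faceted marginal posterior densities of the adjusted draws, with the HPD
#' interval and mode marked.
#'
#' @param object A [estimate_parameters()] result.
#' @param params Parameters to plot (default: all estimated, natural scale).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.posterior_summary <- function(object,
                                       params = NULL, ...) {
  summ <- object$summary[!grepl("_mya$", object$summary$param), ]
  if (is.null(params)) params <- summ$param
  long <- object$sample[, intersect(params, names(object$sample)), drop = FALSE] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "param")
  marks <- summ[summ$param %in% params, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$mode),
                        linetype = 2) +
    ggplot2::geom_segment(data = marks,
                          ggplot2::aes(x = .data$hpd_lo, xend = .data$hpd_hi,
                                       y = 0, yend = 0), linewidth = 1.5,
                          colour = "steelblue") +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = sprintf("ABC posterior (%s)", object$model$label))
}

#' Plot posterior model probabilities
#'
#' @param object A [model_posterior()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$posterior,
                  ggplot2::aes(x = .data$model, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = NULL, y = "posterior model probability") +
    ggplot2::ylim(0, 1)
}

#' Plot per-locus pairwise PhiST
#'
#' Dot plot of pairwise PhiST by locus from a [summary_report()].
#'
#' @param report A `demabc_report`.
#' @return A ggplot object.
#' @export
plot_phist <- function(report) {
  d <- report$divergence
  d$pair <- paste(d$species_a, "vs", d$species_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus_id, y = .data$phi_st,
                                  colour = .data$pair)) +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Phi[ST]))
}
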