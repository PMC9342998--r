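#' Plot a simulated or measured trace set
#'
#' Current (and fluorescence, if present) time courses, one colour per
#' ligand concentration.
#'
#' @param object A `trace_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_set <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::any_of(c("y_curr", "y_flu")),
    names_to = "obs", values_to = "y")
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$y,
                                  colour = factor(.data$conc))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~obs, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal",
                  colour = "ligand (uM)") +
    ggplot2::theme_minimal()
}

#' Plot marginal posteriors of a fit
#'
#' @param object A `pkf_fit`.
#' @param true Optional named vector of true values drawn as vertical
#'   lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pkf_fit <- function(object, true = NULL, ...) {
  pars <- setdiff(names(object), c(".chain", ".iter", "lp"))
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           dplyr::all_of(pars),
                           names_to = "term", values_to = "value")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "seagreen", alpha = 0.4) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
  if (!is.null(true)) {
    td <- tibble::tibble(term = names(true), value = unname(unlist(true)))
    td <- td[td$term %in% pars, ]
    p <- p + ggplot2::geom_vline(data = td,
                                 ggplot2::aes(xintercept = .data$value),
                                 linetype = 2)
  }
  p
}

#' Plot residual autocorrelation with white-noise bands
#'
#' @param resid A `residual_series` (from [normalized_residuals()]) or
#'   an ACF tibble from [residual_acf()].
#' @param max_lag Largest lag (when `resid` is a residual series).
#' @return A ggplot object.
#' @export
plot_residual_acf <- function(resid, max_lag = 20) {
  a <- if ("acf" %in% names(resid)) resid else residual_acf(resid, max_lag)
  ggplot2::ggplot(a, ggplot2::aes(.data$lag, .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = -.data$band,
                                      ymax = .data$band),
                         fill = "grey80", alpha = 0.5) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    {if (all(c("obs", "conc") %in% names(a)))
      ggplot2::facet_grid(obs ~ conc)} +
    ggplot2::labs(x = "lag (samples)", y = "autocorrelation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
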