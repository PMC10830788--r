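#' Plot perturbed eigenvalue branches against the hole radius
#'
#' Draws \eqn{\lambda_n^m(\varepsilon)} for the requested degrees as the hole
#' radius grows, with the unstable interval \eqn{(\gamma L, \gamma M)} of the
#' supplied parameter set as dashed lines: any branch between the dashed
#' lines is excited and contributes to the pattern.
#'
#' @param params A [schnak_params()] object defining the interval.
#' @param n Degrees to draw (default `1:4`).
#' @param eps_max Largest hole radius (default 0.7).
#' @return A ggplot object.
#' @export
plot_perturbed_eigenvalues <- function(params, n = 1:4, eps_max = 0.7) {
  iv <- unstable_interval(params)
  grid <- expand.grid(n = n, eps = seq(0, eps_max, length.out = 80L))
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    nn <- grid$n[i]
    perturbed_eigenvalue(rep(nn, nn + 1L), 0:nn, grid$eps[i])
  }))
  curves$branch <- sprintf("(%d,%d)", curves$n, curves$m)
  p <- ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$epsilon, y = .data$value,
    colour = factor(.data$n), group = .data$branch
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hole radius (rad)",
                  y = expression(lambda[n]^m * (epsilon)),
                  colour = "degree n") +
    ggplot2::theme_minimal()
  if (!iv$empty) {
    p <- p + ggplot2::geom_hline(yintercept = c(iv$gamma_L, iv$gamma_M),
                                 linetype = "dashed")
  }
  p
}

#' Plot percentile summaries of ensemble metrics
#'
#' One panel per metric: the median against the hole radius with a ribbon
#' between the lowest and highest requested percentiles.
#'
#' @param object An `ensemble_summary` from [percentile_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_summary <- function(object, ...) {
  wide <- tidyr::pivot_wider(object, names_from = "percentile",
                             values_from = "value", names_prefix = "p")
  pcols <- sort(as.numeric(sub("^p", "", grep("^p", names(wide),
                                              value = TRUE))))
  lo <- sprintf("p%g", min(pcols))
  hi <- sprintf("p%g", max(pcols))
  mid <- sprintf("p%g", pcols[ceiling(length(pcols) / 2)])
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$epsilon)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo]],
                                      ymax = .data[[hi]],
                                      fill = factor(.data$mode)),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[mid]],
                                    colour = factor(.data$mode))) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "hole radius (rad)", y = NULL,
                  colour = "mode", fill = "mode") +
    ggplot2::theme_minimal()
}
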