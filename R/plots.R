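#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot expected mean fitness against population size
#'
#' Draws the closed-form expected mean fitness as a function of population
#' size for one or more trait architectures, on a log-x axis, marking each
#' finite fitness-maximizing size where one exists.
#'
#' @param params Parameter tibble; one curve per distinct `(u, vm, vs, ve)`
#'   combination (the `ne` column is ignored).
#' @param ne_range Range of population sizes to draw (log-spaced).
#' @param n_points Points per curve.
#' @return A ggplot object.
#' @export
plot_fitness_curves <- function(params, ne_range = c(1, 1e6),
                                n_points = 200) {
  params <- validate_params(params)
  archs <- dplyr::distinct(params, .data$u, .data$vm, .data$vs, .data$ve)
  ne_grid <- 10^seq(log10(ne_range[1]), log10(ne_range[2]),
                    length.out = n_points)
  curves <- archs |>
    dplyr::mutate(arch = sprintf("u = %g, vm = %g", .data$u, .data$vm)) |>
    dplyr::group_by(.data$arch) |>
    dplyr::reframe(
      ne = ne_grid,
      wbar = expected_mean_fitness(
        model_params(ne = ne_grid, u = .data$u[1], vm = .data$vm[1],
                     vs = .data$vs[1], ve = .data$ve[1]))
    )
  peaks <- archs |>
    dplyr::mutate(arch = sprintf("u = %g, vm = %g", .data$u, .data$vm)) |>
    dplyr::bind_cols(optimal_ne(dplyr::mutate(archs, ne = 1))) |>
    dplyr::filter(.data$finite, .data$ne_star >= ne_range[1],
                  .data$ne_star <= ne_range[2]) |>
    dplyr::mutate(wbar = expected_mean_fitness(
      model_params(ne = .data$ne_star, u = .data$u, vm = .data$vm,
                   vs = .data$vs, ve = .data$ve)))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$ne, y = .data$wbar,
                                    colour = .data$arch)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "population size (Ne)",
                  y = "expected mean fitness",
                  colour = "architecture") +
    ggplot2::theme_minimal()
  if (nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$ne_star, y = .data$wbar, colour = .data$arch),
      shape = 17, size = 2.5
    )
  }
  p
}

#' Plot a validation sweep
#'
#' Overlays the simulated mean fitness per grid cell (points with 95% CI
#' error bars) on the closed-form prediction curves, one panel per `(u, vm)`
#' architecture, log-x — the standard visual check of the theory against the
#' Wright-Fisher simulations.
#'
#' @param object A [run_sweep()] result.
#' @param ne_range Range for the prediction curves; defaults to the simulated
#'   sizes widened threefold each way.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stabsel_sweep <- function(object, ne_range = NULL, ...) {
  cells <- dplyr::filter(tibble::as_tibble(object), !.data$failed)
  if (nrow(cells) == 0) stop("no successful cells to plot.", call. = FALSE)
  if (is.null(ne_range)) {
    ne_range <- range(cells$ne) * c(1 / 3, 3)
  }
  ne_grid <- 10^seq(log10(ne_range[1]), log10(ne_range[2]),
                    length.out = 150)
  curves <- cells |>
    dplyr::distinct(.data$u, .data$vm, .data$vs, .data$ve) |>
    dplyr::group_by(.data$u, .data$vm) |>
    dplyr::reframe(
      vs = .data$vs[1], ve = .data$ve[1], ne = ne_grid,
      predicted = expected_mean_fitness(
        model_params(ne = ne_grid, u = .data$u[1], vm = .data$vm[1],
                     vs = .data$vs[1], ve = .data$ve[1]))
    )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$ne)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$predicted)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$simulated, ymin = .data$ci_low,
                   ymax = .data$ci_high),
      colour = "#2166ac", size = 0.3
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$u), cols = ggplot2::vars(.data$vm),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "population size (N)", y = "mean fitness") +
    ggplot2::theme_minimal()
}

#' Plot simulation time series
#'
#' Recorded mean fitness, genetic variance and mean phenotype per replicate
#' over generations, with the closed-form equilibrium predictions as
#' horizontal reference lines.
#'
#' @param object A `wf_sim` object from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wf_sim <- function(object, ...) {
  cfg <- object$config
  pred <- predict_fitness(model_params(
    ne = cfg$n, u = cfg$u, vm = cfg$vm,
    vs = if (is.finite(cfg$vs)) cfg$vs else 1e12, ve = cfg$ve
  ))
  long <- tidyr::pivot_longer(object$samples,
                              c("mean_fitness", "vg", "pbar"),
                              names_to = "quantity")
  refs <- tibble::tibble(
    quantity = c("mean_fitness", "vg", "pbar"),
    value = c(pred$expected_wbar, pred$vg, cfg$optimum)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value,
                                     group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}
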