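#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' a forest plot of lnRR effect sizes, ambient-versus-OA density bands,
#' the ΔSi:N-per-metre against pH scatter with its fitted line, a column
#' profile of fluxes and Si:N, and box-model trajectories.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name silicatepump-plots
NULL

#' @rdname silicatepump-plots
#' @exportS3Method ggplot2::autoplot
autoplot.lnrr_effects <- function(object, ...) {
  d <- dplyr::bind_rows(as_tibble(object), overall_effect(object))
  d$site <- factor(d$site, levels = rev(d$site))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lnrr, y = .data$site)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "lnRR of export Si:N (OA vs ambient)", y = NULL,
                  shape = "95% CI excludes 0")
}

#' @rdname silicatepump-plots
#' @exportS3Method ggplot2::autoplot
autoplot.density_comparison <- function(object, ...) {
  d <- purrr::list_rbind(purrr::map(seq_len(nrow(object)), function(i) {
    dplyr::bind_rows(
      dplyr::mutate(as_tibble(object$ambient[[i]]), treatment = "ambient"),
      dplyr::mutate(as_tibble(object$oa[[i]]), treatment = "OA")
    ) |> dplyr::mutate(site = object$site[i])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grid, colour = .data$treatment,
                                  fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                      ymax = .data$band_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$density)) +
    ggplot2::facet_wrap(~site, scales = "free") +
    ggplot2::labs(x = "export Si:N", y = "probability density",
                  colour = NULL, fill = NULL)
}

#' @rdname silicatepump-plots
#' @param slopes The slope table the fit was computed from (needed for the
#'   scatter layer); defaults to the model frame stored in the fit.
#' @exportS3Method ggplot2::autoplot
autoplot.ph_fit <- function(object, slopes = NULL, ...) {
  d <- slopes %||% as_tibble(object$fit$model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_ph,
                                  y = .data$delta_sin_per_m)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = "mean pH over profile depth range",
                  y = expression(Delta * "Si:N (m"^-1 * ")"))
}

#' @rdname silicatepump-plots
#' @exportS3Method ggplot2::autoplot
autoplot.column_profile <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("si_flux", "n_flux", "si_n"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "depth (m)")
}

#' @rdname silicatepump-plots
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$year, y = .data$si,
                               colour = .data$box)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = expression("Si(OH)"[4] * " (mmol m"^-3 * ")"),
                  colour = "box",
                  title = sprintf("%s, pH effect %s", object$scenario,
                                  if (object$ph_effect) "on" else "off"))
}
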