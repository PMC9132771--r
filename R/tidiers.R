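#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns one row per estimated term or
#' unit, `glance()` a one-row model summary.
#'
#' @param x A fitted/result object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name silicatepump-tidiers
NULL

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::tidy
tidy.ph_fit <- function(x, ...) {
  tibble(term = x$predictor,
         estimate = x$slope,
         std_estimate = x$std_estimate,
         conf_low = x$ci[, 1],
         conf_high = x$ci[, 2])
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::glance
glance.ph_fit <- function(x, ...) {
  tibble(r2 = x$r2, f_stat = x$f_stat, p_value = x$p_value, n = x$n,
         intercept = x$intercept)
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::tidy
tidy.lnrr_effects <- function(x, ...) {
  tibble(term = x$site, estimate = x$lnrr,
         conf_low = x$ci_low, conf_high = x$ci_high,
         significant = x$significant)
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::glance
glance.lnrr_effects <- function(x, ...) {
  ov <- overall_effect(x, level = attr(x, "level") %||% 0.95)
  tibble(lnrr_overall = ov$lnrr,
         percent_change = 100 * (exp(ov$lnrr) - 1),
         ci_low = ov$ci_low, ci_high = ov$ci_high,
         n_studies = nrow(x),
         n_significant = sum(x$significant))
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::tidy
tidy.scenario_run <- function(x, ...) {
  x$trajectory
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::glance
glance.scenario_run <- function(x, ...) {
  b <- x$geometry$boxes
  vol <- setNames(b$volume_m3, b$box)
  last <- dplyr::filter(x$trajectory, .data$year == max(.data$year))
  surf <- startsWith(b$class[match(last$box, b$box)], "surface")
  tibble(scenario = x$scenario, ph_effect = x$ph_effect,
         end_year = max(last$year),
         surface_si = sum(last$si[surf] * vol[last$box[surf]]) /
           sum(vol[last$box[surf]]),
         total_si = sum(last$si * vol[last$box]),
         production = x$production$production[which.max(x$production$year)])
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::tidy
tidy.column_profile <- function(x, ...) {
  as_tibble(unclass(x)[c("depth_m", "si_flux", "n_flux", "si_n")])
}

#' @rdname silicatepump-tidiers
#' @exportS3Method generics::glance
glance.column_profile <- function(x, ...) {
  n <- nrow(x)
  tibble(delta_sin_per_m = attr(x, "delta_sin_per_m"),
         si_n_surface = x$si_n[1], si_n_trap = x$si_n[n],
         si_transfer = x$si_flux[n] / x$si_flux[1],
         n_transfer = x$n_flux[n] / x$n_flux[1])
}
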