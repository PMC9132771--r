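#' Generate a synthetic gridded pH/temperature climatology
#'
#' A smooth, idealized depth-by-latitude climatology standing in for a
#' gridded observational product.  Columns decrease from the surface to
#' depth so that the surface-minus-3000 m pH difference is ~0.3--0.35 at
#' every latitude, and the latitude-mean surface-minus-3000 m temperature
#' difference is ~15--20 °C — the modern vertical gradients over which the
#' temperature effect on opal dissolution is roughly tenfold larger than
#' the pH effect.  A small seeded perturbation makes distinct seeds
#' distinguishable while preserving those gradients.
#'
#' @param seed Integer seed.
#' @param depths Depth grid, m.
#' @param lats Latitude grid, degrees.
#' @return A tibble with columns `depth_m`, `lat`, `ph`, `temp_c`.
#' @export
gen_climatology <- function(seed = 1L,
                            depths = seq(0, 4000, by = 250),
                            lats = seq(-75, 75, by = 15)) {
  withr_seed(seed, {
    grid <- tidyr::expand_grid(depth_m = depths, lat = lats)
    # vertical shape: most of the gradient in the upper 1000 m, saturating
    # below; s(0) = 0, s(3000) ~ 0.97, s(Inf) -> 1
    s <- 1 - exp(-grid$depth_m / 850)
    surf_t <- 30 - 29 * (abs(grid$lat) / 75)^1.7   # 1..30 degC at surface
    deep_t <- 1.0
    surf_ph <- 8.09 + 0.03 * (abs(grid$lat) / 75)  # slightly higher at poles
    dph <- 0.335                                   # full vertical pH drop
    ph <- surf_ph - dph * s + rnorm(nrow(grid), 0, 0.004)
    temp <- surf_t - (surf_t - deep_t) * s + rnorm(nrow(grid), 0, 0.15)
    dplyr::arrange(tibble(depth_m = grid$depth_m, lat = grid$lat,
                          ph = ph, temp_c = temp),
                   .data$lat, .data$depth_m)
  })
}

#' Generate an extended RCP scenario forcing for the box model
#'
#' Per-box pH and temperature anomaly trajectories for 1750--2200 relative
#' to preindustrial, for the extended scenarios RCP6.0 and RCP8.5.
#' Anomalies are zero before 1850, then follow a smooth quadratic ramp to
#' the year-2100 value and a linear continuation to 2200.  Default surface
#' pH anomalies are −0.40 (2100) and −0.65 (2200) for RCP8.5 and −0.25 /
#' −0.35 for RCP6.0, consistent with the projected 0.2--0.4 surface pH
#' decline by 2100; surface warming reaches +3.0 / +4.5 °C (RCP8.5) and
#' +1.5 / +2.0 °C (RCP6.0).  Subsurface boxes feel 40 % of the surface
#' anomaly with a 50-year lag, capturing the delayed, damped penetration
#' of both signals into the ocean interior.  These trajectories are
#' documented, overridable conventions, not observational products.
#'
#' @param scenario `"RCP8.5"` or `"RCP6.0"`.
#' @param geometry A [default_geometry()]-style box geometry naming the
#'   boxes to force.
#' @param years Years covered (default 1750--2200).
#' @param ph_2100,ph_2200 Surface pH anomalies at 2100 and 2200 (<= 0);
#'   defaults depend on `scenario`.
#' @param t_2100,t_2200 Surface temperature anomalies at 2100 and 2200, °C.
#' @param deep_fraction Fraction of the surface anomaly felt by subsurface
#'   boxes.
#' @param deep_lag Subsurface lag, years.
#' @return An object of class `rcp_forcing`: a tibble with columns `year`,
#'   `box`, `ph_anomaly`, `temp_anomaly` and attribute `scenario`.
#' @examples
#' f <- gen_rcp_forcing("RCP8.5")
#' dplyr::filter(f, year == 2100, box == "srf_low")
#' @export
gen_rcp_forcing <- function(scenario = c("RCP8.5", "RCP6.0"),
                            geometry = default_geometry(),
                            years = 1750:2200,
                            ph_2100 = NULL, ph_2200 = NULL,
                            t_2100 = NULL, t_2200 = NULL,
                            deep_fraction = 0.4, deep_lag = 50) {
  if (!is.character(scenario) || !scenario[1] %in% c("RCP8.5", "RCP6.0")) {
    abort(sprintf("Unknown scenario `%s`. Valid scenarios: RCP8.5, RCP6.0.",
                  as.character(scenario[1])),
          class = "silicatepump_unknown_scenario")
  }
  scenario <- scenario[1]
  defaults <- list(
    "RCP8.5" = list(ph_2100 = -0.40, ph_2200 = -0.65, t_2100 = 3.0, t_2200 = 4.5),
    "RCP6.0" = list(ph_2100 = -0.25, ph_2200 = -0.35, t_2100 = 1.5, t_2200 = 2.0)
  )[[scenario]]
  ph_2100 <- ph_2100 %||% defaults$ph_2100
  ph_2200 <- ph_2200 %||% defaults$ph_2200
  t_2100 <- t_2100 %||% defaults$t_2100
  t_2200 <- t_2200 %||% defaults$t_2200

  surface_curve <- function(yr, a2100, a2200) {
    out <- numeric(length(yr))
    ramp <- yr > 1850 & yr <= 2100
    out[ramp] <- a2100 * ((yr[ramp] - 1850) / 250)^2
    late <- yr > 2100
    out[late] <- a2100 + (a2200 - a2100) * (yr[late] - 2100) / 100
    out
  }
  is_surface <- startsWith(geometry$boxes$box, "srf")
  boxes <- geometry$boxes$box
  ph_surf <- surface_curve(years, ph_2100, ph_2200)
  t_surf <- surface_curve(years, t_2100, t_2200)
  ph_deep <- deep_fraction * surface_curve(years - deep_lag, ph_2100, ph_2200)
  t_deep <- deep_fraction * surface_curve(years - deep_lag, t_2100, t_2200)

  out <- purrr::list_rbind(purrr::map(seq_along(boxes), function(i) {
    tibble(year = years, box = boxes[i],
           ph_anomaly = if (is_surface[i]) ph_surf else ph_deep,
           temp_anomaly = if (is_surface[i]) t_surf else t_deep)
  }))
  structure(out, class = c("rcp_forcing", class(out)), scenario = scenario)
}
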