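#' Filter a sediment-trap compilation for eligible profiles
#'
#' Applies the two eligibility rules for computing a Si:N-versus-depth
#' slope: a level counts only where Si and N fluxes were measured
#' simultaneously (rows with a missing or non-positive flux are dropped),
#' and a profile is kept only if at least `min_levels` paired levels with
#' distinct depths remain.  An exclusion log accounts for every input
#' profile, so eligible plus excluded always equals the input count.
#'
#' @param compilation A `trap_compilation` from [gen_trap_compilation()]
#'   or a tibble in the trap schema (`station_id`, `depth_m`, `si_flux`,
#'   `n_flux`, optionally `lat`, `lon`).
#' @param min_levels Minimum paired depth levels (>= 3; with fewer, a
#'   depth slope cannot be estimated meaningfully).
#' @return The eligible profile rows as a tibble, with attribute
#'   `"exclusions"` — a tibble of `station_id` and `reason` for every
#'   excluded profile — also retrievable with [trap_exclusions()].
#' @export
filter_profiles <- function(compilation, min_levels = 3) {
  profiles <- if (inherits(compilation, "trap_compilation")) {
    compilation$profiles
  } else {
    as_tibble(compilation)
  }
  require_columns(profiles, c("station_id", "depth_m", "si_flux", "n_flux"),
                  "Trap compilation")
  if (!nrow(profiles)) {
    abort("The compilation contains no profiles.",
          class = "silicatepump_empty_compilation")
  }
  stop_if_not_count(min_levels, "min_levels", min = 3L)
  paired <- profiles |>
    dplyr::filter(is.finite(.data$si_flux), is.finite(.data$n_flux),
                  .data$si_flux > 0, .data$n_flux > 0)
  status <- profiles |>
    dplyr::distinct(.data$station_id) |>
    dplyr::left_join(
      paired |>
        dplyr::group_by(.data$station_id) |>
        dplyr::summarise(n_levels = dplyr::n_distinct(.data$depth_m),
                         .groups = "drop"),
      by = "station_id"
    ) |>
    dplyr::mutate(n_levels = tidyr::replace_na(.data$n_levels, 0L),
                  eligible = .data$n_levels >= min_levels)
  exclusions <- status |>
    dplyr::filter(!.data$eligible) |>
    dplyr::transmute(.data$station_id, reason = "insufficient depth levels")
  eligible <- paired |>
    dplyr::semi_join(dplyr::filter(status, .data$eligible), by = "station_id")
  structure(eligible, exclusions = exclusions,
            n_input = nrow(dplyr::distinct(profiles, .data$station_id)))
}

#' Exclusion log of a filtered compilation
#'
#' @param filtered Output of [filter_profiles()].
#' @return A tibble with `station_id` and `reason` per excluded profile.
#' @export
trap_exclusions <- function(filtered) {
  attr(filtered, "exclusions") %||%
    abort("`filtered` does not carry an exclusion log; run filter_profiles() first.")
}

#' Si:N-versus-depth slope of a single trap profile
#'
#' Ordinary least squares of the per-level Si:N ratio (molar
#' `si_flux / n_flux`) on depth.  The slope, ΔSi:N per metre, measures the
#' preferential preservation of opal relative to organic nitrogen during
#' sinking; profiles whose slope is not statistically distinguishable from
#' zero at level `alpha` (for example because lateral advection blurred the
#' depth structure) are flagged `retained = FALSE` and drop out of the
#' subsequent pH regression.
#'
#' @param profile Tibble with columns `depth_m`, `si_flux`, `n_flux` (one
#'   station).
#' @param alpha Two-sided significance level for retaining a profile.
#' @return A one-row tibble: `station_id`, `delta_sin_per_m`, `p_value`,
#'   `r2`, `depth_min`, `depth_max`, `n_levels`, `retained`.
#' @export
profile_slope <- function(profile, alpha = 0.05) {
  require_columns(profile, c("depth_m", "si_flux", "n_flux"), "Profile")
  if (var(profile$depth_m) == 0) {
    abort("Profile has zero depth variance; cannot fit a slope.",
          class = "silicatepump_degenerate_profile")
  }
  d <- dplyr::mutate(profile, si_n = .data$si_flux / .data$n_flux)
  fit <- lm(si_n ~ depth_m, data = d)
  sm <- summary(fit)
  p <- sm$coefficients["depth_m", "Pr(>|t|)"]
  if (!is.finite(p)) p <- 1  # perfectly flat or saturated fits: not retained
  tibble(
    station_id = if ("station_id" %in% names(d)) d$station_id[1] else NA_character_,
    delta_sin_per_m = unname(coef(fit)["depth_m"]),
    p_value = p,
    r2 = sm$r.squared,
    depth_min = min(d$depth_m), depth_max = max(d$depth_m),
    n_levels = nrow(d),
    retained = p < alpha
  )
}

#' Per-station slopes for a filtered compilation
#'
#' @param profiles Eligible profile rows from [filter_profiles()].
#' @param alpha Significance level for [profile_slope()].
#' @param keep_all Keep non-retained stations in the output (flagged)?
#'   Default drops them, matching the significance filter applied before
#'   the pH regression.
#' @return A tibble of class `profile_slopes`, one row per (retained)
#'   station.
#' @export
profile_slopes <- function(profiles, alpha = 0.05, keep_all = FALSE) {
  out <- profiles |>
    dplyr::group_by(.data$station_id) |>
    dplyr::group_modify(function(d, key) profile_slope(d, alpha = alpha)[-1]) |>
    dplyr::ungroup()
  if (!keep_all) out <- dplyr::filter(out, .data$retained)
  structure(out, class = c("profile_slopes", class(out)), alpha = alpha)
}

#' Attach climatological pH and temperature to profile slopes
#'
#' For each station, averages the climatology over the profile's depth
#' range at the nearest latitude column: the piecewise-linear pH and
#' temperature profiles are integrated over `[depth_min, depth_max]` and
#' divided by the range (a depth-weighted mean, exact for linear
#' variation).
#'
#' @param slopes A [profile_slopes()] tibble; must carry `lat` per station
#'   or be accompanied by `stations`.
#' @param climatology Tibble with columns `depth_m`, `lat`, `ph`, `temp_c`
#'   (e.g. [gen_climatology()]).
#' @param stations Optional tibble `station_id`, `lat` used when `slopes`
#'   lacks latitudes.
#' @return `slopes` with columns `mean_ph` and `mean_temp` added.
#' @export
attach_environment <- function(slopes, climatology, stations = NULL) {
  require_columns(climatology, c("depth_m", "lat", "ph", "temp_c"),
                  "Climatology")
  if (!"lat" %in% names(slopes)) {
    if (is.null(stations)) {
      abort("`slopes` has no `lat` column; supply `stations` with station_id and lat.",
            class = "silicatepump_schema_error")
    }
    slopes <- dplyr::left_join(slopes,
                               dplyr::select(stations, "station_id", "lat"),
                               by = "station_id")
  }
  lat_cols <- sort(unique(climatology$lat))
  depth_cover <- range(climatology$depth_m)
  env <- purrr::pmap(
    list(slopes$station_id, slopes$lat, slopes$depth_min, slopes$depth_max),
    function(sid, lat, d0, d1) {
      if (is.na(lat) || lat < min(lat_cols) - 10 || lat > max(lat_cols) + 10) {
        abort(sprintf("Station %s (lat %.1f) lies outside the climatology grid.",
                      sid, lat),
              class = "silicatepump_climatology_gap")
      }
      if (d0 < depth_cover[1] || d1 > depth_cover[2]) {
        abort(sprintf(
          "Climatology gap for station %s: depth range %.0f-%.0f m not covered.",
          sid, d0, d1), class = "silicatepump_climatology_gap")
      }
      col <- climatology[climatology$lat ==
                           lat_cols[which.min(abs(lat_cols - lat))], ]
      col <- col[order(col$depth_m), ]
      depth_mean <- function(y) {
        if (d1 == d0) return(approx(col$depth_m, y, xout = d0)$y)
        zz <- sort(unique(c(col$depth_m[col$depth_m >= d0 & col$depth_m <= d1],
                            d0, d1)))
        yy <- approx(col$depth_m, y, xout = zz)$y
        trapz(zz, yy) / (d1 - d0)
      }
      c(ph = depth_mean(col$ph), temp = depth_mean(col$temp_c))
    }
  )
  slopes$mean_ph <- purrr::map_dbl(env, "ph")
  slopes$mean_temp <- purrr::map_dbl(env, "temp")
  slopes
}

#' Regression of ΔSi:N per metre on mean pH
#'
#' Ordinary least squares of the per-profile depth slope of Si:N on the
#' climatological mean pH over each profile's depth range.  A negative
#' coefficient means Si preservation during sinking strengthens as pH
#' falls — the water-column fingerprint of pH-sensitive opal dissolution.
#'
#' @param slopes A tibble with columns `delta_sin_per_m` and `mean_ph`
#'   (e.g. [attach_environment()] output or generator stations joined in).
#' @param level Confidence level for the slope interval.
#' @return An object of class `ph_fit`: a wrapped `lm` with a one-row
#'   summary tibble available through [tidy()]/[glance()], and fields
#'   `slope`, `intercept`, `r2`, `p_value`, `f_stat`, `n`, `ci`.
#' @examples
#' comp <- gen_trap_compilation(trap_compilation_config(n_profiles = 40))
#' sl <- filter_profiles(comp) |> profile_slopes()
#' fit <- ph_regression(dplyr::left_join(sl, comp$stations, by = "station_id"))
#' glance(fit)
#' @export
ph_regression <- function(slopes, level = 0.95) {
  require_columns(slopes, c("delta_sin_per_m", "mean_ph"), "Slope table")
  if (nrow(slopes) < 3L) {
    abort("At least 3 profiles are needed for the pH regression.",
          class = "silicatepump_insufficient_data")
  }
  if (var(slopes$mean_ph) == 0) {
    abort("Degenerate predictor: mean pH is constant across profiles.",
          class = "silicatepump_degenerate_predictor")
  }
  fit <- lm(delta_sin_per_m ~ mean_ph, data = slopes)
  new_ph_fit(fit, predictor = "mean_ph", n = nrow(slopes), level = level)
}

#' Multiple regression of ΔSi:N per metre on pH and temperature
#'
#' Joint ordinary least squares with climatological mean pH and
#' temperature as predictors, reporting partial tests and standardized
#' coefficients (predictors and response scaled to unit variance) so the
#' two effect sizes can be compared directly — in the observational
#' compilation temperature carries an influence of magnitude comparable to
#' pH.
#'
#' @param slopes Tibble with `delta_sin_per_m`, `mean_ph`, `mean_temp`.
#' @param level Confidence level.
#' @param max_cor Collinearity guard: error if |cor(pH, T)| exceeds this.
#' @return A `ph_fit` object with two predictor rows; `tidy()` includes a
#'   `std_estimate` column of standardized coefficients.
#' @export
ph_temperature_regression <- function(slopes, level = 0.95, max_cor = 0.99) {
  require_columns(slopes, c("delta_sin_per_m", "mean_ph", "mean_temp"),
                  "Slope table")
  if (nrow(slopes) < 4L) {
    abort("At least 4 profiles are needed for the two-predictor regression.",
          class = "silicatepump_insufficient_data")
  }
  r <- stats::cor(slopes$mean_ph, slopes$mean_temp)
  if (is.finite(r) && abs(r) > max_cor) {
    abort(sprintf("pH and temperature are collinear (|r| = %.3f > %.2f).",
                  abs(r), max_cor),
          class = "silicatepump_collinearity")
  }
  fit <- lm(delta_sin_per_m ~ mean_ph + mean_temp, data = slopes)
  new_ph_fit(fit, predictor = c("mean_ph", "mean_temp"),
             n = nrow(slopes), level = level)
}

new_ph_fit <- function(fit, predictor, n, level) {
  sm <- summary(fit)
  f <- sm$fstatistic
  p_overall <- unname(pf(f[1], f[2], f[3], lower.tail = FALSE))
  ci <- stats::confint(fit, level = level)
  sd_y <- sd(fit$model[[1]])
  std <- vapply(predictor, function(pr) {
    unname(coef(fit)[pr]) * sd(fit$model[[pr]]) / sd_y
  }, numeric(1))
  structure(
    list(fit = fit, predictor = predictor,
         slope = unname(coef(fit)[predictor]),
         intercept = unname(coef(fit)["(Intercept)"]),
         std_estimate = std,
         r2 = sm$r.squared, f_stat = unname(f[1]), p_value = p_overall,
         n = n, ci = ci[predictor, , drop = FALSE], level = level),
    class = "ph_fit"
  )
}

#' @export
print.ph_fit <- function(x, ...) {
  cat("<ph_fit>  Delta Si:N per m regressed on:",
      paste(x$predictor, collapse = " + "), "\n")
  for (i in seq_along(x$predictor)) {
    cat(sprintf("  %-10s slope = %.4g  [%.4g, %.4g]\n", x$predictor[i],
                x$slope[i], x$ci[i, 1], x$ci[i, 2]))
  }
  cat(sprintf("  R2 = %.3f, F = %.1f, p = %.3g, n = %d\n",
              x$r2, x$f_stat, x$p_value, x$n))
  invisible(x)
}
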