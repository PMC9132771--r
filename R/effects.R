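#' Pool mesocosms into ambient and OA treatment groups
#'
#' Assigns each mesocosm to the ambient group (pCO2 at or below
#' `ambient_max`) or the OA group (pCO2 inside `oa_window`, by default
#' 700--1000 μatm, the end-of-century range spanned by the RCP6.0--RCP8.5
#' scenarios).  Mesocosms outside both windows are excluded and counted.
#' The pooled observation per mesocosm is its time-mean Si:N in the
#' requested compartment — mesocosm means, not daily samples, are the
#' replication unit for effect-size variances, avoiding temporal
#' pseudo-replication.
#'
#' @param data A mesocosm study tibble in the schema of
#'   [gen_mesocosm_study()] (one or several sites).
#' @param oa_window Two-element pCO2 window defining the OA treatment, μatm.
#' @param ambient_max Upper pCO2 bound of the ambient group, μatm.
#' @param compartment `"export"` or `"suspended"`.
#' @return A tibble with one row per pooled mesocosm: `site`,
#'   `mesocosm_id`, `pco2_uatm`, `treatment` (`"ambient"`/`"oa"`) and
#'   `si_n` (the mesocosm-mean ratio).  The number of excluded mesocosms
#'   per site is carried in attribute `"excluded"`.
#' @examples
#' study <- gen_mesocosm_study(mesocosm_site_config(), seed = 1)
#' pool_treatments(study)
#' @export
pool_treatments <- function(data, oa_window = c(700, 1000),
                            ambient_max = 500, compartment = "export") {
  require_columns(data, c("site", "mesocosm_id", "pco2_uatm", "compartment",
                          "si", "n"), "Mesocosm study table")
  stopifnot(length(oa_window) == 2L, oa_window[2] > oa_window[1])
  comp <- match.arg(compartment, c("export", "suspended"))
  meso <- data |>
    dplyr::filter(.data$compartment == comp) |>
    dplyr::group_by(.data$site, .data$mesocosm_id, .data$pco2_uatm) |>
    dplyr::summarise(si_n = mean(.data$si / .data$n), .groups = "drop") |>
    dplyr::mutate(treatment = dplyr::case_when(
      .data$pco2_uatm <= ambient_max ~ "ambient",
      .data$pco2_uatm >= oa_window[1] & .data$pco2_uatm <= oa_window[2] ~ "oa",
      TRUE ~ NA_character_
    ))
  excluded <- meso |>
    dplyr::filter(is.na(.data$treatment)) |>
    dplyr::count(.data$site, name = "n_excluded")
  if (nrow(excluded)) {
    inform(sprintf(
      "Excluded %d mesocosm(s) outside both treatment windows (%s).",
      sum(excluded$n_excluded),
      paste(excluded$site, excluded$n_excluded, sep = ": ", collapse = "; ")
    ))
  }
  pooled <- dplyr::filter(meso, !is.na(.data$treatment))
  counts <- pooled |>
    dplyr::count(.data$site, .data$treatment) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "n",
                       values_fill = 0L)
  group_n <- function(nm) {
    if (nm %in% names(counts)) counts[[nm]] else rep(0L, nrow(counts))
  }
  bad <- counts$site[group_n("ambient") == 0 | group_n("oa") == 0]
  if (length(bad)) {
    abort(sprintf("Empty treatment group after pooling at site(s): %s.",
                  paste(unique(bad), collapse = ", ")),
          class = "silicatepump_pooling_error")
  }
  pooled <- dplyr::select(pooled, "site", "mesocosm_id", "pco2_uatm",
                          "treatment", "si_n")
  attr(pooled, "excluded") <- excluded
  attr(pooled, "compartment") <- comp
  pooled
}

#' Log response ratio of two treatment groups
#'
#' The meta-analytic effect size \eqn{\mathrm{lnRR} = \ln \bar{X}_{OA} -
#' \ln \bar{X}_{control}}, where each \eqn{\bar{X}} is the arithmetic mean
#' of the group's Si:N observations.  Positive values mean the OA
#' treatment increased export Si:N.
#'
#' @param oa,control Numeric vectors of Si:N observations (one per
#'   mesocosm), all positive.
#' @return The lnRR (dimensionless scalar).
#' @examples
#' ln_response_ratio(1.17, 1)  # 0.157, printed as 0.16
#' @export
ln_response_ratio <- function(oa, control) {
  if (!length(oa) || !length(control)) {
    abort("Both groups must be non-empty.", class = "silicatepump_domain_error")
  }
  m_oa <- mean(oa)
  m_ct <- mean(control)
  if (!is.finite(m_oa) || !is.finite(m_ct) || m_oa <= 0 || m_ct <= 0) {
    abort("Group means must be positive for a log response ratio.",
          class = "silicatepump_domain_error")
  }
  log(m_oa) - log(m_ct)
}

#' Effect size with delta-method variance and confidence interval
#'
#' Computes the lnRR of two groups together with its large-sample variance
#' \deqn{v = s_{OA}^2 / (n_{OA} \bar{X}_{OA}^2) +
#'       s_{ctrl}^2 / (n_{ctrl} \bar{X}_{ctrl}^2),}
#' the delta-method form built from the pooled group standard deviations
#' that is standard in response-ratio meta-analysis.  Confidence limits use
#' normal quantiles, and the effect is flagged significant when the
#' interval excludes zero.
#'
#' @inheritParams ln_response_ratio
#' @param level Confidence level (default 0.95).
#' @param site Optional site label carried into the result.
#' @return A one-row tibble: `site`, `lnrr`, `variance`, `ci_low`,
#'   `ci_high`, `n_oa`, `n_control`, `significant`.
#' @export
effect_confidence <- function(oa, control, level = 0.95, site = NA_character_) {
  if (length(oa) < 2L || length(control) < 2L) {
    abort("Each group needs >= 2 observations to estimate a variance.",
          class = "silicatepump_insufficient_replication")
  }
  stop_if_not_number(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  lnrr <- ln_response_ratio(oa, control)
  v <- var(oa) / (length(oa) * mean(oa)^2) +
    var(control) / (length(control) * mean(control)^2)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- lnrr + c(-1, 1) * z * sqrt(v)
  tibble(site = site, lnrr = lnrr, variance = v,
         ci_low = ci[1], ci_high = ci[2],
         n_oa = length(oa), n_control = length(control),
         significant = ci[1] > 0 | ci[2] < 0)
}

#' Per-site effect sizes from a pooled mesocosm table
#'
#' Maps [effect_confidence()] over the sites of a [pool_treatments()]
#' result.
#'
#' @param pooled Output of [pool_treatments()].
#' @param level Confidence level.
#' @return A tibble of class `lnrr_effects`, one row per site.
#' @examples
#' gen_mesocosm_dataset(seed = 1) |>
#'   pool_treatments() |>
#'   site_effect_sizes()
#' @export
site_effect_sizes <- function(pooled, level = 0.95) {
  require_columns(pooled, c("site", "treatment", "si_n"),
                  "Pooled treatment table")
  out <- pooled |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(d, key) {
      effect_confidence(d$si_n[d$treatment == "oa"],
                        d$si_n[d$treatment == "ambient"],
                        level = level)[-1]
    }) |>
    dplyr::ungroup()
  structure(out, class = c("lnrr_effects", class(out)), level = level)
}

#' Variance-weighted overall effect across studies
#'
#' Pools per-study lnRR values with inverse-variance weights, the common
#' meta-analytic rule: \eqn{\widehat{\mu} = \sum w_i \,\mathrm{lnRR}_i /
#' \sum w_i} with \eqn{w_i = 1/v_i} and overall variance
#' \eqn{1/\sum w_i}.
#'
#' @param effects A tibble of effect sizes with columns `lnrr` and
#'   `variance` (e.g. from [site_effect_sizes()]).
#' @param level Confidence level.
#' @return A one-row tibble in the same shape, with `site = "overall"`.
#' @export
overall_effect <- function(effects, level = 0.95) {
  require_columns(effects, c("lnrr", "variance"), "Effect-size table")
  if (!nrow(effects)) {
    abort("No effects to pool.", class = "silicatepump_weighting_error")
  }
  if (any(effects$variance <= 0)) {
    abort(paste("All effect variances must be positive for inverse-variance",
                "weighting; consider jittering or dropping degenerate studies."),
          class = "silicatepump_weighting_error")
  }
  w <- 1 / effects$variance
  lnrr <- sum(w * effects$lnrr) / sum(w)
  v <- 1 / sum(w)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- lnrr + c(-1, 1) * z * sqrt(v)
  tibble(site = "overall", lnrr = lnrr, variance = v,
         ci_low = ci[1], ci_high = ci[2],
         n_oa = sum(effects$n_oa %||% NA), n_control = sum(effects$n_control %||% NA),
         significant = ci[1] > 0 | ci[2] < 0)
}

#' Regression of mesocosm-mean Si:N on pCO2
#'
#' Ordinary least squares of per-mesocosm time-mean Si:N on the mesocosm's
#' pCO2, fitted per site within one compartment.  This is the
#' export-versus-suspended contrast: with an OA effect acting on sinking
#' particles only, the export compartment shows a significant positive
#' slope while the suspended compartment does not.
#'
#' @param data Mesocosm study tibble (schema of [gen_mesocosm_study()]).
#' @param compartment `"export"` or `"suspended"`.
#' @param alpha Significance level for the slope test.
#' @return A tibble with one row per site: `site`, `compartment`, `slope`,
#'   `intercept`, `p_value`, `r2`, `n`, `significant`.
#' @export
co2_response_regression <- function(data, compartment = c("export", "suspended"),
                                    alpha = 0.05) {
  compartment <- match.arg(compartment)
  comp <- compartment
  require_columns(data, c("site", "mesocosm_id", "pco2_uatm", "compartment",
                          "si", "n"), "Mesocosm study table")
  meso <- data |>
    dplyr::filter(.data$compartment == comp) |>
    dplyr::group_by(.data$site, .data$mesocosm_id, .data$pco2_uatm) |>
    dplyr::summarise(si_n = mean(.data$si / .data$n), .groups = "drop")
  meso |>
    dplyr::group_by(.data$site) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$pco2_uatm) < 3L) {
        abort(sprintf("Site `%s` has fewer than 3 distinct pCO2 levels.",
                      key$site[[1]]),
              class = "silicatepump_insufficient_levels")
      }
      fit <- lm(si_n ~ pco2_uatm, data = d)
      sm <- summary(fit)
      p <- sm$coefficients["pco2_uatm", "Pr(>|t|)"]
      tibble(compartment = comp,
             slope = unname(coef(fit)["pco2_uatm"]),
             intercept = unname(coef(fit)["(Intercept)"]),
             p_value = p, r2 = sm$r.squared, n = nrow(d),
             significant = is.finite(p) && p < alpha)
    }) |>
    dplyr::ungroup()
}
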