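#' Idealized seven-box geometry of the global overturning circulation
#'
#' A desk-scale surrogate for the ocean silicon cycle: three surface boxes
#' (Southern Ocean, low latitude, northern high latitude), an intermediate
#' water box (AAIW/SAMW-like), a circumpolar deep box (CDW-like) and two
#' abyssal boxes (southern AABW-like, northern NADW/NPDW-like).  Transport
#' is a non-divergent overturning loop — deep water upwells into the
#' Southern Ocean surface, feeds intermediate water that resurfaces at low
#' latitudes, and returns to depth at the northern and southern ends —
#' plus two vertical exchange (mixing) terms.  Sinking particles from each
#' surface box traverse a documented path of subsurface boxes with a
#' transit time per segment set by layer thickness over a 100 m/day
#' sinking speed.
#'
#' @param psi_loop Overturning strength of the main loop, Sv.
#' @param psi_aabw Strength of the southern abyssal cell, Sv.
#' @return An object of class `box_geometry`: list with tibbles `boxes`
#'   (`box`, `class`, `volume_m3`, `temp_c`, `ph`), `transport` (`from`,
#'   `to`, `sv`), and `paths` (named list per surface box with `boxes` and
#'   `tau_days`).
#' @export
default_geometry <- function(psi_loop = 15, psi_aabw = 10) {
  boxes <- tibble(
    box = c("srf_so", "srf_low", "srf_n", "aaiw", "cdw", "abyss_s", "abyss_n"),
    class = c("surface-SO", "surface-lowlat", "surface-N",
              "intermediate", "deep-S", "deep-S", "deep-N"),
    volume_m3 = c(7.2e15, 2.3e16, 5.4e15, 1.0e17, 3.0e17, 4.0e17, 4.0e17),
    temp_c = c(2, 22, 8, 5, 2, 1, 1.5),
    ph = c(8.12, 8.08, 8.10, 8.05, 7.85, 7.80, 7.75)
  )
  transport <- tibble(
    from = c("srf_n", "abyss_n", "cdw", "srf_so", "aaiw", "srf_low",
             "srf_so", "abyss_s",
             # bidirectional vertical exchange
             "srf_low", "aaiw", "srf_n", "cdw"),
    to = c("abyss_n", "cdw", "srf_so", "aaiw", "srf_low", "srf_n",
           "abyss_s", "cdw",
           "aaiw", "srf_low", "cdw", "srf_n"),
    sv = c(psi_loop, psi_loop, psi_loop + psi_aabw, psi_loop, psi_loop,
           psi_loop, psi_aabw, psi_aabw, 20, 20, 8, 8)
  )
  paths <- list(
    srf_so = list(boxes = c("cdw", "abyss_s"), tau_days = c(15, 25)),
    srf_low = list(boxes = c("aaiw", "cdw", "abyss_n"), tau_days = c(9, 15, 25)),
    srf_n = list(boxes = c("cdw", "abyss_n"), tau_days = c(15, 25))
  )
  geom <- structure(list(boxes = boxes, transport = transport, paths = paths),
                    class = "box_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geometry) {
  b <- geometry$boxes
  tr <- geometry$transport
  stopifnot(all(b$volume_m3 > 0), all(tr$sv > 0),
            all(tr$from %in% b$box), all(tr$to %in% b$box))
  inflow <- tapply(tr$sv, tr$to, sum)
  outflow <- tapply(tr$sv, tr$from, sum)
  net <- setNames(numeric(nrow(b)), b$box)
  net[names(inflow)] <- net[names(inflow)] + inflow
  net[names(outflow)] <- net[names(outflow)] - outflow
  if (any(abs(net) > 1e-9)) {
    abort("Transport is divergent: per-box inflow must equal outflow.",
          class = "silicatepump_invalid_geometry")
  }
  surf <- b$box[startsWith(b$class, "surface")]
  if (!all(surf %in% names(geometry$paths))) {
    abort("Every surface box needs a particle path.",
          class = "silicatepump_invalid_geometry")
  }
  invisible(geometry)
}

#' Biological parameters of the box model
#'
#' Opal production in each surface box follows Michaelis--Menten uptake of
#' silicic acid, `vmax * V * [Si] / ([Si] + k_si_half)` (mmol Si per
#' year), with light, iron and other-nutrient limitation folded into the
#' per-box maximum rate `vmax`.  A fraction `export_fraction` of
#' production sinks out as opal export; the remainder redissolves within
#' the surface box.  The default `vmax` values are tuned once so the
#' preindustrial steady state spans oligotrophic (~2 mmol m^-3) to
#' Southern Ocean (~60 mmol m^-3) surface silicic acid.
#'
#' @param vmax Named maximum uptake rates per surface box,
#'   mmol m^-3 yr^-1.
#' @param k_si_half Half-saturation for Si uptake, mmol m^-3.
#' @param export_fraction Fraction of production exported (0--1].
#' @return An object of class `bio_params`.
#' @export
bio_params <- function(vmax = c(srf_so = 7, srf_low = 11, srf_n = 8.5),
                       k_si_half = 4, export_fraction = 0.5) {
  stopifnot(is.numeric(vmax), !is.null(names(vmax)), all(vmax > 0))
  stop_if_not_number(k_si_half, "k_si_half", lower = 0, strict_lower = TRUE)
  stop_if_not_number(export_fraction, "export_fraction", lower = 0, upper = 1,
                     strict_lower = TRUE)
  structure(list(vmax = vmax, k_si_half = k_si_half,
                 export_fraction = export_fraction),
            class = "bio_params")
}

#' Dissolve a sinking opal export flux along a path of boxes
#'
#' Over each segment a fraction \eqn{e^{-k \tau}} of the flux survives,
#' where \eqn{k} is the opal dissolution rate at the segment box's
#' temperature and pH anomaly and \eqn{\tau} the transit time; the
#' dissolved remainder deposits (as silicic acid) into that box.  Whatever
#' survives the last segment deposits in the terminal box, so deposits sum
#' exactly to the export flux.  With the pH effect enabled, a negative pH
#' anomaly lowers \eqn{k} and shifts the deposition centroid deeper — the
#' mechanism that traps Si in the deep ocean under acidification.
#'
#' @param export_flux Export flux entering the path (mmol/yr).
#' @param path List with `boxes` (names) and `tau_days` (transit times).
#' @param params A [kinetics_params()].
#' @param temp Temperature per segment box, °C.
#' @param ph_anomaly pH anomaly per segment box relative to preindustrial.
#' @param ph_effect Apply the pH sensitivity? When `FALSE` the pH factor
#'   is frozen at its preindustrial value of 1.
#' @return Named vector of deposits per box along the path (mmol/yr).
#' @export
opal_transfer <- function(export_flux, path, params = kinetics_params(),
                          temp, ph_anomaly = 0, ph_effect = TRUE) {
  nseg <- length(path$boxes)
  stopifnot(length(path$tau_days) == nseg, length(temp) == nseg)
  if (any(path$tau_days < 0)) {
    abort("Transit times must be non-negative.",
          class = "silicatepump_invalid_config")
  }
  ph_anomaly <- rep_len(ph_anomaly, nseg)
  phf <- if (ph_effect) ph_factor(params$ph_ref + ph_anomaly, params) else 1
  k <- params$k_si0 * temperature_factor(temp, params, "si") * phf
  surv <- exp(-k * path$tau_days)
  flux <- export_flux * cumprod(c(1, surv))   # flux entering each segment
  deposits <- flux[seq_len(nseg)] - flux[-1]  # dissolved per segment
  deposits[nseg] <- deposits[nseg] + flux[nseg + 1]  # terminal burial-free sink
  setNames(deposits, path$boxes)
}

# one sub-step of length dt (years); state is a named concentration vector
step_core <- function(state, A, geometry, bio, params, temp_anom, ph_anom,
                      ph_effect, dt) {
  b <- geometry$boxes
  # transport (non-divergent, conserves total Si exactly up to round-off)
  state <- state + dt * drop(A %*% state)
  production <- setNames(numeric(length(state)), names(state))
  for (sb in names(geometry$paths)) {
    v <- b$volume_m3[b$box == sb]
    conc <- state[[sb]]
    upt <- bio$vmax[[sb]] * v * conc / (conc + bio$k_si_half)
    export <- bio$export_fraction * upt * dt
    export <- min(export, 0.9 * conc * v)  # never strip a box in one step
    path <- geometry$paths[[sb]]
    seg_t <- b$temp_c[match(path$boxes, b$box)] +
      temp_anom[match(path$boxes, b$box)]
    seg_ph <- ph_anom[match(path$boxes, b$box)]
    dep <- opal_transfer(export, path, params, temp = seg_t,
                         ph_anomaly = seg_ph, ph_effect = ph_effect)
    state[[sb]] <- state[[sb]] - export / v
    for (j in seq_along(dep)) {
      bx <- names(dep)[j]
      state[[bx]] <- state[[bx]] + dep[[j]] / b$volume_m3[b$box == bx]
    }
    production[[sb]] <- upt
  }
  if (any(state < 0)) {
    abort("Negative concentration after step; use a smaller step.",
          class = "silicatepump_stability_error")
  }
  list(state = state, production = production)
}

transport_matrix <- function(geometry) {
  b <- geometry$boxes
  n <- nrow(b)
  A <- matrix(0, n, n, dimnames = list(b$box, b$box))
  m3yr <- 3.15e13  # 1 Sv in m^3/yr
  for (i in seq_len(nrow(geometry$transport))) {
    fr <- geometry$transport$from[i]
    to <- geometry$transport$to[i]
    q <- geometry$transport$sv[i] * m3yr
    A[to, fr] <- A[to, fr] + q / b$volume_m3[b$box == to]
    A[fr, fr] <- A[fr, fr] - q / b$volume_m3[b$box == fr]
  }
  A
}

#' Advance the box model by one year
#'
#' Applies transport, Michaelis--Menten opal production and export in the
#' surface boxes, and path-resolved dissolution deposition, using
#' `n_substeps` equal sub-steps.  Total Si is conserved to round-off; the
#' model is closed (no burial, no river input).
#'
#' @param state Named concentration vector, mmol m^-3.
#' @param geometry A [default_geometry()].
#' @param bio A [bio_params()].
#' @param params A [kinetics_params()].
#' @param temp_anom,ph_anom Named anomaly vectors per box (default 0).
#' @param ph_effect Apply the pH sensitivity of dissolution?
#' @param n_substeps Sub-steps per year.
#' @return List with the new `state` and the annual `production` per box
#'   (mmol/yr).
#' @export
step_box <- function(state, geometry, bio = bio_params(),
                     params = kinetics_params(),
                     temp_anom = NULL, ph_anom = NULL,
                     ph_effect = TRUE, n_substeps = 4L) {
  b <- geometry$boxes
  zero <- setNames(numeric(nrow(b)), b$box)
  temp_anom <- temp_anom %||% zero
  ph_anom <- ph_anom %||% zero
  A <- attr(geometry, "A") %||% transport_matrix(geometry)
  dt <- 1 / n_substeps
  production <- zero
  for (s in seq_len(n_substeps)) {
    res <- step_core(state, A, geometry, bio, params, temp_anom, ph_anom,
                     ph_effect, dt)
    state <- res$state
    production <- production + res$production * dt
  }
  list(state = state, production = production)
}

#' Spin the box model up to its preindustrial steady state
#'
#' Integrates with zero anomalies until the maximum relative concentration
#' drift falls below `tol` per year, or errors if `max_years` is reached
#' first.  The steady state is independent of the pH-effect switch (the
#' pH factor is 1 at preindustrial), so a single spin-up can seed every
#' scenario run.
#'
#' @inheritParams step_box
#' @param init Initial concentration, mmol m^-3 (uniform scalar or named
#'   vector); sets the conserved total inventory.
#' @param tol Drift tolerance, relative per year.
#' @param max_years Spin-up cap.
#' @param check_every Years between drift checks.
#' @return The steady-state named concentration vector, with attribute
#'   `"years"` (spin-up length used).
#' @export
spinup_state <- function(geometry = default_geometry(), bio = bio_params(),
                         params = kinetics_params(), init = 85,
                         tol = 1e-6, max_years = 20000L, check_every = 100L,
                         n_substeps = 4L) {
  b <- geometry$boxes
  state <- if (length(init) == 1L) setNames(rep(init, nrow(b)), b$box) else
    init[b$box]
  attr(geometry, "A") <- transport_matrix(geometry)
  years <- 0L
  repeat {
    prev <- state
    for (y in seq_len(check_every)) {
      state <- step_box(state, geometry, bio, params,
                        ph_effect = FALSE, n_substeps = n_substeps)$state
    }
    years <- years + check_every
    drift <- max(abs(state - prev) / pmax(abs(prev), 1e-12)) / check_every
    if (drift < tol) break
    if (years >= max_years) {
      abort(sprintf(
        "Spin-up did not converge: drift %.3g yr^-1 after %d years (tol %.1g).",
        drift, years, tol), class = "silicatepump_spinup_error")
    }
  }
  structure(state, years = years)
}

#' Run a forced scenario of the silicate-pump box model
#'
#' Starting from the preindustrial steady state, integrates annually from
#' 1750 to `end_year` under an [gen_rcp_forcing()] anomaly trajectory,
#' either with the pH sensitivity of opal dissolution active
#' (`ph_effect = TRUE`) or with the pH factor frozen at preindustrial (the
#' standard configuration).  The paired difference of the two runs
#' isolates the net effect of acidification-slowed dissolution
#' (see [delta_oa()]).
#'
#' @inheritParams step_box
#' @param forcing An `rcp_forcing` tibble from [gen_rcp_forcing()].
#' @param end_year Final simulated year (<= max forcing year).
#' @param init Optional precomputed steady state from [spinup_state()];
#'   spin-up is run if omitted.
#' @param spinup_tol,spinup_max Passed to [spinup_state()].
#' @return An object of class `scenario_run`: list with `trajectory`
#'   (tibble `year`, `box`, `si`), `production` (tibble `year`,
#'   `production` — global total, mmol/yr), `geometry`, `bio`, `params`,
#'   `ph_effect`, `scenario`.
#' @export
run_scenario <- function(geometry = default_geometry(), bio = bio_params(),
                         params = kinetics_params(),
                         forcing = gen_rcp_forcing("RCP8.5", geometry),
                         ph_effect = TRUE, end_year = 2200, init = NULL,
                         n_substeps = 4L, spinup_tol = 1e-6,
                         spinup_max = 20000L) {
  stopifnot(inherits(geometry, "box_geometry"))
  require_columns(forcing, c("year", "box", "ph_anomaly", "temp_anomaly"),
                  "Forcing")
  years <- seq(min(forcing$year), end_year)
  if (end_year > max(forcing$year)) {
    abort("`end_year` exceeds the forcing trajectory.",
          class = "silicatepump_invalid_config")
  }
  b <- geometry$boxes
  if (is.null(init)) {
    init <- spinup_state(geometry, bio, params, tol = spinup_tol,
                         max_years = spinup_max, n_substeps = n_substeps)
  }
  attr(geometry, "A") <- transport_matrix(geometry)
  ph_m <- anomaly_matrix(forcing, "ph_anomaly", years, b$box)
  t_m <- anomaly_matrix(forcing, "temp_anomaly", years, b$box)
  state <- init[b$box]
  traj <- matrix(NA_real_, length(years), nrow(b),
                 dimnames = list(years, b$box))
  prod_total <- numeric(length(years))
  for (i in seq_along(years)) {
    res <- step_box(state, geometry, bio, params,
                    temp_anom = t_m[i, ], ph_anom = ph_m[i, ],
                    ph_effect = ph_effect, n_substeps = n_substeps)
    state <- res$state
    traj[i, ] <- state
    prod_total[i] <- sum(res$production)
  }
  trajectory <- as_tibble(as.data.frame.table(traj, stringsAsFactors = FALSE),
                          .name_repair = "minimal")
  names(trajectory) <- c("year", "box", "si")
  trajectory$year <- as.integer(trajectory$year)
  structure(
    list(trajectory = as_tibble(trajectory),
         production = tibble(year = years, production = prod_total),
         geometry = geometry, bio = bio, params = params,
         ph_effect = ph_effect,
         scenario = attr(forcing, "scenario") %||% NA_character_),
    class = "scenario_run"
  )
}

anomaly_matrix <- function(forcing, col, years, boxes) {
  wide <- forcing |>
    dplyr::select("year", "box", dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "box", values_from = dplyr::all_of(col))
  idx <- match(years, wide$year)
  if (anyNA(idx)) {
    abort("Forcing must cover every simulated year for every box.",
          class = "silicatepump_invalid_config")
  }
  as.matrix(wide[idx, boxes])
}

#' Net effect of pH-sensitive dissolution between paired runs
#'
#' Percentage differences, at a reference year, between a run with the pH
#' effect on and its standard counterpart sharing geometry, parameters and
#' forcing: volume-weighted surface silicic acid, global opal production
#' (the diatom-production proxy), and the Si inventory of the deep boxes.
#' Under acidification the expected signature is surface Si loss, a
#' production decline, and deep-ocean Si accumulation.
#'
#' @param run_on,run_off `scenario_run` objects differing only in
#'   `ph_effect`.
#' @param year Reference year (e.g. 2100 or 2200).
#' @return A one-row tibble: `year`, `delta_oa_surface_si`,
#'   `delta_oa_production`, `deep_si_accumulation` (all %).
#' @export
delta_oa <- function(run_on, run_off, year = 2200) {
  stopifnot(inherits(run_on, "scenario_run"), inherits(run_off, "scenario_run"))
  if (!identical(run_on$geometry$boxes, run_off$geometry$boxes) ||
      !identical(run_on$bio, run_off$bio) ||
      !identical(run_on$scenario, run_off$scenario)) {
    abort("Runs must share geometry, parameters and forcing.",
          class = "silicatepump_config_mismatch")
  }
  b <- run_on$geometry$boxes
  surf <- b$box[startsWith(b$class, "surface")]
  deep <- b$box[startsWith(b$class, "deep")]
  vol <- setNames(b$volume_m3, b$box)
  pick <- function(run, boxes) {
    s <- dplyr::filter(run$trajectory, .data$year == !!year,
                       .data$box %in% boxes)
    sum(s$si * vol[s$box])
  }
  surf_on <- pick(run_on, surf); surf_off <- pick(run_off, surf)
  deep_on <- pick(run_on, deep); deep_off <- pick(run_off, deep)
  p_on <- run_on$production$production[run_on$production$year == year]
  p_off <- run_off$production$production[run_off$production$year == year]
  tibble(year = year,
         delta_oa_surface_si = 100 * (surf_on - surf_off) / surf_off,
         delta_oa_production = 100 * (p_on - p_off) / p_off,
         deep_si_accumulation = 100 * (deep_on - deep_off) / deep_off)
}

#' Total silicon inventory of a state or run (mmol)
#'
#' @param state Named concentration vector or a `scenario_run`.
#' @param geometry Geometry supplying box volumes (unneeded for runs).
#' @param year For runs, which year to evaluate.
#' @return Total dissolved Si, mmol.
#' @export
total_si <- function(state, geometry = default_geometry(), year = NULL) {
  if (inherits(state, "scenario_run")) {
    b <- state$geometry$boxes
    tr <- state$trajectory
    if (!is.null(year)) tr <- dplyr::filter(tr, .data$year == !!year)
    yr <- max(tr$year)
    tr <- dplyr::filter(tr, .data$year == yr)
    return(sum(tr$si * setNames(b$volume_m3, b$box)[tr$box]))
  }
  sum(state[geometry$boxes$box] * geometry$boxes$volume_m3)
}
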