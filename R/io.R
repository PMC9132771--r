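#' Read a mesocosm study CSV
#'
#' Expects the long schema `site, mesocosm_id, day, pco2_uatm, compartment,
#' si, n, c` with `compartment` in `{export, suspended}` and molar units
#' for the elemental columns — the export format of [gen_mesocosm_study()]
#' and the layout into which archived mesocosm Si/N/C time series are
#' readily reshaped.
#'
#' @param path CSV file path.
#' @return A validated tibble in the mesocosm schema.
#' @export
read_mesocosm_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(data, c("site", "mesocosm_id", "day", "pco2_uatm",
                          "compartment", "si", "n", "c"),
                  sprintf("Mesocosm CSV `%s`", path))
  bad <- setdiff(unique(data$compartment), c("export", "suspended"))
  if (length(bad)) {
    abort(sprintf("Unknown compartment value(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "silicatepump_schema_error")
  }
  data
}

#' Read a sediment-trap compilation CSV
#'
#' Expects `station_id, lat, lon, depth_m, si_flux, n_flux` with molar
#' flux units.  Use [mass_to_molar()] first if fluxes are in mass units.
#'
#' @param path CSV file path.
#' @return A validated tibble in the trap schema.
#' @export
read_trap_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(data, c("station_id", "lat", "lon", "depth_m",
                          "si_flux", "n_flux"),
                  sprintf("Trap CSV `%s`", path))
  data
}

#' Read a long-format climatology CSV
#'
#' Expects `depth_m, lat, ph, temp_c`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_climatology_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(data, c("depth_m", "lat", "ph", "temp_c"),
                  sprintf("Climatology CSV `%s`", path))
  data
}

#' Convert mass fluxes to molar fluxes
#'
#' Helper for real-data compilations reported in mass units:
#' biogenic silica as SiO2 (60.08 g/mol) and nitrogen as N (14.007 g/mol).
#'
#' @param x Mass flux value(s), mg per unit area and time.
#' @param element `"si"` (as SiO2) or `"n"`.
#' @return Molar flux, mmol per unit area and time.
#' @export
mass_to_molar <- function(x, element = c("si", "n")) {
  element <- match.arg(element)
  x / c(si = 60.08, n = 14.007)[[element]]
}
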