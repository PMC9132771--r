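# shared fixtures, built once per test run

# small mesocosm configs keep the unit tests fast; acceptance uses defaults
quick_site <- function(...) {
  args <- list(...)
  if (!"n_days" %in% names(args)) args$n_days <- 10
  do.call(mesocosm_site_config, args)
}

# spin the default box model up once and reuse across tests
box_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        geometry = default_geometry(),
        bio = bio_params(),
        params = kinetics_params()
      )
      cache$state <<- spinup_state(cache$geometry, cache$bio, cache$params)
    }
    cache
  }
})

trap_integral <- function(d) {
  sum(diff(d$grid) * (head(d$density, -1) + d$density[-1]) / 2)
}

# a toy three-station trap tibble with known structure
toy_profiles <- function() {
  tibble::tibble(
    station_id = rep(c("A", "B", "C"), times = c(3, 2, 4)),
    lat = 0, lon = 0,
    depth_m = c(1000, 2000, 3000, 500, 1500, 500, 1000, 1500, 2000),
    si_flux = c(1.0, 1.2, 1.4, 1, 1, 2, 2, 2, 2),
    n_flux = 1
  )
}

# minimal reachability helper (avoids an igraph dependency for one check)
igraph_free_reachability <- function(from, to, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adj[cbind(from, to)] <- TRUE
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  reach
}
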