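# internal validation helpers

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "silicatepump_invalid_config")
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  if (bad_low || x > upper) {
    abort(sprintf("`%s` must be in %s%g, %g].", name,
                  if (strict_lower) "(" else "[", lower, upper),
          class = "silicatepump_invalid_config")
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "silicatepump_invalid_config")
  }
  invisible(as.integer(x))
}

require_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")),
          class = "silicatepump_schema_error")
  }
  invisible(data)
}

# lognormal multiplicative noise with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# trapezoidal integral on an (x, y) grid
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
}
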