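#' Assemble the probability surface
#'
#' Combines intercept, temporal trend, covariate effects and the latent
#' spatio-temporal field into the logit-scale predictor and maps it to the
#' probability scale. The cosmopolitan archetype applies a second-degree
#' polynomial (ordinary monomials) to bathymetry; the persistent archetype a
#' linear effect. Temperature enters linearly in both. When
#' `config$standardize` is `TRUE` (default) each covariate is centred and
#' scaled over all its cell-years before the coefficients apply.
#'
#' @param config a [scenario_config()].
#' @param grid a [grid_domain()].
#' @param covariates optional list with elements `bathymetry` (matrix) and
#'   `temperature` (array); computed from the grid formulas when `NULL`.
#' @param U latent field array from [simulate_spatiotemporal_field()], or
#'   `NULL` for a zero field.
#' @param trend per-year trend vector from [simulate_temporal_trend()], or
#'   `NULL` for a flat trend.
#' @return an object of class `latent_surface` with the predictor `eta`, the
#'   probability array `pi`, and the inputs used.
#' @examples
#' g <- grid_domain(nx = 8, ny = 8, years = 1:4)
#' cfg <- scenario_config("persistent")
#' s <- assemble_probability(cfg, g)  # deterministic response surface
#' range(s$pi)
#' @export
assemble_probability <- function(config, grid, covariates = NULL,
                                 U = NULL, trend = NULL) {
  stopifnot(inherits(config, "scenario_config"), inherits(grid, "grid_domain"))
  nx <- length(grid$x); ny <- length(grid$y); nt <- length(grid$years)
  if (is.null(covariates))
    covariates <- list(bathymetry = make_bathymetry(grid),
                       temperature = make_temperature(grid))
  bath <- covariates$bathymetry
  temp <- covariates$temperature
  if (!all(dim(bath) == c(nx, ny)) || !all(dim(temp) == c(nx, ny, nt)))
    stop("structural error: covariate dimensions do not match the grid")
  U <- U %||% array(0, dim = c(nx, ny, nt))
  trend <- trend %||% numeric(nt)
  if (!all(dim(U) == c(nx, ny, nt)) || length(trend) != nt)
    stop("structural error: U or trend does not match the grid")

  if (isTRUE(config$standardize)) {
    bath_s <- (bath - mean(bath)) / sd(bath)
    temp_s <- (temp - mean(temp)) / sd(temp)
  } else {
    bath_s <- bath
    temp_s <- temp
  }
  f2 <- if (config$kind == "cosmopolitan") {
    config$bath_coeffs[1] * bath_s + config$bath_coeffs[2] * bath_s^2
  } else {
    config$bath_coeffs[1] * bath_s
  }
  eta <- array(0, dim = c(nx, ny, nt))
  for (t in seq_len(nt))
    eta[, , t] <- config$beta0 + trend[t] + f2 +
      config$temp_coeff * temp_s[, , t] + U[, , t]
  structure(list(grid = grid, config = config, covariates = covariates,
                 U = U, trend = trend, eta = eta, pi = plogis(eta)),
            class = "latent_surface")
}

#' Draw a binary occurrence field
#'
#' Independent Bernoulli draws per cell-year from the probability surface.
#'
#' @param surface a `latent_surface` from [assemble_probability()].
#' @param seed integer seed.
#' @return an object of class `occurrence_field`: the grid, the binary
#'   `occurrence` array and the generating surface.
#' @export
draw_occurrence <- function(surface, seed = 1L) {
  stopifnot(inherits(surface, "latent_surface"))
  p <- surface$pi
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  set.seed(seed)
  occ <- array(rbinom(length(p), 1, as.vector(p)), dim = dim(p))
  structure(list(grid = surface$grid, occurrence = occ, surface = surface),
            class = "occurrence_field")
}

#' Simulate a full virtual-species world
#'
#' Convenience wrapper running the whole generator: covariate fields, latent
#' spatio-temporal field, temporal trend, probability surface and occurrence
#' draws, with child seeds derived from `config$seed`.
#'
#' @param config a [scenario_config()].
#' @param grid a [grid_domain()].
#' @return an object of class `sim_world` with elements `config`, `grid`,
#'   `surface` (class `latent_surface`) and `field` (class
#'   `occurrence_field`).
#' @examples
#' w <- simulate_scenario(scenario_config("persistent", seed = 7),
#'                        grid_domain(nx = 8, ny = 8, years = 1:4))
#' mean(w$field$occurrence)
#' @export
simulate_scenario <- function(config, grid = grid_domain()) {
  stopifnot(inherits(config, "scenario_config"))
  U <- simulate_spatiotemporal_field(grid, config$spatial_range,
                                     config$spatial_sd, config$rho_st,
                                     seed = derive_seed(config$seed, 1))
  trend <- simulate_temporal_trend(grid$years, config$rho_t,
                                   seed = derive_seed(config$seed, 2))
  surface <- assemble_probability(config, grid, U = U, trend = trend)
  field <- draw_occurrence(surface, seed = derive_seed(config$seed, 3))
  structure(list(config = config, grid = grid, surface = surface,
                 field = field),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf("<sim_world> %s species on %d x %d x %d cell-years; prevalence %.3f\n",
              x$config$kind, length(x$grid$x), length(x$grid$y),
              length(x$grid$years), mean(x$field$occurrence)))
  invisible(x)
}

#' Export a simulated world as a flat table
#'
#' Long-format data frame (one row per cell-year) with coordinates, year,
#' covariates, true probability and the occurrence draw; optionally written
#' to CSV.
#'
#' @param world a `sim_world`.
#' @param path optional CSV path.
#' @return the data frame, invisibly when `path` is given.
#' @export
simulation_table <- function(world, path = NULL) {
  stopifnot(inherits(world, "sim_world"))
  g <- world$grid
  nx <- length(g$x); ny <- length(g$y); nt <- length(g$years)
  df <- data.frame(
    x = rep(g$x, times = ny * nt),
    y = rep(rep(g$y, each = nx), times = nt),
    year = rep(g$years, each = nx * ny),
    bathymetry = rep(as.vector(world$surface$covariates$bathymetry), times = nt),
    temperature = as.vector(world$surface$covariates$temperature),
    pi = as.vector(world$surface$pi),
    occurrence = as.vector(world$field$occurrence))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
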