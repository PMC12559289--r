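#' Matern (smoothness 1) spatial correlation
#'
#' Correlation at distance `d` for a Matern field with smoothness `nu = 1`,
#' using the SPDE range convention: `kappa = sqrt(8 * nu) / range`, so the
#' correlation has dropped to about 0.13 at distance `range`.
#'
#' @param d nonnegative distances.
#' @param range spatial range parameter (> 0).
#' @return correlations in (0, 1], 1 at distance 0.
#' @examples
#' matern_correlation(c(0, 3.5, 10.5), range = 3.5)
#' @export
matern_correlation <- function(d, range) {
  stopifnot(range > 0, all(d >= 0))
  kappa <- sqrt(8) / range
  out <- ifelse(d == 0, 1, kappa * d * besselK(kappa * d, 1))
  pmin(out, 1)
}

#' Simulate the latent spatio-temporal field
#'
#' Draws a zero-mean Gaussian field on the grid for each year and couples the
#' years with an AR(1): `U(., t) = rho * U(., t - 1) + innovation(t)`. The
#' innovations have Matern (smoothness 1) spatial correlation with the given
#' range, scaled so the stationary process has marginal variance `sigma^2`
#' (innovation SD `sigma * sqrt(1 - rho^2)`; the first year is drawn at the
#' stationary scale). Dense Cholesky simulation, adequate at desk scale.
#'
#' @param grid a [grid_domain()].
#' @param range,sigma Matern range and stationary marginal SD.
#' @param rho AR(1) coefficient in (-1, 1).
#' @param seed integer seed.
#' @return an `nx` by `ny` by `T` array.
#' @export
simulate_spatiotemporal_field <- function(grid, range, sigma, rho, seed = 1L) {
  stopifnot(inherits(grid, "grid_domain"), range > 0, sigma >= 0, abs(rho) < 1)
  nx <- length(grid$x); ny <- length(grid$y); nt <- length(grid$years)
  U <- array(0, dim = c(nx, ny, nt))
  if (sigma == 0) return(U)
  coords <- cbind(rep(grid$x, times = ny), rep(grid$y, each = nx))
  D <- as.matrix(stats::dist(coords))
  C <- matern_correlation(D, range)
  diag(C) <- 1 + 1e-8  # jitter for numerical positive definiteness
  L <- tryCatch(chol(C), error = function(e)
    stop("spatial covariance not positive definite (range = ", range,
         ", grid ", nx, "x", ny, "): ", conditionMessage(e)))
  set.seed(seed)
  draw <- function(scale) {
    z <- rnorm(nx * ny)
    matrix(scale * drop(crossprod(L, z)), nx, ny)
  }
  U[, , 1] <- draw(sigma)
  if (nt > 1) {
    innov_sd <- sigma * sqrt(1 - rho^2)
    for (t in 2:nt) U[, , t] <- rho * U[, , t - 1] + draw(innov_sd)
  }
  U
}

#' Simulate the temporal trend
#'
#' Year effects from a stationary AR(1) with unit marginal variance:
#' `f1(t) = rho_t * f1(t - 1) + eps_t`, innovation SD `sqrt(1 - rho_t^2)`,
#' first year drawn standard normal.
#'
#' @param years vector of years (only the length is used).
#' @param rho_t AR(1) coefficient in (-1, 1).
#' @param seed integer seed.
#' @return a numeric vector, one value per year.
#' @export
simulate_temporal_trend <- function(years, rho_t = 0.7, seed = 1L) {
  stopifnot(abs(rho_t) < 1)
  nt <- length(years)
  set.seed(seed)
  f <- numeric(nt)
  f[1] <- rnorm(1)
  if (nt > 1) {
    innov_sd <- sqrt(1 - rho_t^2)
    for (t in 2:nt) f[t] <- rho_t * f[t - 1] + innov_sd * rnorm(1)
  }
  f
}
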