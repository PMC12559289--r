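#' Spatial-temporal grid domain
#'
#' Defines the discrete lattice (cell-centre coordinates in abstract length
#' units) and the contiguous year index over which all simulated fields live.
#' The default extent is chosen so the bathymetry formula
#' `100 * log(x * y + 1)` spans exactly `[0, 800]` metres across the grid:
#' the upper corner sits at `x = y = sqrt(exp(8) - 1)` (about 54.6).
#'
#' @param nx,ny number of cells along each axis (at least 2).
#' @param xmax,ymax upper coordinate bound; cells are centred on an even
#'   subdivision of `(0, xmax]`.
#' @param years ordered, contiguous integer years (default `1:20`).
#' @return an object of class `grid_domain` with elements `x`, `y`, `years`.
#' @examples
#' g <- grid_domain(nx = 10, ny = 10, years = 1:5)
#' range(make_bathymetry(g))
#' @export
grid_domain <- function(nx = 30, ny = 30,
                        xmax = sqrt(exp(8) - 1), ymax = sqrt(exp(8) - 1),
                        years = 1:20) {
  stopifnot(nx >= 2, ny >= 2, xmax > 0, ymax > 0)
  years <- as.integer(years)
  if (length(years) < 1 || any(diff(years) != 1L))
    stop("`years` must be contiguous integers")
  x <- seq(xmax / nx, xmax, length.out = nx)
  y <- seq(ymax / ny, ymax, length.out = ny)
  structure(list(x = x, y = y, years = years), class = "grid_domain")
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("<grid_domain> %d x %d cells, x in (0, %.3f], y in (0, %.3f], years %d..%d\n",
              length(x$x), length(x$y), max(x$x), max(x$y),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Static bathymetry field
#'
#' Bathymetry (depth, metres) over the grid, computed as
#' `100 * log(x * y + 1)` with the natural logarithm. On the default grid the
#' values span 0 to 800 m; coordinate domains that would push the field past
#' 800 m are rejected as a configuration error.
#'
#' @param grid a [grid_domain()].
#' @return an `nx` by `ny` matrix of depths in metres.
#' @examples
#' b <- make_bathymetry(grid_domain())
#' max(b) <= 800 + 1e-6
#' @export
make_bathymetry <- function(grid) {
  stopifnot(inherits(grid, "grid_domain"))
  if (any(grid$x < 0) || any(grid$y < 0))
    stop("grid coordinates must be nonnegative")
  b <- 100 * log(outer(grid$x, grid$y) + 1)
  if (max(b) > 800 + 1e-6)
    stop("configuration error: bathymetry exceeds 800 m (max ",
         sprintf("%.2f", max(b)), " m); shrink the grid extent")
  b
}

#' Dynamic temperature field
#'
#' Temperature (abstract degrees) at each cell for one year or for all years:
#' `sqrt(y + 1) + 10` plus a deterministic warming of 0.5 units per elapsed
#' year, so consecutive years differ by exactly 0.5 everywhere.
#'
#' @param grid a [grid_domain()].
#' @param year a single year in `grid$years`, or `NULL` (default) for the
#'   full `nx` by `ny` by `T` array.
#' @return a matrix (single year) or 3-d array (all years).
#' @examples
#' g <- grid_domain(nx = 4, ny = 4, years = 1:3)
#' t1 <- make_temperature(g, year = 1)
#' t2 <- make_temperature(g, year = 2)
#' unique(round(t2 - t1, 10))  # 0.5 everywhere
#' @export
make_temperature <- function(grid, year = NULL) {
  stopifnot(inherits(grid, "grid_domain"))
  if (any(grid$y < 0)) stop("domain error: negative y coordinate")
  base <- matrix(rep(sqrt(grid$y + 1) + 10, each = length(grid$x)),
                 nrow = length(grid$x))
  if (!is.null(year)) {
    if (!(year %in% grid$years)) stop("`year` not in grid$years")
    return(base + 0.5 * (year - grid$years[1]))
  }
  out <- array(0, dim = c(length(grid$x), length(grid$y), length(grid$years)))
  for (t in seq_along(grid$years))
    out[, , t] <- base + 0.5 * (grid$years[t] - grid$years[1])
  out
}
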