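# Habitat-projection pipeline: covariate stacks, standardization,
# native-range vs suitable-habitat model variants, multi-year projection,
# change maps, richness stacking and aggregation.

#' Gridded covariate stack
#'
#' Named environmental layers on a common grid and year axis. Each layer is
#' an `nx` by `ny` by `T` array; a static layer may be supplied as a matrix
#' and is replicated across years.
#'
#' @param layers named list of matrices/arrays.
#' @param x,y cell-centre coordinates.
#' @param years integer years, one per array slice.
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, x, y, years) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  years <- as.integer(years)
  nx <- length(x); ny <- length(y); nt <- length(years)
  layers <- lapply(layers, function(l) {
    if (is.matrix(l)) l <- array(rep(l, nt), dim = c(dim(l), nt))
    if (!all(dim(l) == c(nx, ny, nt)))
      stop("layer dimensions must be ", nx, " x ", ny, " x ", nt)
    l
  })
  structure(list(layers = layers, x = x, y = y, years = years,
                 standardization = NULL),
            class = "covariate_stack")
}

#' Convert a simulated world into a covariate stack
#'
#' Reinterprets the simulator's bathymetry and temperature fields as a
#' projection-ready stack (temperature is exposed as `sst`), so the habitat
#' pipeline can be exercised end-to-end on purely synthetic fixtures.
#'
#' @param world a `sim_world`.
#' @return a [covariate_stack()].
#' @export
world_to_stack <- function(world) {
  stopifnot(inherits(world, "sim_world"))
  covariate_stack(list(bathymetry = world$surface$covariates$bathymetry,
                       sst = world$surface$covariates$temperature),
                  x = world$grid$x, y = world$grid$y,
                  years = world$grid$years)
}

#' Standardize a covariate stack
#'
#' z-score transformation `(X - mu) / sigma` per layer, with `mu` and
#' `sigma` computed from the historical reference years only and applied to
#' every year, so future anomalies are expressed on the historical scale.
#'
#' @param stack a [covariate_stack()].
#' @param reference_years historical years defining `mu` and `sigma`.
#' @return the standardized stack, with `$standardization` recording `mu`,
#'   `sigma` and the reference years per layer.
#' @export
standardize_stack <- function(stack, reference_years = stack$years) {
  stopifnot(inherits(stack, "covariate_stack"))
  it <- match(reference_years, stack$years)
  if (anyNA(it)) stop("reference years missing from the stack")
  params <- list()
  for (nm in names(stack$layers)) {
    ref <- stack$layers[[nm]][, , it, drop = FALSE]
    mu <- mean(ref); sig <- sd(as.vector(ref))
    if (!is.finite(sig) || sig == 0)
      stop("layer `", nm, "` has zero variance over the reference years")
    stack$layers[[nm]] <- (stack$layers[[nm]] - mu) / sig
    params[[nm]] <- c(mu = mu, sigma = sig)
  }
  stack$standardization <- list(params = params,
                                reference_years = as.integer(reference_years))
  stack
}

#' Undo stack standardization
#'
#' Inverse of [standardize_stack()]: `X = X_std * sigma + mu`, recovering
#' the original layers to machine precision.
#'
#' @param stack a standardized [covariate_stack()].
#' @return the stack on its original scale.
#' @export
unstandardize_stack <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (is.null(stack$standardization)) stop("stack is not standardized")
  for (nm in names(stack$layers)) {
    p <- stack$standardization$params[[nm]]
    stack$layers[[nm]] <- stack$layers[[nm]] * p["sigma"] + p["mu"]
  }
  stack$standardization <- NULL
  stack
}

# Covariate values at records (nearest grid cell).
extract_stack <- function(stack, x, y, year) {
  ix <- vapply(x, function(v) which.min(abs(stack$x - v)), integer(1))
  iy <- vapply(y, function(v) which.min(abs(stack$y - v)), integer(1))
  it <- match(year, stack$years)
  if (anyNA(it)) stop("record years missing from the stack")
  out <- vapply(stack$layers,
                function(l) l[cbind(ix, iy, it)],
                numeric(length(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(stack$layers)))
  out
}

#' Occurrence cleaning filters
#'
#' Pluggable record filters applied in sequence before model fitting. The
#' default drops exact duplicate (x, y, year, label) records.
#'
#' @param table an occurrence data frame.
#' @param filters list of functions `table -> table`.
#' @return the filtered table.
#' @export
clean_occurrences <- function(table, filters = list(filter_duplicates)) {
  for (f in filters) table <- f(table)
  table
}

#' @rdname clean_occurrences
#' @export
filter_duplicates <- function(table) {
  table[!duplicated(table[, intersect(c("x", "y", "year", "label"),
                                      names(table))]), , drop = FALSE]
}

#' Fit a native-range or suitable-habitat model
#'
#' Fits the probit BART classifier to occurrence records with covariates
#' extracted from the stack. The `suitable_habitat` variant uses
#' environmental layers only; `native_range` appends the record coordinates
#' as covariates, constraining predictions toward historically occupied
#' space.
#'
#' @param table occurrence records with columns `x`, `y`, `year`, `label`.
#' @param stack a [covariate_stack()].
#' @param variant `"suitable_habitat"` or `"native_range"`.
#' @param config a [bart_config()].
#' @return an object of class `habitat_model`.
#' @export
fit_variant <- function(table, stack,
                        variant = c("suitable_habitat", "native_range"),
                        config = bart_config(n_draws = 500, n_burn = 100)) {
  variant <- match.arg(variant)
  stopifnot(inherits(stack, "covariate_stack"))
  need <- c("x", "y", "year", "label")
  if (variant == "native_range" && !all(c("x", "y") %in% names(table)))
    stop("native_range variant requires coordinate columns x, y")
  if (!all(need %in% names(table)))
    stop("occurrence table must have columns ", paste(need, collapse = ", "))
  X <- extract_stack(stack, table$x, table$y, table$year)
  if (variant == "native_range")
    X <- cbind(X, x = table$x, y = table$y)
  fit <- bart_probit(X, table$label, config)
  structure(list(fit = fit, variant = variant,
                 layer_names = names(stack$layers)),
            class = "habitat_model")
}

#' Project a habitat model across years
#'
#' One prediction surface per year: the posterior mean probability of
#' presence with 0.025/0.975 quantile envelopes at every cell.
#'
#' @param model a [fit_variant()] result.
#' @param stack the covariate stack to project onto.
#' @param years years to project (must be present in the stack).
#' @param n_draws posterior draws used.
#' @return an object of class `habitat_projection` with arrays `mean`,
#'   `lower`, `upper` of dimension `nx` by `ny` by `length(years)`.
#' @export
project_years <- function(model, stack, years = stack$years, n_draws = 100) {
  stopifnot(inherits(model, "habitat_model"),
            inherits(stack, "covariate_stack"))
  if (!all(years %in% stack$years)) stop("missing layer-years in the stack")
  nx <- length(stack$x); ny <- length(stack$y); nt <- length(years)
  cells <- expand.grid(x = stack$x, y = stack$y)
  mean_a <- lower_a <- upper_a <- array(0, dim = c(nx, ny, nt))
  for (t in seq_len(nt)) {
    X <- extract_stack(stack, cells$x, cells$y, rep(years[t], nrow(cells)))
    if (model$variant == "native_range")
      X <- cbind(X, x = cells$x, y = cells$y)
    pr <- predict(model$fit, X, n_draws = n_draws)
    mean_a[, , t] <- matrix(pr$mean, nx, ny)
    lower_a[, , t] <- matrix(pr$lower, nx, ny)
    upper_a[, , t] <- matrix(pr$upper, nx, ny)
  }
  structure(list(x = stack$x, y = stack$y, years = as.integer(years),
                 mean = mean_a, lower = lower_a, upper = upper_a,
                 variant = model$variant),
            class = "habitat_projection")
}

#' Period-mean probability map
#'
#' Pixelwise mean of the posterior-mean surfaces over the chosen years.
#'
#' @param projection a `habitat_projection`.
#' @param years subset of projected years (default all).
#' @return an `nx` by `ny` matrix.
#' @export
period_mean <- function(projection, years = projection$years) {
  it <- match(years, projection$years)
  if (anyNA(it)) stop("years not present in the projection")
  apply(projection$mean[, , it, drop = FALSE], c(1, 2), mean)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y))
}

#' Habitat change map
#'
#' Pixelwise difference between the future and historical period-mean
#' probabilities: positive values are projected habitat gain, negative loss.
#'
#' @param hist,future `habitat_projection`s on the same grid.
#' @param hist_years,future_years years averaged in each period (defaults:
#'   all years of each projection).
#' @return a difference matrix.
#' @export
change_map <- function(hist, future, hist_years = hist$years,
                       future_years = future$years) {
  if (!same_grid(hist, future)) stop("projections are on different grids")
  period_mean(future, future_years) - period_mean(hist, hist_years)
}

#' Default future summary window
#'
#' The last ten projected years excluding the terminal year (dropped because
#' forcing-model output is least reliable there).
#'
#' @param projection a `habitat_projection`.
#' @return an integer vector of years.
#' @export
future_window <- function(projection) {
  yrs <- projection$years
  if (length(yrs) > 1) yrs <- yrs[-length(yrs)]
  tail(yrs, 10)
}

#' Percentage change in mean habitat suitability
#'
#' `100 * (mean future-window probability - mean historical probability) /
#' mean historical probability`, the scalar summary behind per-species
#' change tables.
#'
#' @param hist historical `habitat_projection`.
#' @param future future `habitat_projection` on the same grid.
#' @param future_years years summarized for the future period; defaults to
#'   [future_window()].
#' @param hist_years years summarized for the historical period.
#' @return the percentage change (scalar).
#' @export
percent_change <- function(hist, future, future_years = future_window(future),
                           hist_years = hist$years) {
  if (!same_grid(hist, future)) stop("projections are on different grids")
  mh <- mean(period_mean(hist, hist_years))
  if (mh == 0) stop("historical mean probability is zero")
  mf <- mean(period_mean(future, future_years))
  100 * (mf - mh) / mh
}

#' Species richness stack
#'
#' Counts, per pixel, the species whose period-mean probability reaches
#' their cutoff (typically each species' own Youden cutoff).
#'
#' @param projections list of `habitat_projection`s on one grid.
#' @param cutoffs one probability cutoff per species.
#' @return an integer richness matrix with values in `0..length(projections)`.
#' @export
richness_stack <- function(projections, cutoffs) {
  stopifnot(length(projections) >= 1, length(cutoffs) == length(projections))
  base <- projections[[1]]
  rich <- matrix(0L, length(base$x), length(base$y))
  for (i in seq_along(projections)) {
    if (!same_grid(base, projections[[i]]))
      stop("projections are on different grids")
    rich <- rich + (period_mean(projections[[i]]) >= cutoffs[i])
  }
  rich
}

#' Functional-group ensemble projection
#'
#' Aggregates species-level projections into a functional-group surface by
#' taking the pixelwise median across species, year by year (applied to the
#' mean surface and, for convenience, to the quantile envelopes).
#'
#' @param projections list of `habitat_projection`s on one grid and year
#'   axis.
#' @return a `habitat_projection` for the group.
#' @export
functional_group_aggregate <- function(projections) {
  stopifnot(length(projections) >= 1)
  base <- projections[[1]]
  for (p in projections) {
    if (!same_grid(base, p) || !identical(p$years, base$years))
      stop("projections must share grid and years")
  }
  med <- function(field) {
    arrs <- lapply(projections, `[[`, field)
    out <- array(0, dim = dim(base[[field]]))
    stacked <- array(unlist(arrs), dim = c(dim(base[[field]]),
                                           length(projections)))
    for (t in seq_along(base$years))
      out[, , t] <- apply(stacked[, , t, , drop = FALSE], c(1, 2), median)
    out
  }
  structure(list(x = base$x, y = base$y, years = base$years,
                 mean = med("mean"), lower = med("lower"),
                 upper = med("upper"), variant = "ensemble"),
            class = "habitat_projection")
}

#' Forward validation against held-out records
#'
#' Scores projected surfaces against occurrence records from years the model
#' never saw. With both classes present the cutoff defaults to the Youden
#' cutoff computed on the held-out records themselves; with presence-only
#' records a cutoff must be supplied and only sensitivity is reported.
#'
#' @param projection a `habitat_projection`.
#' @param new_table records with columns `x`, `y`, `year`, `label`, with
#'   years inside the projection.
#' @param cutoff probability cutoff; `NULL` selects the Youden cutoff (needs
#'   both classes).
#' @return a [confusion()] summary, or (presence-only) a list with `SEN`,
#'   `cutoff` and `n`.
#' @export
forward_validation <- function(projection, new_table, cutoff = NULL) {
  stopifnot(inherits(projection, "habitat_projection"))
  if (!any(new_table$year %in% projection$years))
    stop("no overlapping years between records and projection")
  new_table <- new_table[new_table$year %in% projection$years, , drop = FALSE]
  if (sum(new_table$label == 1) == 0) stop("no presence records to validate")
  ix <- vapply(new_table$x, function(v) which.min(abs(projection$x - v)), integer(1))
  iy <- vapply(new_table$y, function(v) which.min(abs(projection$y - v)), integer(1))
  it <- match(new_table$year, projection$years)
  prob <- projection$mean[cbind(ix, iy, it)]
  if (length(unique(new_table$label)) == 2) {
    cutoff <- cutoff %||% youden_cutoff(new_table$label, prob)
    return(confusion(new_table$label, prob, cutoff))
  }
  if (is.null(cutoff))
    stop("presence-only validation requires an explicit cutoff")
  list(SEN = mean(prob >= cutoff), cutoff = cutoff, n = nrow(new_table))
}

#' Write / read a covariate stack as CSV
#'
#' Long-format round trip (`layer`, `x`, `y`, `year`, `value`) for plain-text
#' exchange of gridded covariates.
#'
#' @param stack a [covariate_stack()].
#' @param path CSV path.
#' @return `read_stack_csv` returns a `covariate_stack`.
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "covariate_stack"))
  nx <- length(stack$x); ny <- length(stack$y); nt <- length(stack$years)
  rows <- lapply(names(stack$layers), function(nm)
    data.frame(layer = nm,
               x = rep(stack$x, times = ny * nt),
               y = rep(rep(stack$y, each = nx), times = nt),
               year = rep(stack$years, each = nx * ny),
               value = as.vector(stack$layers[[nm]])))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  df <- read.csv(path)
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  years <- sort(unique(df$year))
  layers <- lapply(split(df, df$layer), function(d) {
    d <- d[order(d$year, d$y, d$x), ]
    array(d$value, dim = c(length(x), length(y), length(years)))
  })
  covariate_stack(layers, x, y, years)
}
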