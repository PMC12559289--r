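#' Virtual-species scenario configuration
#'
#' Bundles every parameter of the occurrence simulator: the linear-predictor
#' coefficients, the Matern/AR(1) parameters of the latent spatio-temporal
#' field, and the temporal-trend autocorrelation. Two archetypes ship with
#' their published parameterizations:
#'
#' * `"cosmopolitan"` -- broadly dispersed: spatial range 3.5, marginal SD 1,
#'   spatio-temporal AR(1) coefficient 0.7, second-degree polynomial
#'   bathymetry effect with coefficients (-1.5, -1.1), linear temperature
#'   effect (default coefficient -0.5), trend AR(1) coefficient 0.7.
#' * `"persistent"` -- spatially concentrated and temporally stable: range
#'   5.6, SD 1, spatio-temporal AR(1) coefficient 0.1, linear bathymetry
#'   effect 7.5, temperature effect -0.8, trend AR(1) coefficient 0.7.
#'
#' Covariates are standardized (zero mean, unit SD over all cell-years)
#' before the coefficients apply, keeping the logit predictor in a
#' numerically meaningful range; set `standardize = FALSE` to apply the
#' coefficients to raw covariate values.
#'
#' @param kind `"cosmopolitan"` or `"persistent"`.
#' @param beta0 intercept on the logit scale (default 0, neutral prevalence).
#' @param spatial_range,spatial_sd Matern range and marginal SD of the latent
#'   field (defaults per `kind`).
#' @param rho_st AR(1) coefficient of the spatio-temporal field, in (-1, 1).
#' @param rho_t AR(1) coefficient of the temporal trend, in (-1, 1).
#' @param bath_coeffs bathymetry coefficients: length 2 (linear, quadratic)
#'   for the cosmopolitan polynomial, length 1 for the persistent linear
#'   effect.
#' @param temp_coeff linear temperature coefficient.
#' @param temp_increment deterministic warming per year (default 0.5).
#' @param standardize standardize covariates before applying coefficients?
#' @param seed integer seed governing the simulation.
#' @return an object of class `scenario_config`.
#' @examples
#' scenario_config("persistent")
#' @export
scenario_config <- function(kind = c("cosmopolitan", "persistent"),
                            beta0 = 0,
                            spatial_range = NULL, spatial_sd = 1,
                            rho_st = NULL, rho_t = 0.7,
                            bath_coeffs = NULL, temp_coeff = NULL,
                            temp_increment = 0.5,
                            standardize = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "cosmopolitan") {
    spatial_range <- spatial_range %||% 3.5
    rho_st <- rho_st %||% 0.7
    bath_coeffs <- bath_coeffs %||% c(-1.5, -1.1)
    temp_coeff <- temp_coeff %||% -0.5
  } else {
    spatial_range <- spatial_range %||% 5.6
    rho_st <- rho_st %||% 0.1
    bath_coeffs <- bath_coeffs %||% 7.5
    temp_coeff <- temp_coeff %||% -0.8
  }
  stopifnot(spatial_range > 0, spatial_sd >= 0,
            abs(rho_st) < 1, abs(rho_t) < 1)
  if (kind == "cosmopolitan" && length(bath_coeffs) != 2)
    stop("cosmopolitan scenario needs 2 bathymetry coefficients (linear, quadratic)")
  if (kind == "persistent" && length(bath_coeffs) != 1)
    stop("persistent scenario needs a single linear bathymetry coefficient")
  structure(list(kind = kind, beta0 = beta0,
                 spatial_range = spatial_range, spatial_sd = spatial_sd,
                 rho_st = rho_st, rho_t = rho_t,
                 bath_coeffs = bath_coeffs, temp_coeff = temp_coeff,
                 temp_increment = temp_increment,
                 standardize = standardize,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s species\n", x$kind))
  cat(sprintf("  latent field: range %.2f, sd %.2f, rho_st %.2f; trend rho_t %.2f\n",
              x$spatial_range, x$spatial_sd, x$rho_st, x$rho_t))
  cat(sprintf("  beta0 %.2f, bathymetry (%s), temperature %.2f (+%.2f/yr)\n",
              x$beta0, paste(format(x$bath_coeffs), collapse = ", "),
              x$temp_coeff, x$temp_increment))
  invisible(x)
}

#' Read a scenario configuration from YAML
#'
#' Loads a YAML file whose keys mirror the arguments of [scenario_config()];
#' any omitted key falls back to the archetype default.
#'
#' @param path path to a YAML file; a `kind` key is required.
#' @return a `scenario_config` object.
#' @export
scenario_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  if (is.null(vals$kind)) stop("YAML configuration must set `kind`")
  keep <- intersect(names(vals), names(formals(scenario_config)))
  do.call(scenario_config, vals[keep])
}
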