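#' BART sampler configuration
#'
#' MCMC and prior settings for the probit BART classifier. Defaults follow
#' the standard BART prior: `m = 200` trees, depth-penalising split prior
#' with `alpha = 0.95`, `beta = 2`, and leaf-value prior SD
#' `sigma_mu = 3 / (k * sqrt(m))` with `k = 2`. The leaf SD is always
#' computed from `k` and `n_trees`, never stored independently.
#'
#' @param n_trees number of trees `m`.
#' @param k leaf-shrinkage parameter; larger `k` shrinks the latent fit (and
#'   hence the probabilities) toward 0.5.
#' @param alpha,beta split-prior parameters: P(split at depth d) =
#'   `alpha * (1 + d)^(-beta)`.
#' @param n_draws retained posterior draws; `n_burn` discarded burn-in.
#' @param seed integer seed.
#' @return an object of class `bart_config`.
#' @examples
#' cfg <- bart_config()
#' leaf_prior_sd(cfg$k, cfg$n_trees)
#' @export
bart_config <- function(n_trees = 200, k = 2, alpha = 0.95, beta = 2,
                        n_draws = 1000, n_burn = 100, seed = 1L) {
  stopifnot(n_trees >= 1, k > 0, alpha >= 0, alpha <= 1, beta >= 0,
            n_draws >= 1, n_burn >= 0)
  structure(list(n_trees = as.integer(n_trees), k = k, alpha = alpha,
                 beta = beta, n_draws = as.integer(n_draws),
                 n_burn = as.integer(n_burn), seed = as.integer(seed)),
            class = "bart_config")
}

#' Tree split prior
#'
#' Probability that a node at the given depth splits:
#' `alpha * (1 + depth)^(-beta)`. With the defaults a root splits with
#' probability 0.95 but a depth-1 node only with 0.2375, favouring shallow
#' trees.
#'
#' @param depth node depth (root = 0).
#' @param alpha,beta prior parameters.
#' @return split probabilities.
#' @export
split_prior <- function(depth, alpha = 0.95, beta = 2) {
  stopifnot(all(depth >= 0))
  alpha * (1 + depth)^(-beta)
}

#' Leaf-value prior standard deviation
#'
#' `sigma_mu = 3 / (k * sqrt(m))`: the sum of `m` independent leaf
#' contributions then has prior SD `3 / k`, keeping the latent probit score
#' (and hence `Phi(score)`) in a plausible range.
#'
#' @param k shrinkage parameter (> 0).
#' @param m number of trees (>= 1).
#' @return the prior SD.
#' @export
leaf_prior_sd <- function(k, m) {
  stopifnot(k > 0, m >= 1)
  3.0 / (k * sqrt(m))
}

#' Simulate a tree depth from the structural prior
#'
#' Draws one tree from the branching process implied by [split_prior()] and
#' returns the depth of its deepest leaf. Used to check the sampler's prior
#' against the closed-form depth distribution.
#'
#' @param alpha,beta split-prior parameters.
#' @param max_depth recursion guard.
#' @return an integer depth (0 = stump).
#' @export
simulate_tree_depth <- function(alpha = 0.95, beta = 2, max_depth = 12) {
  rec <- function(d) {
    if (d >= max_depth) return(d)
    if (runif(1) < split_prior(d, alpha, beta)) max(rec(d + 1), rec(d + 1)) else d
  }
  rec(0)
}

validate_covariate_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("covariates must be finite")
  x
}

#' Fit a probit BART classifier
#'
#' Sum-of-trees binary classifier with probit data augmentation: the latent
#' score for observation `i` is the sum over `m` trees of their leaf values,
#' the error term is fixed standard normal, and
#' `P(y = 1 | x) = Phi(sum-of-trees)`. Trees are updated by
#' Metropolis-Hastings structural moves (grow 0.25 / prune 0.25 / change
#' 0.40 / swap 0.10) with the leaf values integrated out, followed by
#' conjugate-normal leaf draws; cutpoint proposals are uniform over the
#' observed unique values of the split variable and latent draws are clipped
#' at +/- 10 to avoid overflow. Fits are reproducible under
#' `config$seed`.
#'
#' @param x covariate matrix or data frame (finite values; columns named).
#' @param y binary labels (0/1), both classes present.
#' @param config a [bart_config()].
#' @return an object of class `bart_probit` holding the posterior tree
#'   ensembles (flat node table), the configuration and the training data.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "x1"))
#' y <- as.integer(x[, 1] > 0)
#' fit <- bart_probit(x, y, bart_config(n_trees = 20, n_draws = 100, n_burn = 50))
#' mean((predict(fit, x)$mean >= 0.5) == y)
#' @export
bart_probit <- function(x, y, config = bart_config()) {
  stopifnot(inherits(config, "bart_config"))
  x <- validate_covariate_matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("x and y lengths differ")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("both classes must be present to fit a classifier")
  set.seed(config$seed)
  fit <- bart_probit_fit_cpp(x, y, config$n_trees, config$k, config$alpha,
                             config$beta, config$n_burn, config$n_draws)
  structure(list(posterior = fit, config = config,
                 varnames = colnames(x), x_train = x, y_train = y),
            class = "bart_probit")
}

#' @export
print.bart_probit <- function(x, ...) {
  cat(sprintf("<bart_probit> %d trees, %d retained draws, %d obs, %d covariates\n",
              x$config$n_trees, x$posterior$n_draws, nrow(x$x_train),
              length(x$varnames)))
  cat(sprintf("  sigma_mu = %.4f, MH acceptance %.2f\n",
              x$posterior$sigma_mu, x$posterior$acceptance_rate))
  invisible(x)
}

prepare_newdata <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$varnames, names(newdata))
    if (length(missing) > 0)
      stop("newdata is missing covariates: ", paste(missing, collapse = ", "))
    newdata <- as.matrix(newdata[, object$varnames, drop = FALSE])
  } else {
    newdata <- validate_covariate_matrix(newdata)
    if (!is.null(colnames(newdata)) &&
        all(object$varnames %in% colnames(newdata))) {
      newdata <- newdata[, object$varnames, drop = FALSE]
    } else if (ncol(newdata) != length(object$varnames)) {
      stop("newdata columns do not match training covariates")
    }
  }
  storage.mode(newdata) <- "double"
  newdata
}

select_draws <- function(object, n_draws) {
  total <- object$posterior$n_draws
  if (is.null(n_draws) || n_draws >= total) return(seq_len(total) - 1L)
  as.integer(round(seq(1, total, length.out = n_draws))) - 1L
}

#' Posterior predictions from a probit BART fit
#'
#' Per retained draw the predicted probability is `Phi` of the sum-of-trees
#' score; the summary reports the pointwise posterior mean and the 0.025 /
#' 0.975 quantiles across draws.
#'
#' @param object a [bart_probit()] fit.
#' @param newdata covariate matrix or data frame with the training columns.
#' @param type `"summary"` for mean and quantiles, `"draws"` to also return
#'   the per-draw probability matrix (rows = observations).
#' @param n_draws optionally thin to this many evenly spaced draws.
#' @param probs lower/upper quantile levels.
#' @param ... unused.
#' @return a list of class `bart_prediction` with `mean`, `lower`, `upper`
#'   (and `draws` when requested).
#' @export
predict.bart_probit <- function(object, newdata, type = c("summary", "draws"),
                                n_draws = NULL, probs = c(0.025, 0.975), ...) {
  type <- match.arg(type)
  newdata <- prepare_newdata(object, newdata)
  ids <- select_draws(object, n_draws)
  post <- object$posterior
  out <- bart_predict_cpp(post$var, post$cut, post$value, post$left,
                          post$right, post$roots, post$m, newdata, ids,
                          type == "draws", probs[1], probs[2])
  structure(out, class = "bart_prediction", n_draws = length(ids))
}

#' Serialize a probit BART fit to JSON
#'
#' Writes the posterior node table (split variables, cutpoints, leaf values,
#' child indices, per-draw tree roots) plus the configuration to a
#' documented JSON format; `bart_from_json` restores a fit whose predictions
#' are identical to the original's.
#'
#' @param object a `bart_probit` fit.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `bart_to_json`: the path (or JSON string); `bart_from_json`: a
#'   `bart_probit` object.
#' @export
bart_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "bart_probit"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required for model serialization")
  payload <- list(
    format = "bartsdm-probit-bart-1",
    varnames = object$varnames,
    config = unclass(object$config),
    m = object$posterior$m,
    n_draws = object$posterior$n_draws,
    sigma_mu = object$posterior$sigma_mu,
    nodes = list(var = object$posterior$var, cut = object$posterior$cut,
                 value = object$posterior$value, left = object$posterior$left,
                 right = object$posterior$right),
    roots = object$posterior$roots)
  # I(17) significant digits: doubles (cutpoints especially) must round-trip
  # exactly or boundary observations flip sides of a split
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname bart_to_json
#' @param json a path to, or string of, JSON written by `bart_to_json`.
#' @export
bart_from_json <- function(json) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required for model serialization")
  payload <- jsonlite::fromJSON(json)
  if (!identical(payload$format, "bartsdm-probit-bart-1"))
    stop("unrecognised model JSON format")
  post <- list(var = as.integer(payload$nodes$var),
               cut = as.numeric(payload$nodes$cut),
               value = as.numeric(payload$nodes$value),
               left = as.integer(payload$nodes$left),
               right = as.integer(payload$nodes$right),
               roots = as.integer(payload$roots),
               m = as.integer(payload$m),
               n_draws = as.integer(payload$n_draws),
               sigma_mu = payload$sigma_mu,
               acceptance_rate = NA_real_)
  cfg <- do.call(bart_config, payload$config[c("n_trees", "k", "alpha", "beta",
                                               "n_draws", "n_burn", "seed")])
  structure(list(posterior = post, config = cfg,
                 varnames = payload$varnames,
                 x_train = NULL, y_train = NULL),
            class = "bart_probit")
}
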