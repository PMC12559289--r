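# Comparator species distribution models fitted to the same tables as BART:
# a MaxEnt-style penalized logistic regression and a binomial GAM.

# MaxEnt-style feature expansion: linear, quadratic, pairwise products and
# hinge features (both orientations) at interior quantile knots.
maxent_features <- function(x, spec = NULL, n_hinge = 5) {
  x <- validate_covariate_matrix(x)
  vars <- colnames(x)
  if (is.null(spec)) {
    knots <- lapply(vars, function(v)
      unname(quantile(x[, v], probs = seq_len(n_hinge) / (n_hinge + 1))))
    names(knots) <- vars
    spec <- list(vars = vars, knots = knots)
  }
  cols <- list()
  for (v in spec$vars) {
    xv <- x[, v]
    cols[[paste0("lin_", v)]] <- xv
    cols[[paste0("quad_", v)]] <- xv^2
    for (j in seq_along(spec$knots[[v]])) {
      kj <- spec$knots[[v]][j]
      cols[[paste0("hingeu_", v, "_", j)]] <- pmax(0, xv - kj)
      cols[[paste0("hinged_", v, "_", j)]] <- pmax(0, kj - xv)
    }
  }
  if (length(spec$vars) > 1) {
    cmb <- utils::combn(spec$vars, 2)
    for (j in seq_len(ncol(cmb)))
      cols[[paste0("prod_", cmb[1, j], "_", cmb[2, j])]] <-
        x[, cmb[1, j]] * x[, cmb[2, j]]
  }
  list(features = do.call(cbind, cols), spec = spec)
}

#' MaxEnt-style baseline
#'
#' Penalized (lasso) logistic regression on a MaxEnt-style feature
#' expansion of the covariates -- linear, quadratic, product and hinge
#' features -- with the penalty chosen by cross-validation on the binomial
#' deviance. Serves as the presence/background-flavoured comparator fitted
#' to the same tables as BART.
#'
#' @param x covariate matrix or data frame.
#' @param y binary labels, both classes present.
#' @param n_hinge hinge knots per covariate and orientation.
#' @param seed integer seed (fixes the cross-validation folds).
#' @return an object of class `maxent_sdm`.
#' @export
fit_maxent <- function(x, y, n_hinge = 5, seed = 1L) {
  x <- validate_covariate_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  fx <- maxent_features(x, n_hinge = n_hinge)
  keep <- apply(fx$features, 2, function(col) sd(col) > 0)
  if (!any(keep)) stop("degenerate features: all expansions are constant")
  set.seed(seed)
  foldid <- sample(rep_len(1:5, length(y)))
  cv <- glmnet::cv.glmnet(fx$features[, keep, drop = FALSE], y,
                          family = "binomial", alpha = 1, foldid = foldid)
  structure(list(cv = cv, spec = fx$spec, keep = keep,
                 varnames = colnames(x)),
            class = "maxent_sdm")
}

#' @export
predict.maxent_sdm <- function(object, newdata, ...) {
  newdata <- newdata[, object$varnames, drop = FALSE]
  fx <- maxent_features(as.matrix(newdata), spec = object$spec)
  p <- predict(object$cv, fx$features[, object$keep, drop = FALSE],
               s = "lambda.min", type = "response")
  as.vector(p)
}

#' GAM baseline
#'
#' Binomial generalized additive model with a thin-plate smooth per
#' covariate (REML smoothness selection via mgcv). Basis dimensions are
#' reduced, with a warning, for covariates with too few unique values to
#' support the requested basis.
#'
#' @param x covariate matrix or data frame.
#' @param y binary labels, both classes present.
#' @param k target basis dimension per smooth.
#' @return an object of class `gam_sdm`.
#' @export
fit_gam <- function(x, y, k = 10) {
  x <- validate_covariate_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  df <- as.data.frame(x)
  df$.label <- y
  terms <- vapply(colnames(x), function(v) {
    nu <- length(unique(x[, v]))
    if (nu < 4) {
      warning("covariate `", v, "` has too few unique values for a smooth; ",
              "using a linear term")
      return(v)
    }
    kv <- min(k, nu - 1)
    if (kv < k)
      warning("basis for `", v, "` reduced to k = ", kv,
              " (only ", nu, " unique values)")
    sprintf("s(%s, k = %d)", v, kv)
  }, character(1))
  form <- as.formula(paste(".label ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, family = binomial(), data = df, method = "REML")
  structure(list(gam = fit, varnames = colnames(x)), class = "gam_sdm")
}

#' @export
predict.gam_sdm <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$varnames, drop = FALSE]
  as.vector(predict(object$gam, newdata = newdata, type = "response"))
}
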