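#' Partial-dependence functional response
#'
#' Marginal effect of one covariate on the predicted probability of
#' presence: for each grid value the covariate is forced to that value in
#' every training row, the remaining covariates keep their observed values,
#' and the per-draw predicted probabilities are averaged over rows. The
#' curve reports the posterior mean of that average with 0.025/0.975
#' quantiles.
#'
#' @param object a [bart_probit()] fit (with training data attached).
#' @param variable covariate name.
#' @param values grid of values; defaults to 10 evenly spaced quantiles of
#'   the training covariate.
#' @param n_draws posterior draws used (thinned evenly).
#' @param probs quantile levels for the uncertainty band.
#' @return a data frame with columns `value`, `mean`, `lower`, `upper`.
#' @export
partial_dependence <- function(object, variable, values = NULL,
                               n_draws = 200, probs = c(0.025, 0.975)) {
  stopifnot(inherits(object, "bart_probit"))
  if (is.null(object$x_train))
    stop("partial dependence needs the training data attached to the fit")
  if (!(variable %in% object$varnames))
    stop("`", variable, "` was not a training covariate")
  xt <- object$x_train
  values <- values %||%
    unname(quantile(xt[, variable], probs = seq(0.05, 0.95, length.out = 10)))
  rows <- lapply(values, function(v) {
    xv <- xt
    xv[, variable] <- v
    pr <- predict(object, xv, type = "draws", n_draws = n_draws)
    per_draw <- colMeans(pr$draws)   # average over rows within each draw
    c(mean(per_draw), quantile(per_draw, probs[1]), quantile(per_draw, probs[2]))
  })
  out <- do.call(rbind, rows)
  data.frame(value = values, mean = out[, 1], lower = out[, 2],
             upper = out[, 3], row.names = NULL)
}

#' Permutation variable importance
#'
#' Increase in prediction error when a single covariate is randomly
#' permuted: for each covariate and permutation, the column is shuffled, the
#' model re-predicts, and the change in classification error (at the given
#' cutoff, against the supplied labels) relative to the unpermuted baseline
#' is recorded. Scores are the mean increase per covariate; when all are
#' nonnegative they are also reported normalized to sum to one.
#'
#' @param object a [bart_probit()] fit.
#' @param x,y evaluation covariates and labels; default the training data.
#' @param n_perm permutations per covariate.
#' @param cutoff classification threshold for the error metric.
#' @param n_draws posterior draws used for the predictions.
#' @param seed integer seed for the permutations.
#' @return a data frame with columns `variable`, `raw` (mean error
#'   increase) and `importance` (normalized share, `NA` when any raw score
#'   is negative).
#' @export
permutation_importance <- function(object, x = NULL, y = NULL, n_perm = 10,
                                   cutoff = 0.5, n_draws = 100, seed = 1L) {
  stopifnot(inherits(object, "bart_probit"), n_perm >= 1)
  x <- if (is.null(x)) object$x_train else prepare_newdata(object, x)
  y <- y %||% object$y_train
  if (is.null(x) || is.null(y))
    stop("evaluation data required (fit has no training data attached)")
  err <- function(xx) {
    p <- predict(object, xx, n_draws = n_draws)$mean
    mean((p >= cutoff) != y)
  }
  base <- err(x)
  set.seed(seed)
  raw <- vapply(object$varnames, function(v) {
    mean(vapply(seq_len(n_perm), function(i) {
      xp <- x
      xp[, v] <- xp[sample.int(nrow(xp)), v]
      err(xp) - base
    }, numeric(1)))
  }, numeric(1))
  importance <- if (all(raw >= 0) && sum(raw) > 0) raw / sum(raw)
                else rep(NA_real_, length(raw))
  data.frame(variable = object$varnames, raw = unname(raw),
             importance = unname(importance), row.names = NULL)
}
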