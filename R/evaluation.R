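#' Confusion-matrix summary
#'
#' Thresholds predicted probabilities at `cutoff` (probabilities at or above
#' the cutoff are predicted presences) and derives
#' `SPC = TN / N`, `SEN = TP / P`, `ACC = (TP + TN) / (P + N)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`, along with Youden's `J = SEN + SPC - 1`.
#' Rates whose denominator is zero are `NaN`.
#'
#' @param labels binary 0/1 truth.
#' @param predicted_prob probabilities in `[0, 1]`.
#' @param cutoff threshold in `[0, 1]`.
#' @return an object of class `confusion_summary`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6), cutoff = 0.5)
#' @export
confusion <- function(labels, predicted_prob, cutoff = 0.5) {
  if (length(labels) == 0) stop("empty input")
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)),
            all(predicted_prob >= 0 & predicted_prob <= 1),
            length(labels) == length(predicted_prob))
  pred <- as.integer(predicted_prob >= cutoff)
  TP <- sum(pred == 1 & labels == 1)
  TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  P <- TP + FN; N <- TN + FP
  sen <- TP / P; spc <- TN / N
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, P = P, N = N,
                 SEN = sen, SPC = spc,
                 ACC = (TP + TN) / (P + N),
                 F1 = 2 * TP / (2 * TP + FP + FN),
                 cutoff = cutoff, youden_J = sen + spc - 1),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion> TP %d TN %d FP %d FN %d | SEN %.3f SPC %.3f ACC %.3f F1 %.3f (cutoff %.3f)\n",
              x$TP, x$TN, x$FP, x$FN, x$SEN, x$SPC, x$ACC, x$F1, x$cutoff))
  invisible(x)
}

#' Youden-index cutoff
#'
#' Probability threshold maximizing Youden's index `SEN + SPC - 1` over the
#' candidate set of observed predicted probabilities; ties are broken toward
#' the smaller cutoff.
#'
#' @param labels binary 0/1 truth, both classes present.
#' @param predicted_prob probabilities in `[0, 1]`.
#' @return the selected cutoff.
#' @export
youden_cutoff <- function(labels, predicted_prob) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to select a cutoff")
  cand <- sort(unique(predicted_prob))
  J <- vapply(cand, function(cc) {
    pred <- predicted_prob >= cc
    sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0) - 1
  }, numeric(1))
  cand[which.max(J)]  # which.max returns the first (smallest) maximizer
}

# ---- model dispatch shared by kfold and run_experiment ------------------

fit_sdm <- function(model, x, y, seed, bart = bart_config()) {
  switch(model,
    bart = {
      cfg <- bart
      cfg$seed <- as.integer(seed)
      bart_probit(x, y, cfg)
    },
    maxent = fit_maxent(x, y, seed = seed),
    gam = fit_gam(x, y),
    stop("unknown model: ", model))
}

predict_sdm <- function(fit, newdata, n_draws = NULL) {
  if (inherits(fit, "bart_probit"))
    predict(fit, newdata, n_draws = n_draws)$mean
  else
    predict(fit, newdata)
}

#' k-fold cross-validation
#'
#' Splits the data into `k` disjoint, exhaustive folds, fits the model on
#' `k - 1` folds and scores the held-out fold at the Youden cutoff estimated
#' from the training predictions. If a random split leaves a training set
#' single-class, the folds are re-drawn stratified by class, with a warning.
#'
#' @param x covariate matrix or data frame.
#' @param y binary labels.
#' @param k number of folds (default 10); `k = n` gives leave-one-out.
#' @param model `"bart"`, `"maxent"` or `"gam"`.
#' @param seed integer seed (fold assignment and model fits).
#' @param bart a [bart_config()] used when `model = "bart"`.
#' @return a list with `folds` (assignment vector), `per_fold` (data frame
#'   of per-fold metrics) and `pooled` (a [confusion()] over the pooled
#'   held-out counts).
#' @export
kfold <- function(x, y, k = 10, model = "bart", seed = 1L,
                  bart = bart_config()) {
  x <- validate_covariate_matrix(x)
  y <- as.integer(y)
  n <- length(y)
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  bad <- any(vapply(seq_len(k), function(f)
    length(unique(y[folds != f])) < 2, logical(1)))
  if (bad) {
    warning("a training split lost a class; re-stratifying folds by class")
    folds <- integer(n)
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  rows <- vector("list", k)
  pool_lab <- integer(0); pool_prob <- numeric(0); pool_cut <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_sdm(model, x[tr, , drop = FALSE], y[tr],
                   seed = derive_seed(seed, f), bart = bart)
    cut_f <- youden_cutoff(y[tr], predict_sdm(fit, x[tr, , drop = FALSE]))
    prob <- predict_sdm(fit, x[!tr, , drop = FALSE])
    cm <- confusion(y[!tr], prob, cut_f)
    rows[[f]] <- data.frame(fold = f, cutoff = cut_f, SEN = cm$SEN,
                            SPC = cm$SPC, ACC = cm$ACC, F1 = cm$F1)
    pool_lab <- c(pool_lab, y[!tr]); pool_prob <- c(pool_prob, prob)
    pool_cut <- c(pool_cut, rep(cut_f, sum(!tr)))
  }
  pooled_pred <- as.numeric(pool_prob >= pool_cut)  # per-fold cutoffs
  list(folds = folds, per_fold = do.call(rbind, rows),
       pooled = confusion(pool_lab, pooled_pred, cutoff = 0.5))
}

# Covariate frame (bathymetry, temperature, year) for sampled records or for
# the full prediction grid of a world.
table_covariates <- function(world, table) {
  bath <- world$surface$covariates$bathymetry
  temp <- world$surface$covariates$temperature
  it <- match(table$year, world$grid$years)
  cbind(bathymetry = bath[cbind(table$ix, table$iy)],
        temperature = temp[cbind(table$ix, table$iy, it)],
        year = as.numeric(table$year))
}

grid_covariates <- function(world) {
  g <- world$grid
  nx <- length(g$x); ny <- length(g$y); nt <- length(g$years)
  cbind(bathymetry = rep(as.vector(world$surface$covariates$bathymetry), nt),
        temperature = as.vector(world$surface$covariates$temperature),
        year = rep(as.numeric(g$years), each = nx * ny))
}

#' Run a replicate simulation experiment
#'
#' End-to-end harness: simulate a virtual-species world, draw `R` replicate
#' observation tables (true absences or pseudo-absences) from the training
#' years, fit each requested model to each replicate, predict every
#' cell-year of the grid, and score predictions against the simulated
#' occurrence truth at the Youden cutoff estimated on the training records.
#' All models consume identical replicate tables and identical prediction
#' grids. Covariates offered to every model: bathymetry, temperature, year.
#'
#' @param scenario a [scenario_config()] or its `kind` string.
#' @param mode `"true"` or `"pseudo"` absences.
#' @param models character subset of `c("bart", "maxent", "gam")`.
#' @param R number of replicates.
#' @param n observations per replicate.
#' @param holdout_years years excluded from sampling but kept in evaluation.
#' @param seed master integer seed (world, replicates and fits derive from
#'   it).
#' @param grid a [grid_domain()].
#' @param bart a [bart_config()]; the default uses 200 trees with 100
#'   burn-in and 500 retained draws.
#' @param n_predict_draws posterior draws used for the prediction surfaces.
#' @return an object of class `sdm_experiment`: `metrics` (one row per
#'   scenario/mode/model/replicate/year with SEN, SPC, ACC, F1),
#'   `summary` (per-year replicate median and 0.025/0.975 quantiles, plus a
#'   scalar mean accuracy per model), the `world`, the replicate `tables`
#'   and a record of any per-replicate model `failures`.
#' @examples
#' \donttest{
#' ex <- run_experiment("persistent", mode = "true", models = "gam",
#'                      R = 2, n = 40, holdout_years = 5:6, seed = 1,
#'                      grid = grid_domain(nx = 10, ny = 10, years = 1:6))
#' ex$summary$overall
#' }
#' @export
run_experiment <- function(scenario = "cosmopolitan", mode = c("true", "pseudo"),
                           models = c("bart", "maxent", "gam"),
                           R = 50, n = 50, holdout_years = c(18, 19, 20),
                           seed = 1L, grid = grid_domain(),
                           bart = bart_config(n_draws = 500, n_burn = 100),
                           n_predict_draws = 100) {
  mode <- match.arg(mode)
  models <- match.arg(models, several.ok = TRUE)
  config <- if (inherits(scenario, "scenario_config")) scenario
            else scenario_config(scenario, seed = derive_seed(seed, 101))
  world <- simulate_scenario(config, grid)
  tables <- make_replicates(world, n = n, R = R, mode = mode,
                            base_seed = derive_seed(seed, 202),
                            holdout_years = holdout_years)
  truth <- world$field$occurrence
  Xgrid <- grid_covariates(world)
  nx <- length(grid$x); ny <- length(grid$y)
  years <- grid$years

  rows <- list(); failures <- list()
  for (r in seq_len(R)) {
    tab <- tables[[r]]
    Xtr <- table_covariates(world, tab)
    for (mdl in models) {
      res <- tryCatch({
        fit <- fit_sdm(mdl, Xtr, tab$label, seed = derive_seed(seed, 1000 + r),
                       bart = bart)
        train_prob <- predict_sdm(fit, Xtr, n_draws = n_predict_draws)
        cut_r <- youden_cutoff(tab$label, train_prob)
        grid_prob <- predict_sdm(fit, Xgrid, n_draws = n_predict_draws)
        pred_arr <- array(grid_prob, dim = dim(truth))
        do.call(rbind, lapply(seq_along(years), function(t) {
          cm <- confusion(as.vector(truth[, , t]),
                          as.vector(pred_arr[, , t]), cut_r)
          data.frame(scenario = config$kind, mode = mode, model = mdl,
                     replicate = r, year = years[t], cutoff = cut_r,
                     SEN = cm$SEN, SPC = cm$SPC, ACC = cm$ACC, F1 = cm$F1)
        }))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(model = mdl, replicate = r,
                     message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics,
                 summary = summarize_experiment(metrics),
                 world = world, tables = tables,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL),
            class = "sdm_experiment")
}

#' Aggregate experiment metrics
#'
#' Per model and year: replicate-wise median and 0.025/0.975 quantiles of
#' each metric. The scalar accuracy per model is the mean of ACC over all
#' replicates and evaluated years (each year's ACC covers every grid cell,
#' so this equals the cell-level mean).
#'
#' @param metrics the `metrics` data frame of an `sdm_experiment`.
#' @return a list with `per_year` and `overall` data frames.
#' @export
summarize_experiment <- function(metrics) {
  q <- function(v, p) unname(quantile(v, p, na.rm = TRUE))
  per_year <- do.call(rbind, lapply(
    split(metrics, metrics[c("model", "year")], drop = TRUE),
    function(d) {
      out <- data.frame(model = d$model[1], year = d$year[1])
      for (mm in c("SEN", "SPC", "ACC", "F1")) {
        out[[paste0(mm, "_median")]] <- median(d[[mm]], na.rm = TRUE)
        out[[paste0(mm, "_lower")]] <- q(d[[mm]], 0.025)
        out[[paste0(mm, "_upper")]] <- q(d[[mm]], 0.975)
      }
      out
    }))
  rownames(per_year) <- NULL
  overall <- aggregate(ACC ~ model, data = metrics, FUN = mean)
  names(overall)[2] <- "mean_accuracy"
  list(per_year = per_year[order(per_year$model, per_year$year), ],
       overall = overall)
}

#' @export
print.sdm_experiment <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<sdm_experiment> %s species, %s absences, %d replicates, years %d..%d\n",
              m$scenario[1], m$mode[1], max(m$replicate), min(m$year), max(m$year)))
  print(x$summary$overall, row.names = FALSE)
  if (!is.null(x$failures))
    cat(nrow(x$failures), "model fits failed (see $failures)\n")
  invisible(x)
}

#' Plot experiment metrics
#'
#' Per-year replicate median with 0.025/0.975 ribbon for sensitivity,
#' specificity and accuracy (one facet per metric, one colour per model).
#' Requires ggplot2.
#'
#' @param experiment an `sdm_experiment`.
#' @return a ggplot object.
#' @export
plot_experiment <- function(experiment) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the 'ggplot2' package is required for plotting")
  py <- experiment$summary$per_year
  long <- do.call(rbind, lapply(c("SEN", "SPC", "ACC"), function(mm)
    data.frame(model = py$model, year = py$year, metric = mm,
               median = py[[paste0(mm, "_median")]],
               lower = py[[paste0(mm, "_lower")]],
               upper = py[[paste0(mm, "_upper")]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$median,
                                     colour = .data$model,
                                     fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(y = "metric (replicate median, 95% envelope)") +
    ggplot2::theme_minimal()
}
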