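# Replicate observation sets drawn from a simulated occurrence field.
# Tables carry cell indices alongside coordinates so downstream code can
# look fields up without nearest-neighbour matching.

new_occurrence_table <- function(df, mode, seed, replicate_id = 1L) {
  structure(df, class = c("occurrence_table", "data.frame"),
            mode = mode, seed = seed, replicate_id = replicate_id)
}

cell_year_index <- function(field, years) {
  g <- field$grid
  keep <- which(g$years %in% years)
  if (length(keep) == 0) stop("no usable years in the field")
  expand.grid(ix = seq_along(g$x), iy = seq_along(g$y), it = keep)
}

table_from_cells <- function(field, cells, label, absence_kind) {
  g <- field$grid
  data.frame(x = g$x[cells$ix], y = g$y[cells$iy], year = g$years[cells$it],
             ix = cells$ix, iy = cells$iy,
             label = label, absence_kind = absence_kind,
             stringsAsFactors = FALSE)
}

#' Sample true presence/absence records
#'
#' Draws `n` cell-years uniformly without replacement from the field (over
#' the given years) and copies each cell's simulated occurrence status as the
#' label, so absences are true absences.
#'
#' @param field an `occurrence_field` (or `sim_world`).
#' @param n number of observations.
#' @param seed integer seed.
#' @param years years to sample from (default: all years in the field).
#' @return an `occurrence_table`: a data frame with columns `x`, `y`, `year`,
#'   `ix`, `iy`, `label` (0/1) and `absence_kind`
#'   (`"true"`/`"pseudo"`/`"none"`).
#' @examples
#' w <- simulate_scenario(scenario_config("cosmopolitan", seed = 3),
#'                        grid_domain(nx = 8, ny = 8, years = 1:4))
#' tab <- sample_true(w, n = 20, seed = 1)
#' table(tab$label)
#' @export
sample_true <- function(field, n, seed = 1L, years = NULL) {
  if (inherits(field, "sim_world")) field <- field$field
  stopifnot(inherits(field, "occurrence_field"))
  years <- years %||% field$grid$years
  cells <- cell_year_index(field, years)
  if (n > nrow(cells))
    stop("n = ", n, " exceeds the ", nrow(cells), " available cell-years")
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n), ]
  lab <- field$occurrence[cbind(pick$ix, pick$iy, pick$it)]
  df <- table_from_cells(field, pick, lab, ifelse(lab == 0, "true", "none"))
  new_occurrence_table(df, mode = "true", seed = seed)
}

#' Sample presences plus random pseudo-absences
#'
#' Emulates presence-only data: `n / 2` presences are sampled from cells
#' where the species occurred, and `n / 2` pseudo-absences are placed at
#' uniformly random cell-years regardless of the true state (so a
#' pseudo-absence may fall on an occupied cell -- that contamination is the
#' point of the sensitivity analysis). Presences and pseudo-absences are
#' balanced 1:1 by construction.
#'
#' @inheritParams sample_true
#' @return an `occurrence_table`; pseudo rows have `label = 0` and
#'   `absence_kind = "pseudo"`.
#' @export
sample_pseudo <- function(field, n, seed = 1L, years = NULL) {
  if (inherits(field, "sim_world")) field <- field$field
  stopifnot(inherits(field, "occurrence_field"))
  if (n %% 2 != 0) stop("`n` must be even for 1:1 presence:pseudo-absence balance")
  years <- years %||% field$grid$years
  cells <- cell_year_index(field, years)
  occ <- field$occurrence[cbind(cells$ix, cells$iy, cells$it)]
  pres_pool <- which(occ == 1)
  half <- n / 2
  if (length(pres_pool) < half)
    stop("insufficient presences: need ", half, " presence cell-years, found ",
         length(pres_pool))
  set.seed(seed)
  pres <- cells[sample(pres_pool, half), ]
  pseudo <- cells[sample.int(nrow(cells), half), ]
  df <- rbind(table_from_cells(field, pres, 1L, "none"),
              table_from_cells(field, pseudo, 0L, "pseudo"))
  rownames(df) <- NULL
  new_occurrence_table(df, mode = "pseudo", seed = seed)
}

#' Replicate sampling
#'
#' Draws `R` observation tables with distinct derived seeds, restricted to
#' training years when holdout years are configured.
#'
#' @inheritParams sample_true
#' @param R number of replicates.
#' @param mode `"true"` for presence/absence, `"pseudo"` for presences plus
#'   random pseudo-absences.
#' @param base_seed integer seed from which per-replicate seeds are derived.
#' @param holdout_years years excluded from sampling (e.g. `c(18, 19, 20)`
#'   for temporal extrapolation); `NULL` for none.
#' @return a list of `R` `occurrence_table`s.
#' @export
make_replicates <- function(field, n, R, mode = c("true", "pseudo"),
                            base_seed = 1L, holdout_years = NULL) {
  if (inherits(field, "sim_world")) field <- field$field
  mode <- match.arg(mode)
  stopifnot(R >= 1)
  years <- setdiff(field$grid$years, holdout_years)
  sampler <- if (mode == "true") sample_true else sample_pseudo
  lapply(seq_len(R), function(r) {
    tab <- sampler(field, n, seed = derive_seed(base_seed, r), years = years)
    attr(tab, "replicate_id") <- r
    tab
  })
}

#' Read / write occurrence tables
#'
#' CSV round trip for occurrence records. `read_occurrences` requires
#' columns `x`, `y`, `year`, `label`; `absence_kind` is filled with
#' `"none"`/`"true"` when missing.
#'
#' @param table an `occurrence_table` or plain data frame.
#' @param path CSV path.
#' @return `read_occurrences` returns an `occurrence_table`.
#' @export
write_occurrences <- function(table, path) {
  keep <- intersect(c("x", "y", "year", "label", "absence_kind"), names(table))
  write.csv(as.data.frame(table)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- read.csv(path)
  need <- c("x", "y", "year", "label")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns ", paste(need, collapse = ", "))
  if (!all(df$label %in% c(0, 1))) stop("labels must be binary")
  if (is.null(df$absence_kind))
    df$absence_kind <- ifelse(df$label == 0, "true", "none")
  new_occurrence_table(df, mode = "file", seed = NA_integer_)
}
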