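#' Leave-one-out compatibility screening
#'
#' Removes one candidate at a time (by default all series sharing a
#' specimen id, since femur and tibia of one individual stand or fall
#' together), re-derives the requested dataset variants, refits, rebuilds
#' the simultaneous confidence band, and tabulates the band area per length
#' for each variant plus the row total. The removal that minimizes the
#' total identifies the least compatible series. Removals that disconnect
#' the circumference-overlap graph are marked unusable rather than silently
#' dropped. When the variants of a reduced dataset are identical (no
#' flagged marks), the fit and band are computed once and shared.
#'
#' @param series list of [growth_series] (the full, variant-A source).
#' @param registry model registry used for per-variant selection.
#' @param B bootstrap resamples per band.
#' @param seed integer seed.
#' @param by `"specimen"` (joint removal of all elements of an individual)
#'   or `"series"`.
#' @param variants variant labels to include.
#' @param exclude candidate ids already removed in earlier rounds.
#' @param level band confidence level.
#' @param ... passed to [joint_fit()] via [select_model()].
#' @return object of class `compatibility_table`: data.frame with one row
#'   per candidate removal, per-variant `area_per_length`, `total` and
#'   `usable`; attribute `minimizing_row` holds the minimizing candidate.
#' @export
leave_one_out <- function(series, registry = model_registry(include_diagnostics = FALSE),
                          B = 256L, seed = 1L, by = c("specimen", "series"),
                          variants = variant_labels, exclude = character(0),
                          level = 0.95, ...) {
  by <- match.arg(by)
  ids <- vapply(series, function(s)
    if (by == "specimen") s$specimen_id else series_key(s), character(1))
  series <- series[!ids %in% exclude]
  ids <- ids[!ids %in% exclude]
  candidates <- unique(ids)
  if (length(candidates) < 4)
    stop("leave-one-out needs at least 4 removable candidates")

  rows <- lapply(candidates, function(cand) {
    keep <- series[ids != cand]
    vals <- stats::setNames(rep(NA_real_, length(variants)), variants)
    usable <- TRUE
    cache <- list()
    for (v in variants) {
      res <- tryCatch({
        ds <- pool_dataset(keep, v)
        sig <- paste(dataset_uids(ds), collapse = ";")
        if (is.null(cache[[sig]])) {
          fit <- select_model(ds, registry = registry, seed = seed, ...)
          band <- simultaneous_band(frw_bootstrap(fit, B = B, seed = seed),
                                    level = level)
          cache[[sig]] <- band$area_per_length
        }
        cache[[sig]]
      }, error = function(e) NA_real_)
      if (is.na(res)) usable <- FALSE
      vals[v] <- res
    }
    c(list(removed = cand, usable = usable), as.list(vals),
      list(total = if (usable) sum(vals) else NA_real_))
  })
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  ok <- which(tab$usable & !is.na(tab$total))
  attr(tab, "minimizing_row") <-
    if (length(ok)) tab$removed[ok[which.min(tab$total[ok])]] else NA_character_
  class(tab) <- c("compatibility_table", class(tab))
  tab
}

#' @export
print.compatibility_table <- function(x, ...) {
  NextMethod()
  cat("minimizing removal:", attr(x, "minimizing_row"), "\n")
  invisible(x)
}

#' Synthetic linear-series compatibility probe
#'
#' Appends one idealized linear growth series (constant slope, no flags) to
#' the dataset at a time, refits and re-bands, and records the confidence
#' band area and area per length as a function of the probe slope. The
#' argmin slopes identify the constant growth rate most compatible with the
#' dataset.
#'
#' @param series list of [growth_series].
#' @param start_circumference probe starting circumference (mm).
#' @param n_cgm number of probe marks (>= 3).
#' @param slopes positive slopes to scan (mm/yr).
#' @param variant variant label under which to fit.
#' @param registry model registry.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param ... passed to [joint_fit()].
#' @return data.frame with `slope`, `area`, `area_per_length`; attributes
#'   `argmin_area` and `argmin_area_per_length`.
#' @export
linear_probe <- function(series, start_circumference, n_cgm, slopes,
                         variant = "A",
                         registry = model_registry(include_diagnostics = FALSE),
                         B = 256L, seed = 1L, ...) {
  stopifnot(all(slopes > 0), n_cgm >= 3)
  base_range <- range(unlist(lapply(series, function(s)
    s$records$circumference[s$records$measured])))
  out <- lapply(slopes, function(sl) {
    probe <- make_linear_outlier(start_circumference, sl, n_cgm,
                                 specimen_id = "synthetic-probe")
    pr <- probe$records$circumference
    if (max(pr) < base_range[1] || min(pr) > base_range[2])
      warning("probe series at slope ", sl,
              " lies entirely outside the dataset circumference range")
    ds <- pool_dataset(c(series, list(probe)), variant)
    fit <- select_model(ds, registry = registry, seed = seed, ...)
    band <- simultaneous_band(frw_bootstrap(fit, B = B, seed = seed))
    data.frame(slope = sl, area = band$area,
               area_per_length = band$area_per_length)
  })
  tab <- do.call(rbind, out)
  attr(tab, "argmin_area") <- tab$slope[which.min(tab$area)]
  attr(tab, "argmin_area_per_length") <-
    tab$slope[which.min(tab$area_per_length)]
  tab
}

#' Growth rate as a function of size
#'
#' Samples the fitted curve parametrically as (size, growth rate) pairs over
#' the band grid, the representation in which constant-slope series plot as
#' horizontal lines.
#'
#' @param fit a `cgm_fit`.
#' @param n_grid grid size.
#' @return data.frame with `age`, `circumference`, `rate`.
#' @export
rate_vs_size <- function(fit, n_grid = 512L) {
  ages <- fit_age_grid(fit, n_grid)$ages
  data.frame(age = ages,
             circumference = fit$model_obj$evaluate(fit$params, ages),
             rate = fit$model_obj$derivative(fit$params, ages))
}

#' Mean circumference growth rate of one series
#'
#' Ordinary least-squares slope of circumference against CGM count, the
#' simple per-series summary used to compare specimens against the probe
#' slopes.
#'
#' @param series a [growth_series].
#' @return slope in mm per year.
#' @export
mean_slope <- function(series) {
  r <- series$records[series$records$measured, ]
  if (nrow(r) < 2) stop("mean slope needs at least 2 measured records")
  unname(stats::coef(stats::lm(circumference ~ cgmc, data = r))[2])
}
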