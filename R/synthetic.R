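#' Configuration for the synthetic CGM generator
#'
#' Declares the generative world the estimators assume: a shared population
#' sigmoid; one mark per year of life; per-specimen inner-mark erasure by
#' medullary expansion (producing the relative start ages the pipeline must
#' recover); truncation at death; occasional multi-year runs of depressed
#' growth whose marks are labelled as one multiplet group; faint marks
#' flagged as XPL-only; additive Gaussian measurement noise; and optional
#' slow-growing linear outlier specimens.
#'
#' Defaults describe a mid-sized dataset of the kind the pipeline targets:
#' 8 specimens dying between 8 and 30 years, ~150 measured marks in total,
#' mean 3 erased inner marks, 10 mm noise (a few percent of mid-growth
#' circumference), 5 % annual chance of entering a 2-4 yr bad-year run with
#' increments scaled by 0.2, and 5 % faint-mark probability.
#'
#' @param model sigmoid name from [model_registry()].
#' @param params true parameter vector (a mm, b yr, c yr).
#' @param n_specimens number of specimens.
#' @param death_age integer range (years) of uniform death ages.
#' @param erasure_mean Poisson mean of erased inner marks per specimen.
#' @param noise_sd additive Gaussian noise on circumference (mm).
#' @param multiplet_prob per-year probability of entering a bad-year run.
#' @param multiplet_run integer range of run lengths (years).
#' @param multiplet_factor increment multiplier inside a run, in (0, 0.25].
#' @param xpl_prob per-mark probability of the XPL-only flag.
#' @param xpl_in_runs if TRUE, XPL flags may also fall on run members
#'   (flag-overlap knob); independent assignment either way.
#' @param world `"annual"` (each bad-year mark is a real year; the A
#'   variant is the true reading) or `"single_year"` (a run's marks all
#'   form within one year; the NoM variant is the true reading).
#' @param outliers optional list(count, slope, start_circumference, n_cgm)
#'   of linear outlier specimens to append.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(model = "logistic3",
                             params = c(a = 500, b = 15, c = 4),
                             n_specimens = 8L,
                             death_age = c(8L, 30L),
                             erasure_mean = 3,
                             noise_sd = 10,
                             multiplet_prob = 0.05,
                             multiplet_run = c(2L, 4L),
                             multiplet_factor = 0.2,
                             xpl_prob = 0.05,
                             xpl_in_runs = FALSE,
                             world = c("annual", "single_year"),
                             outliers = NULL,
                             seed = 1L) {
  world <- match.arg(world)
  stopifnot(multiplet_factor > 0, multiplet_factor <= 0.25,
            n_specimens >= 2, death_age[1] <= death_age[2])
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic CGM dataset with ground truth
#'
#' Per specimen: annual true sizes follow the configured sigmoid, with
#' bad-year runs shrinking the annual increments (sizes thereafter stay
#' permanently below the nominal curve, as befits genuinely lost growth);
#' one mark per year up to the death age; the first few marks are erased
#' (Poisson), so the emitted counts restart at 1 and the erased count is
#' the specimen's true start-age offset; Gaussian noise is added and
#' monotonicity restored by a running maximum. In the `single_year` world a
#' bad run's marks all belong to one calendar year instead.
#'
#' @param config a [synthetic_config].
#' @return list with `series` (list of [growth_series]) and `truth`
#'   (config echo plus per-specimen death ages, erased counts, per-mark
#'   flags and the true sigmoid).
#' @export
generate_cgm_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  model <- model_registry(config$model)[[1]]
  f <- function(t) model$evaluate(config$params, t)

  specs <- vector("list", config$n_specimens)
  truth <- vector("list", config$n_specimens)
  for (s in seq_len(config$n_specimens)) {
    death <- sample(seq(config$death_age[1], config$death_age[2]), 1)
    # annual bad-year process: entering a run freezes re-entry until it ends
    run_left <- 0L
    bad <- logical(death); run_id <- integer(death)
    run_counter <- 0L
    for (y in seq_len(death)) {
      if (run_left > 0L) {
        bad[y] <- TRUE; run_id[y] <- run_counter
        run_left <- run_left - 1L
      } else if (stats::runif(1) < config$multiplet_prob && y > 1) {
        run_counter <- run_counter + 1L
        run_left <- sample(seq(config$multiplet_run[1],
                               config$multiplet_run[2]), 1) - 1L
        bad[y] <- TRUE; run_id[y] <- run_counter
      }
    }
    year <- seq_len(death)
    inc <- diff(c(0, f(year)))
    inc[bad] <- inc[bad] * config$multiplet_factor
    size <- cumsum(inc)

    if (config$world == "single_year") {
      # all marks of a run form within one calendar year: continuation
      # marks of a run do not advance true age
      continuation <- bad & run_id > 0 & duplicated(run_id)
      true_age <- year - cumsum(continuation)
    } else {
      true_age <- year
    }

    erased <- stats::rpois(1, config$erasure_mean)
    erased <- min(erased, death - 2L)  # keep at least 2 marks
    keep <- year > erased
    xpl <- stats::runif(death) < config$xpl_prob
    if (!config$xpl_in_runs) xpl[bad] <- FALSE

    circ <- size + stats::rnorm(death, 0, config$noise_sd)
    if (is.unsorted(circ)) {
      # least-squares monotone (isotonic) repair: perimeters cannot shrink,
      # and unlike a running maximum this adds no systematic upward bias
      circ <- stats::isoreg(circ)$yf
    }
    circ <- pmax(circ, 1e-3)

    sid <- sprintf("SYN-%03d", s)
    grp <- ifelse(bad, sprintf("%s-run%02d", sid, run_id), NA_character_)
    rec <- data.frame(
      cgmc = year[keep] - erased,
      circumference = circ[keep],
      measured = TRUE,
      xpl_only = xpl[keep],
      multiplet_group = grp[keep],
      stringsAsFactors = FALSE)
    specs[[s]] <- growth_series(sid, "tibia", rec, taxon_label = "synthetic")
    truth[[s]] <- list(specimen_id = sid, death_age = death,
                       erased = erased, true_ages = true_age[keep],
                       bad_years = bad[keep], xpl = xpl[keep])
  }

  if (!is.null(config$outliers) && config$outliers$count > 0) {
    for (o in seq_len(config$outliers$count)) {
      sid <- sprintf("SYN-OUT-%02d", o)
      specs[[length(specs) + 1]] <- make_linear_outlier(
        config$outliers$start_circumference, config$outliers$slope,
        config$outliers$n_cgm, specimen_id = sid)
      truth[[length(truth) + 1]] <- list(specimen_id = sid, outlier = TRUE)
    }
  }

  list(series = specs,
       truth = list(config = config, model = config$model,
                    params = config$params, specimens = truth))
}

#' Construct an idealized linear growth series
#'
#' Circumference `start_circ + slope * (i - 1)` at marks `i = 1..n_cgm`,
#' with no annotation flags (so the series is identical across variants).
#'
#' @param start_circ starting circumference (mm, > 0).
#' @param slope growth rate (mm/yr, > 0).
#' @param n_cgm number of marks (>= 2).
#' @param specimen_id identifier for the generated series.
#' @param element skeletal element label.
#' @return a [growth_series].
#' @export
make_linear_outlier <- function(start_circ, slope, n_cgm,
                                specimen_id = "synthetic-linear",
                                element = "tibia") {
  stopifnot(start_circ > 0, slope > 0, n_cgm >= 2)
  growth_series(
    specimen_id, element,
    data.frame(cgmc = seq_len(n_cgm),
               circumference = start_circ + slope * (seq_len(n_cgm) - 1)),
    taxon_label = "synthetic")
}

#' Write a synthetic dataset with its truth record
#'
#' Emits the standard series table plus a JSON truth sidecar.
#'
#' @param generated result of [generate_cgm_dataset()].
#' @param table_path CSV path for the series table.
#' @param truth_path JSON path for the truth record.
#' @export
write_synthetic_dataset <- function(generated, table_path, truth_path) {
  write_series_table(generated$series, table_path)
  tr <- generated$truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(generated)
}
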