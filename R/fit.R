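#' Corrected Akaike information criterion for a least-squares fit
#'
#' Uses the Gaussian likelihood with plug-in variance `rss / n`, constants
#' included, and the small-sample correction term. The error variance is not
#' counted in `k`: for a joint fit `k = p + (M - 1)` where `p` is the model
#' parameter count and `M` the number of series.
#'
#' @param rss residual sum of squares on the fitting scale.
#' @param n number of fitted points.
#' @param k number of estimated parameters.
#' @return AICc score (smaller is better).
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  if (rss <= 0) return(-Inf)
  2 * k + n * (log(2 * pi * rss / n) + 1) + (2 * k^2 + 2 * k) / (n - k - 1)
}

# flatten the measured points of a dataset into one fitting table
dataset_points <- function(dataset) {
  do.call(rbind, lapply(seq_along(dataset$series), function(j) {
    s <- dataset$series[[j]]
    r <- s$records[s$records$measured, ]
    data.frame(series = series_key(s), j = j, uid = r$uid,
               cgmc = r$cgmc, circumference = r$circumference,
               stringsAsFactors = FALSE)
  }))
}

#' Jointly fit a growth model and per-series start ages
#'
#' Minimizes the composite least-squares objective
#' `sum_j sum_i (f(params, cgmc_ij + start_j) - circ_ij)^2` over the model
#' parameters and the start ages simultaneously, with the reference series'
#' start fixed at 0. Optimization is Levenberg-Marquardt on the residual
#' vector ([minpack.lm::nls.lm]) from the supplied initialization plus
#' jittered restarts (starts +/- 2 yr uniform, parameters +/- 10 %
#' log-uniform), keeping the best converged solution. On the log scale the
#' circumferences are natural-log transformed first and residuals are
#' reported in log units.
#'
#' @param dataset a `variant_dataset`.
#' @param model a [growth_model] (or a name resolvable by [model_registry]).
#' @param init a `start_assignment` from [cluster_starts()]; computed when
#'   NULL.
#' @param scale `"arithmetic"` or `"log"`.
#' @param seed integer seed fixing the restart jitter.
#' @param restarts number of jittered restarts beyond the plain start.
#' @param freeze_starts if TRUE the starts are held at `init` and only the
#'   model parameters are fitted (the conventional two-step estimator).
#' @param integer_starts if TRUE starts are rounded to whole years after the
#'   continuous fit and model parameters refitted with starts frozen.
#' @param weights optional per-observation non-negative weights applied to
#'   the squared residuals (the fractional-random-weight bootstrap supplies
#'   unit-mean exponential draws here); reported `rss` and `aicc` stay
#'   unweighted.
#' @param param_init optional named starting parameter vector overriding the
#'   model's own initializer (bootstrap refits restart from the base
#'   solution).
#' @return object of class `cgm_fit`.
#' @export
joint_fit <- function(dataset, model, init = NULL,
                      scale = c("arithmetic", "log"), seed = 1L,
                      restarts = 8L, freeze_starts = FALSE,
                      integer_starts = FALSE, weights = NULL,
                      param_init = NULL) {
  scale <- match.arg(scale)
  if (is.character(model)) model <- model_registry(model)[[1]]
  stopifnot(inherits(model, "growth_model"), inherits(dataset, "variant_dataset"))
  if (scale == "log" && !model$log_form)
    stop("model ", model$name, " has no log form")
  pts <- dataset_points(dataset)
  M <- length(dataset$series)
  k_chk <- model$n_params + (M - 1)
  if (nrow(pts) < k_chk + 2)
    stop("underdetermined fit: need n >= k + 2 (n = ", nrow(pts),
         ", k = ", k_chk, ")")
  if (is.null(init) && M > 1) init <- cluster_starts(dataset)
  keys <- vapply(dataset$series, series_key, character(1))
  if (M > 1) {
    start0 <- init$starts[keys]
    ref_key <- init$reference_series
  } else {
    start0 <- stats::setNames(0, keys)
    ref_key <- keys
  }
  free_keys <- setdiff(keys, ref_key)

  k <- model$n_params + (M - 1)
  n <- nrow(pts)
  if (n < k + 2)
    stop("underdetermined fit: need n >= k + 2 (n = ", n, ", k = ", k, ")")

  obs <- if (scale == "log") log(pts$circumference) else pts$circumference
  predict_at <- function(params, ages) {
    f <- model$evaluate(params, ages)
    if (scale == "log") log(pmax(f, 1e-9)) else f
  }
  ages_of <- function(starts) pts$cgmc + starts[pts$series]

  # initial model parameters from the clustered composite series
  ages_init <- ages_of(start0)
  sizes_init <- pts$circumference
  p0 <- if (is.null(param_init)) model$init(ages_init, sizes_init)
        else param_init
  pn <- names(p0)

  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  sw <- sqrt(weights)
  resid_fun <- function(theta) {
    params <- stats::setNames(theta[seq_along(p0)], pn)
    starts <- start0
    if (!freeze_starts && length(free_keys))
      starts[free_keys] <- theta[-seq_along(p0)]
    r <- sw * (predict_at(params, ages_of(starts)) - obs)
    r[!is.finite(r)] <- 1e6
    r
  }
  theta0 <- if (freeze_starts) unname(p0) else
    c(unname(p0), unname(start0[free_keys]))

  run_lm <- function(theta) {
    tryCatch(
      minpack.lm::nls.lm(par = theta, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }

  set.seed(seed)
  cand <- list(theta0)
  for (r in seq_len(restarts)) {
    th <- theta0
    np <- length(p0)
    th[seq_len(np)] <- th[seq_len(np)] *
      exp(stats::runif(np, log(0.9), log(1.1)))
    if (!freeze_starts && length(free_keys))
      th[-seq_len(np)] <- th[-seq_len(np)] +
        stats::runif(length(free_keys), -2, 2)
    cand[[r + 1]] <- th
  }
  fits <- lapply(cand, run_lm)
  rss_of <- function(f) if (is.null(f)) Inf else sum(f$fvec^2)
  best <- fits[[which.min(vapply(fits, rss_of, numeric(1)))]]
  if (is.null(best))
    stop("optimizer failed to converge for model ", model$name)

  params <- stats::setNames(best$par[seq_along(p0)], pn)
  starts <- start0
  if (!freeze_starts && length(free_keys))
    starts[free_keys] <- best$par[-seq_along(p0)]

  if (integer_starts && length(free_keys)) {
    starts[free_keys] <- round(starts[free_keys])
    sub <- joint_fit(dataset, model,
                     init = structure(list(starts = starts,
                                           reference_series = ref_key),
                                      class = "start_assignment"),
                     scale = scale, seed = seed, restarts = restarts,
                     freeze_starts = TRUE)
    sub$starts <- starts
    sub$k <- k
    sub$aicc <- aicc(sub$rss, sub$n, k)
    sub$integer_starts <- TRUE
    return(sub)
  }

  ages <- ages_of(starts)
  pred <- predict_at(params, ages)
  res <- pred - obs
  rss <- sum(res^2)
  pred_raw <- if (scale == "log") exp(pred) else pred
  structure(
    list(model = model$name, model_obj = model, params = params,
         starts = starts, reference_series = ref_key, scale = scale,
         rss = rss, n = n, k = k, aicc = aicc(rss, n, k),
         residuals = data.frame(
           uid = pts$uid, series = pts$series, age = ages,
           observed = pts$circumference, predicted = pred_raw,
           raw = pred - obs,
           percent = 100 * (pts$circumference - pred_raw) / pred_raw,
           stringsAsFactors = FALSE),
         dataset = dataset, seed = seed, integer_starts = FALSE,
         converged = !is.null(best$info) && best$info %in% 1:4),
    class = "cgm_fit")
}

#' @export
print.cgm_fit <- function(x, ...) {
  cat(sprintf("<cgm_fit> %s (%s scale): n = %d, k = %d, rss = %.4g, AICc = %.2f\n",
              x$model, x$scale, x$n, x$k, x$rss, x$aicc))
  cat("params:\n"); print(round(x$params, 4))
  cat("starts (yr, reference", x$reference_series, "= 0):\n")
  print(round(x$starts, 2))
  invisible(x)
}

#' Age extent and grid of a fit
#'
#' The pooled relative-age extent spanned by the fitted points, and an
#' evenly spaced evaluation grid over it.
#'
#' @param fit a `cgm_fit`.
#' @param n_grid grid size.
#' @return list with `extent` (length-2) and `ages` (numeric grid).
#' @export
fit_age_grid <- function(fit, n_grid = 512) {
  extent <- range(fit$residuals$age)
  list(extent = extent,
       ages = seq(extent[1], extent[2], length.out = n_grid))
}

#' Fit every candidate model and select by AICc
#'
#' @param dataset a `variant_dataset`.
#' @param registry named list of [growth_model]s (default: the nine sigmoids).
#' @param init optional `start_assignment` initialization.
#' @param scale `"arithmetic"` or `"log"`.
#' @param seed integer seed.
#' @param ... further arguments to [joint_fit()].
#' @return the minimum-AICc `cgm_fit`, with a `ranking` data.frame attached
#'   (model, rss, aicc, delta_aicc, converged) and `all_fits` holding every
#'   successful fit.
#' @export
select_model <- function(dataset, registry = model_registry(include_diagnostics = FALSE),
                         init = NULL, scale = "arithmetic", seed = 1L, ...) {
  if (inherits(registry, "growth_model")) registry <- list(registry)
  stopifnot(length(registry) >= 1)
  if (is.null(init) && length(dataset$series) > 1)
    init <- cluster_starts(dataset)
  fits <- lapply(registry, function(m) {
    if (scale == "log" && !m$log_form) return(NULL)
    tryCatch(joint_fit(dataset, m, init = init, scale = scale,
                       seed = seed, ...),
             error = function(e) e)
  })
  ok <- vapply(fits, inherits, logical(1), what = "cgm_fit")
  if (!any(ok)) {
    msgs <- vapply(fits, function(f)
      if (inherits(f, "error")) conditionMessage(f) else "skipped",
      character(1))
    stop("all candidate models failed:\n",
         paste(names(registry), msgs, sep = ": ", collapse = "\n"))
  }
  good <- fits[ok]
  scores <- vapply(good, function(f) f$aicc, numeric(1))
  best <- good[[which.min(scores)]]
  best$ranking <- data.frame(
    model = vapply(good, function(f) f$model, character(1)),
    rss = vapply(good, function(f) f$rss, numeric(1)),
    aicc = scores, delta_aicc = scores - min(scores),
    converged = vapply(good, function(f) f$converged, logical(1)),
    row.names = NULL)
  best$ranking <- best$ranking[order(best$ranking$aicc), ]
  best$failed_models <- names(registry)[!ok]
  best$all_fits <- good
  best
}

#' Empirical quantiles of the percent fit residuals
#'
#' Percent residual of a point is `100 * (observed - predicted) / predicted`.
#'
#' @param fit a `cgm_fit`.
#' @param probs quantile levels (default 2.5 %, 50 %, 97.5 %).
#' @return data.frame with `prob` and `percent_residual`.
#' @export
residual_quantiles <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  q <- stats::quantile(fit$residuals$percent, probs = probs, names = FALSE)
  data.frame(prob = probs, percent_residual = q)
}
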