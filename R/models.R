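#' Candidate growth models
#'
#' A growth model couples a size-at-age function with its analytic first
#' derivative, its upper asymptote, and an initializer that proposes starting
#' parameter values from data. Sigmoids are parameterized as location-scale
#' cumulative distribution functions `a * F((t - b) / c)`: `a` is the
#' asymptotic size (mm for circumference data), `b` a location (years) and
#' `c` a scale (years). Linear and quadratic models are included as
#' diagnostics of the fitting machinery, not as growth hypotheses.
#'
#' @param name model name.
#' @param n_params number of shape parameters (2-4).
#' @param evaluate function(params, t) returning size.
#' @param derivative function(params, t) returning size per year.
#' @param asymptote function(params) returning the upper asymptote
#'   (`NA` for unbounded diagnostics).
#' @param init function(ages, sizes) proposing a starting parameter vector.
#' @param sigmoid logical; TRUE for bounded monotone growth forms.
#' @param log_form logical; whether the model is usable on log-transformed
#'   sizes (all positive-valued models are).
#' @param fragile logical; flags models known to interact poorly with local
#'   optimizers (Richards).
#'
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(name, n_params, evaluate, derivative, asymptote,
                         init, sigmoid = TRUE, log_form = TRUE,
                         fragile = FALSE) {
  stopifnot(is.character(name), n_params >= 1,
            is.function(evaluate), is.function(derivative),
            is.function(asymptote), is.function(init))
  structure(
    list(name = name, n_params = n_params, evaluate = evaluate,
         derivative = derivative, asymptote = asymptote, init = init,
         sigmoid = sigmoid, log_form = log_form, fragile = fragile),
    class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s (p = %d%s)\n", x$name, x$n_params,
              if (x$sigmoid) ", sigmoid" else ", diagnostic"))
  invisible(x)
}

# default (a, b, c) initializer shared by the location-scale sigmoids
abc_init <- function(ages, sizes) {
  c(a = max(sizes) * 1.05,
    b = stats::median(ages),
    c = max(diff(range(ages)) / 4, 1))
}

#' Registry of candidate growth functions
#'
#' Returns the standard model set: nine sigmoids (logistic, Gompertz
#' (Gumbel-max kernel), extreme-value (Gumbel-min kernel), arctangent,
#' Laplace, Gaussian (erfc form), hyperbolic tangent, monomolecular /
#' von Bertalanffy, and a two-parameter monomolecular with the location fixed
#' at zero), plus linear and quadratic diagnostics and the optional
#' four-parameter Richards model (flagged fragile).
#'
#' @param names optional character vector restricting the registry.
#' @param include_diagnostics include the linear/quadratic diagnostics
#'   (default TRUE).
#' @param include_richards include the Richards model (default FALSE).
#' @return named list of [growth_model] objects.
#' @export
model_registry <- function(names = NULL, include_diagnostics = TRUE,
                           include_richards = FALSE) {
  z <- function(p, t) (t - p[["b"]]) / p[["c"]]

  reg <- list(
    logistic3 = growth_model(
      "logistic3", 3,
      evaluate   = function(p, t) p[["a"]] * stats::plogis(z(p, t)),
      derivative = function(p, t) p[["a"]] * stats::dlogis(z(p, t)) / p[["c"]],
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    gompertz3 = growth_model(
      "gompertz3", 3,
      evaluate   = function(p, t) p[["a"]] * exp(-exp(-z(p, t))),
      derivative = function(p, t) {
        u <- exp(-z(p, t))
        p[["a"]] * u * exp(-u) / p[["c"]]
      },
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    extreme_value3 = growth_model(
      "extreme_value3", 3,
      evaluate   = function(p, t) p[["a"]] * (1 - exp(-exp(z(p, t)))),
      derivative = function(p, t) {
        u <- exp(z(p, t))
        p[["a"]] * u * exp(-u) / p[["c"]]
      },
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    arctan3 = growth_model(
      "arctan3", 3,
      evaluate   = function(p, t) p[["a"]] * (0.5 + atan(z(p, t)) / pi),
      derivative = function(p, t)
        p[["a"]] / (pi * p[["c"]] * (1 + z(p, t)^2)),
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    laplace3 = growth_model(
      "laplace3", 3,
      evaluate   = function(p, t) {
        u <- z(p, t)
        p[["a"]] * ifelse(u < 0, 0.5 * exp(u), 1 - 0.5 * exp(-u))
      },
      derivative = function(p, t)
        p[["a"]] * 0.5 * exp(-abs(z(p, t))) / p[["c"]],
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    gaussian3 = growth_model(
      "gaussian3", 3,
      evaluate   = function(p, t) p[["a"]] * stats::pnorm(z(p, t)),
      derivative = function(p, t) p[["a"]] * stats::dnorm(z(p, t)) / p[["c"]],
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    tanh3 = growth_model(
      "tanh3", 3,
      evaluate   = function(p, t) p[["a"]] * 0.5 * (1 + tanh(z(p, t))),
      derivative = function(p, t)
        p[["a"]] * 0.5 / (p[["c"]] * cosh(z(p, t))^2),
      asymptote  = function(p) p[["a"]],
      init = abc_init),
    monomolecular3 = growth_model(
      "monomolecular3", 3,
      # bounded above by a; drops below zero for t < b, so the inflection
      # (maximum rate) sits on the lower window edge
      evaluate   = function(p, t) p[["a"]] * (1 - exp(-z(p, t))),
      derivative = function(p, t) p[["a"]] * exp(-z(p, t)) / p[["c"]],
      asymptote  = function(p) p[["a"]],
      init = function(ages, sizes)
        c(a = max(sizes) * 1.1, b = min(ages) - 1,
          c = max(diff(range(ages)) / 2, 1))),
    monomolecular2 = growth_model(
      "monomolecular2", 2,
      evaluate   = function(p, t) p[["a"]] * (1 - exp(-t / p[["c"]])),
      derivative = function(p, t) p[["a"]] * exp(-t / p[["c"]]) / p[["c"]],
      asymptote  = function(p) p[["a"]],
      init = function(ages, sizes)
        c(a = max(sizes) * 1.1, c = max(diff(range(ages)) / 2, 1))),
    linear2 = growth_model(
      "linear2", 2,
      evaluate   = function(p, t) p[["a"]] + p[["b"]] * t,
      derivative = function(p, t) rep(p[["b"]], length(t)),
      asymptote  = function(p) NA_real_,
      init = function(ages, sizes) {
        cf <- stats::coef(stats::lm(sizes ~ ages))
        c(a = unname(cf[1]), b = unname(cf[2]))
      },
      sigmoid = FALSE, log_form = FALSE),
    quadratic3 = growth_model(
      "quadratic3", 3,
      evaluate   = function(p, t) p[["a"]] + p[["b"]] * t + p[["c"]] * t^2,
      derivative = function(p, t) p[["b"]] + 2 * p[["c"]] * t,
      asymptote  = function(p) NA_real_,
      init = function(ages, sizes) {
        cf <- stats::coef(stats::lm(sizes ~ ages + I(ages^2)))
        c(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]))
      },
      sigmoid = FALSE, log_form = FALSE)
  )

  if (include_richards) {
    reg$richards4 <- growth_model(
      "richards4", 4,
      evaluate   = function(p, t)
        p[["a"]] * (1 + p[["d"]] * exp(-(t - p[["b"]]) / p[["c"]]))^(-1 / p[["d"]]),
      derivative = function(p, t) {
        u <- exp(-(t - p[["b"]]) / p[["c"]])
        p[["a"]] * u * (1 + p[["d"]] * u)^(-1 / p[["d"]] - 1) / p[["c"]]
      },
      asymptote  = function(p) p[["a"]],
      init = function(ages, sizes) c(abc_init(ages, sizes), d = 1),
      fragile = TRUE)
  }
  if (!include_diagnostics)
    reg <- reg[vapply(reg, function(m) m$sigmoid, logical(1))]
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(reg))
    if (length(missing))
      stop("unknown model(s): ", paste(missing, collapse = ", "))
    reg <- reg[names]
  }
  reg
}

#' Age of maximum growth rate (inflection age)
#'
#' Locates the age at which the first derivative of `transform(evaluate(t))`
#' is maximal over a stated window, by dense grid search refined by
#' golden-section. When the maximum lies on a window edge the result is
#' marked as a boundary (the monomolecular family, and all percentage-rate
#' metrics, have boundary inflections).
#'
#' @param model a [growth_model].
#' @param params named parameter vector valid for `model`.
#' @param window numeric length-2 age window (years).
#' @param transform optional monotone transform of size applied before
#'   differentiating (e.g. circumference-to-mass); identity when NULL.
#' @param n_grid grid resolution (default 2048).
#' @return list with `age`, `rate` (derivative of the transformed curve at
#'   that age) and `boundary` (`"none"`, `"lower"` or `"upper"`).
#' @export
inflection_age <- function(model, params, window, transform = NULL,
                           n_grid = 2048) {
  stopifnot(inherits(model, "growth_model"), length(window) == 2)
  if (any(!is.finite(params))) stop("non-finite parameters")
  window <- sort(as.numeric(window))

  rate <- if (is.null(transform)) {
    function(t) model$derivative(params, t)
  } else {
    # chain rule via a tight central difference on the transform
    function(t) {
      s <- model$evaluate(params, t)
      h <- pmax(abs(s), 1) * 1e-6
      (transform(s + h) - transform(s - h)) / (2 * h) *
        model$derivative(params, t)
    }
  }

  grid <- seq(window[1], window[2], length.out = n_grid)
  r <- rate(grid)
  i <- which.max(r)
  if (i == 1 || i == n_grid) {
    return(list(age = grid[i], rate = r[i],
                boundary = if (i == 1) "lower" else "upper"))
  }
  opt <- stats::optimize(rate, lower = grid[i - 1], upper = grid[i + 1],
                         maximum = TRUE, tol = 1e-9)
  list(age = opt$maximum, rate = opt$objective, boundary = "none")
}
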