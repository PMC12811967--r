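#' Published circumference-body mass pairs for bipedal dinosaurs
#'
#' Femoral/tibial circumference (mm) and the body masses (kg) published for
#' tyrannosaurid specimens and fitted-curve points under the Campione &
#' Evans bipedal stylopodial scaling. Used to back-calibrate the power-law
#' conversion by log-log regression and to validate it.
#'
#' @return data.frame with `circumference_mm` and `mass_kg`.
#' @export
mass_calibration_pairs <- function() {
  data.frame(
    circumference_mm = c(71.83, 574, 546.3, 338.7, 312.5, 197.3, 399.4,
                         291.7, 166.1, 393.1, 332, 292.5, 369.7, 321.5,
                         261.8, 395.4),
    mass_kg = c(26.9, 8222, 7175, 1922, 1541.4, 434.5, 3029.5,
                1274.9, 270.4, 2898.4, 1821.1, 1284.5, 2447.6, 1666.7,
                946.7, 2945.5))
}

#' Calibrate the circumference-to-mass power law
#'
#' Ordinary least squares on `log10(mass in g) ~ log10(circumference in mm)`
#' over a table of published pairs. With the full published set this
#' reproduces the bipedal stylopodial coefficients (slope 2.754, intercept
#' -0.683 on the log10-gram scale).
#'
#' @param pairs data.frame with `circumference_mm`, `mass_kg`; defaults to
#'   [mass_calibration_pairs()].
#' @return object of class `mass_conversion` with `exponent` and
#'   `intercept` (log10 grams).
#' @export
calibrate_mass_conversion <- function(pairs = mass_calibration_pairs()) {
  stopifnot(nrow(pairs) >= 3)
  fit <- stats::lm(log10(mass_kg * 1000) ~ log10(circumference_mm),
                   data = pairs)
  cf <- unname(stats::coef(fit))
  structure(list(exponent = cf[2], intercept = cf[1]),
            class = "mass_conversion")
}

#' Default circumference-to-mass conversion
#'
#' The bipedal stylopodial power law with fixed coefficients
#' (exponent 2.754, intercept -0.683 on the log10-gram scale), which
#' [calibrate_mass_conversion()] recovers from the published pairs.
#'
#' @return a `mass_conversion`.
#' @export
mass_conversion <- function() {
  structure(list(exponent = 2.754, intercept = -0.683),
            class = "mass_conversion")
}

#' @export
print.mass_conversion <- function(x, ...) {
  cat(sprintf("<mass_conversion> mass(g) = 10^(%.4f log10(circ mm) %+.4f)\n",
              x$exponent, x$intercept))
  invisible(x)
}

#' Convert limb-bone circumference to body mass
#'
#' @param circumference_mm circumference in millimetres (> 0).
#' @param conversion a `mass_conversion` (default: the fixed bipedal
#'   coefficients).
#' @return body mass in kilograms.
#' @export
circ_to_mass <- function(circumference_mm, conversion = mass_conversion()) {
  if (any(circumference_mm <= 0)) stop("circumference must be positive")
  10^(conversion$exponent * log10(circumference_mm) + conversion$intercept) / 1000
}

#' Convert body mass to limb-bone circumference
#'
#' Inverse of [circ_to_mass()].
#'
#' @param mass_kg body mass in kilograms (> 0).
#' @param conversion a `mass_conversion`.
#' @return circumference in millimetres.
#' @export
mass_to_circ <- function(mass_kg, conversion = mass_conversion()) {
  if (any(mass_kg <= 0)) stop("mass must be positive")
  10^((log10(mass_kg * 1000) - conversion$intercept) / conversion$exponent)
}

#' Confidence-band summary in circumference and mass
#'
#' Reads the band bounds at a stated age (by default the age at which the
#' band is widest), converts them to body mass, and reports the high/low
#' ratios on both scales.
#'
#' @param band a `confidence_band` on the arithmetic circumference scale.
#' @param at_age age at which to read the band; default: the age of maximum
#'   band extent.
#' @param conversion a `mass_conversion`.
#' @return list with `age`, `circ` (best/low/high), `mass` (best/low/high),
#'   `circ_ratio`, `mass_ratio`.
#' @export
cb_mass_summary <- function(band, at_age = NULL,
                            conversion = mass_conversion()) {
  if (identical(band$scale, "log"))
    stop("cb_mass_summary expects an arithmetic-scale band")
  if (is.null(at_age))
    at_age <- band$ages[which.max(band$upper - band$lower)]
  if (at_age < min(band$ages) || at_age > max(band$ages))
    stop("at_age outside the band grid")
  pick <- function(y) stats::approx(band$ages, y, xout = at_age)$y
  circ <- c(best = pick(band$best), low = pick(band$lower),
            high = pick(band$upper))
  mass <- stats::setNames(circ_to_mass(circ, conversion), names(circ))
  list(age = at_age, circ = circ, mass = mass,
       circ_ratio = unname(circ["high"] / circ["low"]),
       mass_ratio = unname(mass["high"] / mass["low"]))
}

#' Maximum growth rate under four metrics
#'
#' Maximizes the chosen growth-rate metric of a fitted curve over its age
#' window: `circ_abs` (mm/yr, the curve's first derivative), `mass_abs`
#' (kg/yr, derivative of the mass-transformed curve), and their relative
#' counterparts `circ_pct` / `mass_pct` (percent of current level per
#' year). The window floor is the first-CGM relative age; percentage
#' metrics peak on that boundary for sigmoid fits and are reported there.
#'
#' @param fit an arithmetic-scale `cgm_fit`.
#' @param metric one of `"circ_abs"`, `"mass_abs"`, `"circ_pct"`,
#'   `"mass_pct"`.
#' @param conversion a `mass_conversion`.
#' @param window age window; default `[first fitted age, last + 25]` years
#'   (the upper margin accommodates asymptotes beyond the observed record).
#' @return list with `rate` (metric units), `age`, `boundary`.
#' @export
max_growth_rate <- function(fit, metric = c("circ_abs", "mass_abs",
                                            "circ_pct", "mass_pct"),
                            conversion = mass_conversion(), window = NULL) {
  metric <- match.arg(metric)
  if (identical(fit$scale, "log"))
    stop("growth-rate metrics are defined on arithmetic-scale fits")
  extent <- range(fit$residuals$age)
  if (is.null(window)) window <- c(extent[1], extent[2] + 25)
  model <- fit$model_obj
  params <- fit$params
  to_mass <- function(s) circ_to_mass(pmax(s, 1e-9), conversion)

  rate_fun <- switch(
    metric,
    circ_abs = function(t) model$derivative(params, t),
    mass_abs = function(t) {
      s <- model$evaluate(params, t)
      d_mass <- conversion$exponent * to_mass(s) / pmax(s, 1e-9)
      d_mass * model$derivative(params, t)
    },
    circ_pct = function(t)
      100 * model$derivative(params, t) / pmax(model$evaluate(params, t), 1e-9),
    mass_pct = function(t) {
      s <- pmax(model$evaluate(params, t), 1e-9)
      100 * conversion$exponent * model$derivative(params, t) / s
    })
  if (any(!is.finite(rate_fun(seq(window[1], window[2], length.out = 32)))))
    stop("non-finite growth rate over the window")

  grid <- seq(window[1], window[2], length.out = 2048)
  r <- rate_fun(grid)
  i <- which.max(r)
  if (i == 1 || i == length(grid))
    return(list(rate = r[i], age = grid[i],
                boundary = if (i == 1) "lower" else "upper"))
  opt <- stats::optimize(rate_fun, lower = grid[i - 1], upper = grid[i + 1],
                         maximum = TRUE, tol = 1e-9)
  list(rate = opt$objective, age = opt$maximum, boundary = "none")
}

#' Theoretical maturity-mass threshold
#'
#' The threshold placing the onset of sexual maturity at `W^exponent` for
#' asymptotic mass `W` - computed here so its implausibly low predictions
#' can be examined directly (a 7,000 kg asymptote yields 14.2 kg).
#'
#' @param W asymptotic body mass (kg, > 0).
#' @param exponent threshold exponent (default 0.3).
#' @return mass in kg.
#' @export
maturity_threshold <- function(W, exponent = 0.3) {
  if (any(W <= 0)) stop("asymptotic mass must be positive")
  W^exponent
}
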