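test_that("AICc follows the least-squares Gaussian convention", {
  # penalty-only difference between k = 12 and k = 3 at n = 152
  pen <- function(k, n) 2 * k + (2 * k^2 + 2 * k) / (n - k - 1)
  expect_equal(round(pen(12, 152) - pen(3, 152), 1), 20.1)
  expect_equal(aicc(exp(1) * 152 / (2 * pi), 152, 3) - pen(3, 152),
               152 * 2)  # n*(log(2*pi*rss/n)+1) term sanity
  # strictly decreasing in rss at fixed (n, k)
  r <- seq(10, 1000, length.out = 50)
  expect_true(all(diff(vapply(r, aicc, numeric(1), n = 100, k = 5)) > 0))
  expect_error(aicc(10, 10, 9), "n must exceed")
})

test_that("noise-free sigmoid synthetics are recovered to numerical precision", {
  cfg <- synthetic_config(noise_sd = 0, multiplet_prob = 0, xpl_prob = 0,
                          n_specimens = 3, erasure_mean = 3,
                          death_age = c(15, 28), seed = 3)
  g <- generate_cgm_dataset(cfg)
  ds <- pool_dataset(g$series, "A")
  fit <- joint_fit(ds, "logistic3", seed = 1)

  er <- vapply(g$truth$specimens, function(s) s$erased, numeric(1))
  keys <- paste0(vapply(g$truth$specimens, function(s) s$specimen_id,
                        character(1)), ":tibia")
  ref_er <- er[match(fit$reference_series, keys)]
  # the fitted age axis is translated by the reference's own erased count
  expect_equal(unname(fit$params),
               unname(c(500, 15 - ref_er, 4)), tolerance = 1e-6)
  expect_equal(unname(fit$starts[keys]), er - ref_er, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  # conventional two-step fit with starts frozen at the (already optimal)
  # clustered values reproduces the same parameters
  two_step <- joint_fit(ds, "logistic3", seed = 1, freeze_starts = TRUE)
  expect_equal(two_step$params, fit$params, tolerance = 1e-5)
})

test_that("joint optimization never does worse than the two-step fit", {
  cfg <- synthetic_config(seed = 21, noise_sd = 15)
  ds <- pool_dataset(generate_cgm_dataset(cfg)$series, "A")
  joint <- joint_fit(ds, "gompertz3", seed = 1)
  frozen <- joint_fit(ds, "gompertz3", seed = 1, freeze_starts = TRUE)
  expect_lte(joint$rss, frozen$rss + 1e-8)
})

test_that("single-series fits carry no start variables", {
  s <- noise_free_logistic(offsets = 0, n_marks = 16)[[1]]
  ds <- structure(list(variant = "A", series = list(s),
                       n_points = sum(s$records$measured)),
                  class = "variant_dataset")
  fit <- joint_fit(ds, "logistic3", seed = 1)
  expect_equal(fit$k, 3)
  expect_equal(unname(fit$starts), 0)
})

test_that("parameter count and error conditions follow k = p + M - 1", {
  series <- noise_free_logistic(offsets = c(0, 3, 7))
  ds <- pool_dataset(series, "A")
  fit <- joint_fit(ds, "gaussian3", seed = 1)
  expect_equal(fit$k, 3 + 2)
  expect_equal(fit$n, sum(vapply(series, function(s)
    sum(s$records$measured), integer(1))))

  tiny <- lapply(series, function(s) {
    s$records <- s$records[1:2, ]; s })
  expect_error(joint_fit(pool_dataset(tiny, "A"), "logistic3", seed = 1),
               "underdetermined")
})

test_that("refits from jittered initializations agree", {
  cfg <- synthetic_config(seed = 5, noise_sd = 10, n_specimens = 5)
  ds <- pool_dataset(generate_cgm_dataset(cfg)$series, "A")
  rss <- vapply(1:4, function(s)
    joint_fit(ds, "logistic3", seed = s)$rss, numeric(1))
  expect_lt(diff(range(rss)) / min(rss), 1e-6)
})

test_that("model selection picks the generating shape", {
  # exactly linear data: the linear diagnostic must beat the sigmoid
  lin <- list(linear_series("L1", 100, 8, 10), linear_series("L2", 140, 8, 10))
  ds <- pool_dataset(lin, "A")
  sel <- select_model(ds, registry = model_registry(c("linear2", "logistic3")),
                      seed = 1)
  expect_equal(sel$model, "linear2")
  expect_true(all(c("model", "aicc", "delta_aicc") %in% names(sel$ranking)))
  # independent check: AICc of both fits individually
  f_lin <- joint_fit(ds, "linear2", seed = 1)
  f_log <- joint_fit(ds, "logistic3", seed = 1)
  expect_equal(sel$aicc, min(f_lin$aicc, f_log$aicc))

  # a registry of one model returns that model
  one <- select_model(ds, registry = model_registry("gompertz3"), seed = 1)
  expect_equal(one$model, "gompertz3")
})

test_that("the generating sigmoid family wins or ties on low-noise data", {
  reg <- model_registry(c("gompertz3", "logistic3", "monomolecular2"))
  hits <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(model = "gompertz3",
                            params = c(a = 500, b = 12, c = 5),
                            noise_sd = 4, multiplet_prob = 0, xpl_prob = 0,
                            n_specimens = 5, seed = 300 + r)
    ds <- pool_dataset(generate_cgm_dataset(cfg)$series, "A")
    sel <- select_model(ds, registry = reg, seed = 1)
    d <- sel$ranking$delta_aicc[sel$ranking$model == "gompertz3"]
    if (length(d) && d <= 2) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("residual quantiles behave on degenerate and symmetric noise", {
  series <- noise_free_logistic(offsets = c(0, 2, 5))
  fit <- joint_fit(pool_dataset(series, "A"), "logistic3", seed = 1)
  q0 <- residual_quantiles(fit)
  expect_equal(q0$percent_residual, rep(0, 3), tolerance = 1e-5)

  cfg <- synthetic_config(seed = 77, noise_sd = 12, multiplet_prob = 0,
                          xpl_prob = 0)
  fit2 <- joint_fit(pool_dataset(generate_cgm_dataset(cfg)$series, "A"),
                    "logistic3", seed = 1)
  med <- residual_quantiles(fit2, 0.5)$percent_residual
  expect_lt(abs(med), 3)
})

test_that("log-scale fitting transforms the objective, not the data model", {
  cfg <- synthetic_config(seed = 15, noise_sd = 8)
  ds <- pool_dataset(generate_cgm_dataset(cfg)$series, "A")
  lg <- joint_fit(ds, "gompertz3", scale = "log", seed = 1)
  expect_equal(lg$scale, "log")
  # residual rss is in log units and far smaller than arithmetic rss
  ar <- joint_fit(ds, "gompertz3", seed = 1)
  expect_lt(lg$rss, ar$rss)
  # observed circumferences are reported untransformed
  expect_equal(sort(lg$residuals$observed), sort(ar$residuals$observed))
})
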