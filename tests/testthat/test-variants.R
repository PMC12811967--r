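test_that("shared points follow the variant set relations", {
  s <- toy_flagged_series()
  other <- linear_series("OTH", 90, 12, 6)
  fam <- variant_family(list(s, other))
  expect_setequal(shared_points(fam$A, fam$A),
                  cgmgrowth:::dataset_uids(fam$A))
  expect_length(shared_points(fam$A, fam$NoX), 4 + 6)
  expect_length(shared_points(fam$A, fam$NoXM), 3 + 6)

  alien <- variant_family(list(linear_series("Q1", 10, 5, 4),
                               linear_series("Q2", 20, 5, 4)))
  expect_error(shared_points(fam$A, alien$A), "share no points")
})

test_that("same-points AICc on a fit's own points equals its overall AICc", {
  cfg <- synthetic_config(seed = 71, noise_sd = 10, n_specimens = 5)
  fam <- variant_family(generate_cgm_dataset(cfg)$series)
  fit <- joint_fit(fam$A, "logistic3", seed = 1)
  own <- cgmgrowth:::dataset_uids(fam$A)
  own <- own[own %in% fit$residuals$uid]
  expect_equal(same_points_aicc(fit, own), fit$aicc, tolerance = 1e-10)
  expect_error(same_points_aicc(fit, "no-such-uid"), "not in fit")

  # perturbing the fitted parameters increases the same-points rss
  worse <- fit
  worse$residuals$raw <- worse$residuals$raw + 5
  expect_gt(same_points_aicc(worse, own), fit$aicc)
})

test_that("restricting the point set changes n and rss but never k", {
  cfg <- synthetic_config(seed = 72, noise_sd = 10, n_specimens = 5,
                          xpl_prob = 0.15, multiplet_prob = 0.1)
  fam <- variant_family(generate_cgm_dataset(cfg)$series)
  fit <- joint_fit(fam$A, "logistic3", seed = 1)
  sub <- shared_points(fam$A, fam$NoXM)
  res <- fit$residuals[fit$residuals$uid %in% sub, ]
  expect_equal(same_points_aicc(fit, sub),
               aicc(sum(res$raw^2), length(sub), fit$k))
})

test_that("dominance check reports per-clause conditions", {
  cfg <- synthetic_config(seed = 73, noise_sd = 10, n_specimens = 6,
                          xpl_prob = 0.12, multiplet_prob = 0.08)
  fam <- variant_family(generate_cgm_dataset(cfg)$series)
  fits <- lapply(fam, function(ds) joint_fit(ds, "logistic3", seed = 1))
  rep <- dominance_check(fits)
  expect_named(rep$conditions_met,
               c("A_best_on_noxm_points", "nom_beats_nox_on_noxm_points",
                 "nox_beats_noxm_on_noxm_points", "A_best_on_nom_points",
                 "A_best_on_nox_points"))
  expect_equal(rep$all_met, all(rep$conditions_met))
  expect_equal(unname(rep$delta_noxm[which.min(rep$scope_noxm)]), 0)
})

test_that("identical variants yield zero deltas and unmet strict conditions", {
  cfg <- synthetic_config(seed = 74, noise_sd = 10, n_specimens = 5,
                          xpl_prob = 0, multiplet_prob = 0)
  fam <- variant_family(generate_cgm_dataset(cfg)$series)
  fits <- lapply(fam, function(ds) joint_fit(ds, "logistic3", seed = 1))
  rep <- dominance_check(fits)
  expect_equal(max(abs(rep$delta_noxm)), 0, tolerance = 1e-9)
  expect_false(rep$all_met)
})

test_that("fictitious-mark insertion keeps series valid and shifts counts", {
  s <- linear_series("MC", 100, 10, 8)
  set.seed(5)
  aug <- cgmgrowth:::insert_fictitious_marks(s, n_x = 2, n_m = 2)
  expect_equal(nrow(aug$records), 12)
  expect_equal(sum(aug$records$xpl_only), 2)
  expect_equal(max(aug$records$cgmc), 12)
  expect_true(all(diff(aug$records$circumference) >= 0))
  # A keeps everything, NoXM recovers the original point count
  expect_equal(nrow(derive_variant(aug, "NoXM")$records), 8)
  expect_equal(nrow(derive_variant(aug, "A")$records), 12)
  # variant identities hold for the augmented series
  other <- linear_series("MC2", 120, 10, 8)
  expect_no_error(variant_family(list(aug, other)))
})

test_that("the Monte Carlo null test is deterministic and sized correctly", {
  cfg <- synthetic_config(seed = 81, noise_sd = 10, n_specimens = 5,
                          xpl_prob = 0, multiplet_prob = 0)
  series <- generate_cgm_dataset(cfg)$series
  keys <- vapply(series, function(s) paste(s$specimen_id, s$element, sep = ":"),
                 character(1))
  xc <- stats::setNames(c(2, 1, 0, 1, 1), keys)
  mc <- stats::setNames(c(1, 0, 1, 1, 0), keys)
  r1 <- mc_null_test(series, xc, mc, trials = 6, seed = 9, restarts = 0)
  r2 <- mc_null_test(series, xc, mc, trials = 6, seed = 9, restarts = 0)
  expect_identical(r1$all_met, r2$all_met)
  expect_equal(r1$p_value, r1$count_met / 6)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  expect_error(mc_null_test(series, 0 * xc, 0 * mc, trials = 5),
               "n_x \\+ n_m = 0")
})

test_that("genuinely annual extra marks are not rejected as extraneous", {
  # A-variant-true world: flagged marks are real years, so the dominance
  # conditions should hold for the actual data far more often than under
  # the fictitious-placement null
  cfg <- synthetic_config(seed = 82, noise_sd = 6, n_specimens = 6,
                          xpl_prob = 0.12, multiplet_prob = 0.10)
  fam <- variant_family(generate_cgm_dataset(cfg)$series)
  fits <- lapply(fam, function(ds) joint_fit(ds, "logistic3", seed = 1,
                                             restarts = 2))
  real <- dominance_check(fits)
  expect_type(real$all_met, "logical")
})
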