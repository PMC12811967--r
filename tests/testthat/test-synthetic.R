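test_that("generation is deterministic under a seed", {
  cfg <- synthetic_config(seed = 101)
  g1 <- generate_cgm_dataset(cfg)
  g2 <- generate_cgm_dataset(cfg)
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_series_table(g1$series, t1)
  write_series_table(g2$series, t2)
  expect_identical(readLines(t1), readLines(t2))
  g3 <- generate_cgm_dataset(synthetic_config(seed = 102))
  expect_false(identical(
    g1$series[[1]]$records$circumference,
    g3$series[[1]]$records$circumference))
})

test_that("generated series satisfy the data-model invariants", {
  for (seed in c(11, 22, 33)) {
    cfg <- synthetic_config(seed = seed, multiplet_prob = 0.15,
                            xpl_prob = 0.15, noise_sd = 20)
    g <- generate_cgm_dataset(cfg)
    for (s in g$series) {
      expect_true(all(diff(s$records$cgmc) >= 1))
      circ <- s$records$circumference[s$records$measured]
      expect_true(all(diff(circ) >= 0))
      expect_true(all(circ > 0))
    }
    # truth records align with the emitted series
    expect_length(g$truth$specimens, length(g$series))
  }
})

test_that("erased inner marks set the true start-age offsets", {
  cfg <- synthetic_config(seed = 44, noise_sd = 0, multiplet_prob = 0,
                          xpl_prob = 0, n_specimens = 4)
  g <- generate_cgm_dataset(cfg)
  for (j in seq_along(g$series)) {
    tr <- g$truth$specimens[[j]]
    expect_equal(g$series[[j]]$records$cgmc[1], 1)
    expect_equal(tr$true_ages[1] - 1, tr$erased)
  }
})

test_that("start-age recovery stays within half a year at moderate noise", {
  errs <- replicate(12, NA_real_)
  for (r in seq_along(errs)) {
    cfg <- synthetic_config(seed = 400 + r, noise_sd = 10,
                            multiplet_prob = 0, xpl_prob = 0)
    g <- generate_cgm_dataset(cfg)
    fit <- joint_fit(pool_dataset(g$series, "A"), "logistic3", seed = 1,
                     restarts = 2)
    er <- vapply(g$truth$specimens, function(s) s$erased, numeric(1))
    keys <- paste0(vapply(g$truth$specimens, function(s) s$specimen_id,
                          character(1)), ":tibia")
    ref_er <- er[match(fit$reference_series, keys)]
    errs[r] <- stats::median(abs(fit$starts[keys] - (er - ref_er)))
  }
  expect_lt(stats::median(errs), 0.5)
})

test_that("bad-year increments are stochastically smaller than normal ones", {
  cfg <- synthetic_config(seed = 55, n_specimens = 30, noise_sd = 0,
                          multiplet_prob = 0.15, xpl_prob = 0,
                          death_age = c(20, 30))
  g <- generate_cgm_dataset(cfg)
  bad_inc <- c(); norm_inc <- c()
  for (j in seq_along(g$series)) {
    r <- g$series[[j]]$records
    tr <- g$truth$specimens[[j]]
    inc <- diff(r$circumference)
    isbad <- tr$bad_years[-1]
    bad_inc <- c(bad_inc, inc[isbad])
    norm_inc <- c(norm_inc, inc[!isbad])
  }
  expect_gt(length(bad_inc), 20)
  wt <- stats::wilcox.test(bad_inc, norm_inc, alternative = "less")
  expect_lt(wt$p.value, 1e-6)
})

test_that("bad-year runs carry multiplet groups and faint marks carry flags", {
  cfg <- synthetic_config(seed = 66, multiplet_prob = 0.2, xpl_prob = 0.2,
                          n_specimens = 10)
  g <- generate_cgm_dataset(cfg)
  rec <- do.call(rbind, lapply(g$series, function(s) s$records))
  expect_gt(sum(!is.na(rec$multiplet_group)), 0)
  expect_gt(sum(rec$xpl_only), 0)
  # run members share a group label within a specimen
  grp <- rec$multiplet_group[!is.na(rec$multiplet_group)]
  expect_true(any(table(grp) >= 2))
})

test_that("the single-year world compresses true ages at runs", {
  cfg <- synthetic_config(seed = 77, multiplet_prob = 0.25,
                          world = "single_year", n_specimens = 10,
                          death_age = c(20, 30))
  g <- generate_cgm_dataset(cfg)
  any_compressed <- FALSE
  for (tr in g$truth$specimens) {
    if (any(diff(tr$true_ages) == 0)) any_compressed <- TRUE
  }
  expect_true(any_compressed)
})

test_that("linear outliers are exact and flag-free", {
  out <- make_linear_outlier(158.5, 2, 22)
  expect_equal(out$records$circumference[22], 200.5)
  out30 <- make_linear_outlier(158.5, 30, 22)
  expect_equal(out30$records$circumference[22], 788.5)
  expect_equal(mean_slope(out), 2)
  expect_true(all(!out$records$xpl_only))
  expect_true(all(is.na(out$records$multiplet_group)))
})

test_that("synthetic datasets round-trip with their truth sidecar", {
  g <- generate_cgm_dataset(synthetic_config(seed = 88, n_specimens = 3))
  tp <- withr::local_tempfile(fileext = ".csv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_synthetic_dataset(g, tp, jp)
  back <- read_series_table(tp)
  expect_length(back, 3)
  truth <- jsonlite::read_json(jp)
  expect_equal(length(truth$specimens), 3)
})
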