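test_that("series construction enforces the record invariants", {
  s <- growth_series("X", "tibia",
                     data.frame(cgmc = 1:3, circumference = c(10, 20, 30)))
  expect_s3_class(s, "growth_series")
  expect_equal(nrow(s$records), 3)

  # counted-unmeasured record retained with absent circumference
  s2 <- growth_series("X", "tibia", data.frame(
    cgmc = c(1, 2, 3), circumference = c(10, NA, 30),
    measured = c(TRUE, FALSE, TRUE)))
  expect_equal(sum(s2$records$measured), 2)

  expect_error(growth_series("X", "tibia",
                             data.frame(cgmc = 1:2, circumference = c(100, 90))),
               "cannot shrink")
  expect_error(growth_series("X", "tibia",
                             data.frame(cgmc = c(1, 1, 2),
                                        circumference = c(1, 2, 3))),
               "strictly increasing")
  expect_error(growth_series("X", "tibia", data.frame(
    cgmc = 1:2, circumference = c(10, 20),
    measured = c(TRUE, FALSE))),
    "absent circumference")
})

test_that("series tables round-trip through read and write", {
  series <- list(toy_flagged_series("S1"),
                 linear_series("S2", 50, 10, 4, element = "femur"))
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_series_table(series, path, dialect)
    back <- read_series_table(path, dialect)
    expect_length(back, 2)
    for (i in 1:2) {
      expect_equal(back[[i]]$specimen_id, series[[i]]$specimen_id)
      expect_equal(back[[i]]$records$circumference,
                   series[[i]]$records$circumference)
      expect_equal(back[[i]]$records$xpl_only, series[[i]]$records$xpl_only)
      expect_equal(back[[i]]$records$multiplet_group,
                   series[[i]]$records$multiplet_group)
    }
  }
})

test_that("read_series_table rejects malformed circumference values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,element,cgmc,circumference_mm",
               "X,tibia,1,100", "X,tibia,2,-5"), path)
  expect_error(read_series_table(path), "row")
  writeLines(c("specimen_id,element,cgmc,circumference_mm",
               "X,tibia,1,100", "X,tibia,2,90"), path)
  expect_error(read_series_table(path), "shrink")
})

test_that("variant derivation drops, collapses and renumbers as specified", {
  s <- toy_flagged_series()

  a <- derive_variant(s, "A")
  expect_equal(a$records$cgmc, 1:5)
  expect_equal(nrow(a$records), 5)

  nox <- derive_variant(s, "NoX")
  expect_equal(nox$records$cgmc, 1:4)
  expect_equal(nox$records$circumference, c(100, 120, 135, 150))

  noxm <- derive_variant(s, "NoXM")
  expect_equal(noxm$records$cgmc, 1:3)
  # group collapsed to its outermost (largest-circumference) member
  expect_equal(noxm$records$circumference, c(100, 120, 150))

  nom <- derive_variant(s, "NoM")
  expect_equal(nom$records$circumference, c(100, 120, 130, 150))

  expect_error(derive_variant(s, "nope"), "unknown variant")
})

test_that("variant derivation preserves uids and is idempotent", {
  s <- toy_flagged_series()
  for (v in c("A", "NoM", "NoX", "NoXM")) {
    d <- derive_variant(s, v)
    expect_true(all(d$records$uid %in% s$records$uid))
    again <- derive_variant(d, v)
    expect_equal(again$records, d$records)
  }
})

test_that("counted-unmeasured gaps survive variant renumbering", {
  s <- growth_series("G", "tibia", data.frame(
    cgmc = c(1, 2, 4, 5), circumference = c(10, 20, 40, 45),
    xpl_only = c(FALSE, TRUE, FALSE, FALSE)))
  nox <- derive_variant(s, "NoX")
  # the dropped mark shifts later counts by one; the unmeasured-year gap
  # between original counts 2 and 4 stays a gap
  expect_equal(nox$records$cgmc, c(1, 3, 4))
})

test_that("pooling counts measured points additively and checks identities", {
  s1 <- linear_series("P1", 10, 10, 3)
  s2 <- linear_series("P2", 25, 10, 4)
  ds <- pool_dataset(list(s1, s2), "A")
  expect_equal(ds$n_points, 7)
  expect_error(pool_dataset(list(s1)), "at least 2")

  fam <- variant_family(list(toy_flagged_series("F1"),
                             linear_series("F2", 90, 15, 6)))
  uids <- lapply(fam, cgmgrowth:::dataset_uids)
  expect_setequal(uids$A, union(uids$NoM, uids$NoX))
  expect_setequal(uids$NoXM, intersect(uids$NoM, uids$NoX))
})

test_that("variant point counts are ordered and equal only without flags", {
  set.seed(42)
  for (rep in 1:5) {
    cfg <- synthetic_config(n_specimens = 4, seed = 100 + rep,
                            multiplet_prob = 0.1, xpl_prob = 0.1)
    fam <- variant_family(generate_cgm_dataset(cfg)$series)
    n <- vapply(fam, function(d) d$n_points, integer(1))
    expect_true(n[["A"]] >= n[["NoM"]])
    expect_true(n[["NoX"]] >= n[["NoXM"]])
    expect_true(n[["A"]] >= n[["NoX"]])
  }
  cfg0 <- synthetic_config(n_specimens = 4, multiplet_prob = 0, xpl_prob = 0,
                           seed = 9)
  fam0 <- variant_family(generate_cgm_dataset(cfg0)$series)
  n0 <- vapply(fam0, function(d) d$n_points, integer(1))
  expect_true(all(n0 == n0[["A"]]))
})
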