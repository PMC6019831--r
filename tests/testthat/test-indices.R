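# Index formulas, their error contracts, and the exact HOMA-IR/QUICKI/FIRI
# transformations.

test_that("fasting index formulas match hand-computed values", {
  expect_equal(homa_ir(5.0, 9.0), 2.0)
  expect_equal(homa_ir(22.5, 1.0), 1.0)
  expect_equal(homa_ir(5.5, 10.0), 55 / 22.5)

  expect_equal(quicki(10, 10), 0.5)
  expect_equal(quicki(10, 1), 1.0)
  expect_equal(quicki(5, 9), 0.6048829123101416)

  expect_equal(firi(5, 10), 2.0)
  expect_equal(firi(25, 1), 1.0)
  expect_equal(firi(5, 9), 1.8)

  expect_equal(fasting_ratio(5, 5, "insulin_over_glucose"), 1.0)
  expect_equal(fasting_ratio(5, 10, "insulin_over_glucose"), 2.0)
  expect_equal(fasting_ratio(5, 10, "glucose_over_insulin"), 0.5)
})

test_that("OGTT-based index formulas match hand-computed values", {
  expect_equal(matsuda(100, 10, 100, 10), 10.0)
  expect_equal(matsuda(10000, 1, 1, 1), 100.0)
  expect_equal(matsuda(90, 10, 120, 50), 10000 / sqrt(5400000))

  # intercept check uses zero inputs, allowed only because stumvoll accepts
  # any finite regressors
  expect_equal(stumvoll(0, 0, 0), 18.3)
  expect_equal(stumvoll(25, 400, 5), 8.095)
  expect_equal(stumvoll(10, 100, 10), 12.37)

  expect_equal(revised_quicki(10, 10, 10), 1 / 3)
  expect_equal(revised_quicki(10, 10, 1), 0.5)
  expect_equal(revised_quicki(5, 9, 0.5), 0.7395451328543522)
})

test_that("invalid and degenerate inputs fail naming the field", {
  expect_error(homa_ir(-1, 5), "glucose")
  expect_error(homa_ir(5, 0), "insulin")
  expect_error(homa_ir(NA_real_, 5), "glucose")
  expect_error(homa_ir(Inf, 5), "glucose")
  expect_error(quicki(1, 1), "degenerate")    # G0 * I0 = 1
  expect_error(quicki(2, 0.5), "degenerate")
  expect_error(matsuda(5, 9, NULL, NULL), "missing field")
  expect_error(stumvoll(25, NULL, 5), "missing field")
  expect_error(revised_quicki(5, 9), "missing field")
})

test_that("transforms reproduce Table-style closed forms and identities", {
  expect_equal(transform_index(2.25, "firi", "homa_ir"), 2.5)
  h <- 3.7
  expect_identical(transform_index(h, "homa_ir", "homa_ir"), h)
  # transform through QUICKI must agree with direct computation
  expect_equal(transform_index(quicki(5, 9), "quicki", "homa_ir"),
               homa_ir(5, 9), tolerance = 1e-12)
  expect_error(transform_index(1, "homa_ir", "matsuda"),
               "unsupported transform")
  expect_error(transform_index(0, "quicki", "firi"), "degenerate")
})

test_that("round trips through every ordered index pair are exact", {
  fs <- random_fasting(1000, seed = 42)
  kinds <- c("homa_ir", "quicki", "firi")
  base <- list(homa_ir = homa_ir(fs$glucose, fs$insulin),
               quicki = quicki(fs$glucose, fs$insulin),
               firi = firi(fs$glucose, fs$insulin))
  for (a in kinds) for (b in kinds) {
    back <- transform_index(transform_index(base[[a]], a, b), b, a)
    expect_equal(back, base[[a]], tolerance = 1e-12)
    # consistency: transforming a's values into b matches direct computation
    expect_equal(transform_index(base[[a]], a, b), base[[b]],
                 tolerance = 1e-12)
  }
})

test_that("HOMA-IR / FIRI is the exact constant 25/22.5", {
  fs <- random_fasting(500, seed = 7)
  expect_equal(homa_ir(fs$glucose, fs$insulin) / firi(fs$glucose, fs$insulin),
               rep(25 / 22.5, 500))
})

test_that("indices are strictly monotone in glucose and insulin", {
  g <- seq(3, 12, length.out = 50)
  i <- seq(2, 40, length.out = 50)
  expect_true(all(diff(homa_ir(g, 10)) > 0))
  expect_true(all(diff(homa_ir(5, i)) > 0))
  expect_true(all(diff(firi(g, 10)) > 0))
  expect_true(all(diff(firi(5, i)) > 0))
  # QUICKI decreasing on the domain G0 * I0 > 1
  expect_true(all(diff(quicki(g, 10)) < 0))
  expect_true(all(diff(quicki(5, i)) < 0))
})

test_that("tie-free samples give identical ranks for HOMA-IR and FIRI and reversed ranks for QUICKI", {
  fs <- random_fasting(200, seed = 11)
  h <- homa_ir(fs$glucose, fs$insulin)
  f <- firi(fs$glucose, fs$insulin)
  q <- quicki(fs$glucose, fs$insulin)
  expect_identical(rank(h), rank(f))
  expect_identical(rank(h), length(h) + 1 - rank(q))
})

test_that("compute_indices reports per-kind values and failures in canonical order", {
  rec <- list(glucose_fasting = 5, insulin_fasting = 9)
  res <- compute_indices(rec, c("firi", "homa_ir"))  # order normalized
  expect_identical(res$kind, c("homa_ir", "firi"))
  expect_equal(res$value[res$kind == "homa_ir"] / res$value[res$kind == "firi"],
               25 / 22.5)

  res2 <- compute_indices(rec, "matsuda")
  expect_true(is.na(res2$value))
  expect_match(res2$error, "missing field")

  all_fasting <- c("homa_ir", "quicki", "firi",
                   "insulin_glucose_ratio", "glucose_insulin_ratio")
  res3 <- compute_indices(rec, all_fasting)
  expect_equal(res3$value,
               c(homa_ir(5, 9), quicki(5, 9), firi(5, 9),
                 fasting_ratio(5, 9, "insulin_over_glucose"),
                 fasting_ratio(5, 9, "glucose_over_insulin")))
  expect_true(all(is.na(res3$error)))
})

test_that("orientation flags separate resistance-up from sensitivity-up kinds", {
  expect_identical(index_orientation(c("homa_ir", "firi",
                                       "insulin_glucose_ratio")),
                   rep("resistance_up", 3))
  expect_identical(index_orientation(c("quicki", "matsuda", "stumvoll",
                                       "revised_quicki",
                                       "glucose_insulin_ratio")),
                   rep("sensitivity_up", 5))
})
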