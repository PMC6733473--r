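# Lea-Coulson estimation, total-cell count-back and rate reporting.

test_that("lea_coulson_m evaluates the median estimator and clamps at r/z <= 1", {
  # frozen against independent high-precision evaluation of
  # (r/z - 0.693) / log(r/z + 0.367)
  expect_equal(lea_coulson_m(10, 1), 3.979684, tolerance = 1e-6)
  expect_equal(lea_coulson_m(100, 0.5), 37.60403, tolerance = 1e-6)
  # clamp region: r/z <= 1 always maps to zero events
  expect_identical(lea_coulson_m(0, 1), 0)
  expect_identical(lea_coulson_m(1, 1), 0)
  expect_identical(lea_coulson_m(c(0, 1, 2), 1)[1:2], c(0, 0))
  expect_gt(lea_coulson_m(2, 1), 0)
  expect_error(lea_coulson_m(5, 0), "z")
  expect_error(lea_coulson_m(5, 1.2), "z")
  expect_error(lea_coulson_m(-1, 1), "r")
})

test_that("lea_coulson_m is monotonically increasing in r/z above the clamp", {
  x <- seq(1.01, 5000, length.out = 400)
  m <- lea_coulson_m(x, 1)
  expect_true(all(diff(m) > 0))
  # plating-fraction correction: same r/z, same m
  expect_equal(lea_coulson_m(50, 0.5), lea_coulson_m(100, 1))
})

test_that("total_cells counts back through dilution and volumes", {
  expect_equal(total_cells(100, 1e5, 0.1, 10), 1e9)
  expect_equal(total_cells(260, 1e5, 0.1, 10), 2.6e9)
  expect_error(total_cells(0, 1e5, 0.1, 10), "unmeasurable")
  expect_error(total_cells(100, 1e5, -0.1, 10), "volumes")
})

test_that("estimate_rate reports the median per-culture rate", {
  # 7 cultures, N = 1e9 each; the median of the 7 per-culture rates is
  # the 4th order statistic = lea_coulson_m(2, 1) / 1e9 (sort-and-pick
  # oracle)
  tab <- culture_table(r = c(0, 0, 0, 2, 5, 20, 400))
  est <- estimate_rate(tab)
  expect_s3_class(est, "gcr_rate")
  expect_equal(est$rate, lea_coulson_m(2, 1) / 1e9)
  expect_false(est$is_upper_bound)
  expect_equal(est$n_cultures, 7L)
  expect_true(est$ci_low <= est$rate && est$rate <= est$ci_high)
  # permutation invariance: the median is order-free
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(estimate_rate(perm)$rate, est$rate)
})

test_that("zero-median rule reports 1/N as an upper bound without a CI", {
  tab <- culture_table(r = rep(0, 7), nonselective_count = 100,
                       dilution_factor = 1e5, plated_volume_ml = 0.1,
                       culture_volume_ml = 1)  # N = 1e8
  est <- estimate_rate(tab)
  expect_true(est$is_upper_bound)
  expect_equal(est$rate, 1e-8)
  expect_true(is.na(est$ci_low) && is.na(est$ci_high))
})

test_that("estimate_rate warns below the conventional 7 cultures and errors on empty input", {
  expect_warning(estimate_rate(culture_table(r = c(5, 9, 2, 4, 7, 3))),
                 "at least 7")
  expect_error(estimate_rate(culture_table(r = integer(0))), "at least one")
})

test_that("fold_change reproduces conventional integer reports", {
  expect_equal(fold_change(1.1e-7, 2.6e-9, as_integer = TRUE), 42)
  expect_equal(fold_change(0.85e-7, 2.6e-9, as_integer = TRUE), 33)
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(1, 0), "reference_rate")
  # integer report rounds half away from zero
  expect_equal(fold_change(2.5, 1, as_integer = TRUE), 3)
})

test_that("normalize_per_kb divides by region length", {
  expect_equal(normalize_per_kb(2.6e-9, 16.8, digits = 2), 1.5e-10)
  expect_equal(normalize_per_kb(2.27e-9, 19.2, digits = 2), 1.2e-10)
  expect_equal(normalize_per_kb(0, 16.8), 0)
  expect_error(normalize_per_kb(1e-9, 0), "region_length_kb")
})

test_that("estimate_rate is invariant under count rescalings that preserve r/z and N", {
  tab1 <- culture_table(r = c(2, 6, 14, 3, 9, 40, 11), z = 1)
  # halving both r and z leaves r/z (and N) unchanged
  tab2 <- culture_table(r = c(1, 3, 7, 1.5, 4.5, 20, 5.5), z = 0.5)
  expect_equal(estimate_rate(tab2)$rate, estimate_rate(tab1)$rate)
})
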