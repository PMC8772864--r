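test_that("odds ratios reproduce the published group contrasts", {
  expect_equal(round(as.numeric(odds_ratio(16, 27, 11, 5)), 3), 0.269)
  expect_equal(round(as.numeric(odds_ratio(13, 3, 20, 41)), 3), 8.883)
  expect_equal(as.numeric(odds_ratio(1, 1, 1, 1)), 1)
  expect_error(odds_ratio(0, 0, 0, 0), "all-zero")
  expect_error(odds_ratio(1, 0, 1, 1, correction = "none"), "zero cell")
})

test_that("odds-ratio algebra: reciprocality and joint row/column swaps", {
  set.seed(401)
  for (i in 1:50) {
    x <- rpois(4, 6) + 1
    or1 <- as.numeric(odds_ratio(x[1], x[2], x[3], x[4]))
    expect_equal(or1 * as.numeric(odds_ratio(x[2], x[1], x[4], x[3])), 1)
    # swapping both rows and both columns leaves everything unchanged
    expect_equal(or1, as.numeric(odds_ratio(x[4], x[3], x[2], x[1])))
    expect_equal(woolf_ci(x[1], x[2], x[3], x[4]),
                 woolf_ci(x[4], x[3], x[2], x[1]))
    expect_equal(exact_p(x[1], x[2], x[3], x[4]),
                 exact_p(x[4], x[3], x[2], x[1]))
  }
})

test_that("Woolf intervals reproduce the published bounds and contain the OR", {
  expect_equal(round(as.numeric(woolf_ci(16, 27, 11, 5)), 3), c(0.079, 0.917))
  expect_equal(round(as.numeric(woolf_ci(13, 3, 20, 41)), 3), c(2.270, 34.766))
  ci <- woolf_ci(7, 7, 7, 7)
  expect_equal(unname(ci["low"] * ci["high"]), 1)  # log-symmetric around 1
  set.seed(402)
  for (i in 1:50) {
    x <- rpois(4, 5) + 1
    ci <- woolf_ci(x[1], x[2], x[3], x[4])
    or <- as.numeric(odds_ratio(x[1], x[2], x[3], x[4]))
    expect_true(ci["low"] < or && or < ci["high"])
  }
})

test_that("zero cells trigger the Haldane correction and are flagged", {
  or <- odds_ratio(5, 0, 3, 4)
  expect_true(attr(or, "corrected"))
  expect_equal(as.numeric(or), (5.5 * 4.5) / (0.5 * 3.5))
  expect_true(attr(woolf_ci(5, 0, 3, 4), "corrected"))
  expect_false(attr(odds_ratio(5, 1, 3, 4), "corrected"))
})

test_that("the exact p-value matches hypergeometric enumeration and fisher.test", {
  # extreme diagonal: only the two corner tables are as unlikely
  expect_equal(exact_p(5, 0, 0, 5), 2 * choose(5, 5) * choose(5, 0) /
                 choose(10, 5))
  expect_equal(exact_p(1, 1, 1, 1), 1)
  # published contrast rounds to the printed value
  expect_equal(round(exact_p(16, 27, 11, 5), 3), 0.042)
  # exhaustive agreement with the independent implementation, small n
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(exact_p(a, b, cc, d),
                 fisher.test(matrix(c(a, b, cc, d), 2,
                                    byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  set.seed(403)
  for (i in 1:100) {
    x <- rpois(4, 7)
    if (any(c(x[1] + x[2], x[3] + x[4], x[1] + x[3], x[2] + x[4]) == 0))
      next
    expect_equal(exact_p(x[1], x[2], x[3], x[4]),
                 fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  # doubling convention equals twice the smaller tail, capped at one
  expect_equal(exact_p(5, 0, 0, 5, method = "doubling"),
               2 * dhyper(5, 5, 5, 5))
  expect_lte(exact_p(2, 2, 2, 2, method = "doubling"), 1)
})

test_that("the Woolf z-test p is reported for transparency", {
  expect_equal(round(woolf_p(16, 27, 11, 5), 3), 0.036)
  st <- ct_stats(16, 27, 11, 5)
  expect_equal(round(st$or, 3), 0.269)
  expect_equal(round(st$p, 3), 0.042)
})

test_that("table recovery from printed margins and statistics is unique", {
  r1 <- recover_table(c(43, 16), 0.269, c(0.079, 0.917))
  expect_length(r1, 1L)
  expect_equal(unname(r1[[1]]), c(16, 27, 11, 5))
  r2 <- recover_table(c(16, 61), 8.883, c(2.270, 34.766))
  expect_length(r2, 1L)
  expect_equal(unname(r2[[1]]), c(13, 3, 20, 41))
  # impossible targets yield an empty result
  expect_length(recover_table(c(43, 16), 1e6, c(1, 2)), 0L)
  # the two FFQ group contrasts admit no consistent table on full margins,
  # consistent with item non-response
  expect_length(recover_table(c(16, 61), 4.181, c(1.088, 16.063)), 0L)
  expect_length(recover_table(c(16, 61), 14.800, c(2.950, 74.241)), 0L)
})
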