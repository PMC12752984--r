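econ <- refEconomicParams()

test_that("per-hectare value is yield times margin", {
  expect_equal(unitValue(10, econ), 8800)      # 10 t/hm2 x 880 yuan/t
  expect_equal(unitValue(10, economicParams(price = 2000, cost = 2000)), 0)
  # linearity in the margin
  e2 <- economicParams(price = 2640 + 880, cost = 1760)
  expect_equal(unitValue(10, e2), 2 * unitValue(10, econ))
  expect_warning(unitValue(10, economicParams(price = 100, cost = 200)),
                 "negative margin")
  # per-season inputs average into the annual price and cost
  se <- economicParams(seasonal = data.frame(price = c(2600, 2680),
                                             cost = c(1700, 1820)))
  expect_equal(se@price, 2640)
  expect_equal(se@cost, 1760)
})

test_that("aggregation to totals, shares and regional breakdowns is exact", {
  uv <- c(I = 100)
  rep1 <- totalValue(uv, c(I = 2), econ)
  expect_equal(rep1@grandTotal, 200)
  # region x grade matrix route
  areas <- matrix(c(1, 3, 2, 4), 2, 2,
                  dimnames = list(c("north", "south"), c("I", "II")))
  uv2 <- c(I = 100, II = 10)
  rep2 <- totalValue(uv2, areas, econ)
  expect_equal(unname(rep2@gradeTotals), c(400, 60))
  expect_equal(unname(rep2@regionTotals), c(1 * 100 + 2 * 10,
                                            3 * 100 + 4 * 10))
  expect_equal(rep2@grandTotal, 460)
  # permuting the region rows leaves all totals unchanged
  rep3 <- totalValue(uv2, areas[c(2, 1), ], econ)
  expect_equal(rep3@gradeTotals, rep2@gradeTotals)
  expect_equal(rep3@grandTotal, rep2@grandTotal)
  # homogeneity: scaling areas scales every total
  rep4 <- totalValue(uv2, areas * 3, econ)
  expect_equal(rep4@gradeTotals, rep2@gradeTotals * 3)
  expect_error(totalValue(c(I = 100), areas, econ), "missing unit value")
})

test_that("published unit values times grade areas recover the grand total", {
  ev <- refEconomicValues()
  tot <- refGradeAreaTotals()
  rep <- totalValue(ev$unitValues, tot$grades, econ)
  expect_equal(rep@grandTotal, ev$grand, tolerance = 1e-5)
  expect_equal(unname(rep@gradeTotals), unname(ev$unitValues * tot$grades))
})

test_that("value shares reproduce the published proportions", {
  ev <- refEconomicValues()
  rep <- totalValue(ev$unitValues, refGradeAreaTotals()$grades, econ)
  s <- valueShares(rep)
  expect_equal(sum(s), 100, tolerance = 1e-9)
  # equal totals split evenly
  even <- totalValue(stats::setNames(rep(10, 5), c("I", "II", "III", "IV", "V")),
                     stats::setNames(rep(1, 5), c("I", "II", "III", "IV", "V")),
                     econ)
  expect_equal(unname(valueShares(even)), rep(20, 5))
  # rounding keeps the sum near 100
  expect_lt(abs(sum(valueShares(rep, digits = 1)) - 100), 0.1)
})

test_that("unit values derive back from totals by division", {
  expect_equal(unname(deriveUnitValues(c(I = 200), c(I = 2))), 100)
  ev <- refEconomicValues()
  tot <- refGradeAreaTotals()
  uv <- deriveUnitValues(ev$gradeTotals, tot$grades)
  expect_equal(round(unname(uv["I"]), 2), 3291.13)
  expect_equal(round(unname(uv), 2), unname(ev$unitValues))
  # algebraic round trip on synthetic inputs
  uvs <- c(I = 123.4, II = 56.7)
  areas <- c(I = 10, II = 20)
  rep <- totalValue(uvs, areas, econ)
  expect_equal(deriveUnitValues(rep@gradeTotals, areas), uvs)
  expect_error(deriveUnitValues(c(I = 1), c(I = 0)), "> 0")
})

test_that("single-year discounting divides by 1 + r", {
  expect_equal(presentValue(100, 0), 100)
  expect_equal(presentValue(1363115430.35, 0.03), 1363115430.35 / 1.03)
  expect_equal(round(presentValue(1363115430.35, 0.03), 1), 1323413039.2)
  r <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(presentValue(1000, r)) < 0))
  expect_error(presentValue(100, -1), "> -1")
  # a discount rate on the params flows into the report
  repD <- totalValue(c(I = 100), c(I = 2),
                     economicParams(price = 2640, cost = 1760,
                                    discountRate = 0.03))
  expect_equal(repD@presentValue, 200 / 1.03)
})

test_that("the reference tables pass every internal consistency check", {
  ledger <- consistencyCheck()
  expect_true(is.data.frame(ledger))
  expect_gt(nrow(ledger), 20)
  bad <- ledger[!ledger$pass, ]
  expect_identical(nrow(bad), 0L)
})
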