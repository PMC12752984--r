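specs <- refMembershipSpecs()

test_that("membership functions reproduce hand-computed values", {
  slope <- specs[["I2"]]
  expect_equal(evaluateMembership(slope, 0), 1)              # u = c
  expect_equal(evaluateMembership(slope, 10),
               1 / (1 + 0.0157 * 10^2), tolerance = 1e-12)   # 0.3891
  expect_equal(round(evaluateMembership(slope, 10), 4), 0.3891)
  expect_equal(round(evaluateMembership(slope, 28.0476), 4), 0.0749)
  bulk <- specs[["I4"]]
  expect_equal(evaluateMembership(bulk, 1.2597), 1)
  expect_equal(evaluateMembership(bulk, 1.5),
               1 / (1 + 57.0546 * (1.5 - 1.2597)^2), tolerance = 1e-12)
  expect_equal(round(evaluateMembership(bulk, 1.5), 4), 0.2329)
  om <- specs[["I9"]]
  expect_equal(evaluateMembership(om, 32.2732), 1)  # raw 1.0027, clamped
  expect_gt(0.0417 * 32.2732 - 0.343143, 1)         # clamping was needed
  expect_equal(round(evaluateMembership(om, 8.9648), 4), 0.0307)
})

test_that("inputs clamp to the fitted domain and outputs to [0, 1]", {
  slope <- specs[["I2"]]
  expect_equal(evaluateMembership(slope, -5), evaluateMembership(slope, 0))
  expect_equal(evaluateMembership(slope, 100),
               evaluateMembership(slope, 28.0476))
  bad <- membershipSpec("X", "linear", a = 1, b = 0, uLo = 0, uHi = 10)
  expect_equal(evaluateMembership(bad, 10), 1)  # a*u = 10, clamped
  expect_error(
    evaluateMembership(membershipSpec("X", "wiggly", a = 1, c = 0,
                                      uLo = 0, uHi = 1), 0.5),
    "kind")
  expect_error(evaluateMembership(slope, Inf), "finite")
})

test_that("every reference spec scores into [0,1] with kind monotonicity", {
  set.seed(5)
  for (id in names(specs)) {
    sp <- specs[[id]]
    u <- sort(runif(2000, sp@uLo, sp@uHi))
    y <- evaluateMembership(sp, u)
    expect_true(all(y >= 0 & y <= 1), info = id)
    if (sp@kind == "decreasing" || sp@kind == "peak") {
      # score non-increasing in |u - c| over the domain
      o <- order(abs(u - sp@c))
      expect_true(all(diff(y[o]) <= 1e-12), info = id)
      if (sp@kind == "peak" && sp@c >= sp@uLo && sp@c <= sp@uHi)
        expect_equal(evaluateMembership(sp, sp@c), 1, info = id)
    } else {
      d <- diff(y)
      if (sp@a > 0) expect_true(all(d >= -1e-12), info = id)
      else expect_true(all(d <= 1e-12), info = id)
    }
  }
})

test_that("conceptual scales map categories to the published scores", {
  scales <- refConceptualScales()
  expect_equal(scoreConceptual(scales[["I1"]], "Impact plains"), 1.0)
  expect_equal(scoreConceptual(scales[["I1"]],
                               "Small undulating mountainous terrain"), 0.4)
  expect_equal(scoreConceptual(scales[["I3"]], "Sandy soil"), 0.3)
  expect_equal(scoreConceptual(scales[["I13"]], "Closer"), 1.0)
  expect_equal(scoreConceptual(scales[["I13"]], "Farther"), 0.6)
  expect_error(scoreConceptual(scales[["I1"]], "Mars"), "legal categories")
  # scales are strictly decreasing with the declared order
  for (sc in scales) expect_true(all(diff(sc@scores) < 0))
})

test_that("layer scoring equals scalar scoring cell by cell", {
  g <- gridSpec(15, 15)
  set.seed(8)
  slope <- specs[["I2"]]
  vals <- matrix(runif(225, -2, 30), 15, 15)
  vals[sample(225, 10)] <- NA
  lay <- indicatorLayer(g, vals, "I2")
  sc <- scoreLayer(slope, lay)
  expect_s4_class(sc, "ScoreLayer")
  want <- evaluateMembership(slope, vals)
  dim(want) <- dim(vals)
  expect_identical(layerValues(sc), want)
  expect_identical(is.na(layerValues(sc)), is.na(vals))  # nodata preserved
  # constant layer at u = 0 scores 1 everywhere
  c1 <- scoreLayer(slope, indicatorLayer(g, matrix(0, 15, 15), "I2"))
  expect_true(all(layerValues(c1) == 1))
  # at the upper bound a decreasing spec gives its constant minimum
  cU <- scoreLayer(slope, indicatorLayer(g, matrix(28.0476, 15, 15), "I2"))
  expect_true(all(layerValues(cU) == evaluateMembership(slope, 28.0476)))
  # categorical layers score through their legend names
  topo <- refConceptualScales()[["I1"]]
  cat <- generateCategorical(g, topo@categories, patchScale = 200, seed = 2,
                             indicatorId = "I1")
  sc2 <- scoreLayer(topo, cat)
  ids <- layerValues(cat)
  want2 <- matrix(topo@scores[ids], 15, 15)
  expect_equal(layerValues(sc2), want2)
  # kind mismatches are refused
  expect_error(scoreLayer(slope, cat), "kind mismatch")
  expect_error(scoreLayer(topo, lay), "kind mismatch")
})
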