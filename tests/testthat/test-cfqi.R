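test_that("zonal means equal the naive per-unit oracle", {
  g <- gridSpec(4, 4)
  lab <- matrix(c(1L, 1L, 2L, 2L,
                  1L, 1L, 2L, 2L,
                  0L, 0L, 2L, 2L,
                  0L, 0L, 2L, 2L), 4, 4, byrow = TRUE)
  units <- buildEvaluationUnits(
    categoricalLayer(g, ifelse(lab > 0, 1L, 2L),
                     c("1" = "farmland", "2" = "other")),
    categoricalLayer(g, lab + 1L,
                     c("1" = "s0", "2" = "s1", "3" = "s2")),
    constantCat(g, c("1" = "r")), minAreaHm2 = 0)
  # constant layer: every unit mean is the constant
  z <- zonalMean(indicatorLayer(g, matrix(0.7, 4, 4)), units)
  expect_equal(unname(z), rep(0.7, length(z)))
  # two-cell unit mean
  g2 <- gridSpec(1, 2)
  u2 <- buildEvaluationUnits(constantCat(g2, c("1" = "farmland")),
                             constantCat(g2, c("1" = "s")),
                             constantCat(g2, c("1" = "r")), minAreaHm2 = 0)
  expect_equal(unname(zonalMean(indicatorLayer(g2, matrix(c(0.2, 0.4), 1, 2)),
                                u2)), 0.3)
  # random layers vs looped oracle, nodata included
  set.seed(23)
  for (rep in 1:5) {
    land <- generateLandscape(landscapeConfig(nrows = 20, ncols = 20),
                              seed = rep)
    vals <- matrix(runif(400), 20, 20)
    vals[sample(400, 25)] <- NA
    lay <- indicatorLayer(gridOf(land$units), vals)
    suppressWarnings(got <- zonalMean(lay, land$units))
    want <- naiveZonalMean(vals, unitLabels(land$units),
                           unitTable(land$units)$unit_id)
    expect_equal(got, want)
  }
})

test_that("quality index is the weighted score sum, with strict inputs", {
  sc <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE,
               dimnames = list(c("1", "2"), c("A", "B")))
  expect_equal(unname(computeIFI(sc, c(A = 0.5, B = 0.5))), c(0.5, 0.5))
  w <- refWeights()
  ones <- matrix(1, 3, 16, dimnames = list(1:3, names(w)))
  expect_equal(unname(computeIFI(ones, w)), rep(0.9999, 3))
  zeros <- ones * 0
  expect_equal(unname(computeIFI(zeros, w)), rep(0, 3))
  expect_error(computeIFI(ones[, 1:15], w), "I16")
  nas <- ones; nas[2, 3] <- NA
  expect_error(computeIFI(nas, w), "NA")
})

test_that("quality index stays within [0, sum of weights] on random scores", {
  set.seed(29)
  w <- refWeights()
  sc <- matrix(runif(50 * 16), 50, 16, dimnames = list(1:50, names(w)))
  ifi <- computeIFI(sc, w)
  expect_true(all(ifi >= 0 & ifi <= sum(w)))
})

test_that("natural breaks separate well-separated clusters and handle k = 1", {
  sch <- jenksBreaks(c(1, 2, 3, 100, 101, 102), k = 2)
  g <- classifyGrades(c(1, 2, 3, 100, 101, 102), sch)
  expect_identical(as.character(g), c("II", "II", "II", "I", "I", "I"))
  sch1 <- jenksBreaks(c(1, 5, 9), k = 1)
  expect_equal(gradeBounds(sch1)$lower, 1)
  expect_equal(gradeBounds(sch1)$upper, 9)
  expect_error(jenksBreaks(c(1, 1, 1, 2), k = 3), "distinct")
})

test_that("exact Jenks matches exhaustive enumeration on random instances", {
  set.seed(37)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    k <- sample(2:min(4, n - 1), 1)
    x <- round(runif(n, 0, 10), 3)
    if (length(unique(x)) < k) next
    sch <- jenksBreaks(x, k)
    got <- attr(sch, "withinSSD")
    want <- bruteForceJenksSSD(x, k)
    expect_equal(got, want, tolerance = 1e-9)
    # classifying with the scheme realises the optimal objective
    part <- classifyGrades(x, sch)
    ssd <- sum(tapply(x, part, function(v) sum((v - mean(v))^2)),
               na.rm = TRUE)
    expect_equal(ssd, want, tolerance = 1e-9)
  }
})

test_that("Jenks beats equal-interval classification on its own objective", {
  set.seed(41)
  x <- c(rnorm(60, 0.45, 0.02), rnorm(40, 0.6, 0.03), rnorm(20, 0.72, 0.01))
  x <- pmin(pmax(x, 0), 1)
  k <- 5
  sch <- jenksBreaks(x, k)
  jen <- attr(sch, "withinSSD")
  cuts <- seq(min(x), max(x), length.out = k + 1)
  eq <- cut(x, cuts, include.lowest = TRUE)
  eqSSD <- sum(tapply(x, eq, function(v) sum((v - mean(v))^2)), na.rm = TRUE)
  expect_lte(jen, eqSSD + 1e-12)
})

test_that("classification honours the published thresholds and boundary rules", {
  sch <- refGradeScheme("canonical")
  expect_identical(as.character(classifyGrades(0.70, sch)), "I")
  expect_identical(as.character(classifyGrades(0.7499, sch)), "I")  # top-inclusive
  expect_identical(as.character(classifyGrades(0.6477, sch)), "I")  # lower bound closed
  expect_identical(as.character(classifyGrades(0.6476, sch)), "II")
  expect_identical(as.character(classifyGrades(0.3962, sch)), "V")
  expect_warning(out <- classifyGrades(c(0.2, 0.9), sch), "ungraded")
  expect_true(all(is.na(out)))
  # the alternate printed threshold set is a distinct fixture
  alt <- refGradeScheme("alternate")
  expect_identical(as.character(classifyGrades(0.60, alt)), "II")
  expect_identical(as.character(classifyGrades(0.60, sch)), "III")
})

test_that("higher index values never map to worse grades", {
  set.seed(43)
  x <- runif(300, 0.3, 0.75)
  sch <- jenksBreaks(x, 5)
  grades <- classifyGrades(x, sch)
  gi <- as.integer(grades)  # 1 = best
  o <- order(x, decreasing = TRUE)
  expect_true(all(diff(gi[o]) >= 0))
})

test_that("area tabulation is exact, complete and double-marginal consistent", {
  # two one-hectare units in grades I and V
  areas <- data.frame(unit_id = 1:2, region_id = 1L, soil_id = 1L,
                      landuse_id = 1L, n_cells = c(100L, 100L),
                      area_hm2 = c(1, 1))
  g <- gridSpec(10, 20)
  lab <- cbind(matrix(1L, 10, 10), matrix(2L, 10, 10))
  um <- new("UnitMap", grid = gridSpec(10, 20, cellSize = 10),
            labels = lab, units = areas)
  grades <- factor(c("I", "V"), levels = c("I", "II", "III", "IV", "V"))
  names(grades) <- c("1", "2")
  tab <- tabulateAreas(grades, um)
  expect_equal(unname(tab["1", ]), c(1, 0, 0, 0, 1))
  expect_equal(sum(tab), 2)
  # ungraded units are an error, not a silent drop
  expect_error(tabulateAreas(factor(c("I", NA), levels = levels(grades)),
                             um), "ungraded")
  # synthetic landscape: region totals and grade totals tie out exactly
  land <- generateLandscape(landscapeConfig(nrows = 40, ncols = 40), seed = 3)
  ifi <- runif(nrow(unitTable(land$units)), 0.3, 0.8)
  names(ifi) <- unitTable(land$units)$unit_id
  sch <- jenksBreaks(ifi, 3)
  gr <- classifyGrades(ifi, sch)
  tab2 <- tabulateAreas(gr, land$units)
  farm <- sum(unitTable(land$units)$area_hm2)
  expect_equal(sum(rowSums(tab2)), farm, tolerance = 1e-6)
  expect_equal(sum(colSums(tab2)), farm, tolerance = 1e-6)
})
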