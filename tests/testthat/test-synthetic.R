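test_that("generated fields hit their bounds exactly and are reproducible", {
  g <- gridSpec(50, 50)
  f <- generateField(g, lo = 0, hi = 28.0476, corrLength = 300, seed = 1)
  v <- layerValues(f)
  expect_equal(min(v), 0, tolerance = 1e-12)
  expect_equal(max(v), 28.0476, tolerance = 1e-12)
  # bit-identical regeneration
  f2 <- generateField(g, 0, 28.0476, corrLength = 300, seed = 1)
  expect_identical(layerValues(f2), v)
  # a different seed gives a different field
  f3 <- generateField(g, 0, 28.0476, corrLength = 300, seed = 2)
  expect_false(identical(layerValues(f3), v))
  # corrLength = 0: rescaled white noise, bounds still exact
  f0 <- generateField(g, -2, 3, corrLength = 0, seed = 7)
  expect_equal(range(layerValues(f0)), c(-2, 3), tolerance = 1e-12)
  # smoothing reduces cell-to-cell roughness relative to white noise
  rough <- function(m) mean(abs(diff(m)))
  expect_lt(rough(layerValues(f) / 28.0476), rough((layerValues(f0) + 2) / 5))
})

test_that("field generation rejects bad arguments", {
  g <- gridSpec(5, 5)
  expect_error(generateField(g, lo = 1, hi = 1, seed = 1), "lo must be < hi")
  expect_error(generateField(g, lo = 2, hi = 1, seed = 1), "lo must be < hi")
  expect_error(generateField(g, 0, 1, corrLength = -5, seed = 1), "corrLength")
  expect_error(gridSpec(0, 10), "nrows")
})

test_that("categorical patch maps respect the legend and the seed contract", {
  g <- gridSpec(40, 40)
  topo <- refConceptualScales()[["I1"]]@categories  # 7 classes
  m <- generateCategorical(g, topo, patchScale = 300, seed = 3)
  ids <- unique(as.vector(layerValues(m)))
  expect_true(all(ids %in% 1:7))
  expect_identical(sort(names(classLegend(m))), sort(as.character(1:7)))
  # legend of size 1: constant layer
  one <- generateCategorical(g, "only", seed = 5)
  expect_true(all(layerValues(one) == 1L))
  # different seeds, same legend, different maps
  m2 <- generateCategorical(g, topo, patchScale = 300, seed = 4)
  expect_identical(classLegend(m2), classLegend(m))
  expect_false(identical(layerValues(m2), layerValues(m)))
  expect_error(generateCategorical(g, character(0), seed = 1), "legend")
})

test_that("distance transform is exact against the brute-force oracle", {
  # fixed small cases
  g <- gridSpec(5, 5)
  cls <- matrix(1L, 5, 5)
  cls[3, 3] <- 2L
  lay <- categoricalLayer(g, cls, c("1" = "bg", "2" = "target"))
  d <- layerValues(distanceTransform(lay, 2L))
  expect_identical(d[3, 3], 0)         # on the target
  expect_identical(d[3, 4], 30)        # 4-neighbour, one 30 m cell away
  expect_identical(d[2, 2], 30 * sqrt(2))
  # randomised grids vs all-pairs minimum
  set.seed(11)
  for (rep in 1:8) {
    nr <- sample(3:15, 1); nc <- sample(3:15, 1)
    gg <- gridSpec(nr, nc)
    m <- matrix(sample(c(1L, 2L), nr * nc, replace = TRUE,
                       prob = c(0.85, 0.15)), nr, nc)
    if (!any(m == 2L)) m[1, 1] <- 2L
    lay <- categoricalLayer(gg, m, c("1" = "bg", "2" = "t"))
    got <- layerValues(distanceTransform(lay, 2L))
    want <- bruteForceEDT(m == 2L) * 30
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(distanceTransform(lay, 99L), "does not occur")
})

test_that("buffer rings follow the half-open 500 m intervals and saturate", {
  g <- gridSpec(1, 5)
  d <- indicatorLayer(g, matrix(c(0, 499.9, 500, 2400, 10000), 1, 5))
  r <- ringClassify(d, ringWidth = 500, nRings = 5)
  expect_identical(as.vector(layerValues(r)), c(1L, 1L, 2L, 5L, 5L))
  expect_identical(unname(classLegend(r)[1]), "Closer")
  expect_identical(unname(classLegend(r)[5]), "Farther")
  bad <- indicatorLayer(g, matrix(-1, 1, 5))
  expect_error(ringClassify(bad), ">= 0")
})

test_that("overlay units: constants give one unit, a split gives two", {
  g <- gridSpec(6, 6)
  lu <- constantCat(g, c("1" = "farmland"))
  so <- constantCat(g, c("1" = "soil_a"))
  ad <- constantCat(g, c("1" = "region_a"))
  um <- buildEvaluationUnits(lu, so, ad, minAreaHm2 = 0)
  expect_identical(nrow(unitTable(um)), 1L)
  expect_equal(unitTable(um)$area_hm2, 36 * 0.09)
  # split admin into two halves
  adm <- matrix(1L, 6, 6); adm[, 4:6] <- 2L
  ad2 <- categoricalLayer(g, adm, c("1" = "west", "2" = "east"))
  um2 <- buildEvaluationUnits(lu, so, ad2, minAreaHm2 = 0)
  expect_identical(nrow(unitTable(um2)), 2L)
  expect_equal(sum(unitTable(um2)$area_hm2), 36 * 0.09)
  expect_setequal(unitTable(um2)$region_id, c(1L, 2L))
})

test_that("overlay component count matches the flood-fill oracle", {
  set.seed(21)
  for (rep in 1:5) {
    g <- gridSpec(20, 20)
    lu <- matrix(sample(1:2, 400, replace = TRUE), 20, 20)
    so <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
    ad <- matrix(sample(1:2, 400, replace = TRUE), 20, 20)
    luL <- categoricalLayer(g, lu, c("1" = "farmland", "2" = "other"))
    soL <- categoricalLayer(g, so, c("1" = "a", "2" = "b", "3" = "c"))
    adL <- categoricalLayer(g, ad, c("1" = "w", "2" = "e"))
    um <- buildEvaluationUnits(luL, soL, adL, minAreaHm2 = 0)
    want <- floodFillComponents(lu, so, ad, lu == 1L)
    expect_identical(nrow(unitTable(um)), want)
    # exact area conservation over farmland cells
    expect_equal(sum(unitTable(um)$n_cells), sum(lu == 1L))
  }
})

test_that("sliver merging conserves area and removes sub-threshold units", {
  set.seed(31)
  g <- gridSpec(20, 20)
  lu <- matrix(sample(1:2, 400, replace = TRUE, prob = c(0.7, 0.3)), 20, 20)
  so <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
  ad <- matrix(1L, 20, 20)
  luL <- categoricalLayer(g, lu, c("1" = "farmland", "2" = "other"))
  soL <- categoricalLayer(g, so, c("1" = "a", "2" = "b", "3" = "c"))
  adL <- categoricalLayer(g, ad, c("1" = "r"))
  um0 <- buildEvaluationUnits(luL, soL, adL, minAreaHm2 = 0)
  um <- buildEvaluationUnits(luL, soL, adL, minAreaHm2 = 0.36)
  expect_lte(nrow(unitTable(um)), nrow(unitTable(um0)))
  expect_equal(sum(unitTable(um)$area_hm2), sum(unitTable(um0)$area_hm2))
  # surviving sub-threshold units (if any) must be isolated farmland islands
  small <- unitTable(um)[unitTable(um)$n_cells < 4, ]
  if (nrow(small)) {
    lab <- unitLabels(um)
    for (id in small$unit_id) {
      cells <- which(lab == id, arr.ind = TRUE)
      nb <- integer(0)
      for (kk in seq_len(nrow(cells))) {
        i <- cells[kk, 1]; j <- cells[kk, 2]
        if (i > 1) nb <- c(nb, lab[i - 1, j])
        if (i < 20) nb <- c(nb, lab[i + 1, j])
        if (j > 1) nb <- c(nb, lab[i, j - 1])
        if (j < 20) nb <- c(nb, lab[i, j + 1])
      }
      expect_identical(setdiff(unique(nb), c(0L, id)), integer(0))
    }
  }
  expect_error(
    buildEvaluationUnits(luL, soL,
                         constantCat(gridSpec(5, 5), c("1" = "r"))),
    "grid mismatch")
})

test_that("landscape bundles are deterministic and span the configured ranges", {
  cfg <- landscapeConfig(nrows = 30, ncols = 30)
  land <- generateLandscape(cfg, seed = 42)
  land2 <- generateLandscape(cfg, seed = 42)
  expect_identical(lapply(land$indicators, layerValues),
                   lapply(land2$indicators, layerValues))
  expect_identical(unitTable(land$units), unitTable(land2$units))
  # every continuous indicator spans its configured (membership-domain) range
  specs <- refMembershipSpecs()
  for (id in names(specs)) {
    rg <- range(layerValues(land$indicators[[id]]))
    expect_equal(rg, c(specs[[id]]@uLo, specs[[id]]@uHi), tolerance = 1e-9)
  }
  expect_equal(range(layerValues(land$temperature)), c(15, 17),
               tolerance = 1e-9)
  expect_equal(range(layerValues(land$precipitation)), c(900, 1100),
               tolerance = 1e-9)
  # unit areas are cell counts times the 0.09 hm2 cell area, exactly
  u <- unitTable(land$units)
  expect_identical(u$area_hm2, u$n_cells * 0.09)
  expect_equal(sum(u$n_cells), sum(layerValues(land$landuse) == 1L))
})

test_that("a 1 x 1 landscape degenerates to one farmland cell and one unit", {
  land <- generateLandscape(landscapeConfig(nrows = 1, ncols = 1), seed = 9)
  expect_identical(nrow(unitTable(land$units)), 1L)
  for (id in names(land$indicators))
    expect_identical(dim(layerValues(land$indicators[[id]])), c(1L, 1L))
})
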