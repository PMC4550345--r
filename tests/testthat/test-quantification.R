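test_that("ellipse membership matches hand-derived pixel sets", {
  shape <- c(30, 30)
  one <- ellipsePixels(c(10, 10), c(0.5, 0.5), shape)
  expect_identical(nrow(one), 1L)
  expect_identical(unname(one[1, ]), c(10L, 10L))

  seven <- ellipsePixels(c(10, 10), c(2, 1), shape)
  expect_identical(nrow(seven), 7L)
  want <- rbind(c(10, 9), c(8, 10), c(9, 10), c(10, 10), c(11, 10),
                c(12, 10), c(10, 11))
  expect_identical(unname(seven), matrix(as.integer(want), ncol = 2))

  circle <- ellipsePixels(c(15, 15), c(5, 5), shape)
  expect_lt(abs(nrow(circle) - pi * 25), 4.5)
  expect_error(ellipsePixels(c(500, 500), c(3, 3), shape), "ROI outside image",
               class = "microspotGeometryError")
})

test_that("ellipse membership equals the exhaustive scan oracle", {
  set.seed(5)
  for (i in 1:20) {
    ctr <- runif(2, 5, 58)
    ax <- runif(2, 0.7, 9)
    got <- ellipsePixels(ctr, ax, c(64, 64))
    oracle <- ellipseScanOracle(ctr, ax, 64, 64)
    expect_identical(unname(got),
                     matrix(as.integer(oracle[order(oracle[, 2],
                                                    oracle[, 1]), ]),
                            ncol = 2))
  }
})

test_that("spot medians are robust to outliers and match a sort oracle", {
  img <- matrix(100, 40, 40)
  m <- measureSpot(img, c(20, 20), c(5, 4))
  expect_equal(m$median, 100)

  img3 <- matrix(0, 5, 5)
  img3[1, 1:3] <- c(10, 20, 200)
  expect_equal(measureSpot(img3, c(1, 0), c(1.4, 0.4))$median, 20)

  # 40% saturated pixels leave the median at the base level
  set.seed(6)
  img2 <- matrix(80, 40, 40)
  px <- ellipsePixels(c(20, 20), c(6, 5), dim(img2))
  sat <- px[sample(nrow(px), round(0.4 * nrow(px))), , drop = FALSE]
  img2[cbind(sat[, "y"] + 1, sat[, "x"] + 1)] <- 255
  expect_equal(measureSpot(img2, c(20, 20), c(6, 5))$median, 80)

  vals <- img2[cbind(px[, "y"] + 1, px[, "x"] + 1)]
  expect_equal(measureSpot(img2, c(20, 20), c(6, 5))$median, sortMedian(vals))
})

test_that("measureGrid reports one measurement per layout position", {
  layout <- buildDefaultLayout()
  img <- matrix(0, standardShape(layout)[1], standardShape(layout)[2])
  meas <- measureGrid(img, layout)
  expect_identical(nrow(meas), 48L)
  expect_true(all(meas$median == 0))

  spec <- cleanSpec(layout = buildDefaultLayout(), seed = 12L)
  scn <- renderScene(spec)
  std <- matrix(0, standardShape(layout)[1], standardShape(layout)[2])
  # identity-aberration scene: reference geometry is the image geometry up
  # to the canvas offset, so standardize and measure end to end
  res <- analyzeChip(scn$gray, layout)
  meas2 <- spotMeasurements(res)
  amp <- spec@amplitudes[meas2$role] + 20  # base background
  expect_lt(max(abs(meas2$median - amp)), 2)

  tiny <- matrix(0, 20, 20)
  expect_error(measureGrid(tiny, layout), "grid position",
               class = "microspotGeometryError")
})

test_that("role aggregation uses inner spots, sample SD and role checks", {
  layout <- buildDefaultLayout()
  refs <- referenceCentroids(layout)
  meas <- data.frame(refs, nPixels = 10L, median = 50)
  meas$median[meas$role == "RBST"] <- c(1, 2, 3, 1, 2, 3)
  agg <- aggregateRoles(meas, layout)
  expect_identical(agg$n[agg$role == "RBST"], 6L)
  expect_identical(agg$n[agg$role == "POS"], 3L)
  expect_identical(agg$n[agg$role == "NEG"], 3L)
  expect_equal(agg$mean[agg$role == "RBST"], 2)
  expect_equal(agg$sd[agg$role == "RBST"], sd(c(1, 2, 3, 1, 2, 3)))

  aggAll <- aggregateRoles(meas, layout, innerOnly = FALSE)
  expect_identical(aggAll$n[aggAll$role == "POS"], 15L)

  # textbook mean/sd and the n = 1 convention
  v <- data.frame(row = 1, col = 1:3, role = "RBST", x = 0, y = 0,
                  nPixels = 5L, median = c(1, 2, 3))
  one <- aggregateRoles(v, layout, innerOnly = FALSE)
  expect_equal(one$mean[one$role == "RBST"], 2)
  expect_equal(one$sd[one$role == "RBST"], 1)
  single <- aggregateRoles(v[1, ], layout, innerOnly = FALSE)
  expect_identical(single$sd, 0)

  # a role entirely outside the scope is an error
  onlyRing <- meas[!(paste(meas$row, meas$col) %in%
                     paste(innerPositions(layout)$row,
                           innerPositions(layout)$col)), ]
  expect_error(aggregateRoles(onlyRing, layout, innerOnly = TRUE),
               "absent", class = "microspotQCError")
})

test_that("normalization maps POS to 1, NEG to 0 and scales linearly", {
  agg <- data.frame(role = c("RBST", "POS", "NEG"),
                    mean = c(5, 9, 1), sd = 0, n = 3L)
  n <- normalizeChip(agg)
  expect_equal(unname(n$normalized["RBST"]), 0.5)
  expect_equal(unname(n$normalized["POS"]), 1)
  expect_equal(unname(n$normalized["NEG"]), 0)
  expect_equal(n$qc$posMinusNeg, 8)

  aggEq <- agg; aggEq$mean[1] <- 9
  expect_equal(unname(normalizeChip(aggEq)$normalized["RBST"]), 1)
  aggBg <- agg; aggBg$mean[1] <- 1
  expect_equal(unname(normalizeChip(aggBg)$normalized["RBST"]), 0)

  bad <- agg; bad$mean[2] <- 0.5
  expect_error(normalizeChip(bad), "positive control not above background",
               class = "microspotQCError")
})

test_that("normalization is invariant to gain and offset to 1e-9", {
  set.seed(13)
  for (i in 1:10) {
    means <- c(runif(3, 10, 150), runif(1, 160, 250), runif(1, 1, 9))
    agg <- data.frame(role = c(biomarkerRoles(), "POS", "NEG"),
                      mean = means, sd = 0, n = 3L)
    base <- normalizeChip(agg)$normalized
    g <- runif(1, 0.2, 5); o <- runif(1, -20, 50)
    agg2 <- agg; agg2$mean <- g * agg2$mean + o
    expect_equal(normalizeChip(agg2)$normalized, base, tolerance = 1e-9)
  }
})

test_that("replicate averaging follows the 3-decimal half-away-from-zero rule", {
  expect_identical(combineRuns(c(0.766, 0.658)), 0.712)
  expect_identical(combineRuns(c(0.004, -0.007)), -0.002)
  expect_identical(combineRuns(c(0.019, 0.018)), 0.019)
  expect_identical(combineRuns(c(0.381, 0.252)), 0.317)
  expect_identical(combineRuns(0.42), 0.42)
  expect_error(combineRuns(numeric()), class = "microspotConfigError")

  expect_identical(roundHalfOut(-0.0015), -0.002)
  expect_identical(roundHalfOut(0.0185), 0.019)
  expect_identical(roundHalfOut(0.0025), 0.003)
})
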